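#!/usr/bin/env Rscript
# Generate the synthetic study genome: 50 genes on one chromosome, 20%
# planted hybrid attenuators (pA/Hrp1 at 3x the reference, Nrd1/Nab3
# depleted), 10% NNS attenuators including the NRD1LIKE reference, the
# rest highly transcribed non-attenuated genes. Emits both a noise-free
# genome (for exact checks) and a lognormal cv = 0.2 / Poisson-count
# genome (the realistic screen input), in bedGraph/BED/TSV form.

library(attenscan)

out <- "results/simulated_genome"
cfg_clean <- simulation_config(n_genes = 50, seed = 20260928)
cfg_noisy <- simulation_config(n_genes = 50, seed = 20260928,
                               noise = "lognormal", cv = 0.2)

sim_clean <- simulate_genome(cfg_clean)
sim_noisy <- simulate_genome(cfg_noisy)
write_simulation(sim_clean, file.path(out, "clean"))
write_simulation(sim_noisy, file.path(out, "noisy"))

classes <- table(sim_clean$truth$class)
cat("Simulated", sum(classes), "genes:\n")
print(classes)
cat("Reference attenuator:",
    sim_clean$truth$gene_id[sim_clean$truth$class == "nns_attenuated"][1], "\n")
cat("Planted reference-relative enrichment (R) by class:\n")
print(unique(sim_clean$truth[, c("class", "R_pA", "R_Hrp1", "R_Nrd1", "R_Nab3")]))
cat("Tracks written under", out, "\n")
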