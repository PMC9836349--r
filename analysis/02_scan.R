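#!/usr/bin/env Rscript
# Screen the simulated genome for attenuator candidates: peak enrichment
# of pA sites and Hrp1/Nrd1/Nab3 occupancy in each gene's promoter-
# proximal window (TSS -100/+300 bp), normalized to the local Pol II peak
# and then to the NRD1LIKE reference attenuator; 3-category binning
# (<=0.67 low, <=1.5 intermediate, >1.5 high); candidates require pA and
# Hrp1 R > 1.5 with both Nrd1 and Nab3 R <= 0.67. Run 01_simulate.R first.

library(attenscan)

indir <- "results/simulated_genome/noisy"
stopifnot(dir.exists(indir))
out <- "results/scan"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- load_annotation(file.path(indir, "annotation.tsv"))
tracks <- sapply(c("PolII", "Hrp1", "Nrd1", "Nab3"), function(f)
  load_signal_track(file.path(indir, paste0(f, ".bedGraph"))),
  simplify = FALSE)
pa <- load_sites(file.path(indir, "pA.bed"))

ht <- build_heatmap(genes, tracks, list(pA = pa))
cand <- select_candidates(ht)
write_heatmap_table(ht, file.path(out, "heatmap.tsv"))
write.table(cand, file.path(out, "candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ggplot2::ggsave(file.path(out, "heatmap.pdf"), plot_heatmap(ht),
                width = 6, height = 9)

truth <- read.delim(file.path(indir, "truth.tsv"))
hyb <- truth$gene_id[truth$class == "hybrid_attenuated"]
cat(nrow(cand), "candidate attenuators selected;",
    sum(cand$gene_id %in% hyb), "of", length(hyb),
    "planted hybrid attenuators recovered,",
    sum(!cand$gene_id %in% hyb), "false positives.\n")

# attenuation signature 1: Pol II 5' accumulation vs ORF body
ann <- as.data.frame(genes)
travel <- vapply(seq_len(nrow(ann)), function(i)
  pol2_travel_ratio(tracks$PolII, genes[i, ]), numeric(1))
tr_tab <- data.frame(gene_id = ann$gene_id,
                     class = truth$class[match(ann$gene_id, truth$gene_id)],
                     travel_ratio = travel)
write.table(tr_tab, file.path(out, "travel_ratio.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Median Pol II travel ratio by class:\n")
print(tapply(tr_tab$travel_ratio, tr_tab$class, median))
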