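# attenscan

Genome-wide screening and quantification of RNA polymerase II attenuators
in *Saccharomyces cerevisiae*.

Attenuation — premature Pol II termination near a gene's 5′ end — represses
mRNA synthesis at 10–15% of yeast genes, through the Nrd1–Nab3–Sen1 (NNS)
pathway or a "hybrid" pathway built on cleavage-factor components such as
the RNA-binding protein Hrp1. Hybrid-attenuated genes leave a recognizable
footprint in occupancy data: a 5′ Pol II peak with a depleted ORF body,
promoter-proximal polyadenylation (pA) sites, and an upstream Hrp1 peak
with little Nrd1/Nab3. `attenscan` is for researchers who want to turn
that footprint into a reproducible candidate screen and to quantify the
downstream validation assays (lacZ terminator reporters, growth kinetics)
with the same conventions.

## The score

For each gene *g* and factor *f* ∈ {pA, Hrp1, Nrd1, Nab3, PolII}, with
*p*<sub>*g,f*</sub> the peak height (window maximum) of *f* in *g*'s
promoter-proximal window (TSS −100/+300 bp by default):

    r(g,f) = p(g,f) / p(g,PolII)          Pol II-normalized enrichment
    R(g,f) = r(g,f) / r(ref,f)            relative to a reference NNS attenuator

*R* is binned low (≤ 0.67), intermediate (≤ 1.5) or high (> 1.5), and a
gene is a hybrid-attenuator candidate when R > 1.5 for **both** pA and
Hrp1 while R ≤ 0.67 for **both** Nrd1 and Nab3. The Pol II travel ratio
(5′-window mean over ORF-body mean) quantifies signature 1 independently.

Reporter assays are scored as activity = slope<sub>OD420</sub> /
(0.1 ml × OD600) from the linear reaction window of a 60-min kinetic
trace; terminator strength is the percent decrease versus a no-terminator
control (red > 90%, yellow > 50%, green otherwise); doubling times come
from log-space least squares over 60–360 min, t_d = ln 2 / slope.

## Worked example

```r
library(attenscan)

sim <- simulate_genome(simulation_config(n_genes = 50, seed = 20260928,
                                         noise = "lognormal", cv = 0.2))
ht   <- build_heatmap(sim$annotation, sim$tracks, sim$sites["pA"])
cand <- select_candidates(ht)
nrow(cand)
#> [1] 10
head(cand, 3)
#>    gene_id min_enrich_R
#> 1 SYNG0014     3.481293
#> 2 SYNG0001     3.472622
#> 3 SYNG0042     3.382074
```

All 10 selected genes are the 10 planted hybrid attenuators (the
simulator's `truth` table carries the labels); `NRD1LIKE`, the reference,
scores R = 1 in every column. The same objects can be written to
bedGraph/BED/TSV with `write_simulation()` and read back bit-identically
with `load_signal_track()` / `load_sites()` / `load_annotation()`.

The numbered scripts under `analysis/` run the full study end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # genomes with planted ground truth
Rscript analysis/02_scan.R       # heatmap, candidates, travel ratios
Rscript analysis/03_reporter.R   # kinetic slopes, activities, terminator classes
Rscript analysis/04_growth.R     # doubling times, percent change, Welch stars
```

`02_scan.R` reports, on the noisy genome: `10 candidate attenuators
selected; 10 of 10 planted hybrid attenuators recovered, 0 false
positives`, with median travel ratios ≈ 4 for attenuated classes versus
0.6 for non-attenuated genes. `04_growth.R` recovers a planted 30% growth
defect as `Mean slowdown: 28.5%` with Welch p = 1.2e-05 (\*\*\*\*).

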