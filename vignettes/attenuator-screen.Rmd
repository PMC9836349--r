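---
title: "Screening promoter-proximal occupancy for Pol II attenuators"
author: "attenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening promoter-proximal occupancy for Pol II attenuators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen

Attenuation is premature termination of RNA polymerase II near a gene's 5'
end, producing a short, usually noncoding transcript instead of full-length
mRNA. In budding yeast it proceeds either through the Nrd1--Nab3--Sen1 (NNS)
pathway or through a "hybrid" pathway that uses cleavage-factor components —
notably the RNA-binding protein Hrp1, which recognizes the AU-rich
efficiency element upstream of polyadenylation (pA) sites — together with
Sen1. Genes attenuated by the hybrid pathway leave a characteristic
footprint in genome-wide occupancy data:

1. a 5'-end peak of Pol II with depleted signal over the ORF body,
2. promoter-proximal pA sites, and
3. an upstream Hrp1 peak, with little Nrd1/Nab3.

`attenscan` turns that footprint into a quantitative screen. For each gene
$g$ and factor $f$ (pA sites, Hrp1, Nrd1, Nab3, and Pol II itself) it
computes the peak height $p_{g,f}$ — the maximum per-base occupancy (or
maximum pA read count on the gene's strand) inside the gene's
promoter-proximal window — and forms

$$ r_{g,f} = \frac{p_{g,f}}{p_{g,\mathrm{PolII}}}, \qquad
   R_{g,f} = \frac{r_{g,f}}{r_{\mathrm{ref},f}}, $$

where the reference is a model NNS-dependent attenuator gene (the
simulator always emits one, named `NRD1LIKE`). Normalizing to local Pol II
removes differences in transcription rate; normalizing to the reference
puts all factors on a common "fold versus a known attenuator" scale. Each
$R$ is binned into three categories — low ($R \le 0.67$), intermediate
($0.67 < R \le 1.5$), high ($R > 1.5$) — and a gene is called a hybrid
attenuator candidate when $R > 1.5$ for *both* pA and Hrp1 while
$R \le 0.67$ for Nrd1 and Nab3.

```{r}
library(attenscan)
sim <- simulate_genome(simulation_config(n_genes = 50, seed = 1,
                                         noise = "lognormal", cv = 0.2))
ht <- build_heatmap(sim$annotation, sim$tracks, sim$sites["pA"])
select_candidates(ht)
plot_heatmap(ht)
```

## Parameters that matter

* **Promoter-proximal window** (`upstream_bp = 100`, `downstream_bp = 300`,
  anchored at the TSS when annotated, else at the +1 ATG). "Near the 5'
  end" has no canonical extent; the default covers the span of the ten
  attenuator fragments that have been functionally cloned (which reach
  from −283 to +297 around the ATG; `fixture_attenuator_panel()` carries
  their printed coordinates). Both extents are arguments everywhere.
* **Peak height = window maximum**, not area. A peak height reads
  naturally as a maximum; `peak_height(..., method = "sum")` integrates
  over the window instead, and the same switch decides whether clustered
  pA sites are scored by their tallest site (default) or their summed
  reads. Ratios built from maxima are what the categorical bins below were
  calibrated against.
* **Bin edges 0.67 / 1.5**, each bin closed at its upper edge. The only
  strict inequality in the published convention is "> 1.5", so 0.67 is
  binned low and 1.5 intermediate. `categorize()` exposes both edges.
* **Candidate rule**: enrichment must hold for *every* enrichment factor
  and depletion for *both* NNS factors. The depletion conjunction is the
  stricter reading of "Nrd1/Nab3"; `candidate_criteria(deplete_mode =
  "any")` relaxes it. Thresholds are the bin edges and share their
  defaults.
* **Zero-division guard** `epsilon = 1e-9` signal units: sparse occupancy
  tracks can be empty over a window; ratios are floored with a warning
  rather than failing. Absolute track units cancel in $R$, so inputs may
  be raw or normalized coverage.

Coordinates are 0-based half-open throughout (bedGraph/BED native); GFF3
input is converted on load. Occupancy tracks are unstranded, pA/TSS site
tracks stranded. On the minus strand the promoter window mirrors the plus
convention, `[anchor - downstream, anchor + upstream)`.

## What the simulator emulates — and what it does not

`simulate_genome()` is the package's test bed and ships as first-class,
tested code. It lays alternating-strand genes along one linear chromosome
(lengths 1000--2000 bp, gaps 400--800 bp — wide enough that no promoter
window reaches a neighbor's signal) and plants the three signatures per
gene class:

* *hybrid attenuated* (20% by default): Pol II plateau at
  `polII_body_level x polII_5prime_fold` (20 x 4) exactly over the
  promoter window, body at 20; Hrp1 plateau and tallest pA site at 3x the
  reference's Pol II-normalized ratio; Nrd1/Nab3 at 0.2x.
* *NNS attenuated* (10%, includes the `NRD1LIKE` reference): same Pol II
  shape, Nrd1/Nab3 high (the reference profile), moderate pA/Hrp1.
* *non-attenuated*: uniformly high Pol II across the ORF (no 5' peak,
  travel ratio < 1) with pA/Hrp1 concentrated at the 3' end and only
  0.3x-reference promoter-proximal signal.

Plateau-shaped peaks laid exactly over the scoring window make every
planted ratio analytically exact with noise off: the screen then recovers
$R$ to machine precision, the Pol II travel ratio equals the planted
5':body fold, and candidate selection separates the classes perfectly —
which is what the exactness tests assert. The default planted folds (3x
enrichment, 0.3x for background genes) are free parameters of the
generator; real occupancy data carry no such calibrated ground truth.

Noise is per-base multiplicative lognormal (mean one, `cv = 0.2` by
default) on occupancy and Poisson on site counts — positive,
overdispersed, the right first-order shape for coverage data. Because the
peak statistic is a maximum over ~400 bases, per-base noise concentrates
sharply and the screen keeps sensitivity and specificity above 0.95 at
cv = 0.2.

What passing these tests does *not* show: real tracks have correlated,
peak-shaped (not plateau) signal, mappability artifacts, antisense and
neighboring-gene bleed-through, and window placement that a curator would
adjust per gene. The simulator demonstrates that the scoring chain is
correct and well-behaved, not that the default window reproduces any
published candidate list from the original GEO datasets.

## Kinetic reporter quantification

Terminator strength and readthrough are validated with kinetic lacZ
assays: OD420 read every minute for 60 min, slope taken over a window "in
a linear range with a strong R^2", and activity computed as

$$ \mathrm{activity} = \frac{\mathrm{slope}_{420}}{0.1\,\mathrm{ml} \times \mathrm{OD}_{600}}. $$

The printed activity equation is ambiguous about whether OD600 multiplies
or divides; we divide by (volume x OD600), the kinetic-kit convention.
Folds and percent-repression compare density-matched cultures, so either
reading gives the same relative results.

`fit_kinetic_slope()` operationalizes "linear range" with a lack-of-fit
criterion rather than a fixed R^2 cutoff. An absolute R^2 floor tolerates
a scale-invariant fraction of curvature, so the longest window passing a
0.98 floor systematically drags lag or plateau points in and biases the
slope low by up to ~10% on saturating traces. Instead, the noise variance
is estimated as the median regression MSE over all `min_points`-length
windows (short stretches of a kinetic trace are locally linear whatever
its shape), a window qualifies when its MSE is within `lof_mult = 2` of
that estimate, and the longest qualifying window wins (ties: higher R^2,
then earlier start). With noise off the criterion degenerates to exact
linearity — lag and plateau are excluded to the base point — and at
reading noise of 0.002 OD the recovery error stays under 5%. `r2_floor =
0.98` is retained as a diagnostic: when even the selected window fits
worse, the best short window is returned flagged `low_confidence`.
`min_points = 10` of 60 one-minute readings keeps slope variance usable
in the fallback.

Terminator strength is the percent decrease versus a no-terminator
control, clipped at 0 and classed red (> 90%), yellow (> 50%), green
(otherwise); fold-readthrough is the plain activity ratio, and the two
are consistent: percent = 100(1 − 1/fold) against the same control.

## Growth and significance conventions

Doubling times come from ordinary least squares on ln(OD600) versus time
over 60--360 min (bounds inclusive), $t_d = \ln 2 / \hat\beta$. Fitting
in log space matches a spreadsheet "exponential trendline" exactly on
noise-free data and is closed-form and scale-invariant (a multiplied OD
series only shifts the intercept). A fitted slope below $10^{-10}$ per
minute is reported as non-growing (`Inf`) rather than as an astronomical
doubling time. Strain comparisons use Welch's two-sample *t*-test (two
groups) or Welch's ANOVA (more), two-sided, with the star convention
\* p <= 0.05 through \*\*\*\* p <= 0.0001 and no multiple-testing
correction — comparisons are few and named explicitly by the caller.

## Numerical and degenerate-input choices

* bedGraph/BED writers emit 15-significant-digit decimals: a decimal of
  at most 15 digits survives decimal-to-double-to-decimal unchanged, so
  load/write round-trips are byte-stable in canonical (sorted, merged)
  form.
* Queries on chromosomes absent from a sparse track return zeros with a
  warning, never an error.
* Windows with zero OD420 variance score R^2 = 0 (no linear signal), so
  flat stretches never win on a tie.
* Residual sums of squares are accumulated from explicit residuals; the
  algebraic shortcut through $(1 - R^2)$ cancels catastrophically near
  perfect fits.
* All generators are pure functions of (config, seed); two runs with the
  same seed produce byte-identical output files.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run on 50-gene genomes (20
replicate genomes for oracle-equivalence and noisy-recovery checks), 200
simulated 60-point kinetic traces, 3-replicate growth curves, and 10,000
null draws for the Welch size check — sizes at which every brute-force
oracle (dense per-base rescoring, exhaustive all-window regression) runs
comfortably while leaving no statistical ambiguity in the pass criteria.

## Known limitations

* The default window cannot promise to reproduce any published candidate
  list from real data; the authors' per-gene browser windows were not
  recorded.
* Peak calling from raw reads, statistical testing of enrichment (the
  screen is threshold-based by design), BAM/bigWig ingestion, and
  external "pausing strength" metrics are out of scope.
* pA clustering is modeled as a fixed-size cluster with geometric count
  decay; real pA site architecture is more heterogeneous.
* The kinetic simulator's lag and plateau are piecewise-exact; enzymatic
  onset curvature in real traces is softer, which the lack-of-fit window
  handles but the tests do not separately model.
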