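toy_gene <- function(strand = "+", os = 2000, oe = 3200, tss = NA) {
  gene_annotation(data.frame(gene_id = "G1", chrom = "chrI", strand = strand,
                             orf_start = os, orf_end = oe, tss_pos = tss))[1, ]
}

test_that("promoter windows are anchored, oriented and clipped", {
  g <- toy_gene("+", os = 1000, oe = 2500)           # anchor = ATG = 1000
  w <- promoter_window(g, 100, 300)
  expect_equal(c(w$start, w$end), c(900, 1300))

  gm <- toy_gene("-", os = 100, oe = 1001)           # anchor = 1000
  wm <- promoter_window(gm, 100, 300)
  expect_equal(c(wm$start, wm$end), c(700, 1100))

  # TSS, when present, takes precedence over the ATG
  gt <- toy_gene("+", os = 1000, oe = 2500, tss = 940)
  expect_equal(promoter_window(gt, 100, 300)$start, 840)

  # clipped at chromosome start
  gc <- toy_gene("+", os = 50, oe = 700)
  expect_equal(promoter_window(gc, 100, 300)$start, 0)
  expect_error(promoter_window(g, 0, 0))
})

test_that("peak height is the window maximum for signal and stranded sites", {
  tr <- signal_track(data.frame(chrom = "chrI", start = c(10, 20, 30),
                                end = c(20, 30, 40), value = c(1, 9, 4)))
  w <- genomic_window("chrI", 10, 40, "+")
  expect_equal(peak_height(tr, w), 9)
  expect_equal(peak_height(tr, w, method = "sum"), 10 * (1 + 9 + 4))
  expect_equal(peak_height(signal_track(data.frame(chrom = "chrI", start = 0,
                                                   end = 100, value = 7)), w), 7)
  expect_equal(peak_height(tr, genomic_window("chrI", 500, 600)), 0)

  st <- site_track(data.frame(chrom = "chrI", pos = c(15, 25, 35),
                              strand = c("+", "+", "-"), count = c(12, 30, 99)))
  expect_equal(peak_height(st, w), 30)               # strand-matched max
  expect_equal(peak_height(st, w, method = "sum"), 42)
  expect_equal(peak_height(st, genomic_window("chrI", 10, 40, "-")), 99)
  expect_equal(peak_height(st, genomic_window("chrII", 10, 40, "+")), 0)
})

test_that("Pol II normalization and reference normalization follow the contract", {
  expect_equal(normalized_enrichment(30, 10), 3)
  expect_equal(normalized_enrichment(10, 10), 1)     # self-normalization
  expect_warning(r0 <- normalized_enrichment(5, 0, epsilon = 1), "epsilon")
  expect_equal(r0, 5)

  r <- c(A = 3, B = 1, NRD1LIKE = 2)
  R <- reference_normalize(r, "NRD1LIKE")
  expect_equal(unname(R[c("A", "B")]), c(1.5, 0.5))
  expect_identical(R[["NRD1LIKE"]], 1)
  expect_error(reference_normalize(c(A = 1), "NRD1LIKE", "Hrp1"), "Hrp1")
  expect_error(reference_normalize(c(A = 1, NRD1LIKE = 0), "NRD1LIKE", "pA"),
               "zero pA")
})

test_that("category bins match the printed edges and boundary convention", {
  expect_equal(categorize(c(0.5, 1.0, 1.6)), c("low", "intermediate", "high"))
  expect_equal(categorize(0.67), "low")              # closed upper edge
  expect_equal(categorize(1.5), "intermediate")
  expect_equal(categorize(0), "low")
  expect_error(categorize(-0.1), "R must")
  # dense grid against a direct restatement of the rule
  grid <- c(seq(0, 3, by = 0.01), 0.67, 1.5, 0.67 + 1e-12, 1.5 + 1e-12)
  expected <- ifelse(grid <= 0.67, "low", ifelse(grid <= 1.5, "intermediate", "high"))
  expect_equal(categorize(grid), expected)
})

test_that("candidate selection applies enrichment and depletion rules", {
  mk_table <- function(df) {
    tab <- df
    class(tab) <- c("heatmap_table", "data.frame")
    attr(tab, "criteria") <- candidate_criteria()
    tab
  }
  long <- function(gene, pA, Hrp1, Nrd1, Nab3)
    data.frame(gene_id = gene, factor = c("pA", "Hrp1", "Nrd1", "Nab3"),
               R = c(pA, Hrp1, Nrd1, Nab3), stringsAsFactors = FALSE)
  tab <- mk_table(rbind(long("GOOD", 2, 2, 0.3, 0.3),
                        long("NODEP", 2, 2, 1.0, 0.3),
                        long("BIGGER", 4, 3, 0.1, 0.1),
                        long("WEAK", 1.2, 2, 0.3, 0.3)))
  sel <- select_candidates(tab)
  expect_equal(sel$gene_id, c("BIGGER", "GOOD"))     # ordered by min enrich R
  expect_equal(sel$min_enrich_R, c(3, 2))

  # "any" depletion mode admits NODEP (Nab3 is depleted)
  sel_any <- select_candidates(tab, candidate_criteria(deplete_mode = "any"))
  expect_true("NODEP" %in% sel_any$gene_id)

  # threshold monotonicity: tightening never adds candidates
  for (thr in c(1.6, 2.5, 3.5)) {
    tighter <- select_candidates(tab, candidate_criteria(enrich_threshold = thr))
    expect_true(all(tighter$gene_id %in% sel$gene_id))
  }
  for (dep in c(0.5, 0.2, 0.05)) {
    tighter <- select_candidates(tab, candidate_criteria(deplete_threshold = dep))
    expect_true(all(tighter$gene_id %in% sel$gene_id))
  }
  expect_error(select_candidates(tab, candidate_criteria(enrich_factors = "Xyz")),
               "absent")
  empty <- mk_table(data.frame(gene_id = character(), factor = character(),
                               R = numeric(), stringsAsFactors = FALSE))
  expect_equal(nrow(select_candidates(empty)), 0)
})

test_that("heatmap reference row is identically 1 and intermediate", {
  sim <- simulate_genome(simulation_config(n_genes = 10, seed = 5))
  ht <- build_heatmap(sim$annotation, sim$tracks, sim$sites["pA"])
  ref <- ht[ht$gene_id == "NRD1LIKE", ]
  expect_true(all(ref$R == 1))
  expect_true(all(ref$category == "intermediate"))
})

test_that("heatmap cells equal the dense per-base oracle", {
  sim <- simulate_genome(simulation_config(n_genes = 30, seed = 17,
                                           noise = "lognormal", cv = 0.3))
  ht <- build_heatmap(sim$annotation, sim$tracks, sim$sites["pA"])
  orc <- oracle_heatmap(sim)
  for (f in c("pA", "Hrp1", "Nrd1", "Nab3", "PolII")) {
    cell <- ht[ht$factor == f, ]
    expect_equal(cell$R, unname(orc$R[cell$gene_id, f]), tolerance = 1e-12)
    expect_equal(cell$category, unname(orc$category[cell$gene_id, f]))
  }
  expect_setequal(select_candidates(ht)$gene_id, orc$candidates)
})

test_that("scores are invariant to global scaling; R is invariant per-factor", {
  sim <- simulate_genome(simulation_config(n_genes = 12, seed = 9,
                                           noise = "lognormal", cv = 0.2))
  scale_track <- function(tr, c) {
    df <- as.data.frame(tr); df$value <- df$value * c; signal_track(df)
  }
  ht <- build_heatmap(sim$annotation, sim$tracks, sim$sites["pA"])

  tracks2 <- lapply(sim$tracks, scale_track, c = 7.3)
  sites2 <- sim$sites["pA"]
  sites2$pA$count <- sites2$pA$count * 7.3
  ht2 <- build_heatmap(sim$annotation, tracks2, sites2)
  expect_equal(ht2$R, ht$R, tolerance = 1e-12)
  expect_equal(ht2$category, ht$category)
  expect_equal(select_candidates(ht2), select_candidates(ht))

  # scaling one factor track scales its r but leaves R unchanged
  tracks3 <- sim$tracks
  tracks3$Hrp1 <- scale_track(tracks3$Hrp1, 4)
  ht3 <- build_heatmap(sim$annotation, tracks3, sim$sites["pA"])
  h_old <- ht[ht$factor == "Hrp1", ]; h_new <- ht3[ht3$factor == "Hrp1", ]
  expect_equal(h_new$r, 4 * h_old$r, tolerance = 1e-12)
  expect_equal(h_new$R, h_old$R, tolerance = 1e-12)
})

test_that("genome mirroring leaves the heatmap unchanged up to gene order", {
  sim <- simulate_genome(simulation_config(n_genes = 14, seed = 21))
  ht <- build_heatmap(sim$annotation, sim$tracks, sim$sites["pA"])
  mir <- mirror_sim(sim)
  htm <- build_heatmap(mir$annotation, mir$tracks, mir$sites["pA"])
  for (f in unique(ht$factor)) {
    a <- ht[ht$factor == f, ]; b <- htm[htm$factor == f, ]
    b <- b[match(a$gene_id, b$gene_id), ]
    expect_equal(b$R, a$R, tolerance = 1e-12)
    expect_equal(b$category, a$category)
  }
})

test_that("travel ratio reports 5' accumulation relative to the ORF body", {
  uni <- signal_track(data.frame(chrom = "chrI", start = 0, end = 10000, value = 6))
  g <- toy_gene("+", os = 2000, oe = 3200)
  expect_equal(pol2_travel_ratio(uni, g), 1)

  # planted 5':body fold recovered exactly, checked against a dense scan
  sim <- simulate_genome(simulation_config(n_genes = 10, seed = 2))
  hyb <- sim$truth$gene_id[sim$truth$class == "hybrid_attenuated"]
  ann <- as.data.frame(sim$annotation)
  for (gid in hyb) {
    g <- sim$annotation[ann$gene_id == gid, ]
    expect_equal(pol2_travel_ratio(sim$tracks$PolII, g), 4)
    # dense oracle for the same quantity
    len <- max(ann$orf_end) + 1000
    v <- dense_vector(sim$tracks$PolII, "chrSim", len)
    anchor <- g$tss_pos
    if (g$strand == "+") {
      w <- c(anchor - 100, anchor + 300); body <- c(w[2], g$orf_end)
    } else {
      w <- c(anchor - 300, anchor + 100); body <- c(g$orf_start, w[1])
    }
    m5 <- mean(v[(w[1] + 1):w[2]]); mb <- mean(v[(body[1] + 1):body[2]])
    expect_equal(pol2_travel_ratio(sim$tracks$PolII, g), m5 / mb, tolerance = 1e-12)
  }
  short <- toy_gene("+", os = 2000, oe = 2200)
  expect_error(pol2_travel_ratio(uni, short), "ORF length")
})
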