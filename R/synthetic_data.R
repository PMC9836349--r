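# Seeded generators for genomes, occupancy tracks, site tracks, kinetic
# reporter assays and growth curves with known ground truth. The genome
# generator plants the three attenuation signatures: a 5'-end Pol II peak
# with a depleted ORF body, a promoter-proximal pA cluster, and an upstream
# Hrp1 peak whose height relative to Pol II is controlled per gene class.

#' Default per-class factor enrichment targets
#'
#' Planted Pol II-normalized ratios (r) for each gene class and factor.
#' The NNS class carries the reference-attenuator profile (high Nrd1/Nab3,
#' moderate pA/Hrp1); hybrid attenuators are 3x the reference for pA and
#' Hrp1 and depleted for Nrd1/Nab3; non-attenuated genes are 0.3x for
#' pA/Hrp1. Reference-relative ratios R follow as r(class)/r(nns).
#'
#' @return matrix with rows `hybrid_attenuated`, `nns_attenuated`,
#'   `non_attenuated` and columns `pA`, `Hrp1`, `Nrd1`, `Nab3`.
#' @export
default_factor_enrichment <- function() {
  m <- rbind(hybrid_attenuated = c(pA = 1.5, Hrp1 = 1.5, Nrd1 = 0.2, Nab3 = 0.2),
             nns_attenuated    = c(pA = 0.5, Hrp1 = 0.5, Nrd1 = 1.0, Nab3 = 1.0),
             non_attenuated    = c(pA = 0.15, Hrp1 = 0.15, Nrd1 = 0.1, Nab3 = 0.1))
  m
}

#' Simulation configuration
#'
#' Collects every knob of the genome simulator; a config plus seed fully
#' determines the output.
#'
#' @param n_genes number of genes on the single simulated chromosome.
#' @param fraction_hybrid,fraction_nns class fractions (hybrid attenuated
#'   and NNS attenuated); the remainder is non-attenuated. At least one
#'   NNS gene is always emitted: it anchors reference normalization.
#' @param gene_length,gap `c(min, max)` bp ranges for ORF lengths and
#'   intergenic gaps (gaps are wide enough that promoter windows never
#'   reach a neighboring gene's signal).
#' @param polII_body_level Pol II occupancy over the ORF body of
#'   attenuated genes (arbitrary units).
#' @param polII_5prime_fold planted 5':body Pol II ratio of attenuated
#'   genes; non-attenuated genes carry this level uniformly over the ORF
#'   (high transcription, no 5' accumulation).
#' @param factor_enrichment class x factor matrix of planted r targets,
#'   see [default_factor_enrichment()].
#' @param pA_cluster list `(n_sites, span)`: sites per promoter-proximal
#'   pA cluster and the bp span they occupy.
#' @param tss_offset bp from TSS to the +1 ATG.
#' @param upstream_bp,downstream_bp promoter-window extents the planted
#'   peaks are laid over (must match the scan for exact recovery).
#' @param noise `"none"`, `"poisson"` (counts only) or `"lognormal"`
#'   (per-base multiplicative mean-one lognormal on occupancy plus Poisson
#'   on site counts).
#' @param cv coefficient of variation of the lognormal noise.
#' @param seed integer seed fixing all randomness.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 50, fraction_hybrid = 0.2,
                              fraction_nns = 0.1,
                              gene_length = c(1000, 2000), gap = c(400, 800),
                              polII_body_level = 20, polII_5prime_fold = 4,
                              factor_enrichment = default_factor_enrichment(),
                              pA_cluster = list(n_sites = 3, span = 60),
                              tss_offset = 60,
                              upstream_bp = 100, downstream_bp = 300,
                              noise = c("none", "poisson", "lognormal"),
                              cv = 0.2, seed = 1) {
  noise <- match.arg(noise)
  if (fraction_hybrid < 0 || fraction_nns < 0 || fraction_hybrid + fraction_nns > 1)
    stop("simulation_config: class fractions must be in [0,1] and sum to at most 1")
  stopifnot(n_genes >= 2, polII_body_level > 0, polII_5prime_fold > 0,
            gene_length[1] > downstream_bp, gap[1] >= 2 * (upstream_bp + tss_offset),
            cv >= 0, tss_offset < gene_length[1])
  if (!all(rownames(factor_enrichment) ==
           c("hybrid_attenuated", "nns_attenuated", "non_attenuated")) ||
      any(factor_enrichment < 0))
    stop("simulation_config: malformed factor_enrichment matrix")
  structure(list(n_genes = n_genes, fraction_hybrid = fraction_hybrid,
                 fraction_nns = fraction_nns, gene_length = gene_length,
                 gap = gap, polII_body_level = polII_body_level,
                 polII_5prime_fold = polII_5prime_fold,
                 factor_enrichment = factor_enrichment,
                 pA_cluster = pA_cluster, tss_offset = tss_offset,
                 upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 noise = noise, cv = cv, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a genome with planted attenuation signatures
#'
#' Lays `n_genes` genes with alternating strands along one chromosome.
#' Hybrid and NNS attenuated genes receive a plateau-shaped 5' Pol II peak
#' over the promoter-proximal window with a depleted ORF body;
#' non-attenuated genes receive uniformly high Pol II over the ORF. Factor
#' occupancy plateaus (Hrp1, Nrd1, Nab3) and the tallest pA-cluster site
#' are placed so that each gene's Pol II-normalized promoter-proximal
#' ratio equals its class's planted target exactly when noise is off.
#' Non-attenuated genes additionally concentrate pA/Hrp1 signal at the 3'
#' end. One NNS gene is always emitted as `NRD1LIKE`, the designated
#' reference for normalization.
#'
#' @param config a [simulation_config()].
#' @return list with `annotation` (gene_annotation), `tracks` (named list
#'   of signal_tracks: PolII, Hrp1, Nrd1, Nab3), `sites` (site_tracks: pA,
#'   TSS), `truth` (data.frame: gene_id, class, planted r and R per
#'   factor) and `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_h <- round(n * config$fraction_hybrid)
  n_n <- max(1, round(n * config$fraction_nns))
  n_0 <- n - n_h - n_n
  if (n_0 < 0) stop("simulate_genome: class fractions leave no room for non-attenuated genes")
  classes <- sample(c(rep("hybrid_attenuated", n_h), rep("nns_attenuated", n_n),
                      rep("non_attenuated", n_0)))
  ref_idx <- which(classes == "nns_attenuated")[1]

  chrom <- "chrSim"
  up <- config$upstream_bp; down <- config$downstream_bp
  body <- config$polII_body_level
  fold <- config$polII_5prime_fold
  peak5 <- body * fold               # Pol II peak in every promoter window
  enr <- config$factor_enrichment

  lens <- sample(seq(config$gene_length[1], config$gene_length[2]), n, replace = TRUE)
  gaps <- sample(seq(config$gap[1], config$gap[2]), n, replace = TRUE)

  ann <- vector("list", n); truth <- vector("list", n)
  polII_runs <- list(); fac_runs <- list(Hrp1 = list(), Nrd1 = list(), Nab3 = list())
  pa_rows <- list(); tss_rows <- list()

  cursor <- down + config$tss_offset + 100  # room for the first window
  for (i in seq_len(n)) {
    strand <- if (i %% 2 == 1) "+" else "-"
    os <- cursor; oe <- cursor + lens[i]
    if (strand == "+") {
      atg <- os; tss <- atg - config$tss_offset
      ws <- tss - up; we <- tss + down
    } else {
      atg <- oe - 1; tss <- atg + config$tss_offset
      ws <- tss - down; we <- tss + up
    }
    cls <- classes[i]
    gid <- if (i == ref_idx) "NRD1LIKE" else sprintf("SYNG%04d", i)

    # --- Pol II ---
    if (cls == "non_attenuated") {
      polII_runs[[length(polII_runs) + 1]] <- c(os, oe, peak5)
    } else if (strand == "+") {
      polII_runs[[length(polII_runs) + 1]] <- c(ws, we, peak5)
      polII_runs[[length(polII_runs) + 1]] <- c(we, oe, body)
    } else {
      polII_runs[[length(polII_runs) + 1]] <- c(os, ws, body)
      polII_runs[[length(polII_runs) + 1]] <- c(ws, we, peak5)
    }

    # --- RNA-binding factor plateaus over the promoter window ---
    for (f in c("Hrp1", "Nrd1", "Nab3")) {
      h <- enr[cls, f] * peak5
      if (h > 0)
        fac_runs[[f]][[length(fac_runs[[f]]) + 1]] <- c(ws, we, h)
    }
    # non-attenuated genes: pA/Hrp1 signal concentrated at the 3' end
    if (cls == "non_attenuated") {
      h3 <- 3 * enr[cls, "Hrp1"] * peak5
      if (strand == "+")
        fac_runs$Hrp1[[length(fac_runs$Hrp1) + 1]] <- c(oe - 60, oe, h3)
      else
        fac_runs$Hrp1[[length(fac_runs$Hrp1) + 1]] <- c(os, os + 60, h3)
    }

    # --- pA cluster (tallest site sets the planted peak) ---
    top <- enr[cls, "pA"] * peak5
    ncl <- config$pA_cluster$n_sites
    span <- config$pA_cluster$span
    counts <- pmax(1, round(top * 0.5 ^ (seq_len(ncl) - 1)))
    offs <- round(seq(0, span, length.out = ncl))
    base5 <- if (strand == "+") tss + 80 else tss - 80 - span
    pa_rows[[length(pa_rows) + 1]] <-
      data.frame(chrom = chrom, pos = base5 + offs,
                 name = sprintf("%s_pA5_%d", gid, seq_len(ncl)),
                 count = counts, strand = strand, stringsAsFactors = FALSE)
    if (cls == "non_attenuated") {
      pos3 <- if (strand == "+") oe - 30 + round(seq(0, span / 2, length.out = ncl))
              else os + 30 - round(seq(0, span / 2, length.out = ncl))
      pa_rows[[length(pa_rows) + 1]] <-
        data.frame(chrom = chrom, pos = pos3,
                   name = sprintf("%s_pA3_%d", gid, seq_len(ncl)),
                   count = pmax(1, counts * 3), strand = strand,
                   stringsAsFactors = FALSE)
    }
    tss_rows[[length(tss_rows) + 1]] <-
      data.frame(chrom = chrom, pos = tss, name = paste0(gid, "_TSS"),
                 count = 50, strand = strand, stringsAsFactors = FALSE)

    ann[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                           orf_start = os, orf_end = oe, tss_pos = tss,
                           stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(gene_id = gid, class = cls,
                             t(enr[cls, ]), stringsAsFactors = FALSE)
    cursor <- oe + gaps[i]
  }

  runs_df <- function(lst) {
    m <- do.call(rbind, lst)
    data.frame(chrom = chrom, start = m[, 1], end = m[, 2], value = m[, 3])
  }
  track_list <- c(list(PolII = runs_df(polII_runs)),
                  lapply(fac_runs, runs_df))

  if (config$noise == "lognormal") {
    sdlog <- sqrt(log(1 + config$cv^2))
    track_list <- lapply(track_list, perbase_lognormal, sdlog = sdlog)
  }
  tracks <- lapply(track_list, signal_track)

  pa <- do.call(rbind, pa_rows)
  if (config$noise %in% c("poisson", "lognormal")) {
    pa$count <- pmax(1, stats::rpois(nrow(pa), pa$count))
  }

  annotation <- gene_annotation(do.call(rbind, ann))
  truth <- do.call(rbind, truth)
  names(truth)[3:6] <- paste0("r_", colnames(enr))
  ref_r <- unlist(truth[truth$gene_id == "NRD1LIKE", 3:6][1, ])
  for (j in seq_along(colnames(enr)))
    truth[[paste0("R_", colnames(enr)[j])]] <- truth[[2 + j]] / ref_r[j]

  list(annotation = annotation, tracks = tracks,
       sites = list(pA = site_track(pa),
                    TSS = site_track(do.call(rbind, tss_rows))),
       truth = truth, config = config)
}

# split runs into per-base runs and apply mean-one multiplicative
# lognormal noise; bases are expanded run by run to keep draws ordered
perbase_lognormal <- function(runs, sdlog) {
  if (nrow(runs) == 0) return(runs)
  widths <- runs$end - runs$start
  start <- unlist(lapply(seq_len(nrow(runs)), function(i)
    seq(runs$start[i], runs$end[i] - 1)))
  value <- rep(runs$value, widths)
  noise <- stats::rlnorm(length(value), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  data.frame(chrom = rep(runs$chrom, widths), start = start,
             end = start + 1, value = value * noise)
}

#' Write a simulated genome to disk in standard formats
#'
#' Emits exactly the formats the readers accept: `annotation.tsv`,
#' `<factor>.bedGraph` per occupancy track, `pA.bed`/`TSS.bed`,
#' `truth.tsv`, and a YAML echo of the configuration.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  for (f in names(sim$tracks))
    write_signal_track(sim$tracks[[f]], file.path(dir, paste0(f, ".bedGraph")))
  for (s in names(sim$sites))
    write_sites(sim$sites[[s]], file.path(dir, paste0(s, ".bed")))
  truth <- sim$truth
  num <- vapply(truth, is.numeric, logical(1))
  truth[num] <- lapply(truth[num], fmt_num)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$factor_enrichment <- apply(cfg$factor_enrichment, 1, as.list, simplify = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' The ten cloned attenuator fragments (ATG-relative coordinates)
#'
#' The panel of putative attenuator regions carried into the lacZ
#' terminator reporter, as closed intervals relative to the +1 ATG
#' (position +1 is the A of ATG; negative positions are upstream).
#'
#' @return data.frame with columns `gene`, `rel_start`, `rel_end`.
#' @export
fixture_attenuator_panel <- function() {
  data.frame(
    gene = c("HDA2", "MNR2", "PTI1", "RAD3", "RPN4",
             "SNG1", "SVF1", "TEC1", "UBC1", "VTS1"),
    rel_start = c(-283, -225, -201, -139, -264, -262, -234, -112, -126, -187),
    rel_end   = c(-1,    116,  195,  175,   98,  115,  117,  297,  173,   82),
    stringsAsFactors = FALSE
  )
}

#' Simulate a kinetic beta-galactosidase assay
#'
#' OD420 readings every `interval` minutes: a flat lag, a linear rise at
#' `true_slope`, and a hard plateau at `saturation_od`, plus additive
#' Gaussian noise.
#'
#' @param true_slope OD420 per minute during the linear phase (> 0).
#' @param lag_min minutes before color development starts.
#' @param saturation_od plateau absorbance (`Inf` for no saturation).
#' @param duration,interval assay length and sampling interval (minutes).
#' @param noise_sd additive Gaussian noise SD (OD420 units).
#' @param od600 density of the assayed culture.
#' @param volume_ml lysed culture volume.
#' @param seed optional integer seed.
#' @return a [kinetic_series()].
#' @export
simulate_kinetic_assay <- function(true_slope, lag_min = 0, saturation_od = Inf,
                                   duration = 60, interval = 1, noise_sd = 0,
                                   od600 = 0.3, volume_ml = 0.1, seed = NULL) {
  stopifnot(true_slope > 0, duration / interval >= 2)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = interval)
  od <- pmin(saturation_od, pmax(0, true_slope * (t - lag_min)))
  if (noise_sd > 0) od <- od + stats::rnorm(length(t), 0, noise_sd)
  kinetic_series(time = t, od420 = od, od600 = od600, volume_ml = volume_ml)
}

#' Simulate a growth curve
#'
#' OD600(t) = od0 * 2^(t / doubling_time) under multiplicative mean-one
#' lognormal noise of coefficient of variation `cv`.
#'
#' @param od0 starting density (> 0).
#' @param doubling_time_min doubling time in minutes (> 0).
#' @param duration,interval curve length and sampling interval (minutes).
#' @param cv lognormal noise CV (0 for exact).
#' @param seed optional integer seed.
#' @return data.frame with columns `time_min`, `od600`.
#' @export
simulate_growth_curve <- function(od0 = 0.15, doubling_time_min = 90,
                                  duration = 360, interval = 60, cv = 0,
                                  seed = NULL) {
  stopifnot(od0 > 0, doubling_time_min > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = interval)
  od <- od0 * 2 ^ (t / doubling_time_min)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    od <- od * stats::rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(time_min = t, od600 = od)
}
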