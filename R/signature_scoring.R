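# Promoter-proximal enrichment scoring: factor/site peak heights normalized
# to local Pol II and to a reference NNS-dependent attenuator gene, binned
# into a 3-category heatmap from which hybrid attenuator candidates are
# selected.

#' Promoter-proximal window of a gene
#'
#' The window is anchored at the TSS when annotated, otherwise at the +1
#' ATG, and extends `upstream_bp` 5' and `downstream_bp` 3' in gene
#' orientation. On the + strand the window is `[anchor - upstream_bp,
#' anchor + downstream_bp)`; on the - strand it is mirrored. Windows are
#' clipped at chromosome position 0.
#'
#' @param gene one row of a `gene_annotation` data.frame.
#' @param upstream_bp,downstream_bp nonnegative extents in bp, not both 0.
#'   Defaults (100, 300) cover the span of the ten cloned attenuator
#'   fragments around the ATG.
#' @return A [genomic_window()].
#' @export
promoter_window <- function(gene, upstream_bp = 100, downstream_bp = 300) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0, upstream_bp + downstream_bp > 0)
  anchor <- if (!is.na(gene$tss_pos)) gene$tss_pos else gene$atg_pos
  if (gene$strand == "+") {
    s <- anchor - upstream_bp; e <- anchor + downstream_bp
  } else {
    s <- anchor - downstream_bp; e <- anchor + upstream_bp
  }
  genomic_window(gene$chrom, max(0, s), e, gene$strand)
}

#' Peak height of a signal or site track in a window
#'
#' The screen's unit of promoter-proximal occupancy: for occupancy
#' (signal) tracks the maximum per-base value in the window; for stranded
#' site tracks the maximum read count among sites inside the window on the
#' window's strand. `method = "sum"` instead integrates signal over the
#' window (sum of per-base values, or of matching site counts).
#'
#' @param track a [signal_track()] or [site_track()].
#' @param window a [genomic_window()].
#' @param method `"max"` (peak height, default) or `"sum"` (area).
#' @return nonnegative scalar; 0 when the window is uncovered.
#' @export
peak_height <- function(track, window, method = c("max", "sum")) {
  method <- match.arg(method)
  if (inherits(track, "signal_track")) {
    v <- suppressWarnings(window_values(track, window))
    if (method == "max") max(v, 0) else sum(v)
  } else if (inherits(track, "site_track")) {
    hit <- track$chrom == window$chrom & track$strand == window$strand &
      track$pos >= window$start & track$pos < window$end
    counts <- track$count[hit]
    if (length(counts) == 0) 0
    else if (method == "max") max(counts) else sum(counts)
  } else {
    stop("peak_height: track must be a signal_track or site_track")
  }
}

#' Pol II normalization of a factor peak
#'
#' Divides a factor/site peak by the Pol II peak in the same window to
#' account for differences in gene transcription rate. An epsilon floor on
#' the Pol II peak guards windows with no Pol II coverage (a warning is
#' emitted when the floor engages).
#'
#' @param factor_peak,polII_peak nonnegative peak heights.
#' @param epsilon positive floor for the denominator (signal units).
#' @return the normalized ratio r = factor_peak / max(polII_peak, epsilon).
#' @export
normalized_enrichment <- function(factor_peak, polII_peak, epsilon = 1e-9) {
  stopifnot(factor_peak >= 0, polII_peak >= 0, epsilon > 0)
  if (polII_peak < epsilon)
    warning(sprintf("Pol II peak %g below epsilon %g; ratio floored", polII_peak, epsilon))
  factor_peak / max(polII_peak, epsilon)
}

#' Normalize per-gene ratios to a reference attenuator gene
#'
#' Divides every gene's Pol II-normalized ratio for one factor by the
#' value at the reference gene (the model NNS-dependent attenuator), so
#' the reference maps to exactly 1.
#'
#' @param r named numeric vector of per-gene ratios for one factor (names
#'   are gene ids).
#' @param reference_gene_id gene id present in `names(r)` with `r > 0`.
#' @param factor_name label used in error messages.
#' @return named numeric vector of reference ratios R.
#' @export
reference_normalize <- function(r, reference_gene_id, factor_name = "factor") {
  if (!reference_gene_id %in% names(r))
    stop(sprintf("reference gene '%s' absent from %s ratios", reference_gene_id, factor_name))
  r_ref <- r[[reference_gene_id]]
  if (!is.finite(r_ref) || r_ref <= 0)
    stop(sprintf("reference gene '%s' has zero %s ratio; cannot normalize",
                 reference_gene_id, factor_name))
  R <- r / r_ref
  R[[reference_gene_id]] <- 1  # exact by construction
  R
}

#' Bin reference ratios into the three enrichment categories
#'
#' Categories follow the screen's binning: 0--0.67 low, 0.67--1.5
#' intermediate, >1.5 high. Each bin is closed at its upper edge, so
#' "high" is the only strict inequality (R = 0.67 is low, R = 1.5 is
#' intermediate).
#'
#' @param R nonnegative reference ratio(s).
#' @param low_edge,high_edge bin edges, `0 < low_edge < high_edge`.
#' @return character vector in `{"low","intermediate","high"}`.
#' @export
categorize <- function(R, low_edge = 0.67, high_edge = 1.5) {
  stopifnot(low_edge > 0, low_edge < high_edge)
  if (any(!is.finite(R) | R < 0)) stop("categorize: R must be finite and >= 0")
  ifelse(R <= low_edge, "low", ifelse(R <= high_edge, "intermediate", "high"))
}

#' Candidate selection criteria
#'
#' Default rule: >1.5-fold promoter-proximal enrichment of pA sites and
#' Hrp1 together with depletion (<= 0.67) of both Nrd1 and Nab3, all
#' relative to the reference attenuator. Requiring depletion of *both*
#' NNS factors is the strict reading; `deplete_mode = "any"` relaxes it.
#'
#' @param enrich_factors factors whose R must exceed `enrich_threshold`.
#' @param enrich_threshold strict lower bound for enrichment.
#' @param deplete_factors factors whose R must be `<= deplete_threshold`
#'   (may be `NULL` to drop the depletion requirement).
#' @param deplete_threshold inclusive upper bound for depletion.
#' @param deplete_mode `"all"` (every deplete factor) or `"any"`.
#' @return list of class `candidate_criteria`.
#' @export
candidate_criteria <- function(enrich_factors = c("pA", "Hrp1"),
                               enrich_threshold = 1.5,
                               deplete_factors = c("Nrd1", "Nab3"),
                               deplete_threshold = 0.67,
                               deplete_mode = c("all", "any")) {
  deplete_mode <- match.arg(deplete_mode)
  stopifnot(enrich_threshold > 0, deplete_threshold > 0,
            length(enrich_factors) >= 1)
  if (length(intersect(enrich_factors, deplete_factors)))
    stop("candidate_criteria: enrich and deplete factor sets must be disjoint")
  structure(list(enrich_factors = enrich_factors,
                 enrich_threshold = enrich_threshold,
                 deplete_factors = deplete_factors,
                 deplete_threshold = deplete_threshold,
                 deplete_mode = deplete_mode),
            class = "candidate_criteria")
}

#' Build the gene x factor enrichment heatmap table
#'
#' For every gene and factor this composes the scoring chain: promoter
#' window -> peak height -> Pol II normalization -> reference
#' normalization -> category. Signal-track factors are scored from
#' occupancy; site-track factors (pA) from stranded site counts. Pol II
#' itself is carried as a factor column (r = 1 by self-normalization).
#' Candidate flags are attached per the criteria.
#'
#' @param genes a `gene_annotation` data.frame.
#' @param tracks named list of [signal_track()]s; must contain `PolII`.
#' @param sites named list of [site_track()]s (e.g. `pA`), may be empty.
#' @param reference_gene_id gene whose ratios define R = 1.
#' @param upstream_bp,downstream_bp promoter-window extents (bp).
#' @param bin_edges numeric `c(low, high)` category edges.
#' @param epsilon Pol II zero-division guard.
#' @param peak_method `"max"` or `"sum"`, see [peak_height()].
#' @param criteria a [candidate_criteria()].
#' @return data.frame of class `heatmap_table` (long form: one row per
#'   gene x factor) with attributes `reference_gene_id`, `bin_edges`,
#'   `criteria`, `factors`, `genes`.
#' @export
build_heatmap <- function(genes, tracks, sites = list(),
                          reference_gene_id = "NRD1LIKE",
                          upstream_bp = 100, downstream_bp = 300,
                          bin_edges = c(0.67, 1.5), epsilon = 1e-9,
                          peak_method = "max",
                          criteria = candidate_criteria()) {
  stopifnot(inherits(genes, "gene_annotation"), nrow(genes) >= 1)
  if (!"PolII" %in% names(tracks)) stop("build_heatmap: a 'PolII' signal track is mandatory")
  if (length(tracks) + length(sites) < 2)
    stop("build_heatmap: at least one factor or site track beyond Pol II is required")
  if (!reference_gene_id %in% genes$gene_id)
    stop("build_heatmap: reference gene '", reference_gene_id, "' not in annotation")

  factor_tracks <- c(sites, tracks[setdiff(names(tracks), "PolII")],
                     tracks["PolII"])
  gene_ids <- genes$gene_id

  windows <- lapply(seq_len(nrow(genes)), function(i)
    promoter_window(genes[i, ], upstream_bp, downstream_bp))
  polII_peaks <- vapply(windows, function(w)
    peak_height(tracks$PolII, w, method = peak_method), numeric(1))
  names(polII_peaks) <- gene_ids

  cells <- lapply(names(factor_tracks), function(f) {
    raw <- vapply(windows, function(w)
      peak_height(factor_tracks[[f]], w, method = peak_method), numeric(1))
    r <- vapply(seq_along(raw), function(i)
      normalized_enrichment(raw[i], polII_peaks[i], epsilon), numeric(1))
    names(r) <- gene_ids
    R <- reference_normalize(r, reference_gene_id, factor_name = f)
    data.frame(gene_id = gene_ids, factor = f, raw_peak = as.numeric(raw),
               polII_peak = as.numeric(polII_peaks), r = as.numeric(r),
               R = as.numeric(R),
               category = categorize(as.numeric(R), bin_edges[1], bin_edges[2]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, cells)
  rownames(tab) <- NULL
  class(tab) <- c("heatmap_table", "data.frame")
  attr(tab, "reference_gene_id") <- reference_gene_id
  attr(tab, "bin_edges") <- bin_edges
  attr(tab, "criteria") <- criteria
  attr(tab, "factors") <- names(factor_tracks)
  attr(tab, "genes") <- gene_ids
  cand <- select_candidates(tab, criteria)
  tab$candidate <- tab$gene_id %in% cand$gene_id
  tab
}

#' Select attenuator candidates from a heatmap table
#'
#' A gene is selected iff its reference ratio exceeds the enrichment
#' threshold for every enrichment factor and is at or below the depletion
#' threshold for the depletion factors (all or any, per the criteria).
#' Candidates are ordered by descending minimum enrichment-factor R, ties
#' broken by gene id.
#'
#' @param table a `heatmap_table`.
#' @param criteria a [candidate_criteria()]; defaults to the criteria the
#'   table was built with.
#' @return data.frame with columns `gene_id`, `min_enrich_R`.
#' @export
select_candidates <- function(table, criteria = attr(table, "criteria")) {
  stopifnot(inherits(table, "heatmap_table"), inherits(criteria, "candidate_criteria"))
  if (nrow(table) == 0)
    return(data.frame(gene_id = character(), min_enrich_R = numeric(),
                      stringsAsFactors = FALSE))
  present <- unique(table$factor)
  missing <- setdiff(c(criteria$enrich_factors, criteria$deplete_factors), present)
  if (length(missing))
    stop("select_candidates: criteria name factors absent from table: ",
         paste(missing, collapse = ", "))
  gene_ids <- unique(table$gene_id)
  Rmat <- matrix(NA_real_, length(gene_ids), length(present),
                 dimnames = list(gene_ids, present))
  Rmat[cbind(match(table$gene_id, gene_ids), match(table$factor, present))] <- table$R

  enr <- Rmat[, criteria$enrich_factors, drop = FALSE]
  ok_enr <- rowSums(enr > criteria$enrich_threshold) == length(criteria$enrich_factors)
  if (length(criteria$deplete_factors)) {
    dep <- Rmat[, criteria$deplete_factors, drop = FALSE] <= criteria$deplete_threshold
    ok_dep <- if (criteria$deplete_mode == "all") rowSums(dep) == ncol(dep) else rowSums(dep) > 0
  } else {
    ok_dep <- rep(TRUE, length(gene_ids))
  }
  sel <- gene_ids[ok_enr & ok_dep]
  min_enr <- apply(enr[sel, , drop = FALSE], 1, min)
  out <- data.frame(gene_id = sel, min_enrich_R = as.numeric(min_enr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$min_enrich_R, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pol II travel ratio (5' peak vs ORF body)
#'
#' Mean Pol II occupancy in the promoter-proximal window divided by the
#' mean over the ORF body (the ORF minus its promoter-proximal portion).
#' Values well above 1 indicate promoter-proximal Pol II accumulation,
#' the first attenuation signature.
#'
#' @param polII a [signal_track()].
#' @param gene one row of a `gene_annotation`.
#' @param upstream_bp,downstream_bp promoter-window extents (bp).
#' @param epsilon guard for a zero body mean (warning logged).
#' @return positive scalar ratio.
#' @export
pol2_travel_ratio <- function(polII, gene, upstream_bp = 100, downstream_bp = 300,
                              epsilon = 1e-9) {
  w <- promoter_window(gene, upstream_bp, downstream_bp)
  orf_len <- gene$orf_end - gene$orf_start
  if (orf_len <= downstream_bp)
    stop("pol2_travel_ratio: ORF length must exceed the downstream window extent")
  if (gene$strand == "+") {
    body <- genomic_window(gene$chrom, max(gene$orf_start, w$end), gene$orf_end, "+")
  } else {
    body <- genomic_window(gene$chrom, gene$orf_start, min(gene$orf_end, w$start), "-")
  }
  m5 <- mean(window_values(polII, w))
  mb <- mean(window_values(polII, body))
  if (mb < epsilon) {
    warning("pol2_travel_ratio: zero ORF-body mean; ratio floored by epsilon")
    mb <- epsilon
  }
  m5 / mb
}

#' Write a heatmap table as TSV
#'
#' @param table a `heatmap_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_table <- function(table, path) {
  out <- as.data.frame(table)
  out$raw_peak <- fmt_num(out$raw_peak)
  out$polII_peak <- fmt_num(out$polII_peak)
  out$r <- fmt_num(out$r)
  out$R <- fmt_num(out$R)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot the categorical enrichment heatmap
#'
#' Genes on rows (candidates first), factors on columns, tiles colored by
#' the low/intermediate/high category.
#'
#' @param table a `heatmap_table`.
#' @return a ggplot object.
#' @export
plot_heatmap <- function(table) {
  stopifnot(inherits(table, "heatmap_table"))
  df <- as.data.frame(table)
  ord <- unique(df$gene_id[order(-df$candidate, df$gene_id)])
  df$gene_id <- factor(df$gene_id, levels = rev(ord))
  df$factor <- factor(df$factor, levels = attr(table, "factors"))
  df$category <- factor(df$category, levels = c("low", "intermediate", "high"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$gene_id,
                                   fill = .data$category)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(low = "#2166ac", intermediate = "#f7f7f7",
                                          high = "#b2182b"), drop = FALSE) +
    ggplot2::labs(x = "factor / site", y = NULL,
                  fill = "enrichment\nvs reference") +
    ggplot2::theme_minimal()
}
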