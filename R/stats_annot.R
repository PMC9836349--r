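# Group comparison (Welch tests) and significance-star labels for assay
# summaries. No multiple-testing correction is applied: comparisons are
# named explicitly by the caller, matching how reporter and growth figures
# are annotated.

#' Welch test across replicate groups
#'
#' Two groups: Welch's unequal-variance two-sample t-test (two-sided,
#' Welch-Satterthwaite degrees of freedom). More than two groups: Welch's
#' ANOVA (`oneway.test` without the equal-variance assumption). Degenerate
#' all-equal data return p = 1.
#'
#' @param groups named list of >= 2 numeric vectors, each with >= 2 finite
#'   values.
#' @return list with `p_value`, `statistic`, `method`.
#' @export
welch_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("welch_test: at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("welch_test: every group needs at least 2 replicates")
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("welch_test: non-finite values")
  all_vals <- unlist(groups)
  if (max(all_vals) == min(all_vals))
    return(list(p_value = 1, statistic = 0,
                method = if (length(groups) == 2) "welch_t" else "welch_anova"))
  if (length(groups) == 2) {
    ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
    list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "welch_t")
  } else {
    g <- factor(rep(seq_along(groups), sizes))
    ht <- stats::oneway.test(all_vals ~ g, var.equal = FALSE)
    list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "welch_anova")
  }
}

#' Significance stars for a p-value
#'
#' The reporting convention: `****` p <= 0.0001, `***` p <= 0.001, `**`
#' p <= 0.01, `*` p <= 0.05, otherwise `ns`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of star labels.
#' @export
star_label <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("star_label: p must lie in [0, 1]")
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}
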