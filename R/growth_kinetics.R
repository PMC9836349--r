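# Doubling-time estimation from OD600 growth curves and strain comparison.

#' Doubling time from an OD600 time series
#'
#' Ordinary least squares on ln(OD600) versus time over the points inside
#' the fit window (bounds inclusive); doubling time = ln(2) / slope. A
#' non-positive slope is reported as non-growing (`Inf`).
#'
#' @param time_min sampling times in minutes.
#' @param od600 positive density readings.
#' @param window `c(start, end)` minutes of the exponential fit window.
#' @return doubling time in minutes (`Inf` for a non-growing culture).
#' @export
doubling_time <- function(time_min, od600, window = c(60, 360)) {
  stopifnot(length(time_min) == length(od600))
  sel <- time_min >= window[1] & time_min <= window[2]
  if (sum(sel) < 3)
    stop("doubling_time: at least 3 points inside the fit window are required")
  t <- time_min[sel]; od <- od600[sel]
  if (any(!is.finite(od) | od <= 0))
    stop("doubling_time: OD600 must be positive at all fitted points")
  slope <- stats::coef(stats::lm(log(od) ~ t))[["t"]]
  if (slope <= 1e-10) return(Inf)  # numerically flat cultures are non-growing
  log(2) / slope
}

#' Percent change in doubling time versus a reference strain
#'
#' @param dt_mutant,dt_reference finite positive doubling times (minutes).
#' @return 100 x (dt_mutant - dt_reference) / dt_reference.
#' @export
percent_change <- function(dt_mutant, dt_reference) {
  if (!is.finite(dt_mutant) || !is.finite(dt_reference) ||
      dt_mutant <= 0 || dt_reference <= 0)
    stop("percent_change: non-growing or invalid doubling time; report it directly")
  100 * (dt_mutant - dt_reference) / dt_reference
}

#' Doubling times for a table of growth curves
#'
#' @param curves data.frame with columns `time_min`, `od600`, `strain_id`,
#'   `replicate_id`.
#' @param window exponential fit window in minutes.
#' @param reference_strain optional strain id; when given, a
#'   `percent_change` column versus the reference strain's mean doubling
#'   time is added.
#' @return data.frame: strain_id, replicate_id, doubling_time_min and
#'   optionally percent_change.
#' @export
doubling_time_table <- function(curves, window = c(60, 360),
                                reference_strain = NULL) {
  need <- c("time_min", "od600", "strain_id", "replicate_id")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stop("growth table missing columns: ", paste(miss, collapse = ", "))
  parts <- split(curves, list(curves$strain_id, curves$replicate_id), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d)
    data.frame(strain_id = d$strain_id[1], replicate_id = d$replicate_id[1],
               doubling_time_min = doubling_time(d$time_min, d$od600, window),
               stringsAsFactors = FALSE)))
  out <- out[order(out$strain_id, out$replicate_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(reference_strain)) {
    if (!reference_strain %in% out$strain_id)
      stop("reference strain '", reference_strain, "' absent from curves")
    ref <- mean(out$doubling_time_min[out$strain_id == reference_strain])
    out$percent_change <- vapply(out$doubling_time_min, percent_change,
                                 numeric(1), dt_reference = ref)
  }
  out
}
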