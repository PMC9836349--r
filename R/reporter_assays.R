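# Quantification of kinetic lacZ reporter assays: linear-window slope,
# beta-galactosidase activity, terminator strength and fold-readthrough.

#' Kinetic reporter series
#'
#' Timed OD420 absorbance readings from a lysed culture, together with the
#' culture's OD600 and the lysed volume needed for the activity equation.
#'
#' @param time minutes, strictly increasing, >= 3 points.
#' @param od420 absorbance readings, same length as `time`.
#' @param od600 density of the assayed culture (> 0).
#' @param volume_ml lysed culture volume in ml (default 0.1).
#' @return list of class `kinetic_series`.
#' @export
kinetic_series <- function(time, od420, od600, volume_ml = 0.1) {
  if (length(time) < 3) stop("kinetic_series: at least 3 readings required")
  if (length(time) != length(od420)) stop("kinetic_series: time/od420 length mismatch")
  if (any(diff(time) <= 0)) stop("kinetic_series: times must be strictly increasing")
  if (!is.finite(od600) || od600 <= 0) stop("kinetic_series: od600 must be > 0")
  if (!is.finite(volume_ml) || volume_ml <= 0) stop("kinetic_series: volume_ml must be > 0")
  structure(list(time = as.numeric(time), od420 = as.numeric(od420),
                 od600 = od600, volume_ml = volume_ml),
            class = "kinetic_series")
}

#' Read kinetic series from a TSV file
#'
#' Expects columns `time_min` and `od420` plus per-sample metadata columns
#' `sample_id`, `od600` and optionally `volume_ml` and `group` (constant
#' within a sample).
#'
#' @param path TSV path.
#' @return named list of [kinetic_series()], one per `sample_id`; each
#'   carries its `group` as an attribute.
#' @export
load_kinetic_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("time_min", "od420", "sample_id", "od600")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("kinetic TSV missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(tab, tab$sample_id), function(d) {
    d <- d[order(d$time_min), ]
    ks <- kinetic_series(d$time_min, d$od420, d$od600[1],
                         if (is.null(d$volume_ml)) 0.1 else d$volume_ml[1])
    attr(ks, "group") <- if (is.null(d$group)) NA_character_ else d$group[1]
    ks
  })
  out
}

#' Fit the slope of the linear reaction window
#'
#' Searches every contiguous window of at least `min_points` readings and
#' returns the longest window whose residuals are consistent with reading
#' noise, together with its least-squares slope. A window qualifies as
#' "linear range" when its regression mean squared error is at most
#' `lof_mult` times the noise MSE, estimated as the median regression MSE
#' over all windows of exactly `min_points` readings (short stretches of a
#' kinetic trace are locally linear, so that median tracks pure reading
#' noise whatever the trace's lag/linear/plateau shape). Ties are broken
#' by higher R-squared, then earlier start. With a noise-free trace the
#' criterion degenerates to exact linearity, so lag and plateau phases are
#' excluded to the base point.
#'
#' If the chosen window's R-squared falls below `r2_floor`, the trace has
#' no convincingly linear range: the best-R-squared window of exactly
#' `min_points` readings is returned instead with `low_confidence = TRUE`.
#' Windows with no OD420 variance carry no linear signal and are scored
#' R-squared 0.
#'
#' @param series a [kinetic_series()].
#' @param min_points minimum window length (readings).
#' @param r2_floor R-squared below which the fit is flagged low-confidence.
#' @param lof_mult lack-of-fit tolerance: max window MSE relative to the
#'   estimated noise MSE.
#' @return list with `slope` (OD420/min), `window` (`c(start_idx,
#'   end_idx)`, 1-based inclusive), `r_squared`, `low_confidence`.
#' @export
fit_kinetic_slope <- function(series, min_points = 10, r2_floor = 0.98,
                              lof_mult = 2) {
  stopifnot(inherits(series, "kinetic_series"), min_points >= 3, lof_mult >= 1)
  n <- length(series$time)
  if (n < min_points)
    stop(sprintf("fit_kinetic_slope: %d readings but min_points = %d", n, min_points))
  t <- series$time; y <- series$od420

  fits <- vector("list", (n - min_points + 1) * (n - min_points + 2) / 2)
  k <- 0
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      f <- window_fit(t[i:j], y[i:j])
      k <- k + 1
      fits[[k]] <- list(slope = f$slope, window = c(i, j), r_squared = f$r2,
                        mse = f$mse, len = j - i + 1)
    }
  }
  lens <- vapply(fits, `[[`, numeric(1), "len")
  mses <- vapply(fits, `[[`, numeric(1), "mse")
  sigma2 <- stats::median(mses[lens == min_points])
  # tolerance floor keeps exactly-linear windows admissible despite
  # floating-point residuals
  tol <- lof_mult * sigma2 + (diff(range(y))^2 + 1e-300) * 1e-24
  best <- NULL
  for (f in fits) {
    if (f$mse <= tol && (is.null(best) || cand_better(f, best))) best <- f
  }
  if (!is.null(best) && best$r_squared >= r2_floor) {
    list(slope = best$slope, window = best$window, r_squared = best$r_squared,
         low_confidence = FALSE)
  } else {
    short <- fits[lens == min_points]
    fb <- short[[which.max(vapply(short, `[[`, numeric(1), "r_squared"))]]
    list(slope = fb$slope, window = fb$window, r_squared = fb$r_squared,
         low_confidence = TRUE)
  }
}

# closed-form simple regression on one window; zero y-variance => r2 = 0;
# residuals summed explicitly (the (1 - r2) route cancels near r2 = 1)
window_fit <- function(tt, yy) {
  n <- length(tt)
  vt <- stats::var(tt); vy <- stats::var(yy)
  if (vy < 1e-300) return(list(slope = 0, r2 = 0, mse = 0))
  cv <- stats::cov(tt, yy)
  b <- cv / vt
  res <- yy - (mean(yy) + b * (tt - mean(tt)))
  list(slope = b, r2 = cv^2 / (vt * vy), mse = sum(res^2) / (n - 2))
}

# window preference: longest, then highest r2, then earliest start
cand_better <- function(a, b) {
  if (a$len != b$len) return(a$len > b$len)
  if (a$r_squared != b$r_squared) return(a$r_squared > b$r_squared)
  a$window[1] < b$window[1]
}

#' Beta-galactosidase activity from a kinetic slope
#'
#' activity = slope / (volume_ml x OD600). Dividing by both the lysed
#' volume and the culture density follows the kinetic-kit convention;
#' relative readouts (folds, percent repression) are insensitive to the
#' bracket reading when densities are matched.
#'
#' @param slope OD420 per minute.
#' @param od600 culture density (> 0).
#' @param volume_ml lysed culture volume (default 0.1 ml).
#' @return activity units.
#' @export
beta_gal_activity <- function(slope, od600, volume_ml = 0.1) {
  if (!is.finite(od600) || od600 <= 0) stop("beta_gal_activity: od600 must be > 0")
  if (!is.finite(volume_ml) || volume_ml <= 0) stop("beta_gal_activity: volume_ml must be > 0")
  slope / (volume_ml * od600)
}

#' Terminator strength relative to a no-terminator control
#'
#' Percent repression = 100 x (1 - activity_term / activity_no_term),
#' clipped at 0 (a terminator reporter more active than the control is
#' reported as 0% repression). Strength classes follow the reporter
#' screen's color code: red > 90%, yellow > 50%, green otherwise.
#'
#' @param activity_term activity of the terminator-bearing reporter (>= 0).
#' @param activity_no_term activity of the control lacking a terminator (> 0).
#' @return list with `percent_repression` and `strength_class`.
#' @export
terminator_strength <- function(activity_term, activity_no_term) {
  if (!is.finite(activity_no_term) || activity_no_term <= 0)
    stop("terminator_strength: no-terminator control activity must be > 0")
  if (activity_term < 0) stop("terminator_strength: terminator activity must be >= 0")
  pct <- max(0, 100 * (1 - activity_term / activity_no_term))
  cls <- if (pct > 90) "red" else if (pct > 50) "yellow" else "green"
  list(percent_repression = pct, strength_class = cls)
}

#' Fold-readthrough between two conditions
#'
#' Ratio of reporter activities, e.g. +auxin over solvent control when
#' depleting a termination factor.
#'
#' @param activity_condition activity under the perturbation.
#' @param activity_control activity of the control condition (> 0).
#' @return fold change.
#' @export
fold_readthrough <- function(activity_condition, activity_control) {
  if (!is.finite(activity_control) || activity_control <= 0)
    stop("fold_readthrough: control activity must be > 0")
  activity_condition / activity_control
}

#' Quantify a set of kinetic series
#'
#' Convenience wrapper: fits every sample's linear window and computes its
#' activity.
#'
#' @param series_list named list of [kinetic_series()].
#' @param min_points,r2_floor see [fit_kinetic_slope()].
#' @return data.frame: sample_id, group, slope, window_start, window_end,
#'   r_squared, low_confidence, od600, activity.
#' @export
quantify_kinetics <- function(series_list, min_points = 10, r2_floor = 0.98) {
  rows <- lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    f <- fit_kinetic_slope(s, min_points, r2_floor)
    data.frame(sample_id = id,
               group = if (is.null(attr(s, "group"))) NA_character_ else attr(s, "group"),
               slope = f$slope, window_start = f$window[1], window_end = f$window[2],
               r_squared = f$r_squared, low_confidence = f$low_confidence,
               od600 = s$od600,
               activity = beta_gal_activity(f$slope, s$od600, s$volume_ml),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
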