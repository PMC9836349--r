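# Independent oracles and small utilities shared across tests. The oracles
# deliberately avoid the package's run-length machinery: tracks are
# expanded to dense per-base vectors and regressions go through lm/QR.

# dense per-base vector of a signal track over [0, len) on one chromosome,
# built by direct fill from the run table
dense_vector <- function(track, chrom, len) {
  v <- numeric(len)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != chrom) next
    a <- max(0, track$start[i]); b <- min(len, track$end[i])
    if (b > a) v[(a + 1):b] <- track$value[i]
  }
  v
}

# brute-force recomputation of the whole scoring chain from dense vectors
# and raw site rows; window arithmetic re-derived from first principles
oracle_heatmap <- function(sim, upstream = 100, downstream = 300,
                           reference = "NRD1LIKE", epsilon = 1e-9) {
  genes <- as.data.frame(sim$annotation)
  len <- max(genes$orf_end) + 1000
  dense <- lapply(sim$tracks, dense_vector, chrom = "chrSim", len = len)
  pa <- as.data.frame(sim$sites$pA)

  win_of <- function(g) {
    anchor <- if (!is.na(g$tss_pos)) g$tss_pos else g$atg_pos
    if (g$strand == "+") c(max(0, anchor - upstream), anchor + downstream)
    else c(max(0, anchor - downstream), anchor + upstream)
  }
  raw <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- win_of(g)
    slice <- dense$PolII[(w[1] + 1):w[2]]
    pol <- max(slice, 0)
    row <- c(PolII = pol)
    for (f in c("Hrp1", "Nrd1", "Nab3"))
      row[f] <- max(dense[[f]][(w[1] + 1):w[2]], 0)
    hits <- pa$count[pa$strand == g$strand & pa$pos >= w[1] & pa$pos < w[2]]
    row["pA"] <- if (length(hits)) max(hits) else 0
    raw[[g$gene_id]] <- c(row, polII_peak = pol)
  }
  raw <- do.call(rbind, raw)
  r <- raw[, c("pA", "Hrp1", "Nrd1", "Nab3", "PolII")] /
    pmax(raw[, "polII_peak"], epsilon)
  R <- sweep(r, 2, r[reference, ], "/")
  R[reference, ] <- 1
  cat_of <- function(x) {
    if (x <= 0.67) "low" else if (x <= 1.5) "intermediate" else "high"
  }
  list(r = r, R = R,
       category = apply(R, c(1, 2), cat_of),
       candidates = rownames(R)[R[, "pA"] > 1.5 & R[, "Hrp1"] > 1.5 &
                                  R[, "Nrd1"] <= 0.67 & R[, "Nab3"] <= 0.67])
}

# exhaustive linear-window search using QR least squares (lm.fit route):
# noise MSE = median over min_points windows, windows qualify at
# lof_mult x that MSE, longest qualifying wins (ties: r2, then start);
# chosen window under the r2 floor -> best short window, low confidence
oracle_slope_window <- function(series, min_points = 10, r2_floor = 0.98,
                                lof_mult = 2) {
  t <- series$time; y <- series$od420; n <- length(t)
  rows <- list()
  for (i in 1:(n - min_points + 1)) {
    for (j in (i + min_points - 1):n) {
      tt <- t[i:j]; yy <- y[i:j]
      fit <- .lm.fit(cbind(1, tt), yy)
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((yy - mean(yy))^2)
      r2 <- if (ss_tot < 1e-300) 0 else 1 - ss_res / ss_tot
      mse <- if (ss_tot < 1e-300) 0 else ss_res / (j - i - 1)
      rows[[length(rows) + 1]] <- list(slope = fit$coefficients[2],
                                       window = c(i, j), r_squared = r2,
                                       mse = mse, len = j - i + 1)
    }
  }
  lens <- sapply(rows, `[[`, "len")
  sigma2 <- median(sapply(rows[lens == min_points], `[[`, "mse"))
  tol <- lof_mult * sigma2 + (diff(range(y))^2 + 1e-300) * 1e-24
  best <- NULL
  for (cand in rows) {
    if (cand$mse > tol) next
    if (is.null(best) ||
        cand$len > best$len ||
        (cand$len == best$len && cand$r_squared > best$r_squared) ||
        (cand$len == best$len && cand$r_squared == best$r_squared &&
         cand$window[1] < best$window[1])) best <- cand
  }
  if (!is.null(best) && best$r_squared >= r2_floor) {
    c(best, low_confidence = FALSE)
  } else {
    short <- rows[lens == min_points]
    fb <- short[[which.max(sapply(short, `[[`, "r_squared"))]]
    c(fb, low_confidence = TRUE)
  }
}

# reflect every coordinate of a simulated genome about position len - 1 and
# flip all strands; windows shift by at most one base, which planted
# plateaus and interior site clusters are insensitive to
mirror_sim <- function(sim, len = max(sim$annotation$orf_end) + 1000) {
  flip <- function(s) ifelse(s == "+", "-", "+")
  tracks <- lapply(sim$tracks, function(tr) {
    df <- as.data.frame(tr)
    signal_track(data.frame(chrom = df$chrom, start = len - df$end,
                            end = len - df$start, value = df$value))
  })
  sites <- lapply(sim$sites, function(st) {
    df <- as.data.frame(st)
    site_track(data.frame(chrom = df$chrom, pos = len - 1 - df$pos,
                          name = df$name, count = df$count,
                          strand = flip(df$strand)))
  })
  g <- as.data.frame(sim$annotation)
  ann <- gene_annotation(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                    strand = flip(g$strand),
                                    orf_start = len - g$orf_end,
                                    orf_end = len - g$orf_start,
                                    tss_pos = len - 1 - g$tss_pos))
  list(annotation = ann, tracks = tracks, sites = sites, truth = sim$truth)
}

# write a few lines to a temp file and return the path
write_fixture <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
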