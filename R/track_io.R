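# I/O and window queries for annotation, signal tracks and point-site tracks.
# All internal coordinates are 0-based half-open (bedGraph/BED native); GFF3
# input is converted from 1-based closed on load. Occupancy tracks are
# unstranded; site tracks (pA, TSS) are stranded.

#' Construct a signal track from run intervals
#'
#' A signal track is a sparse, run-length encoded, per-base nonnegative
#' occupancy over one or more chromosomes. Runs are canonicalized on
#' construction: sorted by (chrom, start), overlap-checked, and adjacent
#' runs with equal value merged. Queries outside covered regions return 0.
#'
#' @param runs data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals, `value >= 0`).
#' @return An object of class `signal_track` (a canonicalized data.frame).
#' @export
signal_track <- function(runs = data.frame(chrom = character(), start = integer(),
                                           end = integer(), value = numeric())) {
  stopifnot(is.data.frame(runs),
            all(c("chrom", "start", "end", "value") %in% names(runs)))
  runs <- runs[, c("chrom", "start", "end", "value")]
  runs$chrom <- as.character(runs$chrom)
  if (nrow(runs) > 0) {
    if (any(!is.finite(runs$start) | !is.finite(runs$end) | !is.finite(runs$value)))
      stop("signal_track: non-finite coordinates or values")
    if (any(runs$start >= runs$end))
      stop("signal_track: runs must satisfy start < end")
    if (any(runs$value < 0))
      stop("signal_track: negative occupancy values are not allowed")
    runs <- runs[runs$value != 0, , drop = FALSE]  # implicit zeros
    runs <- runs[order(runs$chrom, runs$start, runs$end), , drop = FALSE]
    if (nrow(runs) > 1) {
      same <- runs$chrom[-1] == runs$chrom[-nrow(runs)]
      if (any(same & runs$start[-1] < runs$end[-nrow(runs)]))
        stop("signal_track: overlapping runs")
      runs <- merge_equal_runs(runs)
    }
    rownames(runs) <- NULL
  }
  class(runs) <- c("signal_track", "data.frame")
  runs
}

# merge adjacent runs on the same chromosome with equal value (canonical
# form); input is already sorted and overlap-free
merge_equal_runs <- function(runs) {
  n <- nrow(runs)
  if (n < 2) return(runs)
  joinable <- runs$chrom[-1] == runs$chrom[-n] &
    runs$start[-1] == runs$end[-n] &
    runs$value[-1] == runs$value[-n]
  if (!any(joinable)) return(runs)
  first <- which(c(TRUE, !joinable))
  last <- c(first[-1] - 1L, n)
  data.frame(chrom = runs$chrom[first], start = runs$start[first],
             end = runs$end[last], value = runs$value[first],
             stringsAsFactors = FALSE)
}

#' Construct a stranded point-site track
#'
#' Site tracks hold punctual genomic events (polyadenylation sites, TSS)
#' with a supporting read count. Sites sharing (chrom, position, strand)
#' are merged by summing their counts; the first name is kept.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand`, `count`
#'   and optionally `name`.
#' @return An object of class `site_track`.
#' @export
site_track <- function(sites = data.frame(chrom = character(), pos = integer(),
                                          strand = character(), count = numeric())) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "strand", "count") %in% names(sites)))
  if (is.null(sites$name)) sites$name <- if (nrow(sites)) paste0("site_", seq_len(nrow(sites))) else character()
  sites <- sites[, c("chrom", "pos", "name", "count", "strand")]
  sites$chrom <- as.character(sites$chrom)
  sites$strand <- as.character(sites$strand)
  if (nrow(sites) > 0) {
    if (!all(sites$strand %in% c("+", "-")))
      stop("site_track: strand must be '+' or '-'")
    if (any(!is.finite(sites$count) | sites$count <= 0))
      stop("site_track: counts must be positive")
    key <- paste(sites$chrom, sites$pos, sites$strand, sep = "\r")
    if (anyDuplicated(key)) {
      agg_count <- tapply(sites$count, key, sum)
      first <- !duplicated(key)
      sites <- sites[first, , drop = FALSE]
      sites$count <- as.numeric(agg_count[paste(sites$chrom, sites$pos, sites$strand, sep = "\r")])
    }
    sites <- sites[order(sites$chrom, sites$strand, sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
  }
  class(sites) <- c("site_track", "data.frame")
  sites
}

#' Read a bedGraph signal track
#'
#' Parses a 4-column bedGraph (chrom, start, end, value). Track definition
#' and comment lines are skipped. Adjacent equal-value runs are merged to
#' canonical form; negative values are rejected. Gzipped files are accepted.
#'
#' @param path path to a bedGraph (optionally .gz) file.
#' @return A [signal_track()].
#' @export
load_signal_track <- function(path) {
  lines <- read_track_lines(path)
  if (length(lines$text) == 0) return(signal_track())
  fields <- strsplit(lines$text, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop(sprintf("bedGraph parse error at line %d: expected 4 fields, got %d",
                 lines$lineno[which(nf < 4)[1]], nf[which(nf < 4)[1]]))
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop(sprintf("bedGraph parse error at line %d: non-numeric field", lines$lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("bedGraph parse error at line %d: start >= end", lines$lineno[bad[1]]))
  if (any(value < 0))
    stop(sprintf("bedGraph validation error at line %d: negative value",
                 lines$lineno[which(value < 0)[1]]))
  signal_track(data.frame(chrom = m[, 1], start = start, end = end,
                          value = value, stringsAsFactors = FALSE))
}

#' Write a signal track as canonical bedGraph
#'
#' Emits the merged, sorted run form so that load/write round-trips are
#' byte-stable.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   fmt_coord(track$start), fmt_coord(track$end), fmt_num(track$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 point-site track
#'
#' BED6 with the score column holding the supporting read count and
#' one-base intervals (end = start + 1). Duplicate (chrom, pos, strand)
#' sites are merged by summing counts.
#'
#' @param path path to a BED6 (optionally .gz) file.
#' @return A [site_track()].
#' @export
load_sites <- function(path) {
  lines <- read_track_lines(path)
  if (length(lines$text) == 0) return(site_track())
  fields <- strsplit(lines$text, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop(sprintf("BED parse error at line %d: expected 6 fields, got %d",
                 lines$lineno[which(nf < 6)[1]], nf[which(nf < 6)[1]]))
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  count <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-numeric coordinate", lines$lineno[bad[1]]))
  if (any(is.na(count)))
    stop(sprintf("BED parse error at line %d: non-numeric score", lines$lineno[which(is.na(count))[1]]))
  if (any(end != start + 1))
    stop(sprintf("BED validation error at line %d: point sites must have end = start + 1",
                 lines$lineno[which(end != start + 1)[1]]))
  if (!all(m[, 6] %in% c("+", "-")))
    stop(sprintf("BED validation error at line %d: strand must be + or -",
                 lines$lineno[which(!(m[, 6] %in% c("+", "-")))[1]]))
  site_track(data.frame(chrom = m[, 1], pos = start, name = m[, 4],
                        count = count, strand = m[, 6], stringsAsFactors = FALSE))
}

#' Write a site track as canonical BED6
#'
#' @param track a [site_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(track, path) {
  stopifnot(inherits(track, "site_track"))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", track$chrom,
                   fmt_coord(track$pos), fmt_coord(track$pos + 1),
                   track$name, fmt_num(track$count), track$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Load gene annotation from GFF3 or TSV
#'
#' Accepts either GFF3 (records of type `gene` carrying an `ID` attribute;
#' 1-based closed coordinates converted to 0-based half-open) or a 6-column
#' TSV with header `gene_id chrom strand orf_start orf_end tss` already in
#' 0-based half-open coordinates (`tss` may be `NA` or `.`). The +1 ATG
#' anchor is the first ORF base in gene orientation: `orf_start` on the +
#' strand, `orf_end - 1` on the - strand.
#'
#' @param path annotation file (optionally .gz); `.gff`/`.gff3` suffix
#'   selects the GFF3 parser.
#' @return data.frame of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `strand`, `orf_start`, `orf_end`, `atg_pos`, `tss_pos`.
#' @export
load_annotation <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    genes <- parse_gff3_genes(path)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "NA",
                             colClasses = "character")
    need <- c("gene_id", "chrom", "strand", "orf_start", "orf_end")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("annotation TSV missing columns: ", paste(miss, collapse = ", "))
    if (is.null(tab$tss)) tab$tss <- NA_character_
    tab$tss[tab$tss %in% "."] <- NA  # "." marks an absent TSS, not NA data
    genes <- data.frame(gene_id = as.character(tab$gene_id),
                        chrom = as.character(tab$chrom),
                        strand = as.character(tab$strand),
                        orf_start = as.numeric(tab$orf_start),
                        orf_end = as.numeric(tab$orf_end),
                        tss_pos = as.numeric(tab$tss),
                        stringsAsFactors = FALSE)
  }
  gene_annotation(genes)
}

#' Validate and finalize a gene annotation table
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `orf_start`,
#'   `orf_end` and optional `tss_pos`.
#' @return data.frame of class `gene_annotation` (adds `atg_pos`).
#' @export
gene_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "orf_start", "orf_end")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene annotation missing fields: ", paste(miss, collapse = ", "))
  if (is.null(genes$tss_pos)) genes$tss_pos <- NA_real_
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    id <- if (is.na(g$gene_id) || !nzchar(g$gene_id)) sprintf("<record %d>", i) else g$gene_id
    if (any(is.na(c(g$chrom, g$strand, g$orf_start, g$orf_end))))
      stop("gene ", id, ": missing mandatory field")
    if (!g$strand %in% c("+", "-"))
      stop("gene ", id, ": unknown strand '", g$strand, "'")
    if (g$orf_start >= g$orf_end)
      stop("gene ", id, ": orf_start must be < orf_end")
  }
  genes$atg_pos <- ifelse(genes$strand == "+", genes$orf_start, genes$orf_end - 1)
  bad <- !is.na(genes$tss_pos) &
    ifelse(genes$strand == "+", genes$tss_pos >= genes$atg_pos, genes$tss_pos <= genes$atg_pos)
  if (any(bad))
    stop("gene ", genes$gene_id[which(bad)[1]], ": tss_pos must be 5' of the ATG in gene orientation")
  genes <- genes[, c("gene_id", "chrom", "strand", "orf_start", "orf_end", "atg_pos", "tss_pos")]
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Write gene annotation as TSV
#'
#' Emits the 6-column 0-based half-open TSV that [load_annotation()] reads.
#'
#' @param genes a `gene_annotation` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    orf_start = fmt_coord(genes$orf_start),
                    orf_end = fmt_coord(genes$orf_end),
                    tss = ifelse(is.na(genes$tss_pos), ".", fmt_coord(genes$tss_pos)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genomic window
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param strand `"+"` or `"-"`; orients [window_values()] output 5'->3'.
#' @return list of class `genomic_window`.
#' @export
genomic_window <- function(chrom, start, end, strand = "+") {
  if (!strand %in% c("+", "-")) stop("genomic_window: strand must be '+' or '-'")
  if (!(start < end)) stop("genomic_window: start must be < end")
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), strand = strand),
            class = "genomic_window")
}

#' Per-base values of a signal track over a window
#'
#' Returns one value per base; uncovered bases are 0. For minus-strand
#' windows the vector is returned 5'->3' in gene orientation (reversed
#' relative to genome coordinates). A chromosome absent from the track
#' yields all zeros with a warning (tracks are sparse).
#'
#' @param track a [signal_track()].
#' @param window a [genomic_window()].
#' @return numeric vector of length `end - start`.
#' @export
window_values <- function(track, window) {
  stopifnot(inherits(track, "signal_track"), inherits(window, "genomic_window"))
  v <- numeric(window$end - window$start)
  runs <- track[track$chrom == window$chrom, , drop = FALSE]
  if (nrow(runs) == 0) {
    if (!(window$chrom %in% track$chrom))
      warning("chromosome '", window$chrom, "' absent from track; returning zeros")
  } else {
    hit <- runs$end > window$start & runs$start < window$end
    runs <- runs[hit, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      a <- max(runs$start[i], window$start) - window$start
      b <- min(runs$end[i], window$end) - window$start
      v[(a + 1):b] <- runs$value[i]
    }
  }
  if (window$strand == "-") rev(v) else v
}

# ---- internal helpers -------------------------------------------------------

# read non-header lines of a track file, keeping original line numbers
read_track_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  text <- readLines(con, warn = FALSE)
  lineno <- seq_along(text)
  keep <- !grepl("^(#|track\\b|browser\\b)", text) & nzchar(trimws(text))
  list(text = text[keep], lineno = lineno[keep])
}

fmt_coord <- function(x) sprintf("%d", as.integer(round(x)))

# 15 significant digits: decimal -> double -> decimal round-trips exactly,
# so rewriting a loaded file is byte-stable
fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  sub("^(-?[0-9]+)\\.0*$", "\\1", s)
}

parse_gff3_genes <- function(path) {
  lines <- read_track_lines(path)
  if (length(lines$text) == 0)
    return(data.frame(gene_id = character(), chrom = character(), strand = character(),
                      orf_start = numeric(), orf_end = numeric(), tss_pos = numeric()))
  fields <- strsplit(lines$text, "\t")
  nf <- lengths(fields)
  if (any(nf < 9))
    stop(sprintf("GFF3 parse error at line %d: expected 9 fields", lines$lineno[which(nf < 9)[1]]))
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  ids <- sub(".*(^|;)ID=([^;]+).*", "\\2", m[, 9])
  no_id <- !grepl("(^|;)ID=", m[, 9])
  if (any(no_id)) stop("GFF3 gene record without ID attribute")
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  if (any(is.na(start1) | is.na(end1))) stop("GFF3 parse error: non-numeric coordinates")
  data.frame(gene_id = ids, chrom = m[, 1], strand = m[, 7],
             orf_start = start1 - 1, orf_end = end1,   # 1-based closed -> 0-based half-open
             tss_pos = NA_real_, stringsAsFactors = FALSE)
}
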