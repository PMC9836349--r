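test_that("bedGraph loading reads runs back, merges, and validates", {
  p <- write_fixture("chrI\t0\t10\t5.0", ".bedGraph")
  tr <- load_signal_track(p)
  expect_equal(window_values(tr, genomic_window("chrI", 0, 10)), rep(5, 10))
  expect_equal(window_values(tr, genomic_window("chrI", 10, 20)), rep(0, 10))

  # empty file -> empty track, queries return 0
  empty <- load_signal_track(write_fixture(character(), ".bedGraph"))
  expect_equal(nrow(empty), 0)
  expect_warning(v <- window_values(empty, genomic_window("chrI", 0, 5)),
                 "absent")
  expect_equal(v, rep(0, 5))

  # adjacent equal-value runs are merged to one canonical run
  tr2 <- load_signal_track(write_fixture(c("chrI\t0\t5\t2", "chrI\t5\t9\t2",
                                           "chrI\t9\t12\t3")))
  expect_equal(nrow(tr2), 2)
  expect_equal(tr2$end[1], 9)

  # header/comment lines are skipped, line numbers reported on errors
  tr3 <- load_signal_track(write_fixture(c("track type=bedGraph", "# c",
                                           "chrI\t0\t3\t1")))
  expect_equal(nrow(tr3), 1)
  expect_error(load_signal_track(write_fixture("chrI\t5\t3\t1.0")),
               "line 1.*start >= end")
  expect_error(load_signal_track(write_fixture(c("chrI\t0\t3\t1", "chrI\t3\t6\t-2"))),
               "line 2.*negative")
  expect_error(load_signal_track(write_fixture("chrI\t0\tx\t1")), "non-numeric")
})

test_that("bedGraph round-trips bit-exactly in canonical form", {
  set.seed(11)
  for (rep in 1:5) {
    runs <- do.call(rbind, lapply(c("chrI", "chrII"), function(ch) {
      n <- 15
      widths <- sample(1:15, n, replace = TRUE)
      gaps <- sample(0:10, n, replace = TRUE)        # 0 gap exercises merging
      ends <- cumsum(widths + gaps)
      data.frame(chrom = ch, start = ends - widths, end = ends,
                 value = signif(stats::rlnorm(n, 2, 1), 6))
    }))
    tr <- signal_track(runs)
    p1 <- tempfile(); p2 <- tempfile()
    write_signal_track(tr, p1)
    write_signal_track(load_signal_track(p1), p2)
    expect_identical(readLines(p1), readLines(p2))
  }
  # BED site round-trip
  st <- site_track(data.frame(chrom = "chrI", pos = c(5, 9, 120),
                              strand = c("+", "-", "+"), count = c(3, 8, 12.5)))
  p1 <- tempfile(); p2 <- tempfile()
  write_sites(st, p1)
  write_sites(load_sites(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("BED site loading preserves strand and sums duplicate positions", {
  st <- load_sites(write_fixture("chrI\t99\t100\tpA1\t12\t+", ".bed"))
  expect_equal(st$pos, 99)
  expect_equal(st$count, 12)
  expect_equal(st$strand, "+")

  dup <- load_sites(write_fixture(c("chrI\t99\t100\ta\t12\t+",
                                    "chrI\t99\t100\tb\t5\t+",
                                    "chrI\t99\t100\tc\t5\t-")))
  expect_equal(dup$count[dup$strand == "+"], 17)
  expect_equal(dup$count[dup$strand == "-"], 5)

  expect_equal(nrow(load_sites(write_fixture(character()))), 0)
  expect_error(load_sites(write_fixture("chrI\t99\t100\tpA1\thigh\t+")),
               "non-numeric score")
  expect_error(load_sites(write_fixture("chrI\t99\t105\tpA1\t3\t+")),
               "end = start \\+ 1")
})

test_that("annotation loading applies the strand convention and validates", {
  p <- write_fixture(c("gene_id\tchrom\tstrand\torf_start\torf_end\ttss",
                       "GENEA\tchrI\t-\t100\t400\t.",
                       "GENEB\tchrI\t+\t1000\t1600\t940"))
  ann <- load_annotation(p)
  expect_equal(ann$atg_pos[ann$gene_id == "GENEA"], 399)  # last base, - strand
  expect_equal(ann$atg_pos[ann$gene_id == "GENEB"], 1000)
  expect_true(is.na(ann$tss_pos[ann$gene_id == "GENEA"]))
  expect_equal(ann$tss_pos[ann$gene_id == "GENEB"], 940)

  expect_error(load_annotation(write_fixture(
    c("gene_id\tchrom\tstrand\torf_start\torf_end\ttss",
      "GENEC\tchrI\t.\t5\t50\t."))), "GENEC.*strand")
  expect_error(load_annotation(write_fixture(
    c("gene_id\tchrom\tstrand\torf_start\torf_end\ttss",
      "GENED\tchrI\t+\t50\t5\t."))), "GENED")

  # GFF3: 1-based closed converted to 0-based half-open
  g <- load_annotation(write_fixture(
    c("##gff-version 3",
      "chrI\tsrc\tgene\t101\t400\t.\t+\t.\tID=GENEG;Name=G",
      "chrI\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=GENEG"),
    ".gff3"))
  expect_equal(nrow(g), 1)
  expect_equal(g$orf_start, 100)
  expect_equal(g$orf_end, 400)
})

test_that("window queries respect orientation, concatenation and mirroring", {
  tr <- signal_track(data.frame(chrom = "chrI", start = c(0, 10, 25),
                                end = c(10, 20, 40), value = c(7, 3, 1.5)))
  expect_equal(window_values(tr, genomic_window("chrI", 2, 7)), rep(7, 5))
  expect_equal(window_values(tr, genomic_window("chrI", 100, 105)), rep(0, 5))

  # minus-strand output is the reverse of the plus-strand values
  wplus <- window_values(tr, genomic_window("chrI", 5, 30, "+"))
  wminus <- window_values(tr, genomic_window("chrI", 5, 30, "-"))
  expect_equal(wminus, rev(wplus))

  # abutting windows concatenate to the union window (+ strand)
  u <- window_values(tr, genomic_window("chrI", 3, 33))
  a <- window_values(tr, genomic_window("chrI", 3, 18))
  b <- window_values(tr, genomic_window("chrI", 18, 33))
  expect_equal(c(a, b), u)

  # mirroring the genome leaves gene-oriented values unchanged
  L <- 60
  mt <- signal_track(data.frame(chrom = "chrI", start = L - c(10, 20, 40),
                                end = L - c(0, 10, 25), value = c(7, 3, 1.5)))
  wm <- window_values(mt, genomic_window("chrI", L - 30, L - 5, "-"))
  expect_equal(wm, wplus)

  # dense-vector oracle agrees with the run-length query
  v <- dense_vector(tr, "chrI", 40)
  expect_equal(window_values(tr, genomic_window("chrI", 0, 40)), v)
})

test_that("bedGraph reading agrees with rtracklayer as an independent parser", {
  p <- write_fixture(c("track type=bedGraph",
                       "chrI\t0\t10\t5.5", "chrI\t25\t40\t2",
                       "chrII\t3\t9\t7.25"), ".bedGraph")
  ours <- load_signal_track(p)
  gr <- rtracklayer::import(p, format = "bedGraph")
  ref <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,  # 1-based -> 0-based
                    end = GenomicRanges::end(gr),
                    value = gr$score)
  ref <- ref[order(ref$chrom, ref$start), ]
  expect_equal(as.data.frame(ours), ref, ignore_attr = TRUE)
})

test_that("track constructors reject invalid runs and sites", {
  expect_error(signal_track(data.frame(chrom = "c", start = 5, end = 5, value = 1)),
               "start < end")
  expect_error(signal_track(data.frame(chrom = "c", start = c(0, 3), end = c(5, 8),
                                       value = c(1, 2))), "overlap")
  expect_error(signal_track(data.frame(chrom = "c", start = 0, end = 5, value = -1)),
               "negative")
  expect_error(site_track(data.frame(chrom = "c", pos = 1, strand = "*", count = 2)),
               "strand")
  expect_error(site_track(data.frame(chrom = "c", pos = 1, strand = "+", count = 0)),
               "positive")
})
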