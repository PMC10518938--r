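test_that("read_bed maps BED fields, skips comments, preserves order", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "track name=peaks",
               "chr1\t100\t200\tpeak1\t250",
               "chr2\t0\t50\tpeak2\t90",
               "chr1\t5\t6"), path)
  ps <- read_bed(path, genome = "hg38", experiment_id = "ex1",
                 antigen = "CTCF", cell_type_class = "Blood")
  expect_s3_class(ps, "PeakSet")
  expect_equal(ps$intervals$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(ps$intervals$start, c(100L, 0L, 5L))
  expect_equal(ps$intervals$end, c(200L, 50L, 6L))
  expect_equal(ps$intervals$score, c(250L, 90L, NA_integer_))
  expect_equal(ps$antigen, "CTCF")

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_bed(empty)$intervals), 0L)
})

test_that("read_bed rejects malformed lines with the offending line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t200\t100"), path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\t10\t20", "chr1\txx\t30"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t10"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("write_bed round-trips canonical BED3 and BED5 byte-for-byte", {
  p3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chrX\t0\t10"), p3)
  out3 <- withr::local_tempfile(fileext = ".bed")
  write_bed(read_bed(p3, experiment_id = "e"), out3)
  expect_identical(readBin(p3, "raw", file.size(p3)),
                   readBin(out3, "raw", file.size(out3)))

  p5 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tex.1\t250", "chr2\t5\t9\tex.2\t1000"), p5)
  out5 <- withr::local_tempfile(fileext = ".bed")
  write_bed(read_bed(p5, experiment_id = "ex"), out5)
  expect_identical(readBin(p5, "raw", file.size(p5)),
                   readBin(out5, "raw", file.size(out5)))

  # empty set -> zero-length file; single interval -> one terminated line
  out0 <- withr::local_tempfile(fileext = ".bed")
  write_bed(peak_set(iv(list("chrX", 0, 10))[0, ], "e", genome = NA), out0)
  expect_equal(file.size(out0), 0)
  write_bed(peak_set(iv(list("chrX", 0, 10)), "e", genome = NA), out0)
  expect_identical(readChar(out0, file.size(out0)), "chrX\t0\t10\n")
})

test_that("write_bed/read_bed round-trip random intervals field-by-field", {
  set.seed(11)
  df <- unique(rand_intervals(100))
  df$score <- sample(0:1000, nrow(df), replace = TRUE)
  ps <- peak_set(df, "rt", genome = "toy")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, path)
  back <- read_bed(path, genome = "toy", experiment_id = "rt")
  expect_equal(back$intervals$chrom, df$chrom)
  expect_equal(back$intervals$start, df$start)
  expect_equal(back$intervals$end, df$end)
  expect_equal(back$intervals$score, df$score)
})

test_that("filter_by_score applies the MACS2 Q<=1e-10 convention", {
  df <- iv(list("chr1", 0, 10), list("chr1", 20, 30), list("chr1", 40, 50))
  df$score <- c(99L, 100L, 250L)
  ps <- peak_set(df, "e", genome = NA)
  expect_equal(nrow(filter_by_score(ps, 100L)$intervals), 2L)
  expect_equal(filter_by_score(ps, 0L)$intervals, ps$intervals)
  expect_equal(nrow(filter_by_score(ps, 251L)$intervals), 0L)
  unscored <- peak_set(df[, 1:3], "e", genome = NA)
  expect_error(filter_by_score(unscored, 100L), "unfiltered")
})

test_that("count_overlapping_queries uses half-open, per-query-binary counting", {
  peaks <- peak_set(iv(list("chr1", 15, 30)), "p", genome = NA)
  expect_equal(count_overlapping_queries(iv(list("chr1", 10, 20)), peaks), 1L)
  # half-open adjacency does not overlap
  adj <- peak_set(iv(list("chr1", 20, 30)), "p", genome = NA)
  expect_equal(count_overlapping_queries(iv(list("chr1", 10, 20)), adj), 0L)
  # a query touching many peaks counts once; chromosomes match as strings
  multi <- peak_set(iv(list("chr1", 0, 5), list("chr1", 6, 12),
                       list("1", 0, 100)), "p", genome = NA)
  expect_equal(count_overlapping_queries(iv(list("chr1", 0, 100)), multi), 1L)
  expect_equal(count_overlapping_queries(iv(list("chr1", 0, 1))[0, ], multi), 0L)
  expect_equal(count_overlapping_queries(iv(list("chr1", 0, 1)),
                                         peak_set(iv(list("chr1", 5, 6))[0, ],
                                                  "p", genome = NA)), 0L)
})

test_that("indexed overlap counting matches the all-pairs oracle", {
  set.seed(23)
  for (rep in 1:100) {
    q <- rand_intervals(sample(0:120, 1))
    p <- rand_intervals(sample(0:120, 1))
    ps <- peak_set(p, "p", genome = NA)
    n <- count_overlapping_queries(q, ps)
    expect_identical(n, brute_count_overlaps(q, p))
    expect_lte(n, nrow(q))
    # invariant under reordering of both inputs
    expect_identical(
      count_overlapping_queries(q[sample(nrow(q)), , drop = FALSE],
                                peak_set(p[sample(nrow(p)), , drop = FALSE],
                                         "p", genome = NA)),
      n)
  }
})

test_that("peak-library manifests load, filter by cell class, reject dup ids", {
  dir <- withr::local_tempdir()
  df1 <- iv(list("chr1", 0, 10)); df1$score <- 200L
  df2 <- iv(list("chr1", 5, 15)); df2$score <- 300L
  write_bed(peak_set(df1, "e1", genome = "toy"), file.path(dir, "e1.bed"))
  write_bed(peak_set(df2, "e2", genome = "toy"), file.path(dir, "e2.bed"))
  man <- data.frame(experiment_id = c("e1", "e2"),
                    antigen = c("TFA", "TFB"),
                    cell_type_class = c("Blood", "Liver"),
                    genome = "toy", path = c("e1.bed", "e2.bed"))
  mp <- file.path(dir, "manifest.tsv")
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- read_peak_library(mp)
  expect_named(lib, c("e1", "e2"))
  expect_equal(lib$e2$antigen, "TFB")
  expect_named(read_peak_library(mp, cell_type_class_filter = "Liver"), "e2")
  man$experiment_id <- c("e1", "e1")
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_peak_library(mp), "unique")
})

test_that("BED coordinates agree with rtracklayer's import convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t250", "chr2\t0\t50\tp2\t90"), path)
  ours <- read_bed(path, experiment_id = "x")$intervals
  gr <- rtracklayer::import.bed(path)
  # rtracklayer is 1-based closed; ours is BED-native 0-based half-open
  expect_equal(ours$start + 1L, GenomicRanges::start(gr))
  expect_equal(ours$end, GenomicRanges::end(gr))
  expect_equal(ours$score, as.integer(gr$score))
})
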