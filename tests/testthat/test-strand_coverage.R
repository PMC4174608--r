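# strand_coverage: orientation tallies, SSLR, support filter, coverage.

make_pair_sam <- function(path, sq, pairs) {
  # pairs: data.frame(read, tid, r1_strand) -> emits proper FR pair lines
  lines <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
    r1_plus <- pairs$r1_strand[i] == "+"
    f1 <- if (r1_plus) 99L else 83L
    f2 <- if (r1_plus) 147L else 163L
    c(sam_line(pairs$read[i], f1, pairs$tid[i], 1L, "50M"),
      sam_line(pairs$read[i], f2, pairs$tid[i], 100L, "50M"))
  }))
  write_sam(path, sq, lines)
}

test_that("tally_orientation counts pairs by first-in-pair strand", {
  f <- withr::local_tempfile(fileext = ".sam")
  make_pair_sam(f, c(t1 = 500L, t2 = 500L),
                data.frame(read = sprintf("r%d", 1:10), tid = "t1",
                           r1_strand = "-"))
  tal <- tally_orientation(read_sam_pairs(f))
  expect_equal(tal$n_read1_plus, 0L)
  expect_equal(tal$n_read2_plus, 10L)
  expect_equal(tal$n_proper_pairs, 10L)

  make_pair_sam(f, c(t1 = 500L),
                data.frame(read = sprintf("r%d", 1:10), tid = "t1",
                           r1_strand = rep(c("+", "-"), 5)))
  tal <- tally_orientation(read_sam_pairs(f))
  expect_equal(tal$n_read1_plus, 5L)
  expect_equal(tal$n_read2_plus, 5L)
})

test_that("a multi-mapped pair is counted once on each transcript", {
  f <- withr::local_tempfile(fileext = ".sam")
  make_pair_sam(f, c(t1 = 500L, t2 = 500L),
                data.frame(read = c("r1", "r1", "r2"),
                           tid = c("t1", "t2", "t1"),
                           r1_strand = "-"))
  tal <- tally_orientation(read_sam_pairs(f))
  expect_equal(tal[tal$transcript_id == "t1", ]$n_proper_pairs, 2L)
  expect_equal(tal[tal$transcript_id == "t2", ]$n_proper_pairs, 1L)
  # non-proper alignments contribute nothing
  expect_equal(nrow(tally_orientation(empty_mappings <- read_sam_pairs(f)[0])), 0L)
})

test_that("SSLR arithmetic with the 0.5 pseudocount", {
  counts <- data.table::data.table(
    transcript_id = c("a", "b", "c"),
    n_read1_plus = c(4L, 0L, 16L), n_read2_plus = c(4L, 31L, 1L),
    n_proper_pairs = c(8L, 31L, 17L))
  s <- compute_sslr(counts)
  expect_equal(s$sslr, c(0, log2(0.5 / 31.5), log2(16.5 / 1.5)))
  expect_equal(round(s$sslr[2], 2), -5.98)
  expect_equal(round(s$sslr[3], 2), 3.46)
  expect_error(compute_sslr(counts, pseudocount = 0), "pseudocount")
})

test_that("SSLR is antisymmetric under count exchange", {
  set.seed(42)
  for (i in 1:50) {
    n1 <- sample(0:200, 1L); n2 <- sample(0:200, 1L)
    a <- data.table::data.table(transcript_id = "x", n_read1_plus = n1,
                                n_read2_plus = n2, n_proper_pairs = n1 + n2)
    b <- data.table::data.table(transcript_id = "x", n_read1_plus = n2,
                                n_read2_plus = n1, n_proper_pairs = n1 + n2)
    expect_equal(compute_sslr(a)$sslr, -compute_sslr(b)$sslr)
  }
})

test_that("support filter is inclusive at the threshold", {
  counts <- data.table::data.table(
    transcript_id = c("a", "b", "c"),
    n_read1_plus = 0L, n_read2_plus = 0L,
    n_proper_pairs = c(19L, 20L, 0L))
  d <- support_filter(counts)
  expect_equal(d$kept, c(FALSE, TRUE, FALSE))
  expect_equal(d$reason, c("low_support", "ok", "low_support"))
  expect_true(all(support_filter(counts, min_pairs = 0L)$kept))
  expect_error(support_filter(counts, min_pairs = -1L), "min_pairs")
})

test_that("coverage dips follow the adjacent-window fold rule", {
  # uniform depth: reads tile the transcript evenly
  m <- make_mappings(data.frame(
    transcript_id = "t", pos = seq(1L, 351L, by = 50L), cigar = "50M",
    seq = "*"))
  cp <- coverage_profile(m, 400L, window_bp = 100L)
  expect_equal(cp$n_dips, 0L)
  expect_equal(sum(cp$per_base_depth), 8L * 50L)

  # windows [100, 15]: ratio 6.7 > 5 -> one dip; [100, 25]: ratio 4 -> none
  deep <- make_mappings(data.frame(
    transcript_id = "t",
    pos = c(rep(1L, 100L), rep(101L, 15L)),
    cigar = "100M", seq = "*"))
  expect_equal(coverage_profile(deep, 200L)$n_dips, 1L)
  ok <- make_mappings(data.frame(
    transcript_id = "t",
    pos = c(rep(1L, 100L), rep(101L, 25L)),
    cigar = "100M", seq = "*"))
  expect_equal(coverage_profile(ok, 200L)$n_dips, 0L)
  expect_error(coverage_profile(ok, 0L), "positive")
})

test_that("dip count is invariant under uniform depth scaling", {
  set.seed(7)
  base <- data.frame(transcript_id = "t",
                     pos = sample(1:250, 40, replace = TRUE),
                     cigar = "50M", seq = "*")
  m1 <- make_mappings(base)
  m3 <- make_mappings(base[rep(1:40, each = 3), ])  # every read x3
  expect_equal(coverage_profile(m1, 300L)$n_dips,
               coverage_profile(m3, 300L)$n_dips)
})

test_that("per-base depth sums match brute-force accumulation", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1L)
    df <- data.frame(transcript_id = "t",
                     pos = sample(1:200, n, replace = TRUE),
                     cigar = replicate(n, random_cigar()), seq = "*")
    m <- make_mappings(df)
    cp <- coverage_profile(m, 400L)
    expected <- integer(400)
    for (j in seq_len(n)) {
      pp <- oracle_cigar_positions(df$cigar[j], df$pos[j])
      pp <- pp[pp >= 1 & pp <= 400]
      expected[pp] <- expected[pp] + 1L
    }
    expect_equal(cp$per_base_depth, expected)
    expect_equal(sum(cp$per_base_depth), sum(expected))
  }
})
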