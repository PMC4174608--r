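# leakage_filter: alternate-orientation pair detection and discard rules.

sslr_tab <- function(...) {
  v <- c(...)
  data.table::data.table(transcript_id = names(v), sslr = unname(v))
}

test_that("an exact reverse complement is found at overlap 1.0", {
  set.seed(5)
  s <- random_dna(1000)
  rec <- data.table::data.table(
    transcript_id = c("comp1_c0_seq1", "comp2_c0_seq1"),
    component_id = c("comp1_c0", "comp2_c0"),
    sequence = c(s, ssfilter::revcomp(s)), length_bp = 1000L)
  hits <- self_alternate_hits(rec)
  lens <- c(comp1_c0_seq1 = 1000L, comp2_c0_seq1 = 1000L)
  pairs <- find_alternate_orientation_pairs(
    hits, sslr_tab(comp1_c0_seq1 = -4, comp2_c0_seq1 = +4), lens)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap_fraction_of_shorter, 1.0)
  expect_equal(pairs$sense_id, "comp1_c0_seq1")
  expect_equal(pairs$antisense_id, "comp2_c0_seq1")
})

test_that("same-orientation matches are never emitted", {
  hits <- data.table::data.table(
    query_id = "a", subject_id = "b", pident = 100, align_len = 950L,
    mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = 950L,
    s_start = 1L, s_end = 950L, evalue = 1e-100, bitscore = 1900,
    q_len = 1000L, s_len = 1000L, db = "nucl_self")
  pairs <- find_alternate_orientation_pairs(
    hits, sslr_tab(a = -4, b = 4), c(a = 1000L, b = 1000L))
  expect_equal(nrow(pairs), 0L)
})

test_that("HSP intervals are unioned on the shorter member", {
  # reversed HSPs covering [1,500] and [400,850] of the 1000-bp shorter
  # member: union 850/1000 = 0.85 > 0.8
  hits <- data.table::rbindlist(list(
    data.table::data.table(query_id = "short", subject_id = "long",
                           pident = 95, align_len = 500L, mismatch = 0L,
                           gapopen = 0L, q_start = 1L, q_end = 500L,
                           s_start = 700L, s_end = 201L, evalue = 1e-90,
                           bitscore = 900, q_len = 1000L, s_len = 1100L,
                           db = "nucl_self"),
    data.table::data.table(query_id = "short", subject_id = "long",
                           pident = 95, align_len = 451L, mismatch = 0L,
                           gapopen = 0L, q_start = 400L, q_end = 850L,
                           s_start = 1000L, s_end = 550L, evalue = 1e-80,
                           bitscore = 880, q_len = 1000L, s_len = 1100L,
                           db = "nucl_self")))
  pairs <- find_alternate_orientation_pairs(
    hits, sslr_tab(short = 4, long = -4), c(short = 1000L, long = 1100L))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap_fraction_of_shorter, 0.85)
  # a single HSP covering [1,500] alone (0.5) stays below the gate
  pairs2 <- find_alternate_orientation_pairs(
    hits[1], sslr_tab(short = 4, long = -4), c(short = 1000L, long = 1100L))
  expect_equal(nrow(pairs2), 0L)
})

test_that("hits referencing unknown transcripts are skipped with a warning", {
  hits <- data.table::data.table(
    query_id = "a", subject_id = "ghost", pident = 100, align_len = 900L,
    mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = 900L,
    s_start = 900L, s_end = 1L, evalue = 1e-100, bitscore = 1800,
    q_len = 1000L, s_len = 1000L, db = "nucl_self")
  expect_warning(
    pairs <- find_alternate_orientation_pairs(hits, sslr_tab(a = -4),
                                              c(a = 1000L)),
    "unknown")
  expect_equal(nrow(pairs), 0L)
})

leak_pair <- function(sense_sslr, anti_sslr, len_sense, len_anti) {
  data.table::data.table(
    sense_id = "s", antisense_id = "a",
    overlap_fraction_of_shorter = 0.95,
    sense_sslr = sense_sslr, antisense_sslr = anti_sslr,
    length_ratio = len_anti / len_sense)
}

test_that("strict leakage rules fire only when all three conditions hold", {
  expect_equal(apply_leakage_rules(leak_pair(-4.0, 3.8, 1000, 990))$transcript_id,
               "a")
  expect_equal(nrow(apply_leakage_rules(leak_pair(-4.0, 1.0, 1000, 990))), 0L)
  expect_equal(nrow(apply_leakage_rules(leak_pair(-4.0, 3.8, 1000, 1200))), 0L)
  expect_equal(nrow(apply_leakage_rules(leak_pair(-2.0, 3.8, 1000, 990))), 0L)
  # boundary: 10% longer is still allowed (<=), beyond is not
  expect_equal(nrow(apply_leakage_rules(leak_pair(-4.0, 3.8, 1000, 1100))), 1L)
})

test_that("permissive mode discards on positive SSLR alone", {
  expect_equal(nrow(apply_leakage_rules(leak_pair(-1.0, 0.7, 1000, 990))), 0L)
  expect_equal(apply_leakage_rules(leak_pair(-1.0, 0.7, 1000, 990),
                                   mode = "permissive")$transcript_id, "a")
})

test_that("discards are idempotent and order-independent", {
  set.seed(9)
  s1 <- random_dna(800); s2 <- random_dna(700)
  rec <- data.table::data.table(
    transcript_id = c("w", "x", "y", "z"),
    component_id = c("c1", "c1", "c2", "c2"),
    sequence = c(s1, ssfilter::revcomp(s1), s2, ssfilter::revcomp(s2)),
    length_bp = c(800L, 800L, 700L, 700L))
  lens <- stats::setNames(rec$length_bp, rec$transcript_id)
  st <- sslr_tab(w = -4, x = 4, y = 3.9, z = -3.2)
  run <- function(r) {
    hits <- self_alternate_hits(r)
    apply_leakage_rules(
      find_alternate_orientation_pairs(hits, st, lens))
  }
  d1 <- run(rec)
  expect_setequal(d1$transcript_id, c("x", "y"))
  # permuting input order changes nothing
  d2 <- run(rec[c(3, 1, 4, 2)])
  expect_setequal(d2$transcript_id, d1$transcript_id)
  # rerunning on the survivors removes nothing further
  d3 <- run(rec[!rec$transcript_id %in% d1$transcript_id])
  expect_equal(nrow(d3), 0L)
})
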