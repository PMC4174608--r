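# representative_scoring: Table-of-weights metrics, selection, LCA.

mk_hit <- function(q_start, q_end, s_start, s_end, s_len, evalue = 1e-50) {
  data.frame(q_start = q_start, q_end = q_end, s_start = s_start,
             s_end = s_end, s_len = s_len, evalue = evalue)
}

ideal_evidence <- function() {
  # both hits cover 100% of subject and query, plus-strand matches,
  # longest in component, sslr = -max|SSLR|, one plus ORF, no dips
  list(transcript_id = "comp1_c0_seq1", component_id = "comp1_c0",
       length_bp = 900L, sslr = -4, n_dips = 0L,
       uniref_hit = mk_hit(1L, 900L, 1L, 300L, 300L),
       nr_hit = mk_hit(1L, 900L, 1L, 300L, 300L),
       orfs = data.frame(strand = "+", best_subject = "P1",
                         has_nr_hit = TRUE))
}

bare_evidence <- function() {
  # no hits, no ORFs, longest in component, sslr = -max|SSLR|, no dips
  list(transcript_id = "comp1_c0_seq1", component_id = "comp1_c0",
       length_bp = 900L, sslr = -4, n_dips = 0L,
       uniref_hit = NULL, nr_hit = NULL, orfs = NULL)
}

test_that("the ideal transcript scores exactly 85, the analytic maximum", {
  ev <- ideal_evidence()
  ctx <- component_context(list(ev))
  sb <- score_transcript(ev, ctx)
  expect_equal(sb$aggregate_score, 85)
  mcols <- grep("^m_", names(sb), value = TRUE)
  expect_equal(unname(unlist(sb[, mcols, with = FALSE])),
               c(rep(1, 12), 0, 0, 0, 0, 0, 1, 0),
               tolerance = 1e-12)
})

test_that("a hit-less, ORF-less best-in-component transcript scores exactly 14", {
  ev <- bare_evidence()
  ctx <- component_context(list(ev))
  sb <- score_transcript(ev, ctx)
  expect_equal(sb$aggregate_score, 14)  # A11 (7) + A12 (7) only
  sb[, length_bp := 900L]
  sel <- select_representatives(sb, min_score = 14)
  expect_false(sel$kept)               # strict > 14
})

test_that("opposite-strand ORFs with NR hits draw the b2 and b1 penalties", {
  ev <- bare_evidence()
  ev$orfs <- data.frame(strand = c("+", "-"),
                        best_subject = c("P1", "P2"),
                        has_nr_hit = c(TRUE, TRUE))
  ctx <- component_context(list(ev))
  sb <- score_transcript(ev, ctx)
  expect_equal(sb$m_b2, -1)            # balanced strands, both with hits
  expect_equal(sb$m_b1, (1 - 2) / 2)   # two distinct best subjects
  expect_equal(sb$m_b5, (1 - 2) / 2)
  expect_equal(sb$m_b6, 0)             # mixed strands
  # contributions: b2 x (-1) = -10 and b1 x (-1/2) = -5
  w <- score_weights()
  expect_equal(sb$aggregate_score,
               14 + w[["b2"]] * -1 + w[["b1"]] * -0.5 + w[["b5"]] * -0.5)
})

test_that("score_transcript agrees with the naive oracle on 200 random bundles", {
  set.seed(1009)
  w <- score_weights()
  for (i in 1:200) {
    n_members <- sample(1:4, 1L)
    evs <- lapply(seq_len(n_members), function(k)
      random_evidence(tid = sprintf("comp1_c0_seq%d", k)))
    ctx <- component_context(evs)
    for (ev in evs) {
      got <- score_transcript(ev, ctx)$aggregate_score
      want <- oracle_score(ev, ctx, w)
      expect_equal(got, want, tolerance = 1e-9)
      expect_lte(got, 85 + 1e-9)
    }
  }
})

test_that("increasing first-hit subject coverage never lowers the aggregate", {
  set.seed(31)
  for (i in 1:30) {
    ev <- random_evidence()
    if (is.null(ev$uniref_hit)) next
    ctx <- component_context(list(ev))
    base <- score_transcript(ev, ctx)$aggregate_score
    ev2 <- ev
    ev2$uniref_hit$s_end <- ev2$uniref_hit$s_len       # full subject coverage
    ev2$uniref_hit$s_start <- 1L
    ctx2 <- component_context(list(ev2))
    expect_gte(score_transcript(ev2, ctx2)$aggregate_score, base - 1e-9)
  }
})

test_that("context and evidence must belong to the same component", {
  ev <- bare_evidence()
  other <- bare_evidence(); other$component_id <- "comp2_c0"
  other$transcript_id <- "comp2_c0_seq1"
  ctx2 <- component_context(list(other))
  expect_error(score_transcript(ev, ctx2), "component")
  expect_error(component_context(list(ev, other)), "multiple components")
})

test_that("selection keeps at most one transcript per component, argmax first", {
  sc <- data.table::data.table(
    transcript_id = c("comp1_c0_seq1", "comp1_c0_seq2",
                      "comp2_c0_seq1", "comp2_c0_seq2",
                      "comp3_c0_seq1"),
    component_id = c("comp1_c0", "comp1_c0", "comp2_c0", "comp2_c0",
                     "comp3_c0"),
    aggregate_score = c(85, 40, 30, 30, 14),
    length_bp = c(900L, 500L, 900L, 1200L, 700L))
  sel <- select_representatives(sc)
  expect_equal(nrow(sel), 3L)
  expect_equal(sel[component_id == "comp1_c0", transcript_id], "comp1_c0_seq1")
  # tie 30/30 broken by the longer transcript
  expect_equal(sel[component_id == "comp2_c0", transcript_id], "comp2_c0_seq2")
  # best score exactly 14 contributes nothing
  expect_false(sel[component_id == "comp3_c0", kept])
  # stable under input permutation
  sel2 <- select_representatives(sc[sample(nrow(sc))])
  data.table::setorder(sel, component_id)
  data.table::setorder(sel2, component_id)
  expect_equal(sel, sel2)
})

test_that("LCA aggregates ties at the minimal e-value", {
  tax <- list(parent = c(root = "root", euk = "root", bact = "root",
                         genusG = "euk", spX = "genusG", spY = "genusG",
                         spB = "bact"))
  hit <- function(taxon, evalue) data.table::data.table(
    query_id = "q", subject_id = taxon, evalue = evalue,
    subject_taxon = taxon)
  expect_equal(lca_assign(hit("spX", 1e-40), tax), "spX")
  # tied siblings resolve to their genus; the worse hit is ignored
  h <- rbind(hit("spX", 1e-40), hit("spY", 1e-40), hit("spB", 1e-20))
  expect_equal(lca_assign(h, tax), "genusG")
  # best hits spanning both domains resolve to the root
  h2 <- rbind(hit("spX", 1e-40), hit("spB", 1e-40))
  expect_equal(lca_assign(h2, tax), "root")
  # unknown taxa are dropped with a warning; all-dropped is unassigned
  h3 <- rbind(hit("spX", 1e-40), hit("ghost", 1e-40))
  expect_warning(r <- lca_assign(h3, tax), "absent")
  expect_equal(r, "spX")
  expect_warning(r2 <- lca_assign(hit("ghost", 1e-10), tax), "absent")
  expect_true(is.na(r2))
  # lca_table assigns per query
  lt <- lca_table(rbind(hit("spX", 1e-40), hit("spY", 1e-40)), tax)
  expect_equal(lt$lca_taxon, "genusG")
})
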