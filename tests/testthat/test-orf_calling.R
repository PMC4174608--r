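# orf_calling: six-frame discovery, strand restriction, reconciliation.

# 300-bp ORF: ATG + 98 non-stop codons + TAA
make_orf300 <- function() {
  set.seed(301)
  paste0("ATG", rand_nostop(98), "TAA")
}
rand_nostop <- function(n) {
  cods <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  cods <- setdiff(cods, c("TAA", "TAG", "TGA"))
  paste(sample(cods, n, replace = TRUE), collapse = "")
}

test_that("a clean 300-bp ORF is found once, with strand symmetry", {
  s <- make_orf300()
  expect_equal(nchar(s), 300L)
  o <- find_orfs_sixframe(s)
  expect_equal(nrow(o), 1L)
  expect_equal(o$strand, "+")
  expect_equal(o$length_bp, 300L)
  expect_equal(c(o$start, o$end), c(1L, 300L))
  expect_false(o$partial)
  orc <- find_orfs_sixframe(ssfilter::revcomp(s))
  expect_equal(nrow(orc), 1L)
  expect_equal(orc$strand, "-")
  expect_equal(orc$length_bp, 300L)
  expect_equal(c(orc$start, orc$end), c(1L, 300L))
})

test_that("sequences without start/stop structure yield no ORFs", {
  expect_equal(nrow(find_orfs_sixframe(strrep("A", 500))), 0L)
  expect_equal(nrow(find_orfs_sixframe("ACGT")), 0L)
  expect_error(find_orfs_sixframe("ACGT", min_len = 100L), "divisible")
  expect_error(find_orfs_sixframe("ACGT", min_len = 0L), "divisible")
})

test_that("stop_to_stop mode reports inter-stop segments without ATG", {
  set.seed(77)
  s <- paste0(rand_nostop(100), "TAA")  # 303 bp, no guaranteed ATG start
  o <- find_orfs_sixframe(s, mode = "stop_to_stop")
  expect_true(nrow(o) >= 1L)
  expect_true(all(o$length_bp %% 3L == 0L))
  expect_true(all(o$mode == "stop_to_stop"))
})

test_that("six-frame finder agrees with the brute-force codon scan", {
  set.seed(601)
  for (i in 1:200) {
    s <- random_dna(sample(100:1500, 1L), gc = runif(1, 0.2, 0.6))
    got <- find_orfs_sixframe(s, min_len = 99L)
    want <- oracle_orfs(s, min_len = 99L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
      expect_equal(got$length_bp, want$length_bp)
      expect_equal(got$partial, want$partial)
    }
  }
})

test_that("strand_restrict keeps the longest ORF's strand, plus on ties", {
  o <- data.table::data.table(
    transcript_id = "t", start = c(1L, 50L), end = c(600L, 349L),
    strand = c("+", "-"), frame = 0L, length_bp = c(600L, 300L),
    partial = FALSE, mode = "start_to_stop", source = "builtin_sixframe")
  expect_equal(strand_restrict(o)$strand, "+")
  expect_equal(strand_restrict(o[strand == "-"]), o[strand == "-"])
  tie <- data.table::copy(o)[, length_bp := 600L]
  expect_equal(unique(strand_restrict(tie)$strand), "+")
  # with a positive SSLR the predicted sense strand (minus) wins the tie
  expect_equal(unique(strand_restrict(tie, sslr = 3)$strand), "-")
  expect_equal(unique(strand_restrict(tie, sslr = -3)$strand), "+")
})

orf_row <- function(start, end, strand = "+", source = "builtin_sixframe") {
  data.table::data.table(
    transcript_id = "t", start = start, end = end, strand = strand,
    frame = 0L, length_bp = end - start + 1L, partial = FALSE,
    mode = "start_to_stop", source = source)
}

test_that("reconciliation admits priority plus, then minus, then builtin", {
  # priority plus [1,600] suppresses overlapping priority minus [100,500]
  out <- reconcile_orfs(rbind(orf_row(1L, 600L, "+"), orf_row(100L, 500L, "-")),
                        orf_row(1L, 300L)[0])
  expect_equal(nrow(out), 1L)
  expect_equal(out$strand, "+")
  # disjoint builtin is admitted alongside priority
  out2 <- reconcile_orfs(orf_row(1L, 300L, "+"), orf_row(400L, 900L, "+"))
  expect_equal(nrow(out2), 2L)
  # two builtins overlapping 60% of the shorter: only the longer survives
  b1 <- orf_row(1L, 600L); b2 <- orf_row(421L, 720L)  # share 180/300 = 60%
  out3 <- reconcile_orfs(b1[0], rbind(b1, b2))
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$end, 600L)
  # at exactly 50% of the shorter, both are kept (strict >)
  b3 <- orf_row(451L, 750L)  # share 150/300 = 50%
  expect_equal(nrow(reconcile_orfs(b1[0], rbind(b1, b3))), 2L)
})

test_that("reconciliation output never violates the overlap rule", {
  set.seed(88)
  for (rep in 1:25) {
    n <- sample(2:6, 1L)
    st <- sample(1:900, n) ; en <- pmin(1200L, st + 3L * sample(34:160, n))
    pri <- orf_row(1L, 3L)[0]
    blt <- data.table::rbindlist(lapply(seq_len(n), function(i)
      orf_row(st[i], en[i], sample(c("+", "-"), 1L))))
    out <- reconcile_orfs(pri, blt)
    if (nrow(out) >= 2L) {
      for (i in 1:(nrow(out) - 1L)) for (j in (i + 1L):nrow(out)) {
        shared <- max(0L, min(out$end[i], out$end[j]) -
                        max(out$start[i], out$start[j]) + 1L)
        expect_lte(shared, 0.5 * min(out$length_bp[i], out$length_bp[j]))
      }
    }
    # admission is deterministic under permutation
    out_perm <- reconcile_orfs(pri, blt[sample(nrow(blt))])
    data.table::setorder(out, start, strand)
    data.table::setorder(out_perm, start, strand)
    expect_equal(out, out_perm)
  }
})

test_that("ORF peptides translate the admitted frame", {
  s <- paste0("ATGAAATTTGGG", "TAA")   # M K F G *
  rec <- data.table::data.table(transcript_id = "comp1_c0_seq1",
                                component_id = "comp1_c0",
                                sequence = s, length_bp = nchar(s))
  o <- find_orfs_sixframe(s, min_len = 15L, transcript_id = "comp1_c0_seq1")
  pep <- orf_peptides(o, rec)
  expect_equal(pep$peptide, "MKFG")
})
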