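# Six-frame ORF discovery and reconciliation.
#
# ORF coordinates are reported on the transcript with start < end always;
# the strand column carries the reading orientation. Lengths include the
# stop codon and are codon-granular (divisible by 3).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' Scans both strands in all three frames for maximal qualifying ORFs of at
#' least `min_len` bases. In `start_to_stop` mode an ORF runs from the
#' first ATG after the previous stop to the next stop codon (inclusive);
#' if the reading frame ends before a stop the ORF runs to the sequence
#' edge and is flagged partial. In `stop_to_stop` mode every inter-stop
#' segment qualifies regardless of a start codon.
#'
#' @param seq nucleotide sequence (A/C/G/T/N).
#' @param min_len minimum ORF length in bp, divisible by 3 (includes the
#'   stop codon when present).
#' @param mode `"start_to_stop"` (default) or `"stop_to_stop"`.
#' @param transcript_id optional id attached to the output rows.
#' @param source source tag (`"builtin_sixframe"` for this finder).
#' @return a `data.table` of ORF calls ordered by (start, strand):
#'   `transcript_id`, `start`, `end`, `strand`, `frame`, `length_bp`,
#'   `partial`, `mode`, `source`.
#' @export
find_orfs_sixframe <- function(seq, min_len = 300L,
                               mode = c("start_to_stop", "stop_to_stop"),
                               transcript_id = NA_character_,
                               source = "builtin_sixframe") {
  mode <- match.arg(mode)
  if (min_len < 3L || min_len %% 3L != 0L) {
    stop_config("min_len must be >= 3 and divisible by 3")
  }
  L <- nchar(seq)
  out <- list()
  if (L >= min_len) {
    for (str in c("+", "-")) {
      s <- if (str == "+") seq else revcomp(seq)
      for (fr in 0:2) {
        n_cod <- (L - fr) %/% 3L
        if (n_cod * 3L < min_len) next
        cs <- fr + 1L + 3L * (0:(n_cod - 1L))
        codons <- substring(s, cs, cs + 2L)
        orfs <- scan_frame(codons, mode)
        if (is.null(orfs)) next
        for (r in seq_len(nrow(orfs))) {
          a_cod <- orfs[r, 1L]; b_cod <- orfs[r, 2L]
          len <- 3L * (b_cod - a_cod + 1L)
          if (len < min_len) next
          a <- cs[a_cod]                # 1-based on reading strand
          b <- cs[b_cod] + 2L
          if (str == "+") {
            st <- a; en <- b
          } else {
            st <- L - b + 1L; en <- L - a + 1L
          }
          out[[length(out) + 1L]] <- data.table(
            transcript_id = transcript_id, start = st, end = en,
            strand = str, frame = fr, length_bp = len,
            partial = orfs[r, 3L] == 1L, mode = mode, source = source
          )
        }
      }
    }
  }
  if (!length(out)) return(empty_orfs(mode))
  res <- rbindlist(out)
  setorder(res, start, strand, frame)
  res[]
}

# Scan one frame's codon vector; returns matrix [first_codon, last_codon,
# partial] in codon indices, or NULL. Codons containing N never match ATG
# nor a stop (conservative).
scan_frame <- function(codons, mode) {
  is_stop <- codons %in% STOP_CODONS
  stops <- which(is_stop)
  n <- length(codons)
  segs <- list()
  seg_start <- 1L
  for (sp in c(stops, NA_integer_)) {
    if (is.na(sp)) {
      if (seg_start <= n) segs[[length(segs) + 1L]] <- c(seg_start, n, 1L)
      break
    }
    if (sp >= seg_start) segs[[length(segs) + 1L]] <- c(seg_start, sp, 0L)
    seg_start <- sp + 1L
  }
  rows <- list()
  for (sg in segs) {
    a <- sg[1L]; b <- sg[2L]; partial <- sg[3L]
    if (mode == "start_to_stop") {
      atg <- which(codons[a:b] == "ATG")
      if (!length(atg)) next
      rows[[length(rows) + 1L]] <- c(a + atg[1L] - 1L, b, partial)
    } else {
      rows[[length(rows) + 1L]] <- c(a, b, partial)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

empty_orfs <- function(mode = "start_to_stop") {
  data.table(transcript_id = character(0), start = integer(0),
             end = integer(0), strand = character(0), frame = integer(0),
             length_bp = integer(0), partial = logical(0),
             mode = character(0), source = character(0))
}

#' Restrict ORFs to the strand of the longest ORF
#'
#' Applied to the built-in six-frame calls before reconciliation: only the
#' ORFs on the strand carrying the longest ORF survive. A tie between
#' strands is broken by the strand the SSLR predicts as sense (plus for
#' negative SSLR) when one is supplied, else by the plus strand.
#'
#' @param orfs ORF table for one transcript.
#' @param sslr optional SSLR value used for the tie-break.
#' @return the surviving subset of `orfs`.
#' @export
strand_restrict <- function(orfs, sslr = NULL) {
  if (!nrow(orfs)) return(orfs)
  best_plus <- suppressWarnings(max(orfs$length_bp[orfs$strand == "+"], -Inf))
  best_minus <- suppressWarnings(max(orfs$length_bp[orfs$strand == "-"], -Inf))
  keep_strand <- if (best_plus > best_minus) {
    "+"
  } else if (best_minus > best_plus) {
    "-"
  } else if (!is.null(sslr) && !is.na(sslr) && sslr > 0) {
    "-"   # positive SSLR predicts the minus strand as sense
  } else {
    "+"
  }
  orfs[orfs$strand == keep_strand, ]
}

#' Reconcile externally predicted and built-in ORFs
#'
#' Ordered admission mirroring the published priority: (1) priority
#' (externally predicted) plus-strand ORFs; (2) priority minus-strand ORFs
#' not overlapping anything admitted; (3) built-in ORFs on any strand not
#' overlapping anything admitted. Two ORFs overlap when their shared span
#' exceeds `overlap_frac` of the shorter ORF's length; within each
#' admission group candidates are taken longest-first so that of two
#' mutually overlapping ORFs only the longer is retained.
#'
#' @param priority_orfs externally predicted ORF table (may be empty).
#' @param builtin_orfs built-in six-frame ORF table (may be empty).
#' @param overlap_frac overlap threshold as a fraction of the shorter ORF.
#' @return admitted ORF `data.table` ordered by (start, strand).
#' @export
reconcile_orfs <- function(priority_orfs, builtin_orfs, overlap_frac = 0.5) {
  pri <- data.table::as.data.table(priority_orfs)
  blt <- data.table::as.data.table(builtin_orfs)
  if (nrow(pri)) pri[, source := "priority_external"]
  groups <- list(
    if (nrow(pri)) pri[strand == "+"] else pri,
    if (nrow(pri)) pri[strand == "-"] else pri,
    blt
  )
  admitted <- empty_orfs()
  for (g in groups) {
    if (is.null(g) || !nrow(g)) next
    g <- g[order(-length_bp, start, strand)]
    for (i in seq_len(nrow(g))) {
      cand <- g[i]
      ok <- TRUE
      if (nrow(admitted)) {
        for (j in seq_len(nrow(admitted))) {
          shared <- interval_overlap(cand$start, cand$end,
                                     admitted$start[j], admitted$end[j])
          shorter <- min(cand$length_bp, admitted$length_bp[j])
          if (shared > overlap_frac * shorter) { ok <- FALSE; break }
        }
      }
      if (ok) admitted <- rbindlist(list(admitted, cand), fill = TRUE)
    }
  }
  if (nrow(admitted)) setorder(admitted, start, strand)
  admitted[]
}

#' Translate admitted ORFs to peptides
#'
#' @param orfs ORF table with `transcript_id`, `start`, `end`, `strand`.
#' @param records transcript table from [read_fasta()].
#' @return a `data.table` with `orf_id` and `peptide` (terminal stop, when
#'   present, trimmed).
#' @export
orf_peptides <- function(orfs, records) {
  if (!nrow(orfs)) return(data.table(orf_id = character(0), peptide = character(0)))
  seqs <- stats::setNames(records$sequence, records$transcript_id)
  ids <- if ("orf_id" %in% names(orfs)) orfs$orf_id else
    sprintf("%s.orf%d", orfs$transcript_id, seq_len(nrow(orfs)))
  pep <- vapply(seq_len(nrow(orfs)), function(i) {
    s <- substring(seqs[[orfs$transcript_id[i]]], orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") s <- revcomp(s)
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                            if.fuzzy.codon = "solve"))
    sub("\\*$", "", p)
  }, "")
  data.table(orf_id = ids, peptide = pep)
}

utils::globalVariables(c("length_bp", "start", "source"))
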