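# Antisense "leakage" duplicate detection and removal.
#
# Imperfect second-strand degradation in a dUTP library lets a fraction of
# fragments be sequenced in flipped orientation; assembled, these create a
# reverse-complement twin of a genuine sense transcript. A twin is
# recognizable by (a) matching the sense transcript in alternate
# orientation over >80% of the shorter member, (b) a strongly negative
# SSLR on the sense member and a positive one on the twin, and (c) about
# the same or shorter length.

#' Find transcript pairs matching in alternate orientation
#'
#' Consumes self-vs-self nucleotide hits (all-vs-all BLASTN outfmt 6, or
#' the built-in fallback of [self_alternate_hits()]), merges the HSP
#' intervals of each transcript pair on its shorter member, and emits the
#' pairs whose reversed-orientation overlap exceeds `min_overlap` of the
#' shorter member's length.
#'
#' @param hits nucleotide hit table (`db = "nucl_self"` dialect; self-hits
#'   with `query_id == subject_id` are ignored).
#' @param sslr_table table with `transcript_id` and `sslr` columns.
#' @param transcript_lens named integer vector of transcript lengths.
#' @param min_overlap minimum union-overlap fraction of the shorter member.
#' @param max_evalue hit e-value cutoff (the published screen used 1e-5).
#' @return a `data.table` of candidate pairs: `sense_id` (lower-SSLR
#'   member), `antisense_id`, `overlap_fraction_of_shorter`, `sense_sslr`,
#'   `antisense_sslr`, `length_ratio` (antisense/sense length).
#' @export
find_alternate_orientation_pairs <- function(hits, sslr_table, transcript_lens,
                                             min_overlap = 0.80,
                                             max_evalue = 1e-5) {
  empty <- data.table(
    sense_id = character(0), antisense_id = character(0),
    overlap_fraction_of_shorter = numeric(0), sense_sslr = numeric(0),
    antisense_sslr = numeric(0), length_ratio = numeric(0)
  )
  if (!nrow(hits)) return(empty)
  h <- hits[query_id != subject_id & evalue <= max_evalue]
  known <- h$query_id %in% names(transcript_lens) &
    h$subject_id %in% names(transcript_lens)
  if (any(!known)) {
    warning(sprintf("find_alternate_orientation_pairs: %d hit(s) referencing unknown transcripts skipped",
                    sum(!known)), call. = FALSE)
    h <- h[known]
  }
  # alternate orientation: exactly one side's coordinates are reversed
  rev_q <- h$q_start > h$q_end
  rev_s <- h$s_start > h$s_end
  h <- h[xor(rev_q, rev_s)]
  if (!nrow(h)) return(empty)
  sslr <- stats::setNames(sslr_table$sslr, sslr_table$transcript_id)
  # canonical unordered pair key so (A,B) and (B,A) merge
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  h[, pair_key := paste(a, b, sep = "\r")]
  pairs <- h[, {
    qa <- query_id[1L]; sb <- subject_id[1L]
    len_q <- transcript_lens[[qa]]; len_s <- transcript_lens[[sb]]
    # collect intervals on the shorter member of THIS pair; rows may have
    # query/subject swapped relative to each other
    ids <- sort(c(qa, sb))
    short_id <- ids[which.min(c(transcript_lens[[ids[1L]]],
                                transcript_lens[[ids[2L]]]))]
    iv <- lapply(seq_len(.N), function(i) {
      if (query_id[i] == short_id) {
        c(min(q_start[i], q_end[i]), max(q_start[i], q_end[i]))
      } else {
        c(min(s_start[i], s_end[i]), max(s_start[i], s_end[i]))
      }
    })
    iv <- do.call(rbind, iv)
    ov <- interval_union_length(iv) / transcript_lens[[short_id]]
    .(member_a = ids[1L], member_b = ids[2L], overlap = ov)
  }, by = pair_key]
  pairs <- pairs[overlap > min_overlap]
  if (!nrow(pairs)) return(empty)
  out <- pairs[, {
    sa <- sslr[[member_a]] %||% NA_real_
    sb2 <- sslr[[member_b]] %||% NA_real_
    if (is.na(sa) || is.na(sb2)) {
      sense <- member_a; anti <- member_b
    } else if (sa <= sb2) {
      sense <- member_a; anti <- member_b
    } else {
      sense <- member_b; anti <- member_a
    }
    .(sense_id = sense, antisense_id = anti,
      overlap_fraction_of_shorter = overlap,
      sense_sslr = sslr[[sense]] %||% NA_real_,
      antisense_sslr = sslr[[anti]] %||% NA_real_,
      length_ratio = transcript_lens[[anti]] / transcript_lens[[sense]])
  }, by = pair_key]
  out[, pair_key := NULL]
  out[]
}

#' Apply the leakage discard rules to candidate pairs
#'
#' Under the strict (default) rule the positive-SSLR member of a pair is
#' discarded iff the other member's SSLR is below `sslr_neg_max`, its own
#' SSLR is above `sslr_pos_min`, and it is at most `max_len_excess` longer
#' than the sense member. The permissive mode discards any
#' alternate-orientation member with positive SSLR paired to a
#' non-positive one. Decisions are idempotent: a transcript discarded once
#' is never re-examined.
#'
#' @param pairs candidate pairs from [find_alternate_orientation_pairs()].
#' @param sslr_neg_max sense-member SSLR upper bound (default -2.5).
#' @param sslr_pos_min antisense-member SSLR lower bound (default +1.5).
#' @param max_len_excess maximum relative length excess of the antisense
#'   member (default 0.10, i.e. "<10% difference in length").
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return a `data.table` with one row per discarded transcript:
#'   `transcript_id`, `paired_with`, `reason`, plus the pair evidence.
#' @export
apply_leakage_rules <- function(pairs, sslr_neg_max = -2.5,
                                sslr_pos_min = 1.5, max_len_excess = 0.10,
                                mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  empty <- data.table(transcript_id = character(0), paired_with = character(0),
                      reason = character(0),
                      sense_sslr = numeric(0), antisense_sslr = numeric(0),
                      overlap_fraction_of_shorter = numeric(0),
                      length_ratio = numeric(0))
  if (!nrow(pairs)) return(empty)
  trig <- if (mode == "strict") {
    !is.na(pairs$sense_sslr) & !is.na(pairs$antisense_sslr) &
      pairs$sense_sslr < sslr_neg_max &
      pairs$antisense_sslr > sslr_pos_min &
      pairs$length_ratio <= 1 + max_len_excess
  } else {
    !is.na(pairs$antisense_sslr) & pairs$antisense_sslr > 0 &
      !is.na(pairs$sense_sslr) & pairs$sense_sslr <= 0
  }
  hit <- pairs[trig]
  if (!nrow(hit)) return(empty)
  out <- hit[, .(transcript_id = antisense_id, paired_with = sense_id,
                 reason = "leakage_antisense",
                 sense_sslr, antisense_sslr,
                 overlap_fraction_of_shorter, length_ratio)]
  unique(out, by = "transcript_id")
}

#' Built-in alternate-orientation detector
#'
#' Hermetic fallback used when no external all-vs-all BLASTN table is
#' supplied: exact k-mer seeding of each transcript against the reverse
#' complements of the others, with greedy ungapped extension of seeds into
#' matched intervals. Emits hits in the `nucl_self` tabular dialect so the
#' downstream pair logic is shared with the BLASTN path.
#'
#' @param records transcript table from [read_fasta()].
#' @param k seed length (exact match).
#' @return hit `data.table` in the [read_blast_tab()] layout
#'   (`db = "nucl_self"`), with reversed subject coordinates for
#'   alternate-orientation matches.
#' @export
self_alternate_hits <- function(records, k = 16L) {
  n <- nrow(records)
  if (n < 2L) return(empty_hits("nucl_self"))
  seqs <- records$sequence
  ids <- records$transcript_id
  lens <- records$length_bp
  # index: k-mer -> transcript rows containing it (forward orientation)
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  }
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (km in kmers_of(seqs[i])) {
      assign(km, c(get0(km, envir = idx, ifnotfound = integer(0)), i),
             envir = idx)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    rc <- revcomp(seqs[i])
    cand <- integer(0)
    for (km in kmers_of(rc)) {
      cand <- c(cand, get0(km, envir = idx, ifnotfound = integer(0)))
    }
    cand <- setdiff(unique(cand), i)
    cand <- cand[cand > i]  # each unordered pair examined once
    for (j in cand) {
      iv <- matched_intervals(rc, seqs[j], k)
      if (is.null(iv)) next
      # iv: intervals on seqs[j]; mirror to coordinates on transcript i
      for (r in seq_len(nrow(iv))) {
        js <- iv[r, 1L]; je <- iv[r, 2L]; qs <- iv[r, 3L]; qe <- iv[r, 4L]
        # positions qs..qe on rc(i) map to lens[i]-qe+1 .. lens[i]-qs+1 on i
        rows[[length(rows) + 1L]] <- data.table(
          query_id = ids[i], subject_id = ids[j], pident = 100,
          align_len = je - js + 1L, mismatch = 0L, gapopen = 0L,
          q_start = lens[i] - qe + 1L, q_end = lens[i] - qs + 1L,
          s_start = je, s_end = js,     # reversed: alternate orientation
          evalue = 1e-180, bitscore = 2 * (je - js + 1L),
          q_len = lens[i], s_len = lens[j], db = "nucl_self"
        )
      }
    }
  }
  if (!length(rows)) return(empty_hits("nucl_self"))
  rbindlist(rows)
}

# Greedy ungapped matched intervals between strings a and b from shared
# k-mer seeds. Returns matrix [b_start, b_end, a_start, a_end] or NULL.
matched_intervals <- function(a, b, k) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k) return(NULL)
  akm <- substring(a, 1:(la - k + 1L), k:la)
  bkm <- substring(b, 1:(lb - k + 1L), k:lb)
  common <- intersect(akm, bkm)
  if (!length(common)) return(NULL)
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  seen <- matrix(FALSE, nrow = 0, ncol = 0)  # placeholder
  done_b <- logical(lb)
  ivs <- list()
  for (km in common) {
    pa <- which(akm == km)
    pb <- which(bkm == km)
    for (i0 in pa) {
      for (j0 in pb) {
        if (done_b[j0]) next
        # extend left
        di <- 0L
        while (i0 - di - 1L >= 1L && j0 - di - 1L >= 1L &&
               ac[i0 - di - 1L] == bc[j0 - di - 1L]) di <- di + 1L
        # extend right
        dr <- k - 1L
        while (i0 + dr + 1L <= la && j0 + dr + 1L <= lb &&
               ac[i0 + dr + 1L] == bc[j0 + dr + 1L]) dr <- dr + 1L
        ivs[[length(ivs) + 1L]] <-
          c(j0 - di, j0 + dr, i0 - di, i0 + dr)
        done_b[pmax(1L, j0 - di):pmin(lb, j0 + dr)] <- TRUE
      }
    }
  }
  if (!length(ivs)) return(NULL)
  unique(do.call(rbind, ivs))
}

utils::globalVariables(c("pair_key", "overlap", "member_a", "member_b",
                         "q_start", "q_end", "s_start", "s_end",
                         "sense_id", "antisense_id", "sense_sslr",
                         "antisense_sslr", "overlap_fraction_of_shorter",
                         "length_ratio", "paired_with"))
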