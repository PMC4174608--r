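# Strand-specificity (SSLR), read-pair support, and coverage profiling.
#
# Under the dUTP protocol the second-in-pair read of a proper pair maps on
# the sense (plus) strand of the mRNA, so genuine sense transcripts have a
# negative SSLR and antisense artifacts a positive one.

#' Tally proper-pair orientations per transcript
#'
#' Counts, for every transcript, the proper pairs whose first-in-pair read
#' mapped on the plus strand and those whose second-in-pair read did. Each
#' proper pair contributes once per (read, transcript) combination, so a
#' multi-mapped pair is counted once on every transcript it aligns to.
#'
#' @param mappings alignment table from [read_sam_pairs()].
#' @return a `data.table` with columns `transcript_id`, `n_read1_plus`,
#'   `n_read2_plus`, `n_proper_pairs`.
#' @export
tally_orientation <- function(mappings) {
  empty <- data.table(transcript_id = character(0), n_read1_plus = integer(0),
                      n_read2_plus = integer(0), n_proper_pairs = integer(0))
  if (!nrow(mappings)) return(empty)
  m <- mappings[proper == TRUE,
                .(transcript_id, read_id, mate, strand)]
  if (!nrow(m)) return(empty)
  m <- unique(m, by = c("transcript_id", "read_id", "mate"))
  # orient each pair by its first-in-pair mate; fall back to the mate-2
  # record (FR orientation: read1 plus <=> read2 minus) if mate 1 is absent
  m1 <- m[mate == 1L, .(transcript_id, read_id, s1 = strand)]
  m2 <- m[mate == 2L, .(transcript_id, read_id, s2 = strand)]
  pair <- merge(m1, m2, by = c("transcript_id", "read_id"), all = TRUE)
  pair[, r1_plus := ifelse(!is.na(s1), s1 == "+", s2 == "-")]
  pair[, r2_plus := ifelse(!is.na(s2), s2 == "+", s1 == "-")]
  out <- pair[, .(
    n_read1_plus = sum(r1_plus),
    n_read2_plus = sum(r2_plus),
    n_proper_pairs = .N
  ), by = transcript_id]
  setorder(out, transcript_id)
  out[]
}

#' Strand-specific log ratio (SSLR)
#'
#' `sslr = log2((n_read1_plus + pseudocount) / (n_read2_plus + pseudocount))`.
#' The symmetric pseudocount keeps the ratio finite for zero counts and
#' makes the statistic exactly antisymmetric under count exchange.
#'
#' @param counts orientation counts from [tally_orientation()].
#' @param pseudocount positive pseudocount added to both counts.
#' @return `counts` with an added `sslr` column.
#' @export
compute_sslr <- function(counts, pseudocount = 0.5) {
  if (pseudocount <= 0) stop_config("pseudocount must be > 0")
  out <- data.table::copy(data.table::as.data.table(counts))
  out[, sslr := log2((n_read1_plus + pseudocount) / (n_read2_plus + pseudocount))]
  out[]
}

#' Read-pair support filter
#'
#' Keeps transcripts supported by at least `min_pairs` proper read pairs
#' (inclusive threshold; the published cutoff of 20 pairs is the default).
#'
#' @param counts orientation counts from [tally_orientation()].
#' @param min_pairs minimum number of proper pairs.
#' @return a `data.table` with `transcript_id`, `n_proper_pairs`, `kept`
#'   and `reason` (`"ok"` or `"low_support"`).
#' @export
support_filter <- function(counts, min_pairs = 20L) {
  if (min_pairs < 0) stop_config("min_pairs must be >= 0")
  dt <- data.table::as.data.table(counts)[, .(transcript_id, n_proper_pairs)]
  dt[, kept := n_proper_pairs >= min_pairs]
  dt[, reason := ifelse(kept, "ok", "low_support")]
  dt[]
}

#' Per-base coverage profile with dip detection
#'
#' Accumulates per-base depth from the aligned reference blocks of all
#' mappings to one transcript, partitions the transcript into consecutive
#' fixed-width windows (the trailing remainder is included when it spans at
#' least half a window), and counts a coverage dip whenever the mean depths
#' of adjacent windows differ by more than `dip_fold`.
#'
#' @param mappings alignment rows for one transcript (needs `blocks`).
#' @param transcript_len transcript length in bp.
#' @param window_bp window width (stands in for assembler graph nodes,
#'   which are unavailable post-assembly).
#' @param dip_fold adjacent-window fold-change threshold (strict `>`).
#' @return list with `per_base_depth` (integer vector), `window_means`,
#'   `n_dips`, and `mean_depth`.
#' @export
coverage_profile <- function(mappings, transcript_len, window_bp = 100L,
                             dip_fold = 5.0) {
  if (transcript_len <= 0) stop_data("transcript_len must be positive")
  if (window_bp < 1) stop_config("window_bp must be >= 1")
  if (dip_fold <= 1) stop_config("dip_fold must be > 1")
  # difference-array accumulation of aligned blocks
  depth <- numeric(transcript_len)
  if (nrow(mappings)) {
    bl <- mappings$blocks
    ss <- unlist(lapply(bl, function(b) b[, 1L]), use.names = FALSE)
    ee <- unlist(lapply(bl, function(b) b[, 2L]), use.names = FALSE)
    if (length(ss)) {
      s <- pmax(1L, ss); e <- pmin(transcript_len, ee)
      ok <- s <= e
      inc <- tabulate(s[ok], transcript_len)
      dec <- tabulate(e[ok] + 1L, transcript_len + 1L)[seq_len(transcript_len)]
      depth <- cumsum(inc - dec)
    }
  }
  starts <- seq(1L, transcript_len, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, transcript_len)
  widths <- ends - starts + 1L
  keep <- widths >= window_bp / 2 | seq_along(starts) == 1L
  starts <- starts[keep]; ends <- ends[keep]
  wm <- vapply(seq_along(starts),
               function(i) mean(depth[starts[i]:ends[i]]), 0.0)
  n_dips <- 0L
  if (length(wm) >= 2L) {
    eps <- 1e-9
    hi <- pmax(wm[-length(wm)], wm[-1L])
    lo <- pmin(wm[-length(wm)], wm[-1L])
    n_dips <- sum(hi / pmax(lo, eps) > dip_fold)
  }
  list(per_base_depth = as.integer(round(depth)),
       window_means = wm, n_dips = as.integer(n_dips),
       mean_depth = mean(depth))
}

#' Coverage table for many transcripts
#'
#' Convenience wrapper running [coverage_profile()] per transcript.
#'
#' @param mappings alignment table from [read_sam_pairs()].
#' @param transcript_lens named integer vector of transcript lengths.
#' @inheritParams coverage_profile
#' @return a `data.table` with `transcript_id`, `mean_depth`, `n_dips`.
#' @export
coverage_table <- function(mappings, transcript_lens, window_bp = 100L,
                           dip_fold = 5.0) {
  ids <- names(transcript_lens)
  rows_by_id <- split(seq_len(nrow(mappings)), mappings$transcript_id)
  res <- lapply(ids, function(id) {
    cp <- coverage_profile(mappings[rows_by_id[[id]] %||% integer(0)],
                           transcript_lens[[id]], window_bp, dip_fold)
    data.table(transcript_id = id, mean_depth = cp$mean_depth,
               n_dips = cp$n_dips)
  })
  rbindlist(res)
}

utils::globalVariables(c("r1_plus", "r2_plus", "reason"))
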