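# Two-pool differential expression ratios with mode centering.
#
# The published design had one DSN-normalized library per pool and no
# replicates, so this module is deliberately descriptive: per-transcript
# log2 ratios, a histogram-mode centering normalization, and fold-change
# tallies. No dispersion modeling or significance testing.

#' Per-transcript log2 ratios between two pools
#'
#' Includes transcripts whose pooled count strictly exceeds `min_reads`.
#' A zero count in either pool is replaced by `zero_value` before the
#' ratio so transcripts expressed in only one pool remain analyzable.
#'
#' @param counts_a,counts_b named non-negative count vectors over the same
#'   transcripts.
#' @param min_reads strict lower bound on `count_a + count_b`.
#' @param zero_value pseudo-count substituted for zeros.
#' @return `data.table` with `transcript_id`, `count_pool_a`,
#'   `count_pool_b`, `raw_log2_ratio`.
#' @export
compute_ratios <- function(counts_a, counts_b, min_reads = 50L,
                           zero_value = 0.5) {
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop_data("negative read count")
  }
  ids <- union(names(counts_a), names(counts_b))
  a <- ifelse(ids %in% names(counts_a), counts_a[ids], 0)
  b <- ifelse(ids %in% names(counts_b), counts_b[ids], 0)
  keep <- (a + b) > min_reads
  ea <- ifelse(a[keep] > 0, a[keep], zero_value)
  eb <- ifelse(b[keep] > 0, b[keep], zero_value)
  data.table(transcript_id = ids[keep],
             count_pool_a = unname(a[keep]),
             count_pool_b = unname(b[keep]),
             raw_log2_ratio = unname(log2(ea / eb)))
}

#' Mode-centering normalization of log ratios
#'
#' Builds a histogram of the raw ratios with bins `[k*w, (k+1)*w)`, takes
#' the center of the most populated bin as the offset, and subtracts it
#' from every record. A tie between modal bins is broken by the bin whose
#' center is nearer zero, then by the lower bin.
#'
#' @param records ratio table from [compute_ratios()].
#' @param bin_width histogram interval width (default 0.1).
#' @return `records` with added `normalized_log2_ratio`; the offset is
#'   attached as attribute `mode_offset`.
#' @export
mode_center <- function(records, bin_width = 0.1) {
  if (!nrow(records)) stop_data("mode_center: no records")
  x <- records$raw_log2_ratio
  # rounding before floor keeps bin assignment stable under float noise,
  # so shifting by an exact multiple of bin_width shifts bins exactly
  k <- floor(round(x / bin_width, 6L))
  tab <- table(k)
  kk <- as.numeric(names(tab))
  nmax <- max(tab)
  cand <- kk[tab == nmax]
  centers <- (cand + 0.5) * bin_width
  cand <- cand[order(abs(centers), cand)]
  offset <- (cand[1L] + 0.5) * bin_width
  out <- data.table::copy(data.table::as.data.table(records))
  out[, normalized_log2_ratio := raw_log2_ratio - offset]
  data.table::setattr(out, "mode_offset", offset)
  out[]
}

#' Fold-change summary counts
#'
#' @param records table with `normalized_log2_ratio`.
#' @param thresholds fold changes (e.g. `c(2, 16)`), each > 1.
#' @return `data.table` with `fold` and `n` (records with
#'   `|normalized| > log2(fold)`).
#' @export
fold_change_table <- function(records, thresholds = c(2, 16)) {
  if (any(thresholds <= 1)) stop_config("fold-change thresholds must be > 1")
  x <- if (nrow(records)) records$normalized_log2_ratio else numeric(0)
  data.table(fold = thresholds,
             n = vapply(thresholds,
                        function(f) sum(abs(x) > log2(f)), 0L))
}

utils::globalVariables(c("normalized_log2_ratio", "raw_log2_ratio"))
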