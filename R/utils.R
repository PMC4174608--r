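# Internal helpers shared across modules.

#' @importFrom data.table data.table fread fwrite setDT setorder rbindlist :=
#' @importFrom stats runif rpois rbinom setNames
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", "transcript_id", "component_id", "read_id", "mate", "strand",
  "proper", "evalue", "query_id", "subject_id", "aggregate_score", "pos",
  "depth", "n_proper_pairs", "sslr", "kept"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Union length of a set of 1-based inclusive intervals given as a
# two-column matrix [start, end]. Intervals may overlap or touch.
interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(0L)
  o <- order(iv[, 1L], iv[, 2L])
  s <- iv[o, 1L]; e <- iv[o, 2L]
  total <- 0L; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

# Overlap (shared span, bp) of two 1-based inclusive intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# Deterministic seed derivation: keep derived seeds well below 2^31.
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 1009L + as.integer(salt)) %% 2000000011L
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssfilter_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ssfilter_config_error", "error")))
}
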