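# BLAST tabular (outfmt 6) input.
#
# Native dialect: the 12 standard columns plus qlen and slen appended as
# columns 13-14. Plain 12-column output is accepted only when sidecar
# length tables supply query/subject lengths, since the coverage-based
# score metrics are undefined without them.

BLAST6_COLS <- c("query_id", "subject_id", "pident", "align_len", "mismatch",
                 "gapopen", "q_start", "q_end", "s_start", "s_end",
                 "evalue", "bitscore")

#' Read a BLAST tabular hit file
#'
#' @param path tab-separated hit file, 12 or 14 columns (outfmt 6, with
#'   `qlen` and `slen` appended as columns 13-14 in the 14-column dialect).
#' @param db database tag attached to every hit: one of `"uniref100"`,
#'   `"nr"`, `"nucl_self"`, `"other"`.
#' @param q_lens,s_lens named integer vectors of query/subject lengths,
#'   required for 12-column input.
#' @return a `data.table` of hits in file order with columns
#'   `query_id`, `subject_id`, ..., `evalue`, `bitscore`, `q_len`, `s_len`,
#'   `db`. For translated searches a minus-strand query match is encoded by
#'   `q_start > q_end` (and likewise `s_start > s_end` for nucleotide
#'   minus-strand subjects).
#' @export
read_blast_tab <- function(path, db = c("other", "uniref100", "nr", "nucl_self"),
                           q_lens = NULL, s_lens = NULL) {
  db <- match.arg(db)
  if (!file.exists(path)) stop_data("BLAST file not found: ", path)
  if (file.size(path) == 0L) return(empty_hits(db))
  dt <- fread(path, header = FALSE, sep = "\t")
  if (!nrow(dt)) return(empty_hits(db))
  if (!ncol(dt) %in% c(12L, 14L)) {
    stop_data("expected 12 or 14 tab-separated columns, got ", ncol(dt))
  }
  if (ncol(dt) == 14L) {
    data.table::setnames(dt, c(BLAST6_COLS, "q_len", "s_len"))
  } else {
    data.table::setnames(dt, BLAST6_COLS)
    if (is.null(q_lens) || is.null(s_lens)) {
      stop_data("12-column BLAST input needs q_lens/s_lens sidecar tables ",
                "(coverage metrics are undefined without them)")
    }
    dt[, `:=`(q_len = as.integer(q_lens[query_id]),
              s_len = as.integer(s_lens[subject_id]))]
    if (anyNA(dt$q_len) || anyNA(dt$s_len)) {
      stop_data("sidecar length table missing entries for some hits")
    }
  }
  data.table::set(dt, j = "db", value = db)
  dt[]
}

empty_hits <- function(db = "other") {
  dt <- data.table(
    query_id = character(0), subject_id = character(0), pident = numeric(0),
    align_len = integer(0), mismatch = integer(0), gapopen = integer(0),
    q_start = integer(0), q_end = integer(0), s_start = integer(0),
    s_end = integer(0), evalue = numeric(0), bitscore = numeric(0),
    q_len = integer(0), s_len = integer(0), db = character(0)
  )
  dt
}

#' First (best) hit per query
#'
#' BLAST convention: the first hit of a query is the one with the lowest
#' e-value, ties broken by file order.
#'
#' @param hits hit table from [read_blast_tab()].
#' @param max_evalue keep only hits at or below this e-value before
#'   selecting (the published screens used 1e-10 for protein searches).
#' @return one row per query.
#' @export
first_hits <- function(hits, max_evalue = Inf) {
  h <- hits[evalue <= max_evalue]
  if (!nrow(h)) return(h)
  # which.min returns the first minimum, i.e. file order breaks ties
  h[h[, .I[which.min(evalue)], by = query_id]$V1]
}

utils::globalVariables(c("db", "q_len", "s_len", "V1"))
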