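# FASTA input/output for assembled putative transcripts.

#' Read an assembly FASTA of putative transcripts
#'
#' Reads a FASTA file of assembled putative transcripts and returns one row
#' per transcript with its component assignment. Trinity-style identifiers
#' (`comp<int>_c<int>_seq<int>`) have their component derived by stripping
#' the `_seq<K>` suffix; other identifiers require an explicit component map.
#'
#' @param path path to a FASTA file with unique headers.
#' @param component_map optional named character vector mapping
#'   `transcript_id` to `component_id`, for non-Trinity identifiers.
#' @return a `data.table` with columns `transcript_id`, `component_id`,
#'   `sequence` (uppercase, alphabet A/C/G/T/N) and `length_bp`.
#' @details Duplicate identifiers and characters outside A/C/G/T/N (after
#'   uppercasing) are hard errors; the offending record is named. RNA
#'   letters (U) are rejected: the assembly is expected as DNA.
#' @export
read_fasta <- function(path, component_map = NULL) {
  if (!file.exists(path)) stop_data("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop_data("duplicate FASTA identifier(s): ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_data("non-IUPAC DNA character in record(s): ",
              paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(seqs) < 1L)) {
    stop_data("empty sequence in record(s): ",
              paste(ids[nchar(seqs) < 1L], collapse = ", "))
  }
  data.table(
    transcript_id = ids,
    component_id  = component_from_id(ids, component_map),
    sequence      = unname(seqs),
    length_bp     = nchar(seqs)
  )
}

#' Derive component identifiers from transcript identifiers
#'
#' @param ids character vector of transcript identifiers.
#' @param component_map optional named character vector overriding the
#'   Trinity-style derivation.
#' @return character vector of component identifiers.
#' @export
component_from_id <- function(ids, component_map = NULL) {
  if (!is.null(component_map)) {
    missing <- setdiff(ids, names(component_map))
    if (length(missing)) {
      stop_data("transcript(s) absent from component map: ",
                paste(head(missing, 5L), collapse = ", "))
    }
    return(unname(component_map[ids]))
  }
  trinity <- grepl("^comp[0-9]+_c[0-9]+_seq[0-9]+$", ids)
  if (!all(trinity)) {
    stop_data("non-Trinity identifier(s) without a component map: ",
              paste(head(ids[!trinity], 5L), collapse = ", "))
  }
  sub("_seq[0-9]+$", "", ids)
}

#' Write transcripts to FASTA
#'
#' @param records a data.frame with `transcript_id` and `sequence` columns.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$transcript_id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
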