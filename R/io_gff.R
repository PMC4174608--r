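# GFF3 and TSV report writers/readers.
#
# The GFF3 dialect is deliberately small: CDS features with 1-based
# inclusive coordinates, +/- strand, frame in the phase column, and an
# `ID=` attribute, which is all the ORF exchange needs.

#' Write ORF calls to GFF3
#'
#' @param orfs a data.frame of ORF calls with columns `transcript_id`,
#'   `start`, `end`, `strand`, `frame`, and optionally `orf_id`, `source`,
#'   `mode`, `partial`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop_data("cannot write: ", path)
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    ids <- if ("orf_id" %in% names(orfs)) orfs$orf_id else
      sprintf("%s.orf%d", orfs$transcript_id, seq_len(nrow(orfs)))
    src <- if ("source" %in% names(orfs)) orfs$source else "ssfilter"
    attrs <- sprintf("ID=%s;mode=%s;partial=%s", ids,
                     if ("mode" %in% names(orfs)) orfs$mode else "start_to_stop",
                     if ("partial" %in% names(orfs)) tolower(as.character(orfs$partial)) else "false")
    writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                       orfs$transcript_id, src, orfs$start, orfs$end,
                       orfs$strand, orfs$frame, attrs), con)
  }
  invisible(path)
}

#' Read ORF calls from GFF3
#'
#' Counterpart of [write_orfs_gff3()]; also accepts externally predicted
#' ORFs in the same minimal dialect (CDS rows, `ID=` attribute).
#'
#' @param path GFF3 file.
#' @return a `data.table` with the columns written by [write_orfs_gff3()].
#' @export
read_orfs_gff3 <- function(path) {
  if (!file.exists(path)) stop_data("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.table(
    transcript_id = character(0), orf_id = character(0), source = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    frame = integer(0), length_bp = integer(0), mode = character(0),
    partial = logical(0)
  )
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop_data("malformed GFF3 line (need 9 columns)")
  attr_get <- function(a, key, default = NA_character_) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else default, "")
  }
  a9 <- vapply(f, `[[`, "", 9L)
  ph <- vapply(f, `[[`, "", 8L)
  data.table(
    transcript_id = vapply(f, `[[`, "", 1L),
    orf_id = attr_get(a9, "ID"),
    source = vapply(f, `[[`, "", 2L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    frame = ifelse(ph == ".", 0L, as.integer(ph)),
    length_bp = as.integer(vapply(f, `[[`, "", 5L)) -
      as.integer(vapply(f, `[[`, "", 4L)) + 1L,
    mode = ifelse(is.na(attr_get(a9, "mode")), "start_to_stop", attr_get(a9, "mode")),
    partial = attr_get(a9, "partial") %in% "true"
  )
}

#' Write a decision/report table as TSV
#'
#' @param records data.frame to write; list columns are not supported.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_tsv <- function(records, path) {
  ok <- try(fwrite(records, path, sep = "\t"), silent = TRUE)
  if (inherits(ok, "try-error")) stop_data("cannot write: ", path)
  invisible(path)
}

#' Read back a TSV report
#' @param path TSV path.
#' @return a `data.table`.
#' @export
read_report_tsv <- function(path) {
  if (!file.exists(path)) stop_data("TSV file not found: ", path)
  fread(path, sep = "\t")
}
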