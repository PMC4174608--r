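# Lowest-common-ancestor taxonomy assignment from best-e-value hits.

#' Read a taxonomy parent map
#'
#' @param path TSV with two columns `taxid`, `parent` (root is its own
#'   parent or has parent `NA`/empty); an optional third column `name` is
#'   preserved.
#' @return list with `parent` (named character vector) and optional
#'   `name` (named character vector).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_data("taxonomy file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(dt) < 2L) stop_data("taxonomy map needs taxid and parent columns")
  parent <- stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
  nm <- if (ncol(dt) >= 3L) stats::setNames(as.character(dt[[3L]]),
                                            as.character(dt[[1L]])) else NULL
  list(parent = parent, name = nm)
}

# root-to-node path through the parent map; NULL when the node is unknown
taxon_path <- function(taxid, parent) {
  if (!taxid %in% names(parent)) return(NULL)
  path <- character(0)
  cur <- taxid
  for (i in seq_len(length(parent) + 1L)) {
    path <- c(cur, path)
    p <- parent[[cur]]
    if (is.na(p) || !nzchar(p) || identical(p, cur)) return(path)
    if (!p %in% names(parent)) return(c(p, path))
    cur <- p
  }
  stop_data("taxonomy parent map contains a cycle at ", taxid)
}

#' Lowest common ancestor of the best-e-value hits
#'
#' Aggregates all hits tied at the minimal e-value for one query and
#' returns the deepest taxonomy node ancestral to all of their subject
#' taxa. Hits with a worse e-value are ignored; hits whose taxon is absent
#' from the parent map are dropped with a warning.
#'
#' @param hits hit table for one query carrying a `subject_taxon` column
#'   and `evalue`.
#' @param taxonomy parent map from [read_taxonomy()] (or a bare named
#'   parent vector).
#' @return the LCA taxon id, or `NA_character_` when no usable hit
#'   remains.
#' @export
lca_assign <- function(hits, taxonomy) {
  parent <- if (is.list(taxonomy)) taxonomy$parent else taxonomy
  if (!nrow(hits)) return(NA_character_)
  best <- hits[hits$evalue == min(hits$evalue), ]
  taxa <- unique(as.character(best$subject_taxon))
  taxa <- taxa[!is.na(taxa) & nzchar(taxa)]
  paths <- lapply(taxa, taxon_path, parent = parent)
  missing <- taxa[vapply(paths, is.null, TRUE)]
  if (length(missing)) {
    warning("lca_assign: taxa absent from parent map dropped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  paths <- paths[!vapply(paths, is.null, TRUE)]
  if (!length(paths)) return(NA_character_)
  common <- paths[[1L]]
  for (p in paths[-1L]) {
    k <- min(length(common), length(p))
    eq <- common[seq_len(k)] == p[seq_len(k)]
    nprefix <- if (all(eq)) k else which(!eq)[1L] - 1L
    if (nprefix == 0L) return(NA_character_)  # disjoint forests
    common <- common[seq_len(nprefix)]
  }
  common[length(common)]
}

#' LCA assignment for every query in a hit table
#'
#' @param hits hit table with `query_id`, `evalue`, `subject_taxon`.
#' @param taxonomy parent map from [read_taxonomy()].
#' @return `data.table` with `query_id` and `lca_taxon`.
#' @export
lca_table <- function(hits, taxonomy) {
  h <- data.table::as.data.table(hits)
  if (!nrow(h)) return(data.table(query_id = character(0), lca_taxon = character(0)))
  h[, .(lca_taxon = lca_assign(.SD, taxonomy)), by = query_id]
}
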