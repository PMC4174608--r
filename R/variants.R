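# Pileup-based substitution-site scan.
#
# The assembly itself is the reference, so the consensus at each position
# is the majority of observed bases rather than an external genome. Only
# substitutions are called; indel and reference-skip positions count
# toward depth as "skipped" but never toward allele fractions.

#' Build a pileup from paired alignments
#'
#' Walks every alignment's CIGAR/SEQ and accumulates per-position base
#' counts. Deleted/skipped reference positions (`D`/`N`) and bases outside
#' A/C/G/T are tallied in `n_skipped`. Uncovered positions are omitted.
#'
#' @param mappings alignment table from [read_sam_pairs()] with `seq`.
#' @param drop_duplicates skip records flagged as duplicates (0x400).
#' @return `data.table` with `transcript_id`, `pos`, `A`, `C`, `G`, `T`,
#'   `n_skipped`, `depth` (`= A+C+G+T+n_skipped`).
#' @export
build_pileup <- function(mappings, drop_duplicates = TRUE) {
  empty <- data.table(transcript_id = character(0), pos = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), n_skipped = integer(0),
                      depth = integer(0))
  m <- mappings
  if (drop_duplicates && nrow(m)) m <- m[duplicate == FALSE]
  m <- m[m$seq != "*" & nzchar(m$seq), ]
  if (!nrow(m)) return(empty)
  # fast path: plain "<n>M" CIGAR with matching SEQ length
  mlen <- suppressWarnings(as.integer(sub("^([0-9]+)M$", "\\1", m$cigar)))
  simple <- grepl("^[0-9]+M$", m$cigar) & !is.na(mlen) & nchar(m$seq) == mlen
  parts <- list()
  if (any(simple)) {
    ms <- m[simple]
    rl <- nchar(ms$seq)
    parts[[1L]] <- data.table(
      transcript_id = rep(ms$transcript_id, rl),
      pos = rep(ms$pos, rl) + sequence(rl) - 1L,
      base = unlist(strsplit(ms$seq, "", fixed = TRUE), use.names = FALSE))
  }
  if (any(!simple)) {
    mc <- m[!simple]
    recs <- lapply(seq_len(nrow(mc)), function(i) {
      ab <- aligned_ref_bases(mc$cigar[i], mc$pos[i], mc$seq[i])
      if (!length(ab$pos)) return(NULL)
      data.table(transcript_id = mc$transcript_id[i], pos = ab$pos,
                 base = ab$base)
    })
    parts[[length(parts) + 1L]] <- rbindlist(recs)
  }
  long <- rbindlist(parts)
  if (!nrow(long)) return(empty)
  long[, base := ifelse(base %in% c("A", "C", "G", "T"), base, "skip")]
  wide <- data.table::dcast(long[, .N, by = .(transcript_id, pos, base)],
                            transcript_id + pos ~ base, value.var = "N",
                            fill = 0L)
  for (col in c("A", "C", "G", "T", "skip")) {
    if (!col %in% names(wide)) wide[, (col) := 0L]
  }
  data.table::setnames(wide, "skip", "n_skipped")
  wide[, depth := A + C + G + T + n_skipped]
  setorder(wide, transcript_id, pos)
  wide[, .(transcript_id, pos, A, C, G, T, n_skipped, depth)]
}

#' Call substitution sites from a pileup
#'
#' Evaluates columns supported by more than 20 reads (i.e. depth at least
#' `min_depth`). The consensus is the majority base (ties broken in
#' A < C < G < T order); every non-consensus base whose fraction of the
#' called bases strictly exceeds `relaxed_frac` is emitted, and flagged
#' strict when it also strictly exceeds `strict_frac`. Fractions are
#' computed over `A+C+G+T` (skipped reads excluded).
#'
#' @param columns pileup from [build_pileup()].
#' @param min_depth minimum depth, inclusive (default 21, the published
#'   ">20 reads").
#' @param relaxed_frac,strict_frac strict allele-fraction thresholds
#'   (defaults 0.05 and 0.20).
#' @return `data.table` of sites: `transcript_id`, `pos`, `consensus`,
#'   `alt`, `alt_count`, `depth`, `alt_fraction`, `tier`
#'   (`"relaxed_5pct"` or `"strict_20pct"`).
#' @export
call_substitutions <- function(columns, min_depth = 21L,
                               relaxed_frac = 0.05, strict_frac = 0.20) {
  if (relaxed_frac <= 0 || relaxed_frac >= 1 || strict_frac <= 0 ||
      strict_frac >= 1 || relaxed_frac > strict_frac) {
    stop_config("allele-fraction thresholds must satisfy 0 < relaxed <= strict < 1")
  }
  empty <- data.table(transcript_id = character(0), pos = integer(0),
                      consensus = character(0), alt = character(0),
                      alt_count = integer(0), depth = integer(0),
                      alt_fraction = numeric(0), tier = character(0))
  cc <- data.table::as.data.table(columns)
  cc <- cc[depth >= min_depth]
  if (!nrow(cc)) return(empty)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(cc[, .(A, C, G, T)])
  tot <- rowSums(cnt)
  cons_idx <- max.col(cnt, ties.method = "first")  # A<C<G<T tie order
  rows <- list()
  for (bi in seq_along(bases)) {
    alt <- bases[bi]
    sel <- cons_idx != bi & tot > 0 & (cnt[, bi] / pmax(tot, 1)) > relaxed_frac
    if (!any(sel)) next
    frac <- cnt[sel, bi] / tot[sel]
    rows[[length(rows) + 1L]] <- data.table(
      transcript_id = cc$transcript_id[sel], pos = cc$pos[sel],
      consensus = bases[cons_idx[sel]], alt = alt,
      alt_count = cnt[sel, bi], depth = cc$depth[sel],
      alt_fraction = frac,
      tier = ifelse(frac > strict_frac, "strict_20pct", "relaxed_5pct")
    )
  }
  if (!length(rows)) return(empty)
  out <- rbindlist(rows)
  setorder(out, transcript_id, pos, alt)
  out[]
}

#' Write substitution sites as a minimal VCF
#'
#' Minimal VCFv4.2: `CHROM` = transcript id, 1-based `POS`, `REF` =
#' consensus, `ALT`, and `INFO` with `DP` and `AF`.
#'
#' @param sites site table from [call_substitutions()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sites_vcf <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Threshold tier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f;TIER=%s",
                       sites$transcript_id, sites$pos, sites$consensus,
                       sites$alt, sites$depth, sites$alt_fraction,
                       sites$tier), con)
  }
  invisible(path)
}

utils::globalVariables(c("A", "C", "G", "T", "base", "duplicate",
                         "n_skipped", "alt"))
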