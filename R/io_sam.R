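# SAM (text) reader for paired-end alignments against the assembly.
#
# Only the subset of SAM needed downstream is decoded: FLAG, RNAME, POS,
# CIGAR and SEQ. Coordinates are 1-based inclusive throughout, matching the
# SAM convention.

# Parse one CIGAR string into an op/length matrix.
parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop_data("malformed CIGAR: ", cigar)
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- substring(toks, nchar(toks), nchar(toks))
  cbind_ops <- list(op = op, len = len)
  cbind_ops
}

#' Reference blocks covered by an alignment
#'
#' Walks a CIGAR string from a 1-based start position and returns the
#' reference intervals in which the read contributes aligned bases
#' (operations `M`, `=`, `X`). `D` and `N` consume reference but contribute
#' no aligned base and split blocks; `I`, `S`, `H`, `P` consume no reference.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based leftmost reference position.
#' @return integer matrix with columns `start`, `end` (1-based inclusive).
#' @export
cigar_ref_blocks <- function(cigar, pos) {
  cg <- parse_cigar(cigar)
  starts <- integer(0); ends <- integer(0)
  at <- as.integer(pos)
  open_s <- NA_integer_
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      if (is.na(open_s)) open_s <- at
      at <- at + len
    } else if (op %in% c("D", "N")) {
      if (!is.na(open_s)) {
        starts <- c(starts, open_s); ends <- c(ends, at - 1L)
        open_s <- NA_integer_
      }
      at <- at + len
    }
    # I/S/H/P: no reference consumption
  }
  if (!is.na(open_s)) {
    starts <- c(starts, open_s); ends <- c(ends, at - 1L)
  }
  matrix(c(starts, ends), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

# Per-reference-position base calls for one alignment. Returns a list with
# integer vector `pos` and character vector `base`; deleted/skipped
# reference positions (D/N) carry base "-" so the pileup can count them as
# spanned-but-skipped.
aligned_ref_bases <- function(cigar, pos, seq) {
  cg <- parse_cigar(cigar)
  rpos <- integer(0); base <- character(0)
  at <- as.integer(pos); q <- 1L
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      rpos <- c(rpos, at:(at + len - 1L))
      base <- c(base, chars[q:(q + len - 1L)])
      at <- at + len; q <- q + len
    } else if (op %in% c("D", "N")) {
      rpos <- c(rpos, at:(at + len - 1L))
      base <- c(base, rep("-", len))
      at <- at + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
  }
  list(pos = rpos, base = base)
}

#' Read paired-end alignments from a SAM text file
#'
#' Decodes one record per alignment line: strand from FLAG bit 0x10,
#' mate rank from 0x40/0x80, proper pairing from 0x2 and duplicate marking
#' from 0x400. Unmapped records (0x4), records with CIGAR `*` and records
#' carrying neither mate bit are skipped with a counted warning.
#'
#' @param path SAM text file with `@SQ` headers.
#' @param drop_duplicates drop records flagged 0x400 (duplicate marking is
#'   expected upstream).
#' @param include_secondary keep secondary (0x100) and supplementary
#'   (0x800) alignment lines; the default keeps all lines since the SSLR
#'   is computed over multi-mapped reads.
#' @return a `data.table` with columns `read_id`, `transcript_id`, `flag`,
#'   `mate` (1 or 2), `strand` (`"+"`/`"-"`), `proper`, `duplicate`, `pos`,
#'   `cigar`, `seq`, and list column `blocks` of reference intervals. The
#'   attribute `n_skipped` carries the number of skipped lines, and
#'   `seq_lengths` the named `@SQ` lengths.
#' @export
read_sam_pairs <- function(path, drop_duplicates = FALSE,
                           include_secondary = TRUE) {
  if (!file.exists(path)) stop_data("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  seq_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seq_lengths <- stats::setNames(ln, sn)
  }
  n_skip <- 0L
  if (!length(body)) {
    out <- empty_pair_mappings()
    attr(out, "n_skipped") <- 0L
    attr(out, "seq_lengths") <- seq_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop_data("SAM line with fewer than 11 fields")
  qname <- vapply(f, `[[`, "", 1L)
  flag  <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos   <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  seqf  <- vapply(f, `[[`, "", 10L)

  unmapped  <- bitwAnd(flag, 0x4L) != 0L | rname == "*"
  no_cigar  <- cigar == "*"
  unpaired  <- bitwAnd(flag, 0x40L) == 0L & bitwAnd(flag, 0x80L) == 0L
  drop <- unmapped | no_cigar | unpaired
  if (!include_secondary) {
    drop <- drop | bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  }
  if (drop_duplicates) drop <- drop | bitwAnd(flag, 0x400L) != 0L
  n_skip <- sum(unmapped | no_cigar | unpaired)
  if (n_skip > 0L) {
    warning(sprintf("read_sam_pairs: skipped %d alignment line(s) (unmapped, CIGAR '*', or unpaired)",
                    n_skip), call. = FALSE)
  }
  keep <- !drop
  dt <- data.table(
    read_id       = qname[keep],
    transcript_id = rname[keep],
    flag          = flag[keep],
    mate          = ifelse(bitwAnd(flag[keep], 0x40L) != 0L, 1L, 2L),
    strand        = ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+"),
    proper        = bitwAnd(flag[keep], 0x2L) != 0L,
    duplicate     = bitwAnd(flag[keep], 0x400L) != 0L,
    pos           = pos[keep],
    cigar         = cigar[keep],
    seq           = seqf[keep]
  )
  # fast path: a plain "<n>M" CIGAR is a single block
  simple <- grepl("^[0-9]+M$", dt$cigar)
  nm <- integer(nrow(dt))
  nm[simple] <- as.integer(sub("M$", "", dt$cigar[simple]))
  dt[, blocks := lapply(seq_len(.N), function(i) {
    if (simple[i]) {
      matrix(c(pos[i], pos[i] + nm[i] - 1L), ncol = 2L,
             dimnames = list(NULL, c("start", "end")))
    } else {
      cigar_ref_blocks(cigar[i], pos[i])
    }
  })]
  attr(dt, "n_skipped") <- n_skip
  attr(dt, "seq_lengths") <- seq_lengths
  dt[]
}

empty_pair_mappings <- function() {
  data.table(
    read_id = character(0), transcript_id = character(0),
    flag = integer(0), mate = integer(0), strand = character(0),
    proper = logical(0), duplicate = logical(0), pos = integer(0),
    cigar = character(0), seq = character(0), blocks = list()
  )
}
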