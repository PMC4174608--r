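# Independent brute-force oracles. These deliberately share no code with
# the package internals: each one recomputes its quantity the slow,
# obvious way so the fast implementations can be checked against them.

# --- CIGAR: per-base reference walk -----------------------------------
# Returns the sorted vector of reference positions carrying an aligned
# base, stepping one op-unit at a time.
oracle_cigar_positions <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  at <- pos
  out <- integer(0)
  for (tok in ops) {
    n <- as.integer(sub(".$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    for (k in seq_len(n)) {
      if (op %in% c("M", "=", "X")) {
        out <- c(out, at); at <- at + 1L
      } else if (op %in% c("D", "N")) {
        at <- at + 1L
      }
      # I/S/H/P: reference untouched
    }
  }
  out
}

random_cigar <- function() {
  ops <- c("M", "I", "D", "S", "N", "=", "X")
  wts <- c(10, 2, 2, 2, 1, 1, 1)
  n <- sample(1:6, 1L)
  chosen <- sample(ops, n, replace = TRUE, prob = wts)
  # must start/end sensibly and contain at least one aligned op
  if (!any(chosen %in% c("M", "=", "X"))) chosen[1L] <- "M"
  lens <- sample(1:20, n, replace = TRUE)
  paste0(paste0(lens, chosen), collapse = "")
}

# --- ORFs: naive six-frame codon scan ---------------------------------
# Walks codon triplets one at a time per strand/frame, tracking segment
# state explicitly; start_to_stop only (the mode under oracle test).
oracle_orfs <- function(seq, min_len = 300L) {
  rc <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (fr in 0:2) {
      i <- fr + 1L
      atg_at <- NA_integer_
      while (i + 2L <= L) {
        cod <- substr(s, i, i + 2L)
        if (is.na(atg_at) && cod == "ATG") atg_at <- i
        if (cod %in% stops) {
          if (!is.na(atg_at)) {
            len <- i + 2L - atg_at + 1L
            if (len >= min_len) {
              res[[length(res) + 1L]] <-
                list(a = atg_at, b = i + 2L, strand = strand,
                     frame = fr, partial = FALSE)
            }
          }
          atg_at <- NA_integer_
        }
        i <- i + 3L
      }
      if (!is.na(atg_at)) {       # ran off the edge without a stop
        b <- i - 1L               # last complete codon end
        len <- b - atg_at + 1L
        if (len >= min_len) {
          res[[length(res) + 1L]] <-
            list(a = atg_at, b = b, strand = strand, frame = fr,
                 partial = TRUE)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_bp = integer(0), partial = logical(0)))
  }
  df <- do.call(rbind, lapply(res, function(r) {
    st <- if (r$strand == "+") r$a else L - r$b + 1L
    en <- if (r$strand == "+") r$b else L - r$a + 1L
    data.frame(start = st, end = en, strand = r$strand, frame = r$frame,
               length_bp = r$b - r$a + 1L, partial = r$partial)
  }))
  df[order(df$start, df$strand, df$frame), , drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# --- pileup: per-position counter -------------------------------------
# Walks every read base-by-base through its CIGAR, tallying A/C/G/T and
# skips into plain R vectors.
oracle_pileup <- function(mappings, transcript_len) {
  counts <- matrix(0L, nrow = transcript_len, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "skip")))
  for (i in seq_len(nrow(mappings))) {
    cg <- mappings$cigar[i]
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    at <- mappings$pos[i]; q <- 1L
    sq <- mappings$seq[i]
    for (tok in ops) {
      n <- as.integer(sub(".$", "", tok))
      op <- sub("^[0-9]+", "", tok)
      for (k in seq_len(n)) {
        if (op %in% c("M", "=", "X")) {
          b <- substr(sq, q, q)
          col <- if (b %in% c("A", "C", "G", "T")) b else "skip"
          if (at >= 1L && at <= transcript_len) {
            counts[at, col] <- counts[at, col] + 1L
          }
          at <- at + 1L; q <- q + 1L
        } else if (op %in% c("D", "N")) {
          if (at >= 1L && at <= transcript_len) {
            counts[at, "skip"] <- counts[at, "skip"] + 1L
          }
          at <- at + 1L
        } else if (op %in% c("I", "S")) {
          q <- q + 1L
        }
      }
    }
  }
  counts
}

# --- Table-1 scoring: naive scalar re-implementation ------------------
# Recomputes all 19 metrics directly from the written formulas, without
# reusing any package helper.
oracle_score <- function(ev, ctx, w) {
  sc <- function(h) abs(h$s_end - h$s_start) + 1       # subject covered
  qc <- function(h) abs(h$q_end - h$q_start) + 1       # query covered
  div0 <- function(a, b) if (is.null(b) || is.na(b) || b == 0) 0 else a / b
  ns <- div0(-ev$sslr, ctx$max_abs_sslr)
  m <- numeric(19)
  blocks <- list(list(ev$uniref_hit, "uniref100", 1),
                 list(ev$nr_hit, "nr", 6))
  for (bl in blocks) {
    h <- bl[[1]]; dbn <- bl[[2]]; off <- bl[[3]]
    if (!is.null(h) && nrow(h) > 0) {
      h <- as.list(h[1, ])
      m[off]     <- div0(sc(h), h$s_len)
      m[off + 1] <- div0(qc(h), ev$length_bp)
      m[off + 2] <- div0(sc(h), ctx$longest_subject_hit[[dbn]])
      m[off + 3] <- div0(qc(h), ctx$longest_query_hit[[dbn]])
      m[off + 4] <- (if (h$q_start <= h$q_end) 1 else -1) * ns
    }
  }
  m[11] <- ns
  m[12] <- div0(ev$length_bp, ctx$longest_transcript)
  o <- ev$orfs
  if (!is.null(o) && nrow(o) > 0) {
    bs <- unique(o$best_subject[!is.na(o$best_subject)])
    if (length(bs) > 0) m[13] <- (1 - length(bs)) / length(bs)
    np <- sum(o$strand == "+"); nm <- sum(o$strand == "-")
    if (np > 0 && nm > 0) {
      pen <- -min(np, nm) / max(np, nm)
      ph <- any(o$has_nr_hit[o$strand == "+"])
      mh <- any(o$has_nr_hit[o$strand == "-"])
      if (ph && mh) m[14] <- pen else if (ph || mh) m[15] <- pen else m[16] <- pen
    }
    m[17] <- (1 - nrow(o)) / nrow(o)
    sgn <- if (nm == 0) 1 else if (np == 0) -1 else 0
    m[18] <- sgn * ns
  }
  m[19] <- -div0(ev$n_dips, ctx$max_dips)
  sum(w * m)
}

# random evidence bundle for the scoring oracle tests
random_evidence <- function(component_id = "comp1_c0", tid = "comp1_c0_seq1") {
  len <- sample(300:3000, 1L)
  mk_hit <- function() {
    if (runif(1) < 0.25) return(NULL)
    slen <- sample(100:800, 1L)
    scov <- sample(10:slen, 1L)
    qcov <- sample(10:len, 1L)
    qs <- sample(1:(len - qcov + 1L), 1L)
    minus <- runif(1) < 0.3
    data.frame(q_start = if (minus) qs + qcov - 1L else qs,
               q_end = if (minus) qs else qs + qcov - 1L,
               s_start = 1L, s_end = scov, s_len = slen,
               evalue = 10^-sample(11:150, 1L))
  }
  n_orf <- sample(0:3, 1L)
  orfs <- if (n_orf > 0) {
    data.frame(strand = sample(c("+", "-"), n_orf, replace = TRUE),
               best_subject = ifelse(runif(n_orf) < 0.7,
                                     paste0("S", sample(1:3, n_orf, replace = TRUE)),
                                     NA_character_),
               has_nr_hit = runif(n_orf) < 0.6)
  } else NULL
  list(transcript_id = tid, component_id = component_id, length_bp = len,
       sslr = runif(1, -6, 6), n_dips = sample(0:3, 1L),
       uniref_hit = mk_hit(), nr_hit = mk_hit(), orfs = orfs)
}

# Batched pileup-vs-oracle comparison: n_sets independent random mapping
# sets, each under its own transcript id, piled up in one call and then
# compared set-by-set against the brute-force counter.
pileup_vs_oracle <- function(n_sets, tlen = 200L) {
  sets <- lapply(seq_len(n_sets), function(i) {
    n <- sample(2:8, 1L)
    cigs <- replicate(n, random_cigar())
    qlen <- vapply(cigs, function(cg) {
      toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
      sum(as.integer(sub(".$", "", toks))[sub("^[0-9]+", "", toks) %in%
                                            c("M", "=", "X", "I", "S")])
    }, 0L)
    data.frame(transcript_id = sprintf("s%06d", i),
               pos = sample(1:30, n, replace = TRUE),
               cigar = cigs,
               seq = vapply(qlen, function(q) random_dna(max(q, 1L)), ""))
  })
  pooled <- data.table::rbindlist(sets)
  got <- ssfilter::build_pileup(make_mappings(pooled), drop_duplicates = FALSE)
  by_tid <- split(got, got$transcript_id)
  mismatches <- 0L; n_nonempty <- 0L
  for (i in seq_len(n_sets)) {
    want <- oracle_pileup(sets[[i]], tlen)
    covered <- which(rowSums(want) > 0L)
    g <- by_tid[[sets[[i]]$transcript_id[1L]]]
    if (is.null(g)) {
      if (length(covered)) mismatches <- mismatches + 1L
      next
    }
    n_nonempty <- n_nonempty + 1L
    ok <- identical(g$pos, covered) &&
      identical(g$A, unname(want[covered, "A"])) &&
      identical(g$C, unname(want[covered, "C"])) &&
      identical(g$G, unname(want[covered, "G"])) &&
      identical(g$T, unname(want[covered, "T"])) &&
      identical(g$n_skipped, unname(want[covered, "skip"]))
    if (!ok) mismatches <- mismatches + 1L
  }
  list(mismatches = mismatches, n_nonempty = n_nonempty, got = got)
}

# small in-memory mapping table (bypasses SAM text) for pileup tests
make_mappings <- function(df) {
  dt <- data.table::as.data.table(df)
  if (!"read_id" %in% names(dt)) dt[, read_id := sprintf("r%d", .I)]
  if (!"mate" %in% names(dt)) dt[, mate := 1L]
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  if (!"proper" %in% names(dt)) dt[, proper := TRUE]
  if (!"duplicate" %in% names(dt)) dt[, duplicate := FALSE]
  if (!"flag" %in% names(dt)) dt[, flag := 99L]
  dt[, blocks := lapply(seq_len(.N), function(i)
    ssfilter::cigar_ref_blocks(cigar[i], pos[i]))]
  dt[]
}

# minimal SAM text builder
write_sam <- function(path, sq, lines) {
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)),
               lines), path)
  path
}
sam_line <- function(qname, flag, rname, pos, cigar, seq = "*",
                     rnext = "=", pnext = 1L, tlen = 0L) {
  sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t*",
          qname, flag, rname, pos, cigar, rnext, pnext, tlen, seq)
}
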