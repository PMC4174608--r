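# Seeded simulator of strand-specific assemblies, alignments and hit
# tables, with truth files for every planted feature.
#
# The generator emulates the statistical structure the pipeline assumes:
# multi-isoform components each anchored by a full-length coding isoform,
# exact reverse-complement "leakage" twins of a fraction of sense
# transcripts, short weakly supported unstranded contamination contigs,
# dUTP read-pair orientation with a configurable leakage probability,
# planted substitution alleles, and homology tables whose coverage tracks
# isoform completeness. Everything is bit-reproducible for a fixed seed.

#' Simulation configuration
#'
#' Defaults describe the emulated world: 100-bp paired reads (the
#' published libraries were 100-bp paired-end), a 250-bp fixed fragment,
#' a 5% orientation-leakage probability, one-in-ten sense transcripts
#' acquiring an antisense twin, and contamination contigs that are short
#' and supported by fewer than 20 pairs so the default support filter
#' removes them.
#'
#' @param seed integer RNG seed.
#' @param n_components number of genuine components.
#' @param isoforms_per_component integer range `c(min, max)` of isoforms.
#' @param transcript_len range of full-length transcript lengths (bp).
#' @param coding_fraction fraction of components whose anchor isoform
#'   carries a planted ORF.
#' @param leak_prob probability that a fragment is sequenced in flipped
#'   orientation (in `[0, 0.5]`).
#' @param twin_fraction fraction of sense anchor transcripts that get an
#'   exact reverse-complement leakage twin contig.
#' @param contamination_fraction number of contamination contigs as a
#'   fraction of `n_components`.
#' @param pairs_per_transcript range of proper pairs per sense transcript.
#' @param contamination_pairs range of pairs per contamination contig.
#' @param read_len read length (bp).
#' @param fragment_len fragment length (bp, fixed; clipped to the
#'   transcript).
#' @param snp_sites_per_kb expected planted substitution sites per kb.
#' @param snp_fractions pool of planted minor-allele fractions.
#' @param error_rate per-base sequencing substitution error rate.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_components = 50L,
                       isoforms_per_component = c(1L, 3L),
                       transcript_len = c(600L, 2000L),
                       coding_fraction = 0.9,
                       leak_prob = 0.05,
                       twin_fraction = 0.1,
                       contamination_fraction = 0.1,
                       pairs_per_transcript = c(50L, 300L),
                       contamination_pairs = c(2L, 15L),
                       read_len = 100L,
                       fragment_len = 250L,
                       snp_sites_per_kb = 0.5,
                       snp_fractions = c(0.3),
                       error_rate = 0.005) {
  cfg <- list(seed = as.integer(seed), n_components = as.integer(n_components),
              isoforms_per_component = as.integer(isoforms_per_component),
              transcript_len = as.integer(transcript_len),
              coding_fraction = coding_fraction, leak_prob = leak_prob,
              twin_fraction = twin_fraction,
              contamination_fraction = contamination_fraction,
              pairs_per_transcript = as.integer(pairs_per_transcript),
              contamination_pairs = as.integer(contamination_pairs),
              read_len = as.integer(read_len),
              fragment_len = as.integer(fragment_len),
              snp_sites_per_kb = snp_sites_per_kb,
              snp_fractions = snp_fractions, error_rate = error_rate)
  probs <- c(cfg$coding_fraction, cfg$twin_fraction,
             cfg$contamination_fraction, cfg$error_rate)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must be in [0,1]")
  if (cfg$leak_prob < 0 || cfg$leak_prob > 0.5) {
    stop_config("leak_prob must be in [0, 0.5]")
  }
  if (any(diff(cfg$transcript_len) < 0) || any(diff(cfg$pairs_per_transcript) < 0)) {
    stop_config("ranges must be non-decreasing c(min, max)")
  }
  if (cfg$transcript_len[1L] < 600L && cfg$coding_fraction > 0) {
    stop_config("transcript_len min must be >= 600 so a 300-bp ORF fits")
  }
  class(cfg) <- "sim_config"
  cfg
}

# length-safe sample(): never triggers scalar expansion on length-1 x
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random codons avoiding stops (and ATG is allowed)
rand_codons <- function(n_codons) {
  all3 <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  cods <- paste0(all3$b1, all3$b2, all3$b3)
  cods <- cods[!cods %in% STOP_CODONS]
  paste(sample(cods, n_codons, replace = TRUE), collapse = "")
}

#' Simulate an assembled transcriptome with truth tables
#'
#' @param cfg configuration from [sim_config()].
#' @return list with `records` (transcript table in the [read_fasta()]
#'   layout plus a `label` column: `sense`, `leakage_antisense`,
#'   `contamination`), and `truth` containing `orfs` (planted ORF
#'   coordinates), `twins` (sense/twin id pairs), `snps` (planted sites),
#'   `representative` (planted full-length anchor per component) and
#'   `fragment_of` (parent and window of each fragment isoform).
#' @export
simulate_assembly <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  recs <- list(); orfs <- list(); twins <- list(); frag <- list()
  reps <- list()
  comp_i <- 0L
  for (ci in seq_len(cfg$n_components)) {
    comp_i <- comp_i + 1L
    comp <- sprintf("comp%d_c0", comp_i)
    L <- resample(cfg$transcript_len[1L]:cfg$transcript_len[2L], 1L)
    coding <- runif(1L) < cfg$coding_fraction
    if (coding) {
      # plant an ORF occupying ~60% of the transcript, centered-ish
      orf_len <- 3L * ((round(0.6 * L) %/% 3L))
      orf_len <- max(300L, orf_len)
      utr5 <- max(1L, (L - orf_len) %/% 2L)
      body <- paste0("ATG", rand_codons(orf_len %/% 3L - 2L),
                     sample(STOP_CODONS, 1L))
      # guard the planted frame: upstream base count utr5
      seqv <- paste0(rand_dna(utr5), body, rand_dna(L - utr5 - orf_len))
      orf_start <- utr5 + 1L
      orf_end <- utr5 + orf_len
    } else {
      seqv <- rand_dna(L)
      orf_start <- NA_integer_; orf_end <- NA_integer_
    }
    anchor_id <- sprintf("%s_seq1", comp)
    recs[[length(recs) + 1L]] <- data.table(
      transcript_id = anchor_id, component_id = comp, sequence = seqv,
      length_bp = nchar(seqv), label = "sense")
    reps[[length(reps) + 1L]] <- data.table(component_id = comp,
                                            transcript_id = anchor_id)
    if (coding) {
      orfs[[length(orfs) + 1L]] <- data.table(
        transcript_id = anchor_id, start = orf_start, end = orf_end,
        strand = "+", length_bp = orf_end - orf_start + 1L)
    }
    n_iso <- resample(cfg$isoforms_per_component[1L]:cfg$isoforms_per_component[2L], 1L)
    if (n_iso > 1L) {
      for (k in 2L:n_iso) {
        # fragments are end-truncations (as assembly fragments from
        # coverage gaps typically are), so their hits cover the planted
        # ORF only proportionally
        wfrac <- runif(1L, 0.3, 0.7)
        wlen <- max(200L, round(wfrac * L))
        ws <- if (runif(1L) < 0.5) 1L else L - wlen + 1L
        recs[[length(recs) + 1L]] <- data.table(
          transcript_id = sprintf("%s_seq%d", comp, k), component_id = comp,
          sequence = substring(seqv, ws, ws + wlen - 1L),
          length_bp = wlen, label = "sense")
        frag[[length(frag) + 1L]] <- data.table(
          transcript_id = sprintf("%s_seq%d", comp, k),
          parent_id = anchor_id, win_start = ws, win_end = ws + wlen - 1L)
      }
    }
  }
  rec_dt <- rbindlist(recs)
  # leakage twins for a fraction of anchors, each in its own component
  anchors <- vapply(reps, function(r) r$transcript_id, "")
  n_twin <- round(cfg$twin_fraction * length(anchors))
  twin_of <- if (n_twin > 0L) resample(anchors, n_twin) else character(0)
  for (tid in twin_of) {
    comp_i <- comp_i + 1L
    comp <- sprintf("comp%d_c0", comp_i)
    twin_id <- sprintf("%s_seq1", comp)
    sense_seq <- rec_dt[transcript_id == tid, sequence]
    recs[[length(recs) + 1L]] <- data.table(
      transcript_id = twin_id, component_id = comp,
      sequence = revcomp(sense_seq), length_bp = nchar(sense_seq),
      label = "leakage_antisense")
    twins[[length(twins) + 1L]] <- data.table(sense_id = tid,
                                              antisense_id = twin_id)
  }
  # contamination contigs: short, own components
  n_cont <- round(cfg$contamination_fraction * cfg$n_components)
  for (k in seq_len(n_cont)) {
    comp_i <- comp_i + 1L
    comp <- sprintf("comp%d_c0", comp_i)
    # short-biased lengths: most below 300 bp
    L <- resample(80L:400L, 1L, prob = (400:80)^2)
    recs[[length(recs) + 1L]] <- data.table(
      transcript_id = sprintf("%s_seq1", comp), component_id = comp,
      sequence = rand_dna(L), length_bp = L, label = "contamination")
  }
  rec_dt <- rbindlist(recs)
  # planted substitution sites on sense transcripts
  snps <- list()
  for (i in which(rec_dt$label == "sense")) {
    lam <- rec_dt$length_bp[i] / 1000 * cfg$snp_sites_per_kb
    nsnp <- rpois(1L, lam)
    if (nsnp < 1L) next
    # plant sites in the fully covered interior: positions within one
    # fragment length of an edge are depth-starved by construction
    Li <- rec_dt$length_bp[i]
    frag_bp <- min(cfg$fragment_len, Li)
    span <- if (Li > 2L * frag_bp) frag_bp:(Li - frag_bp) else seq_len(Li)
    p <- resample(span, min(nsnp, length(span)))
    refb <- substring(rec_dt$sequence[i], p, p)
    altb <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    snps[[length(snps) + 1L]] <- data.table(
      transcript_id = rec_dt$transcript_id[i], pos = p, ref = refb,
      alt = unname(altb),
      fraction = resample(cfg$snp_fractions, length(p), replace = TRUE))
  }
  list(records = rec_dt,
       truth = list(
         orfs = if (length(orfs)) rbindlist(orfs) else NULL,
         twins = if (length(twins)) rbindlist(twins) else
           data.table(sense_id = character(0), antisense_id = character(0)),
         snps = if (length(snps)) rbindlist(snps) else
           data.table(transcript_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      fraction = numeric(0)),
         representative = rbindlist(reps),
         fragment_of = if (length(frag)) rbindlist(frag) else NULL))
}

#' Simulate read-pair alignments as SAM text
#'
#' Generates proper FR pairs along every sense transcript: with
#' probability `1 - leak_prob` the second-in-pair read maps on the plus
#' strand (the dUTP expectation), otherwise the pair is flipped
#' ("leakage"). When a sense transcript has a reverse-complement twin
#' every pair is also reported against the twin with mirrored coordinates
#' and flipped strands, emulating the multi-mapped alignment of identical
#' sequence in both orientations (this is what gives twins their strongly
#' positive SSLR). Contamination contigs receive few, orientation-balanced
#' pairs. Planted alleles and uniform sequencing errors are substituted
#' into the read sequences.
#'
#' @param cfg configuration from [sim_config()].
#' @param sim simulated assembly from [simulate_assembly()].
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
simulate_pairs <- function(cfg, sim, path) {
  set.seed(derive_seed(cfg$seed, 2L))
  rec <- sim$records
  twins <- sim$truth$twins
  twin_map <- stats::setNames(twins$antisense_id, twins$sense_id)
  snps <- sim$truth$snps
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rec$transcript_id, rec$length_bp), con)
  bases <- c("A", "C", "G", "T")
  # substitute alleles/errors into read i of a read vector, few at a time
  poke <- function(reads, idx, local_pos, new_base) {
    for (j in seq_along(idx)) {
      substr(reads[idx[j]], local_pos[j], local_pos[j]) <- new_base[j]
    }
    reads
  }
  sam_lines <- function(qname, flag, tid, p, cig, pnext, tlen, sq) {
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t%s\t*",
            qname, flag, tid, p, cig, pnext, tlen, sq)
  }
  for (i in seq_len(nrow(rec))) {
    tid <- rec$transcript_id[i]
    lab <- rec$label[i]
    if (lab == "leakage_antisense") next  # reads arrive via the sense twin
    L <- rec$length_bp[i]
    sq <- rec$sequence[i]
    n <- if (lab == "contamination") {
      resample(cfg$contamination_pairs[1L]:cfg$contamination_pairs[2L], 1L)
    } else {
      resample(cfg$pairs_per_transcript[1L]:cfg$pairs_per_transcript[2L], 1L)
    }
    frag <- min(cfg$fragment_len, L)
    rl <- min(cfg$read_len, frag)
    fs <- if (L > frag) sample.int(L - frag + 1L, n, replace = TRUE) else
      rep(1L, n)
    fe <- fs + frag - 1L
    p_plus <- fs
    p_minus <- fe - rl + 1L
    cig <- sprintf("%dM", rl)
    seq_plus <- substring(sq, p_plus, p_plus + rl - 1L)
    seq_minus <- substring(sq, p_minus, p_minus + rl - 1L)
    # planted alleles: each pair carries each allele with its fraction
    tsnp <- snps[transcript_id == tid]
    if (nrow(tsnp)) {
      for (s in seq_len(nrow(tsnp))) {
        carry <- runif(n) < tsnp$fraction[s]
        sp <- tsnp$pos[s]
        in_p <- carry & sp >= p_plus & sp <= p_plus + rl - 1L
        seq_plus <- poke(seq_plus, which(in_p), sp - p_plus[in_p] + 1L,
                         rep(tsnp$alt[s], sum(in_p)))
        in_m <- carry & sp >= p_minus & sp <= p_minus + rl - 1L
        seq_minus <- poke(seq_minus, which(in_m), sp - p_minus[in_m] + 1L,
                          rep(tsnp$alt[s], sum(in_m)))
      }
    }
    # uniform sequencing errors, drawn per read
    add_err <- function(reads) {
      ne <- rbinom(length(reads), rl, cfg$error_rate)
      for (j in which(ne > 0L)) {
        p <- sample.int(rl, ne[j])
        for (pp in p) {
          old <- substr(reads[j], pp, pp)
          substr(reads[j], pp, pp) <- sample(setdiff(bases, old), 1L)
        }
      }
      reads
    }
    seq_plus <- add_err(seq_plus)
    seq_minus <- add_err(seq_minus)
    flipped <- if (lab == "contamination") runif(n) < 0.5 else
      runif(n) < cfg$leak_prob
    qname <- sprintf("%s:p%d", tid, seq_len(n))
    tl <- fe - fs + 1L
    # FR proper pair: plus-strand mate at fragment start, minus-strand
    # mate at fragment end. Under dUTP the second-in-pair read is the
    # plus mate of a non-flipped (sense) pair; a flipped pair swaps the
    # mate ranks, not the geometry.
    f_plus <- ifelse(flipped, 99L, 163L)    # 0x1|0x2|0x20|0x40 / |0x80
    f_minus <- ifelse(flipped, 147L, 83L)   # 0x1|0x2|0x10|0x80 / |0x40
    out <- c(sam_lines(qname, f_plus, tid, p_plus, cig, p_minus, tl, seq_plus),
             sam_lines(qname, f_minus, tid, p_minus, cig, p_plus, -tl, seq_minus))
    if (lab == "sense" && tid %in% names(twin_map)) {
      # mirrored multi-mapped alignment on the reverse-complement twin:
      # coordinates reflect and strands flip, so the majority (sense)
      # pairs appear antisense there, giving the twin its positive SSLR
      twin_id <- twin_map[[tid]]
      t_plus <- L - fe + 1L                 # plus mate start on the twin
      t_minus <- L - fs + 1L - rl + 1L
      tseq_plus <- revcomp(seq_minus)
      tseq_minus <- revcomp(seq_plus)
      tf_plus <- ifelse(!flipped, 99L, 163L)
      tf_minus <- ifelse(!flipped, 147L, 83L)
      out <- c(out,
               sam_lines(qname, tf_plus, twin_id, t_plus, cig, t_minus, tl, tseq_plus),
               sam_lines(qname, tf_minus, twin_id, t_minus, cig, t_plus, -tl, tseq_minus))
    }
    writeLines(out, con)
  }
  invisible(path)
}

#' Simulate protein and self-nucleotide hit tables
#'
#' Full-length coding isoforms receive a protein hit covering ~100% of a
#' fictitious subject of matched length in both the curated
#' (`uniref100`-like) and general (`nr`-like) tables; fragment isoforms
#' receive proportionally partial hits; e-values are monotone in subject
#' coverage. Each leakage twin appears in the self-nucleotide table as a
#' full-length reversed-coordinate match of its sense transcript.
#'
#' @param cfg configuration from [sim_config()].
#' @param sim simulated assembly from [simulate_assembly()].
#' @param dir output directory; writes `uniref.tsv`, `nr.tsv`,
#'   `self.tsv`.
#' @return invisibly, named vector of the three paths.
#' @export
simulate_hits <- function(cfg, sim, dir) {
  set.seed(derive_seed(cfg$seed, 3L))
  rec <- sim$records
  orfs <- sim$truth$orfs
  frag <- sim$truth$fragment_of
  rows_u <- list(); rows_n <- list(); rows_s <- list()
  if (!is.null(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      tid <- orfs$transcript_id[i]
      slen <- orfs$length_bp[i] %/% 3L  # subject = full protein, aa
      subj <- sprintf("PROT_%s", sub("_seq[0-9]+$", "", tid))
      mk <- function(qid, qs, qe, ss, se, qlen, noise) {
        cov <- (se - ss + 1L) / slen
        ev <- 10^-(pmin(180, pmax(11, 160 * cov + noise)))
        data.table(query_id = qid, subject_id = subj,
                   pident = 98.0, align_len = se - ss + 1L, mismatch = 1L,
                   gapopen = 0L, q_start = qs, q_end = qe,
                   s_start = ss, s_end = se, evalue = ev,
                   bitscore = round(2.2 * (se - ss + 1L), 1),
                   q_len = qlen, s_len = slen)
      }
      qlen <- rec[transcript_id == tid, length_bp]
      rows_u[[length(rows_u) + 1L]] <- mk(tid, orfs$start[i], orfs$end[i] - 3L,
                                          1L, slen - 1L, qlen, runif(1L, 0, 4))
      rows_n[[length(rows_n) + 1L]] <- mk(tid, orfs$start[i], orfs$end[i] - 3L,
                                          1L, slen - 1L, qlen, runif(1L, 0, 4))
      # fragments of this anchor: partial hits clipped to their window
      if (!is.null(frag)) {
        fr <- frag[frag$parent_id == tid, ]
        for (j in seq_len(nrow(fr))) {
          os <- max(orfs$start[i], fr$win_start[j])
          oe <- min(orfs$end[i] - 3L, fr$win_end[j])
          if (oe - os + 1L < 60L) next  # too little of the ORF in window
          # protein coordinates of the covered ORF slice
          ss <- (os - orfs$start[i]) %/% 3L + 1L
          se <- (oe - orfs$start[i]) %/% 3L + 1L
          qs <- os - fr$win_start[j] + 1L
          qe <- oe - fr$win_start[j] + 1L
          qlenf <- rec[transcript_id == fr$transcript_id[j], length_bp]
          rows_u[[length(rows_u) + 1L]] <-
            mk(fr$transcript_id[j], qs, qe, ss, se, qlenf, runif(1L, 0, 4))
          rows_n[[length(rows_n) + 1L]] <-
            mk(fr$transcript_id[j], qs, qe, ss, se, qlenf, runif(1L, 0, 4))
        }
      }
    }
  }
  twins <- sim$truth$twins
  for (i in seq_len(nrow(twins))) {
    sid <- twins$sense_id[i]; aid <- twins$antisense_id[i]
    L <- rec[transcript_id == sid, length_bp]
    rows_s[[length(rows_s) + 1L]] <- data.table(
      query_id = sid, subject_id = aid, pident = 100.0, align_len = L,
      mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = L,
      s_start = L, s_end = 1L, evalue = 1e-180, bitscore = 2 * L,
      q_len = L, s_len = L)
  }
  paths <- c(uniref = file.path(dir, "uniref.tsv"),
             nr = file.path(dir, "nr.tsv"),
             self = file.path(dir, "self.tsv"))
  wr <- function(rows, p) {
    if (length(rows)) {
      fwrite(rbindlist(rows), p, sep = "\t", col.names = FALSE)
    } else {
      file.create(p)
    }
  }
  wr(rows_u, paths[["uniref"]])
  wr(rows_n, paths[["nr"]])
  wr(rows_s, paths[["self"]])
  invisible(paths)
}

#' Simulate two-pool read counts with a planted global offset
#'
#' Null transcripts share expression between pools up to a global
#' log2-scale offset `delta` (pool A over pool B); a fraction of
#' transcripts carry an additional per-transcript differential effect.
#'
#' @param n number of transcripts.
#' @param delta planted global log2 offset.
#' @param de_fraction fraction of genuinely differential transcripts.
#' @param de_log2fc magnitude range of the planted differential effects.
#' @param mean_count mean expression scale.
#' @param seed RNG seed.
#' @return list with `counts_a`, `counts_b` (named vectors) and `truth`
#'   (`data.table` of per-transcript planted effects).
#' @export
simulate_de_counts <- function(n = 1000L, delta = 0, de_fraction = 0.1,
                               de_log2fc = c(1.5, 5), mean_count = 200,
                               seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  ids <- sprintf("comp%d_c0_seq1", seq_len(n))
  base <- exp(log(mean_count) + stats::rnorm(n, 0, 0.8))
  is_de <- runif(n) < de_fraction
  fc <- numeric(n)
  fc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
    runif(sum(is_de), de_log2fc[1L], de_log2fc[2L])
  a <- rpois(n, base * 2^(fc / 2 + delta / 2))
  b <- rpois(n, base * 2^(-fc / 2 - delta / 2))
  list(counts_a = stats::setNames(as.numeric(a), ids),
       counts_b = stats::setNames(as.numeric(b), ids),
       truth = data.table(transcript_id = ids, is_de = is_de, log2fc = fc))
}

#' Run the full simulator and write all artifacts
#'
#' @param cfg configuration from [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of written paths plus the in-memory
#'   simulation object.
#' @export
simulate_run <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_assembly(cfg)
  fa <- file.path(dir, "assembly.fasta")
  write_fasta(sim$records, fa)
  sam <- file.path(dir, "pairs.sam")
  simulate_pairs(cfg, sim, sam)
  hits <- simulate_hits(cfg, sim, dir)
  write_report_tsv(sim$records[, .(transcript_id, component_id, label)],
                   file.path(dir, "truth_labels.tsv"))
  write_report_tsv(sim$truth$twins, file.path(dir, "truth_twins.tsv"))
  write_report_tsv(sim$truth$snps, file.path(dir, "truth_snps.tsv"))
  invisible(list(fasta = fa, sam = sam, hits = hits, sim = sim))
}

utils::globalVariables(c("label", "sequence", "parent_id", "win_start",
                         "win_end", "is_de", "log2fc"))
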