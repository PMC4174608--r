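# End-to-end pipeline: SSLR + leakage filter -> support/coverage filter ->
# ORF reconciliation -> scoring + representative selection -> optional DE
# and variant scan on the representatives. Every discard carries a reason
# code and the run manifest conserves record counts at every stage.

#' Default pipeline parameters
#'
#' All thresholds at their published defaults: SSLR pseudocount 0.5,
#' leakage SSLR bounds -2.5/+1.5, 80% overlap, 10% length excess, 20
#' read pairs, 5-fold dip, 300-bp ORFs, 50% ORF overlap, score > 14,
#' DE inclusion > 50 reads with 0.1 bins and 0.5 zero value, variant
#' depth > 20 with 5%/20% fractions.
#'
#' @return named list of parameters.
#' @export
default_params <- function() {
  list(pseudocount = 0.5,
       sslr_neg_max = -2.5, sslr_pos_min = 1.5, max_len_excess = 0.10,
       min_overlap = 0.80, leakage_mode = "strict",
       min_pairs = 20L, window_bp = 100L, dip_fold = 5.0,
       orf_min_len = 300L, orf_mode = "start_to_stop", overlap_frac = 0.5,
       min_score = 14, max_evalue_protein = 1e-10, max_evalue_nucl = 1e-5,
       de_min_reads = 50L, de_bin_width = 0.1, de_zero_value = 0.5,
       var_min_depth = 21L, var_relaxed_frac = 0.05, var_strict_frac = 0.20,
       drop_duplicates = FALSE, kmer = 16L)
}

#' Run the full post-assembly triage pipeline
#'
#' @param config list naming the inputs and output directory:
#'   `fasta` (required), `sam` (required), `uniref`, `nr` (protein hit
#'   tables), `self_hits` (all-vs-all nucleotide hits; when absent the
#'   built-in detector is used), `priority_orfs` (GFF3),
#'   `taxonomy` (parent-map TSV), `counts_a`/`counts_b` (count TSVs with
#'   columns transcript_id, count), `contaminant_ids` (character vector
#'   flagged upstream, removed before selection), `out_dir` (required),
#'   and `params` overriding any of [default_params()].
#' @return the run manifest (list), invisibly written as
#'   `manifest.json` in `out_dir` along with all stage TSVs.
#' @export
run_pipeline <- function(config) {
  for (need in c("fasta", "sam", "out_dir")) {
    if (is.null(config[[need]])) stop_config("config lacks '", need, "'")
  }
  for (f in c("fasta", "sam", "uniref", "nr", "self_hits", "priority_orfs",
              "taxonomy", "counts_a", "counts_b")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop_data("input file missing: ", config[[f]])
    }
  }
  p <- utils::modifyList(default_params(), config$params %||% list())
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "ssfilter",
                   version = as.character(utils::packageVersion("ssfilter")),
                   params = p, stages = list())
  note_stage <- function(name, n_in, kept, discards) {
    manifest$stages[[name]] <<- list(
      input = n_in, kept = kept,
      discarded = as.list(discards),
      conserved = (n_in == kept + sum(unlist(discards))))
  }

  records <- read_fasta(config$fasta)
  lens <- stats::setNames(records$length_bp, records$transcript_id)
  mappings <- suppressWarnings(
    read_sam_pairs(config$sam, drop_duplicates = isTRUE(p$drop_duplicates)))

  # stage 1: SSLR + leakage filter ------------------------------------
  counts <- tally_orientation(mappings)
  counts <- merge(data.table(transcript_id = records$transcript_id),
                  counts, by = "transcript_id", all.x = TRUE)
  for (cc in c("n_read1_plus", "n_read2_plus", "n_proper_pairs")) {
    counts[is.na(get(cc)), (cc) := 0L]
  }
  sslr_tab <- compute_sslr(counts, pseudocount = p$pseudocount)
  write_report_tsv(sslr_tab, file.path(out_dir, "sslr.tsv"))

  self_hits <- if (!is.null(config$self_hits)) {
    read_blast_tab(config$self_hits, db = "nucl_self")
  } else {
    self_alternate_hits(records, k = p$kmer)
  }
  pairs <- find_alternate_orientation_pairs(self_hits, sslr_tab, lens,
                                            min_overlap = p$min_overlap,
                                            max_evalue = p$max_evalue_nucl)
  discards <- apply_leakage_rules(pairs, sslr_neg_max = p$sslr_neg_max,
                                  sslr_pos_min = p$sslr_pos_min,
                                  max_len_excess = p$max_len_excess,
                                  mode = p$leakage_mode)
  write_report_tsv(discards, file.path(out_dir, "leakage_discards.tsv"))
  surv1 <- records[!transcript_id %in% discards$transcript_id]
  note_stage("leakage", nrow(records), nrow(surv1),
             c(leakage_antisense = nrow(records) - nrow(surv1)))

  # stage 2: support filter (+ contaminant flags) ---------------------
  supp <- support_filter(sslr_tab[transcript_id %in% surv1$transcript_id],
                         min_pairs = p$min_pairs)
  contam <- intersect(config$contaminant_ids %||% character(0),
                      surv1$transcript_id)
  low <- supp[kept == FALSE, transcript_id]
  surv2 <- surv1[!transcript_id %in% c(low, contam)]
  note_stage("support", nrow(surv1), nrow(surv2),
             c(low_support = length(setdiff(low, contam)),
               contaminant = length(contam)))
  cov <- coverage_table(mappings[transcript_id %in% surv2$transcript_id],
                        lens[surv2$transcript_id],
                        window_bp = p$window_bp, dip_fold = p$dip_fold)
  cov <- merge(cov, supp[, .(transcript_id, n_proper_pairs)],
               by = "transcript_id", all.x = TRUE)
  write_report_tsv(cov, file.path(out_dir, "coverage.tsv"))

  # stage 3: ORFs ------------------------------------------------------
  sslr_map <- stats::setNames(sslr_tab$sslr, sslr_tab$transcript_id)
  priority <- if (!is.null(config$priority_orfs)) {
    read_orfs_gff3(config$priority_orfs)
  } else empty_orfs()
  orf_list <- lapply(seq_len(nrow(surv2)), function(i) {
    tid <- surv2$transcript_id[i]
    blt <- find_orfs_sixframe(surv2$sequence[i], min_len = p$orf_min_len,
                              mode = p$orf_mode, transcript_id = tid)
    blt <- strand_restrict(blt, sslr = sslr_map[[tid]])
    pri <- priority[priority$transcript_id == tid, ]
    reconcile_orfs(pri, blt, overlap_frac = p$overlap_frac)
  })
  orfs <- rbindlist(orf_list, fill = TRUE)
  if (nrow(orfs)) {
    orfs[, orf_id := sprintf("%s.orf%d", transcript_id,
                             seq_len(.N)), by = transcript_id]
  }
  write_orfs_gff3(orfs, file.path(out_dir, "orfs.gff3"))

  # stage 4: scoring + representative selection ------------------------
  uniref <- if (!is.null(config$uniref)) {
    first_hits(read_blast_tab(config$uniref, db = "uniref100"),
               max_evalue = p$max_evalue_protein)
  } else empty_hits("uniref100")
  nr <- if (!is.null(config$nr)) {
    first_hits(read_blast_tab(config$nr, db = "nr"),
               max_evalue = p$max_evalue_protein)
  } else empty_hits("nr")
  nr_all <- if (!is.null(config$nr)) {
    read_blast_tab(config$nr, db = "nr")[evalue <= p$max_evalue_protein]
  } else empty_hits("nr")
  dips <- stats::setNames(cov$n_dips, cov$transcript_id)
  evidence <- lapply(seq_len(nrow(surv2)), function(i) {
    tid <- surv2$transcript_id[i]
    torfs <- orfs[orfs$transcript_id == tid, ]
    torfs <- annotate_orf_hits(torfs, nr_all[nr_all$query_id == tid, ])
    list(transcript_id = tid, component_id = surv2$component_id[i],
         length_bp = surv2$length_bp[i],
         sslr = sslr_map[[tid]] %||% 0,
         n_dips = dips[[tid]] %||% 0L,
         uniref_hit = uniref[uniref$query_id == tid, ],
         nr_hit = nr[nr$query_id == tid, ],
         orfs = torfs)
  })
  weights <- score_weights()
  if (!is.null(config$weights)) {
    weights[names(config$weights)] <- unlist(config$weights)
  }
  scores <- score_all(evidence, weights = weights)
  scores <- merge(scores, surv2[, .(transcript_id, length_bp)],
                  by = "transcript_id")
  write_report_tsv(scores, file.path(out_dir, "scores.tsv"))
  reps <- select_representatives(scores, min_score = p$min_score)
  kept_ids <- reps[kept == TRUE, transcript_id]
  rep_rec <- surv2[transcript_id %in% kept_ids]
  write_report_tsv(reps, file.path(out_dir, "representatives.tsv"))
  write_fasta(rep_rec, file.path(out_dir, "representatives.fasta"))
  note_stage("selection", nrow(surv2), length(kept_ids),
             c(not_selected = nrow(surv2) - nrow(reps),
               low_score = nrow(reps[kept == FALSE])))

  # optional: LCA -------------------------------------------------------
  if (!is.null(config$taxonomy) && nrow(nr_all) &&
      "subject_taxon" %in% names(nr_all)) {
    tax <- read_taxonomy(config$taxonomy)
    lt <- lca_table(nr_all[nr_all$query_id %in% kept_ids, ], tax)
    write_report_tsv(lt, file.path(out_dir, "lca.tsv"))
  }

  # optional stage 5: DE ------------------------------------------------
  if (!is.null(config$counts_a) && !is.null(config$counts_b)) {
    ca <- read_counts_tsv(config$counts_a)
    cb <- read_counts_tsv(config$counts_b)
    de <- compute_ratios(ca, cb, min_reads = p$de_min_reads,
                         zero_value = p$de_zero_value)
    de <- mode_center(de, bin_width = p$de_bin_width)
    setorder(de, normalized_log2_ratio)
    write_report_tsv(de, file.path(out_dir, "de.tsv"))
    manifest$stages[["de"]] <- list(input = length(union(names(ca), names(cb))),
                                    kept = nrow(de),
                                    mode_offset = attr(de, "mode_offset"))
  }

  # optional stage 6: variant scan on representatives -------------------
  if (isTRUE(config$variants %||% TRUE)) {
    pl <- build_pileup(mappings[transcript_id %in% kept_ids],
                       drop_duplicates = TRUE)
    sites <- call_substitutions(pl, min_depth = p$var_min_depth,
                                relaxed_frac = p$var_relaxed_frac,
                                strict_frac = p$var_strict_frac)
    write_report_tsv(sites, file.path(out_dir, "sites.tsv"))
    write_sites_vcf(sites, file.path(out_dir, "sites.vcf"))
    manifest$stages[["variants"]] <- list(
      positions = nrow(pl), sites_relaxed = nrow(sites),
      sites_strict = nrow(sites[tier == "strict_20pct"]))
  }

  manifest$inputs <- lapply(
    Filter(Negate(is.null),
           config[intersect(names(config),
                            c("fasta", "sam", "uniref", "nr", "self_hits",
                              "priority_orfs", "taxonomy", "counts_a",
                              "counts_b"))]),
    function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# attach best NR subject / hit presence to each ORF by query-coordinate
# overlap with the ORF span
annotate_orf_hits <- function(orfs, nr_hits) {
  if (!nrow(orfs)) return(orfs)
  out <- data.table::copy(orfs)
  out[, best_subject := NA_character_]
  out[, has_nr_hit := FALSE]
  if (!nrow(nr_hits)) return(out)
  for (i in seq_len(nrow(out))) {
    qs <- pmin(nr_hits$q_start, nr_hits$q_end)
    qe <- pmax(nr_hits$q_start, nr_hits$q_end)
    ov <- pmin(qe, out$end[i]) - pmax(qs, out$start[i]) + 1L
    cand <- which(ov > 0L)
    if (length(cand)) {
      best <- cand[which.min(nr_hits$evalue[cand])]
      out[i, best_subject := nr_hits$subject_id[best]]
      out[i, has_nr_hit := TRUE]
    }
  }
  out
}

read_counts_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  if (ncol(dt) < 2L) stop_data("count TSV needs id and count columns")
  stats::setNames(as.numeric(dt[[2L]]), as.character(dt[[1L]]))
}

utils::globalVariables(c("orf_id", "tier", "n_dips"))
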