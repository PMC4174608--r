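# Weighted evidence scoring and representative selection.
#
# Every surviving putative transcript of a component receives an aggregate
# score: 19 metrics, each normalized into a bounded range and multiplied
# by a non-negative weight. Twelve metrics (A1-A12) derive from the
# transcript sequence and its best protein hits, six (B1-B6) from its
# reconciled ORFs, and one (C1) from coverage dips. The best-scoring
# transcript per component is the representative, retained only when its
# aggregate exceeds the score threshold (default >14, which a transcript
# reaches only with a protein hit or a predicted ORF).

#' Default metric weights
#'
#' @return named numeric vector of the 19 published weights:
#'   A1-A12 = 10, 8, 7, 5, 4, 9, 7, 6, 4, 3, 7, 7; B1-B6 = 10, 10, 8, 3,
#'   8, 8; C1 = 10.
#' @export
score_weights <- function() {
  c(a1 = 10, a2 = 8, a3 = 7, a4 = 5, a5 = 4,
    a6 = 9, a7 = 7, a8 = 6, a9 = 4, a10 = 3,
    a11 = 7, a12 = 7,
    b1 = 10, b2 = 10, b3 = 8, b4 = 3, b5 = 8, b6 = 8,
    c1 = 10)
}

METRIC_NAMES <- names(score_weights())

# subject/query covered lengths of one hit row (orientation-insensitive)
hit_subject_covered <- function(hit) abs(hit$s_end - hit$s_start) + 1L
hit_query_covered <- function(hit) abs(hit$q_end - hit$q_start) + 1L

#' Component context for score normalization
#'
#' Aggregates the per-component maxima that normalize the relative metrics:
#' longest subject/query covered hit lengths per database, longest
#' transcript, maximum |SSLR| and maximum dip count, over all
#' same-component transcripts that reached the scoring stage.
#'
#' @param evidence list of per-transcript evidence bundles (see
#'   [score_transcript()]) belonging to one component.
#' @return a `component_context` list.
#' @export
component_context <- function(evidence) {
  comp <- unique(vapply(evidence, function(e) e$component_id, ""))
  if (length(comp) != 1L) {
    stop_data("component_context: evidence from multiple components: ",
              paste(comp, collapse = ", "))
  }
  maxhit <- function(db, what) {
    v <- vapply(evidence, function(e) {
      h <- e[[db]]
      if (is.null(h) || !nrow(h)) return(0L)
      as.integer(what(h[1L, ]))
    }, 0L)
    max(v)
  }
  structure(list(
    component_id = comp,
    longest_subject_hit = c(uniref100 = maxhit("uniref_hit", hit_subject_covered),
                            nr = maxhit("nr_hit", hit_subject_covered)),
    longest_query_hit = c(uniref100 = maxhit("uniref_hit", hit_query_covered),
                          nr = maxhit("nr_hit", hit_query_covered)),
    longest_transcript = max(vapply(evidence, function(e) e$length_bp, 0L)),
    max_abs_sslr = max(vapply(evidence, function(e) abs(e$sslr), 0.0)),
    max_dips = max(vapply(evidence, function(e) as.integer(e$n_dips), 0L))
  ), class = "component_context")
}

# guarded ratio: 0/0 (or anything over a zero denominator) is neutral 0
gdiv <- function(num, den) if (is.na(den) || den == 0) 0 else num / den

#' Score one transcript against its component context
#'
#' Computes the 19 metrics and their weighted aggregate. The evidence
#' bundle is a list with elements:
#' \describe{
#'   \item{transcript_id, component_id, length_bp}{identity and length}
#'   \item{sslr}{strand-specific log ratio}
#'   \item{n_dips}{coverage dip count}
#'   \item{uniref_hit, nr_hit}{one-row hit tables (first hit per database)
#'     or `NULL`/empty when the database returned nothing}
#'   \item{orfs}{reconciled ORF table with `strand` and, per ORF, optional
#'     `best_subject` (best protein-database subject id) and `has_nr_hit`}
#' }
#' Missing evidence is neutral: absent hits zero that database's A
#' metrics, absent ORFs zero all B metrics, and any 0/0 ratio is 0.
#'
#' @param evidence evidence bundle for one transcript.
#' @param ctx [component_context()] of the transcript's component.
#' @param weights named weight vector as from [score_weights()].
#' @return one-row `data.table`: `transcript_id`, `component_id`, the 19
#'   metric values `m_a1` ... `m_c1`, and `aggregate_score`.
#' @export
score_transcript <- function(evidence, ctx, weights = score_weights()) {
  if (!identical(evidence$component_id, ctx$component_id)) {
    stop_data("score_transcript: context is for component ", ctx$component_id,
              " but transcript belongs to ", evidence$component_id)
  }
  m <- stats::setNames(numeric(length(METRIC_NAMES)), METRIC_NAMES)
  sslr <- evidence$sslr
  norm_sslr <- gdiv(-sslr, ctx$max_abs_sslr)

  a_block <- function(hit, db) {
    v <- c(0, 0, 0, 0, 0)
    if (!is.null(hit) && nrow(hit)) {
      h <- hit[1L, ]
      v[1] <- gdiv(hit_subject_covered(h), h$s_len)
      v[2] <- gdiv(hit_query_covered(h), evidence$length_bp)
      v[3] <- gdiv(hit_subject_covered(h), ctx$longest_subject_hit[[db]])
      v[4] <- gdiv(hit_query_covered(h), ctx$longest_query_hit[[db]])
      match_sign <- if (h$q_start <= h$q_end) 1 else -1
      v[5] <- match_sign * norm_sslr
    }
    v
  }
  m[c("a1", "a2", "a3", "a4", "a5")] <- a_block(evidence$uniref_hit, "uniref100")
  m[c("a6", "a7", "a8", "a9", "a10")] <- a_block(evidence$nr_hit, "nr")
  m["a11"] <- norm_sslr
  m["a12"] <- gdiv(evidence$length_bp, ctx$longest_transcript)

  orfs <- evidence$orfs
  if (!is.null(orfs) && nrow(orfs)) {
    n_orfs <- nrow(orfs)
    subs <- if ("best_subject" %in% names(orfs)) {
      unique(orfs$best_subject[!is.na(orfs$best_subject)])
    } else character(0)
    n_sub <- length(subs)
    m["b1"] <- if (n_sub > 0) (1 - n_sub) / n_sub else 0
    n_plus <- sum(orfs$strand == "+")
    n_minus <- sum(orfs$strand == "-")
    if (n_plus > 0 && n_minus > 0) {
      penalty <- -min(n_plus, n_minus) / max(n_plus, n_minus)
      has_nr <- if ("has_nr_hit" %in% names(orfs)) orfs$has_nr_hit else
        rep(FALSE, n_orfs)
      plus_has <- any(has_nr[orfs$strand == "+"])
      minus_has <- any(has_nr[orfs$strand == "-"])
      slot <- if (plus_has && minus_has) "b2" else
        if (plus_has || minus_has) "b3" else "b4"
      m[slot] <- penalty
    }
    m["b5"] <- (1 - n_orfs) / n_orfs
    orf_sign <- if (n_minus == 0L) 1 else if (n_plus == 0L) -1 else 0
    m["b6"] <- orf_sign * norm_sslr
  }
  m["c1"] <- -gdiv(evidence$n_dips, ctx$max_dips)

  agg <- sum(weights[METRIC_NAMES] * m)
  out <- data.table(transcript_id = evidence$transcript_id,
                    component_id = evidence$component_id)
  for (nm in METRIC_NAMES) out[, paste0("m_", nm) := m[[nm]]]
  out[, aggregate_score := agg]
  out[]
}

#' Score every transcript of an assembly
#'
#' Groups evidence bundles by component, builds each component's context
#' and scores all members.
#'
#' @param evidence list of evidence bundles (all components mixed).
#' @param weights named weight vector.
#' @return `data.table` of score breakdowns, one row per transcript.
#' @export
score_all <- function(evidence, weights = score_weights()) {
  comps <- split(evidence, vapply(evidence, function(e) e$component_id, ""))
  rbindlist(lapply(comps, function(ev) {
    ctx <- component_context(ev)
    rbindlist(lapply(ev, score_transcript, ctx = ctx, weights = weights))
  }))
}

#' Select one representative transcript per component
#'
#' Keeps, per component, the transcript with the maximal aggregate score
#' (ties broken by longer transcript, then lexicographically smaller id),
#' and only when that score strictly exceeds `min_score`.
#'
#' @param scores score table from [score_all()] with an added `length_bp`
#'   column (joined from the assembly).
#' @param min_score strict lower bound on the aggregate (default 14).
#' @return `data.table` with one row per component: the winning transcript
#'   and a `kept` flag (`FALSE` when the best score is <= `min_score`).
#' @export
select_representatives <- function(scores, min_score = 14) {
  s <- data.table::as.data.table(scores)
  if (!"length_bp" %in% names(s)) {
    stop_data("select_representatives: scores need a length_bp column")
  }
  setorder(s, component_id, -aggregate_score, -length_bp, transcript_id)
  best <- s[, .SD[1L], by = component_id]
  best[, kept := aggregate_score > min_score]
  best[, reason := ifelse(kept, "representative", "low_score")]
  best[]
}

utils::globalVariables(c(".SD", "best_subject", "has_nr_hit"))
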