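# Enrichment metrics for virtual-screening validation.

# Rank-sum (Mann-Whitney) AUROC with midrank tie handling: probability
# that a random positive outscores a random negative, ties counting 1/2.
auroc_scores <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: need both positives and negatives")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Enrichment metrics for a screen
#'
#' Evaluates how well known actives rank above the rest of the screened
#' library. AUROC uses the rank-sum formulation with midrank ties on the
#' final scores; enrichment factor and recall use the deterministic rank
#' column of the screen result (ties already broken by compound id).
#'
#' @param results A `screen_result` (see [screen_library()]).
#' @param truth Character vector of compound ids that are true actives;
#'   must be a non-empty proper subset of the screened compounds.
#' @param ef_fraction Top fraction f for the enrichment factor
#'   EF@f = (actives in top f*n / (f*n)) / (actives / n); default 0.1.
#' @param k Cutoff for recall@k (actives in top k / total actives);
#'   default `length(truth)`.
#' @return List with `auroc`, `enrichment_factor`, `ef_fraction`,
#'   `recall_at_k`, `k`, `n`, `n_actives`.
#' @export
evaluate_enrichment <- function(results, truth, ef_fraction = 0.1, k = NULL) {
  stopifnot(inherits(results, "data.frame"),
            all(c("compound_id", "final_score", "rank") %in% names(results)))
  truth <- unique(as.character(truth))
  if (length(truth) == 0L) stop("'truth' is empty: enrichment undefined")
  missing_ids <- setdiff(truth, results$compound_id)
  if (length(missing_ids))
    stop("truth id(s) absent from results: ", paste(missing_ids, collapse = ", "))
  is_active <- results$compound_id %in% truth
  if (all(is_active))
    stop("every screened compound is in 'truth': enrichment undefined")
  n <- nrow(results)
  n_act <- sum(is_active)
  if (is.null(k)) k <- n_act
  if (ef_fraction <= 0 || ef_fraction > 1) stop("'ef_fraction' must be in (0, 1]")
  m <- max(1L, round(ef_fraction * n))
  top_m_actives <- sum(is_active[results$rank <= m])
  top_k_actives <- sum(is_active[results$rank <= k])
  list(auroc = auroc_scores(results$final_score, is_active),
       enrichment_factor = (top_m_actives / m) / (n_act / n),
       ef_fraction = ef_fraction,
       recall_at_k = top_k_actives / n_act,
       k = as.integer(k), n = n, n_actives = n_act)
}
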