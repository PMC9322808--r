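#' Screen a chemical library against reference ligands
#'
#' Scores every library compound against every reference ligand with the
#' trained pair model and assigns each library compound the maximum
#' pairwise score over references as its final target-binding score — the
#' max-aggregation rule of similarity-ensemble screening. The best
#' (arg-max) reference is recorded, ties going to the lexicographically
#' smallest reference id.
#'
#' @param model A trained `ecbs_model` (same fingerprint configuration as
#'   the compound sets).
#' @param references Non-empty `compound_set` of known actives for the
#'   focal target.
#' @param library `compound_set` to screen; may be empty (empty result).
#' @return A data frame of class `screen_result`, sorted by descending
#'   `final_score` with ties broken by ascending `compound_id`, columns:
#'   `compound_id`, `smiles`, `final_score`, `best_reference`, `rank`
#'   (1..n, a strict permutation under the tie rule).
#' @export
screen_library <- function(model, references, library) {
  check_model(model)
  stopifnot(inherits(references, "compound_set"), inherits(library, "compound_set"))
  if (length(references) == 0L) stop("'references' must be non-empty")
  if (!same_fp_config(model$fp_config, references$fp_config) ||
      !same_fp_config(model$fp_config, library$fp_config))
    stop("fingerprint configuration of model, references and library must match")
  empty <- data.frame(compound_id = character(), smiles = character(),
                      final_score = numeric(), best_reference = character(),
                      rank = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("screen_result", "data.frame")
  if (length(library) == 0L) return(empty)

  ref_order <- order(references$compound_id)
  refs <- references[ref_order]
  scores <- ecbs_score_matrix(model, library$fp, refs$fp)
  final <- apply(scores, 1L, max)
  # columns are in ascending reference-id order, so the first max is the
  # lexicographically smallest tied reference
  best <- refs$compound_id[max.col(scores, ties.method = "first")]
  out <- data.frame(compound_id = library$compound_id, smiles = library$smiles,
                    final_score = as.numeric(final), best_reference = best,
                    stringsAsFactors = FALSE)
  ord <- order(-out$final_score, out$compound_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  attr(out, "n_references") <- length(refs)
  out
}

#' Funnel stage constructors
#'
#' Build the ordered stage rules for [apply_funnel()]: a score cutoff
#' (keep `final_score >= cutoff`), a top-k selection (keep the `k`
#' best-ranked survivors), or an externally supplied keep-list — the
#' stand-in for expert manual selection, which the pipeline records but
#' never computes.
#'
#' @param cutoff Minimum final score to survive.
#' @param k Number of best-ranked compounds to keep.
#' @param ids Character vector of compound ids to keep.
#' @return A `funnel_stage` object.
#' @export
stage_score_cutoff <- function(cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  structure(list(type = "score_cutoff", cutoff = cutoff), class = "funnel_stage")
}

#' @rdname stage_score_cutoff
#' @export
stage_top_k <- function(k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  structure(list(type = "top_k", k = k), class = "funnel_stage")
}

#' @rdname stage_score_cutoff
#' @export
stage_keep_list <- function(ids) {
  structure(list(type = "keep_list", ids = as.character(ids)),
            class = "funnel_stage")
}

stage_label <- function(stage) {
  switch(stage$type,
         score_cutoff = sprintf("score_cutoff(%g)", stage$cutoff),
         top_k = sprintf("top_k(%d)", stage$k),
         keep_list = sprintf("keep_list(%d ids)", length(stage$ids)))
}

#' Apply a staged screening funnel
#'
#' Stages are applied in order to the ranked screen result; each stage
#' keeps a subset of the previous stage's survivors, so survivor counts
#' are non-increasing. Ranking from the screen is preserved.
#'
#' @param results A `screen_result`.
#' @param stages List of `funnel_stage` objects (possibly empty).
#' @return The surviving rows (rank order preserved) with a
#'   `stages_passed` column. Attribute `"stage_summary"` is a data frame
#'   (stage, rule, n_in, n_out); attribute `"stage_flags"` records, for
#'   every input compound, a logical per stage (FALSE from the first
#'   failed stage onward) and the number of stages passed.
#' @export
apply_funnel <- function(results, stages) {
  stopifnot(inherits(results, "data.frame"))
  if (!length(stages)) {
    out <- results
    attr(out, "stage_summary") <- data.frame(stage = integer(), rule = character(),
                                             n_in = integer(), n_out = integer())
    return(out)
  }
  if (!all(vapply(stages, inherits, logical(1), "funnel_stage")))
    stop("every stage must be a 'funnel_stage' (see stage_score_cutoff() etc.)")
  flags <- matrix(FALSE, nrow = nrow(results), ncol = length(stages),
                  dimnames = list(results$compound_id,
                                  vapply(stages, stage_label, character(1))))
  current <- results
  summary_rows <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    stage <- stages[[s]]
    n_in <- nrow(current)
    keep <- switch(stage$type,
      score_cutoff = current$final_score >= stage$cutoff,
      top_k = {
        if (stage$k > n_in)
          warning(sprintf("funnel stage %d: top_k = %d > %d compounds; keeping all",
                          s, stage$k, n_in), call. = FALSE)
        seq_len(n_in) <= stage$k  # current is in rank order
      },
      keep_list = {
        unknown <- setdiff(stage$ids, current$compound_id)
        if (length(unknown))
          warning(sprintf("funnel stage %d: keep_list id(s) not among survivors: %s",
                          s, paste(unknown, collapse = ", ")), call. = FALSE)
        current$compound_id %in% stage$ids
      })
    current <- current[keep, , drop = FALSE]
    flags[current$compound_id, s] <- TRUE
    summary_rows[[s]] <- data.frame(stage = s, rule = stage_label(stage),
                                    n_in = n_in, n_out = nrow(current),
                                    stringsAsFactors = FALSE)
  }
  out <- current
  out$stages_passed <- rep(length(stages), nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  attr(out, "stage_summary") <- do.call(rbind, summary_rows)
  attr(out, "stage_flags") <- data.frame(
    compound_id = results$compound_id, flags,
    stages_passed = rowSums(flags), check.names = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

format_stage_flags <- function(results) {
  if (!"stages_passed" %in% names(results)) return(rep(".", nrow(results)))
  n <- results$stages_passed
  vapply(n, function(k) paste(rep("1", k), collapse = ""), character(1))
}

#' Write screen results to TSV/CSV
#'
#' Fixed layout: header plus one row per compound with `compound_id`,
#' `smiles`, `final_score` (6 decimals), `best_reference`, `rank`,
#' `stage_flags` ("1" per funnel stage passed, "." when no funnel was
#' applied). Output is byte-stable for identical inputs.
#'
#' @param results A `screen_result`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`; they differ only in the
#'   delimiter.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  delim <- if (format == "tsv") "\t" else ","
  header <- paste(c("compound_id", "smiles", "final_score", "best_reference",
                    "rank", "stage_flags"), collapse = delim)
  rows <- paste(results$compound_id, results$smiles,
                sprintf("%.6f", results$final_score), results$best_reference,
                results$rank, format_stage_flags(results), sep = delim)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path Path to a TSV/CSV results file.
#' @param format `"tsv"` or `"csv"`.
#' @return A `screen_result` data frame.
#' @export
read_results <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  df <- utils::read.delim(path, sep = if (format == "tsv") "\t" else ",",
                          colClasses = c("character", "character", "numeric",
                                         "character", "integer", "character"))
  class(df) <- c("screen_result", "data.frame")
  df
}
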