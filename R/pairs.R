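# Evolutionarily related chemical pairs (ERCPs): the positive class for
# similarity learning. A pair is positive when both compounds bind targets
# that are identical or homologous to the focal target; negatives pair a
# focal-universe ligand with a compound sharing no related target with it.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards (keeps library-level determinism without
# clobbering the user's RNG).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

compound_ids_of <- function(compounds) {
  if (inherits(compounds, "compound_set")) compounds$compound_id
  else as.character(compounds)
}

#' Enumerate evolutionarily related chemical pairs
#'
#' Positives are all unordered pairs of distinct compounds in the ligand
#' universe U: the compounds active against the focal target or any of its
#' homologs ([related_targets()]). Negatives pair a member of U with a
#' compound outside U that shares no related target with it, sampled
#' uniformly without replacement to `round(negative_ratio * n_positives)`
#' pairs under `seed`.
#'
#' @param activities An `activity_table`; only `active == TRUE` rows define
#'   ligand sets. Every active target must be a node of `graph`.
#' @param graph A `homology_graph`.
#' @param focal_target Focal target id.
#' @param negative_ratio Negatives per positive (default 1).
#' @param seed Integer seed for negative sampling (mandatory: negative
#'   choice is part of the model definition).
#' @param compounds Optional `compound_set` (or character vector of ids)
#'   widening the negative-candidate universe beyond compounds present in
#'   `activities` — e.g. presumed-inactive library decoys. Default: the
#'   compounds appearing in `activities`.
#' @return A data frame of class `ercp_set` with columns `compound_a`,
#'   `compound_b` (unordered, stored with a < b) and `label`
#'   (`"positive"`/`"negative"`). Attributes: `focal_target`, `universe`
#'   (the ligand universe U), `seed`.
#' @export
enumerate_ercps <- function(activities, graph, focal_target,
                            negative_ratio = 1, seed, compounds = NULL) {
  stopifnot(inherits(activities, "data.frame"), nrow(activities) >= 1L,
            inherits(graph, "homology_graph"))
  if (missing(seed)) stop("'seed' is required for negative sampling")
  if (negative_ratio < 0) stop("'negative_ratio' must be non-negative")
  act <- activities[activities$active, , drop = FALSE]
  unknown <- setdiff(unique(act$target_id), graph$nodes)
  if (length(unknown))
    stop("activity table references target(s) absent from the homology graph: ",
         paste(unknown, collapse = ", "))
  rel <- related_targets(graph, focal_target)
  universe <- sort(unique(act$compound_id[act$target_id %in% rel]))
  if (length(universe) < 2L)
    stop("insufficient ligands for focal target '", focal_target,
         "' (need >= 2, found ", length(universe), ")")
  pos <- t(utils::combn(universe, 2L))  # universe sorted => a < b rowwise
  all_ids <- if (is.null(compounds)) sort(unique(activities$compound_id))
             else sort(unique(compound_ids_of(compounds)))
  non_universe <- setdiff(all_ids, universe)

  targets_of <- split(act$target_id, act$compound_id)
  related_of <- lapply(targets_of, function(ts)
    unique(unlist(lapply(unique(ts), related_targets, graph = graph))))
  # eligible negatives: u in U, d outside U, and no target of d is related
  # to any target of u (relatedness is symmetric, so one direction suffices)
  elig_a <- character(0); elig_b <- character(0)
  for (u in universe) {
    rel_u <- related_of[[u]]
    ok <- vapply(non_universe, function(d) {
      td <- targets_of[[d]]
      is.null(td) || !any(td %in% rel_u)
    }, logical(1))
    d_ok <- non_universe[ok]
    elig_a <- c(elig_a, rep(u, length(d_ok)))
    elig_b <- c(elig_b, d_ok)
  }
  neg_a <- pmin(elig_a, elig_b)
  neg_b <- pmax(elig_a, elig_b)
  n_neg_want <- round(negative_ratio * nrow(pos))
  if (length(neg_a) < n_neg_want) {
    warning(sprintf("only %d eligible negative pairs available (wanted %d); using all",
                    length(neg_a), n_neg_want), call. = FALSE)
    keep <- seq_along(neg_a)
  } else {
    keep <- with_seed(seed, sample.int(length(neg_a), n_neg_want))
  }
  neg <- data.frame(compound_a = neg_a[keep], compound_b = neg_b[keep],
                    stringsAsFactors = FALSE)
  neg <- neg[order(neg$compound_a, neg$compound_b), , drop = FALSE]
  out <- data.frame(
    compound_a = c(pos[, 1L], neg$compound_a),
    compound_b = c(pos[, 2L], neg$compound_b),
    label = c(rep("positive", nrow(pos)), rep("negative", nrow(neg))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ercp_set", "data.frame")
  attr(out, "focal_target") <- focal_target
  attr(out, "universe") <- universe
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Symmetric pair feature vector
#'
#' Features of an unordered fingerprint pair, symmetric by construction:
#' an element-wise AND block and an element-wise XOR block (each of length
#' L), followed by a scalar block of Tanimoto similarity, min and max
#' popcount, and shared-bit count. Swapping the arguments leaves every
#' feature unchanged.
#'
#' @param fp_a,fp_b Equal-length bit vectors.
#' @return Numeric vector of length `2 * L + 4`.
#' @export
featurize_pair <- function(fp_a, fp_b) {
  fp_a <- as_fp_logical(fp_a)
  fp_b <- as_fp_logical(fp_b)
  if (length(fp_a) != length(fp_b))
    stop(sprintf("fingerprint length mismatch: %d vs %d",
                 length(fp_a), length(fp_b)))
  and <- as.numeric(fp_a & fp_b)
  xor <- as.numeric(xor(fp_a, fp_b))
  na <- sum(fp_a); nb <- sum(fp_b); common <- sum(and)
  un <- na + nb - common
  tan <- if (un == 0) 0 else common / un
  c(and, xor, tan, min(na, nb), max(na, nb), common)
}

# Batch pair featurization: rows ia/ib index into the fingerprint matrix;
# returns a sparse matrix (pairs x (2L + 4)) suitable for glmnet.
featurize_pairs <- function(fp, ia, ib) {
  a <- fp[ia, , drop = FALSE] * 1
  b <- fp[ib, , drop = FALSE] * 1
  and <- a * b
  xor <- abs(a - b)
  na <- rowSums(a); nb <- rowSums(b); common <- rowSums(and)
  un <- na + nb - common
  tan <- ifelse(un == 0, 0, common / un)
  scal <- cbind(tan, pmin(na, nb), pmax(na, nb), common)
  out <- Matrix::Matrix(cbind(and, xor, scal), sparse = TRUE)
  dimnames(out) <- NULL
  out
}

n_pair_features <- function(n_bits) 2L * n_bits + 4L
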