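# Independent brute-force oracles and tiny fixture builders. These
# re-derive the pair rules and metrics from first principles (O(n^2)
# loops over the raw tables) and must stay independent of the package
# code paths they check.

# compound_set with explicit on-bit lists (1-based)
make_compounds <- function(bits, n_bits = 16L, smiles = NULL) {
  ids <- names(bits)
  fp <- matrix(FALSE, length(bits), n_bits)
  for (i in seq_along(bits)) fp[i, bits[[i]]] <- TRUE
  if (is.null(smiles)) smiles <- paste0("*SYN:", ids)
  compound_set(ids, smiles, fp, fp_config = fingerprint_config(n_bits = n_bits))
}

random_fp_matrix <- function(n, n_bits, density = 0.2) {
  matrix(runif(n * n_bits) < density, n, n_bits)
}

# Brute-force ERCP oracle. Works directly off the identity matrix and the
# raw activity rows: related(t) = {t} + {s : identity >= threshold}.
# Returns canonical "a|b" keys for the positive set and the
# negative-eligible set.
brute_force_ercps <- function(activities, identity, threshold, focal,
                              universe_ids) {
  act <- activities[activities$active, , drop = FALSE]
  related <- function(t) {
    others <- setdiff(rownames(identity), t)
    c(t, others[identity[t, others] >= threshold])
  }
  targets_of <- function(c) unique(act$target_id[act$compound_id == c])
  rel_focal <- related(focal)
  U <- sort(unique(act$compound_id[act$target_id %in% rel_focal]))
  key <- function(a, b) paste(min(a, b), max(a, b), sep = "|")
  positives <- character(0)
  if (length(U) >= 2) {
    for (i in seq_len(length(U) - 1)) for (j in seq(i + 1, length(U)))
      positives <- c(positives, key(U[i], U[j]))
  }
  eligible <- character(0)
  for (u in U) {
    rel_u <- unique(unlist(lapply(targets_of(u), related)))
    for (d in setdiff(universe_ids, U)) {
      td <- targets_of(d)
      if (length(td) == 0 || !any(td %in% rel_u))
        eligible <- c(eligible, key(u, d))
    }
  }
  list(universe = U, positives = sort(unique(positives)),
       eligible_negatives = sort(unique(eligible)))
}

pair_keys <- function(pairs) paste(pairs$compound_a, pairs$compound_b, sep = "|")

# Exhaustive pairwise-concordance AUROC: ties count 1/2.
brute_force_auroc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Random small world for oracle-equivalence suites: <= 30 compounds,
# <= 6 targets, random identities and ligand assignments.
random_small_world <- function(seed) {
  set.seed(seed)
  n_t <- sample(2:6, 1)
  n_c <- sample(8:30, 1)
  t_ids <- sprintf("T%d", seq_len(n_t))
  c_ids <- sprintf("c%02d", seq_len(n_c))
  identity <- matrix(0, n_t, n_t, dimnames = list(t_ids, t_ids))
  for (i in seq_len(n_t - 1)) for (j in seq(i + 1, n_t))
    identity[i, j] <- identity[j, i] <- round(runif(1), 2)
  diag(identity) <- 1
  # each compound binds 0-2 targets (0 = pure decoy)
  rows_c <- character(0); rows_t <- character(0)
  for (cc in c_ids) {
    k <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
    if (k > 0) {
      for (tt in sample(t_ids, k)) {
        rows_c <- c(rows_c, cc); rows_t <- c(rows_t, tt)
      }
    }
  }
  threshold <- sample(c(0.3, 0.5, 0.7), 1)
  list(targets = target_set(t_ids),
       activities = if (length(rows_c))
         activity_table(rows_c, rows_t, TRUE) else NULL,
       identity = identity,
       identity_table = data.frame(
         target_a = rep(t_ids, times = n_t)[upper.tri(identity)],
         target_b = rep(t_ids, each = n_t)[upper.tri(identity)],
         identity = identity[upper.tri(identity)]),
       compounds = c_ids, threshold = threshold)
}

# hand-built ranked screen result (bypasses any model)
fake_results <- function(scores, ids = sprintf("x%02d", seq_along(scores))) {
  ord <- order(-scores, ids)
  out <- data.frame(compound_id = ids[ord], smiles = paste0("*SYN:", ids[ord]),
                    final_score = scores[ord],
                    best_reference = "r1", rank = seq_along(scores),
                    stringsAsFactors = FALSE)
  class(out) <- c("screen_result", "data.frame")
  out
}

# tiny trained model shared across score-contract tests
fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- generate_world(world_config(seed = 42, actives_per_target = 6,
                                       n_decoys = 30,
                                       fingerprint_length = 128L,
                                       motif_size = 16L))
      run <- suppressWarnings(screen_synthetic_world(w, n_ensemble = 3L))
      cache <<- list(world = w, run = run, model = run$model)
    }
    cache
  }
})
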