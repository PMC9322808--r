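#' Training configuration for an ECBS model
#'
#' @param n_ensemble Number of bootstrap-trained ensemble members (default
#'   10). The final score is the mean of the members' positive-class
#'   probabilities.
#' @param learner Probabilistic binary classifier family. Currently
#'   `"glmnet"`: penalized logistic regression, the probabilistic learner
#'   available in this stack; any learner emitting positive-class
#'   probabilities satisfies the contract.
#' @param alpha Elastic-net mixing for glmnet (0 = ridge, default).
#' @param lambda Regularization strength at which members predict
#'   (default 0.01).
#' @param test_fraction Fraction of compounds held out for the
#'   compound-disjoint evaluation split (default 0.25). Pairs straddling
#'   the split are used for neither training nor testing, which prevents
#'   the leakage of one molecule into both sides.
#' @param seed Integer seed controlling the split and the bootstrap
#'   resampling.
#' @return A list of class `ecbs_training_config`.
#' @export
ecbs_training_config <- function(n_ensemble = 10L, learner = "glmnet",
                                 alpha = 0, lambda = 0.01,
                                 test_fraction = 0.25, seed = 1L) {
  learner <- match.arg(learner, c("glmnet"))
  n_ensemble <- as.integer(n_ensemble)
  if (n_ensemble < 1L) stop("'n_ensemble' must be >= 1")
  if (test_fraction < 0 || test_fraction >= 1)
    stop("'test_fraction' must be in [0, 1)")
  if (lambda <= 0) stop("'lambda' must be positive")
  structure(list(n_ensemble = n_ensemble, learner = learner, alpha = alpha,
                 lambda = lambda, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "ecbs_training_config")
}

fit_member <- function(x, y, config) {
  # short warm-start path down to the target lambda; predictions are taken
  # at s = config$lambda
  path <- config$lambda * c(100, 10, 1)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = config$alpha,
                        lambda = path, standardize = FALSE)
  list(fit = fit, s = config$lambda)
}

predict_member <- function(member, x) {
  as.numeric(stats::predict(member$fit, newx = x, s = member$s,
                            type = "response"))
}

#' Train a target-specific ensemble ECBS model
#'
#' Fits a bootstrap ensemble of probabilistic pair classifiers on labelled
#' chemical pairs ([enumerate_ercps()]). Pair features are the symmetric
#' AND/XOR/scalar blocks of [featurize_pair()]. Held-out performance is
#' estimated on a compound-disjoint split: test pairs share no compound
#' with any training pair.
#'
#' @param pairs An `ercp_set` (or data frame with `compound_a`,
#'   `compound_b`, `label`) containing both labels.
#' @param compounds A `compound_set` resolving every id in `pairs`.
#' @param config An [ecbs_training_config()].
#' @return An object of class `ecbs_model` with the fitted members, the
#'   fingerprint configuration it was trained under, the focal target, and
#'   `cv_auroc`, the out-of-sample pair AUROC on the compound-disjoint
#'   test split (NA when the split is too small to evaluate).
#' @export
train_ecbs_model <- function(pairs, compounds, config = ecbs_training_config()) {
  stopifnot(inherits(pairs, "data.frame"), inherits(compounds, "compound_set"),
            inherits(config, "ecbs_training_config"))
  labs <- unique(pairs$label)
  if (!all(c("positive", "negative") %in% labs))
    stop("training pairs must contain both positive and negative labels")
  involved <- unique(c(pairs$compound_a, pairs$compound_b))
  missing_ids <- setdiff(involved, compounds$compound_id)
  if (length(missing_ids))
    stop("pair compound id(s) not found in compound set: ",
         paste(missing_ids, collapse = ", "))

  n_test <- round(config$test_fraction * length(involved))
  test_ids <- if (n_test >= 2L)
    with_seed(config$seed, sample(sort(involved), n_test)) else character(0)
  in_test <- pairs$compound_a %in% test_ids | pairs$compound_b %in% test_ids
  both_test <- pairs$compound_a %in% test_ids & pairs$compound_b %in% test_ids
  train_pairs <- pairs[!in_test, , drop = FALSE]
  test_pairs <- pairs[both_test, , drop = FALSE]
  if (min(table(factor(train_pairs$label,
                       c("positive", "negative")))) < 2L) {
    warning("compound-disjoint split left fewer than 2 pairs of one label; ",
            "training on all pairs without held-out evaluation", call. = FALSE)
    train_pairs <- pairs
    test_pairs <- pairs[0L, , drop = FALSE]
  }

  fp <- compounds$fp
  idx <- function(p) list(a = match(p$compound_a, compounds$compound_id),
                          b = match(p$compound_b, compounds$compound_id))
  it <- idx(train_pairs)
  x_train <- featurize_pairs(fp, it$a, it$b)
  y_train <- as.integer(train_pairs$label == "positive")

  members <- vector("list", config$n_ensemble)
  for (b in seq_len(config$n_ensemble)) {
    class_min <- function(y) min(tabulate(y + 1L, nbins = 2L))
    rows <- with_seed(config$seed * 1000L + b, {
      r <- sample.int(nrow(x_train), replace = TRUE)
      tries <- 0L
      while (class_min(y_train[r]) < 2L && tries < 100L) {
        r <- sample.int(nrow(x_train), replace = TRUE)
        tries <- tries + 1L
      }
      r
    })
    if (class_min(y_train[rows]) < 2L) rows <- seq_len(nrow(x_train))
    members[[b]] <- fit_member(x_train[rows, , drop = FALSE], y_train[rows],
                               config)
  }

  cv_auroc <- NA_real_
  if (nrow(test_pairs) >= 4L && length(unique(test_pairs$label)) == 2L) {
    ie <- idx(test_pairs)
    x_test <- featurize_pairs(fp, ie$a, ie$b)
    probs <- rowMeans(vapply(members, predict_member, numeric(nrow(x_test)),
                             x = x_test))
    cv_auroc <- auroc_scores(probs, test_pairs$label == "positive")
  }

  structure(list(members = members, config = config,
                 fp_config = compounds$fp_config,
                 focal_target = attr(pairs, "focal_target"),
                 cv_auroc = cv_auroc,
                 n_train_pairs = nrow(train_pairs),
                 n_test_pairs = nrow(test_pairs),
                 package_version = as.character(utils::packageVersion("ecbscreen"))),
            class = "ecbs_model")
}

#' @export
print.ecbs_model <- function(x, ...) {
  cat(sprintf("<ecbs_model> focal target %s: %d-member %s ensemble, %d-bit fingerprints\n",
              x$focal_target %||% "<unset>", length(x$members),
              x$config$learner, x$fp_config$n_bits))
  cat(sprintf("  trained on %d pairs; held-out pair AUROC %s\n", x$n_train_pairs,
              if (is.na(x$cv_auroc)) "NA" else sprintf("%.3f", x$cv_auroc)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_model <- function(model) {
  if (!inherits(model, "ecbs_model") || !length(model$members) ||
      is.null(model$fp_config))
    stop("not a trained ecbs_model")
}

#' Pairwise ECBS score
#'
#' Mean positive-class probability of the ensemble members for one
#' fingerprint pair: the learned chemical binding similarity, in \[0, 1\]
#' and symmetric in its arguments.
#'
#' @param model A trained `ecbs_model`.
#' @param fp_a,fp_b Fingerprints of the model's configured length.
#' @return Score in \[0, 1\].
#' @export
ecbs_score <- function(model, fp_a, fp_b) {
  check_model(model)
  fp_a <- as_fp_logical(fp_a); fp_b <- as_fp_logical(fp_b)
  L <- model$fp_config$n_bits
  if (length(fp_a) != L || length(fp_b) != L)
    stop(sprintf("fingerprint length mismatch: model expects %d bits, got %d and %d",
                 L, length(fp_a), length(fp_b)))
  x <- featurize_pairs(rbind(fp_a, fp_b), 1L, 2L)
  mean(vapply(model$members, function(m) predict_member(m, x), numeric(1)))
}

#' All-against-all ECBS score matrix
#'
#' @param model A trained `ecbs_model`.
#' @param fp_rows,fp_cols Fingerprint matrices (one compound per row) of
#'   the model's configured length.
#' @return `nrow(fp_rows) x nrow(fp_cols)` matrix of scores in \[0, 1\].
#' @export
ecbs_score_matrix <- function(model, fp_rows, fp_cols) {
  check_model(model)
  L <- model$fp_config$n_bits
  if (ncol(fp_rows) != L || ncol(fp_cols) != L)
    stop(sprintf("fingerprint length mismatch: model expects %d bits, got %d and %d",
                 L, ncol(fp_rows), ncol(fp_cols)))
  n <- nrow(fp_rows); m <- nrow(fp_cols)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  fp <- rbind(fp_rows, fp_cols)
  ia <- rep(seq_len(n), times = m)
  ib <- rep(n + seq_len(m), each = n)
  x <- featurize_pairs(fp, ia, ib)
  probs <- rowMeans(vapply(model$members, predict_member,
                           numeric(length(ia)), x = x))
  matrix(probs, nrow = n, ncol = m)
}

#' Save / load an ECBS model
#'
#' The archive embeds the training and fingerprint configuration; a
#' reloaded model produces identical scores. [ecbs_score()] refuses
#' fingerprints whose length disagrees with the embedded configuration.
#'
#' @param model A trained `ecbs_model`.
#' @param path Archive path (RDS).
#' @return `save_ecbs_model` returns `path` invisibly; `load_ecbs_model`
#'   returns the model.
#' @export
save_ecbs_model <- function(model, path) {
  check_model(model)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ecbs_model
#' @export
load_ecbs_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  model <- readRDS(path)
  check_model(model)
  model
}
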