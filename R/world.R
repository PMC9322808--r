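# Synthetic compound/target worlds with planted signal. Each target family
# carries a disjoint fingerprint motif; its actives set each motif bit with
# probability motif_strength on top of uniform background bits, and decoys
# carry background only. The family structure plus a matching identity
# table give every other module a fully known ground truth to recover.

#' Synthetic world configuration
#'
#' @param n_target_families Number of target families (default 2).
#' @param targets_per_family Targets per family (default 2).
#' @param within_family_identity Fractional sequence identity assigned to
#'   target pairs within a family (default 0.6 — comfortably above the 0.4
#'   homology threshold).
#' @param across_family_identity Identity across families (default 0.1);
#'   must be below `within_family_identity`.
#' @param actives_per_target Planted active compounds per target
#'   (default 10).
#' @param n_decoys Background-only decoy compounds (default 200).
#' @param motif_strength Probability that an active carries each of its
#'   family's motif bits (1 = fully planted signal, 0 = no signal).
#' @param fingerprint_length Bit-vector length L (default 512 for
#'   simulation speed; real-chemistry runs default to 2048).
#' @param motif_size Motif bits per family (default 32); family motifs are
#'   disjoint, so `n_target_families * motif_size <= fingerprint_length`.
#' @param background_density Probability of each background bit being set
#'   (default 0.05, i.e. ~26 on-bits at L = 512, a typical small-molecule
#'   popcount density).
#' @param smiles_mode `"placeholder"` (default): fingerprints are generated
#'   directly and SMILES are inert placeholders — fast, no chemistry
#'   toolkit involved. `"fragment"`: compounds are assembled from a small
#'   fragment grammar as real, parseable SMILES (family scaffold fragment
#'   plays the motif role) and fingerprinted with RDKit — for end-to-end
#'   CLI tests.
#' @param seed Integer seed; worlds are deterministic given the config.
#' @return A `world_config` object.
#' @export
world_config <- function(n_target_families = 2L, targets_per_family = 2L,
                         within_family_identity = 0.6,
                         across_family_identity = 0.1,
                         actives_per_target = 10L, n_decoys = 200L,
                         motif_strength = 1.0, fingerprint_length = 512L,
                         motif_size = 32L, background_density = 0.05,
                         smiles_mode = c("placeholder", "fragment"),
                         seed = 1L) {
  smiles_mode <- match.arg(smiles_mode)
  cfg <- list(n_target_families = as.integer(n_target_families),
              targets_per_family = as.integer(targets_per_family),
              within_family_identity = within_family_identity,
              across_family_identity = across_family_identity,
              actives_per_target = as.integer(actives_per_target),
              n_decoys = as.integer(n_decoys),
              motif_strength = motif_strength,
              fingerprint_length = as.integer(fingerprint_length),
              motif_size = as.integer(motif_size),
              background_density = background_density,
              smiles_mode = smiles_mode,
              seed = as.integer(seed))
  for (f in c("n_target_families", "targets_per_family", "actives_per_target",
              "n_decoys", "motif_size", "fingerprint_length"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop("'", f, "' must be >= 1")
  for (f in c("within_family_identity", "across_family_identity",
              "motif_strength", "background_density"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be a fraction in [0, 1]")
  if (cfg$within_family_identity <= cfg$across_family_identity)
    stop("'within_family_identity' must exceed 'across_family_identity'")
  if (cfg$n_target_families * cfg$motif_size > cfg$fingerprint_length)
    stop("family motifs cannot be disjoint: n_target_families * motif_size = ",
         cfg$n_target_families * cfg$motif_size, " > fingerprint_length = ",
         cfg$fingerprint_length)
  structure(cfg, class = "world_config")
}

# fragment grammar for smiles_mode = "fragment": compounds are dot-
# disconnected unions of valid fragments, so concatenation stays parseable
world_scaffolds <- c("c1ccc2ccccc2c1",          # naphthalene
                     "C1CCC2CCCCC2C1",          # decalin
                     "c1ccc2[nH]ccc2c1",        # indole
                     "c1ccc(-c2ccccc2)cc1",     # biphenyl
                     "C1CCC2(CC1)CCCC2",        # spiro[4.5]decane
                     "c1ccc2ncccc2c1")          # quinoline
world_fragments <- c("CCO", "CCN", "CC(C)C", "CCCl", "CC=O", "c1ccccc1",
                     "C1CCCC1", "CC#N", "CSC", "CO", "CC(N)=O", "C1CCOC1",
                     "c1ccncc1", "CCC(C)O")

random_fragment_smiles <- function(n_bg) {
  paste(sample(world_fragments, n_bg, replace = TRUE), collapse = ".")
}

#' Generate a synthetic compound/target world
#'
#' See [world_config()] for the generative model. The returned world
#' contains a `compound_set` (fingerprints generated directly in
#' placeholder mode, or RDKit fingerprints of grammar-built SMILES in
#' fragment mode), a `target_set` with family labels, a symmetric pairwise
#' identity table consistent with the config, an `activity_table` linking
#' each active to its target, and the ground-truth binder set of the focal
#' family (the first family; its first target is the focal target).
#'
#' @param config A [world_config()].
#' @param fp_config Fingerprint configuration for fragment mode; default
#'   radius 2 with `config$fingerprint_length` bits.
#' @return A `synthetic_world` list: `compounds`, `targets`, `identity`,
#'   `activities`, `ground_truth`, `focal_family`, `focal_target`,
#'   `motifs`, `config`.
#' @export
generate_world <- function(config, fp_config = NULL) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, generate_world_impl(config, fp_config))
}

generate_world_impl <- function(config, fp_config) {
  nf <- config$n_target_families
  tp <- config$targets_per_family
  L <- config$fingerprint_length
  fam <- rep(seq_len(nf), each = tp)
  targets <- target_set(sprintf("T%d_%d", fam, rep(seq_len(tp), times = nf)),
                        family = sprintf("FAM%d", fam))
  # symmetric all-pairs identity table from the two configured levels
  pair_idx <- t(utils::combn(nrow(targets), 2L))
  identity <- data.frame(
    target_a = targets$target_id[pair_idx[, 1L]],
    target_b = targets$target_id[pair_idx[, 2L]],
    identity = ifelse(targets$family[pair_idx[, 1L]] ==
                        targets$family[pair_idx[, 2L]],
                      config$within_family_identity,
                      config$across_family_identity),
    stringsAsFactors = FALSE)

  motif_bits <- sample.int(L, nf * config$motif_size)
  motifs <- split(motif_bits, rep(seq_len(nf), each = config$motif_size))
  names(motifs) <- sprintf("FAM%d", seq_len(nf))

  active_ids <- character(0); active_target <- character(0)
  for (t in seq_len(nrow(targets))) {
    ids <- sprintf("CPD_%s_%02d", targets$target_id[t],
                   seq_len(config$actives_per_target))
    active_ids <- c(active_ids, ids)
    active_target <- c(active_target, rep(targets$target_id[t], length(ids)))
  }
  decoy_ids <- sprintf("DEC_%04d", seq_len(config$n_decoys))
  all_ids <- c(active_ids, decoy_ids)
  fam_of_active <- targets$family[match(active_target, targets$target_id)]

  if (config$smiles_mode == "placeholder") {
    fp <- matrix(stats::runif(length(all_ids) * L) < config$background_density,
                 nrow = length(all_ids), ncol = L)
    for (i in seq_along(active_ids)) {
      m <- motifs[[fam_of_active[i]]]
      fp[i, m[stats::runif(length(m)) < config$motif_strength]] <- TRUE
    }
    smiles <- paste0("*SYN:", all_ids)  # inert placeholder, not parseable
    compounds <- compound_set(all_ids, smiles, fp, source = "synthetic",
                              fp_config = fingerprint_config(n_bits = L))
  } else {
    if (nf > length(world_scaffolds))
      stop("fragment mode supports at most ", length(world_scaffolds),
           " families")
    scaffold_of <- world_scaffolds[seq_len(nf)]
    names(scaffold_of) <- sprintf("FAM%d", seq_len(nf))
    smiles <- character(length(all_ids))
    for (i in seq_along(active_ids)) {
      bg <- random_fragment_smiles(sample(2:4, 1L))
      smiles[i] <- if (stats::runif(1) < config$motif_strength)
        paste(scaffold_of[[fam_of_active[i]]], bg, sep = ".") else bg
    }
    for (j in seq_along(decoy_ids))
      smiles[length(active_ids) + j] <- random_fragment_smiles(sample(3:5, 1L))
    if (is.null(fp_config)) fp_config <- fingerprint_config(n_bits = L)
    fp <- compute_fingerprint(smiles, fp_config)
    compounds <- compound_set(all_ids, smiles, fp, source = "synthetic",
                              fp_config = fp_config)
  }

  activities <- activity_table(active_ids, active_target, active = TRUE)
  ground_truth <- active_ids[fam_of_active == "FAM1"]
  structure(list(compounds = compounds, targets = targets,
                 identity = identity, activities = activities,
                 ground_truth = ground_truth, focal_family = "FAM1",
                 focal_target = targets$target_id[1L],
                 motifs = motifs, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d compounds (%d actives + %d decoys), %d targets in %d families\n",
              length(x$compounds),
              length(x$compounds) - x$config$n_decoys, x$config$n_decoys,
              nrow(x$targets), x$config$n_target_families))
  cat(sprintf("  focal target %s (family %s), motif_strength %g, seed %d\n",
              x$focal_target, x$focal_family, x$config$motif_strength,
              x$config$seed))
  invisible(x)
}

#' Train-and-screen validation run on a synthetic world
#'
#' The canonical validation loop, with a strict compound-level holdout so
#' the screen is evaluated only on molecules the model has never seen
#' (screening a compound that was itself a training pair member lets the
#' classifier recognize it outright and inflates enrichment even without
#' signal). Per target, `1 - holdout_fraction` of the ligands play the
#' "known ligand" role: the focal target's known ligands are the
#' references, known ligands define the ERCP training universe, and
#' training negatives are drawn only from known compounds plus half of the
#' decoys. The screened library is everything held out: unseen actives of
#' every family plus the unseen decoys; the recoverable truth is the
#' held-out focal-family actives. Also reports the unlearned baseline —
#' ranking by maximum Tanimoto similarity to any reference.
#'
#' @param world A `synthetic_world`.
#' @param threshold Homology identity threshold (default 0.4).
#' @param negative_ratio Negatives per positive for training (default 1).
#' @param n_ensemble Ensemble size (default 10).
#' @param holdout_fraction Fraction of each target's ligands (and of the
#'   decoys) reserved for the screened library (default 0.5).
#' @param seed Integer seed for the holdout split, pair sampling and
#'   bootstrap resampling; defaults to the world's seed.
#' @return List: `model`, `results` (`screen_result` over the held-out
#'   library), `references`, `truth` (held-out focal-family actives),
#'   `metrics` ([evaluate_enrichment()] output), `baseline_auroc`
#'   (max-Tanimoto ranking of the same library), `graph`.
#' @export
screen_synthetic_world <- function(world, threshold = 0.4, negative_ratio = 1,
                                   n_ensemble = 10L, holdout_fraction = 0.5,
                                   seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (is.null(seed)) seed <- world$config$seed
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("'holdout_fraction' must be in (0, 1)")
  graph <- build_homology_graph(world$targets, "identity_table",
                                threshold = threshold,
                                identity_table = world$identity)
  act <- world$activities[world$activities$active, , drop = FALSE]
  ligands_of <- split(act$compound_id, act$target_id)
  all_ids <- world$compounds$compound_id
  decoys <- setdiff(all_ids, act$compound_id)

  held_out <- with_seed(seed, {
    per_target <- lapply(names(ligands_of), function(t) {
      ids <- sort(ligands_of[[t]])
      sample(ids, floor(holdout_fraction * length(ids)))
    })
    c(unlist(per_target), sample(sort(decoys),
                                 floor(holdout_fraction * length(decoys))))
  })
  known <- setdiff(all_ids, held_out)

  train_act <- act[act$compound_id %in% known, , drop = FALSE]
  ref_ids <- sort(train_act$compound_id[train_act$target_id == world$focal_target])
  if (length(ref_ids) < 2L)
    stop("holdout left fewer than 2 known ligands for the focal target; ",
         "increase actives_per_target or lower holdout_fraction")
  references <- world$compounds[ref_ids]
  library_set <- world$compounds[sort(held_out)]

  pairs <- enumerate_ercps(train_act, graph, world$focal_target,
                           negative_ratio = negative_ratio, seed = seed,
                           compounds = world$compounds[known])
  model <- train_ecbs_model(pairs, world$compounds,
                            ecbs_training_config(n_ensemble = n_ensemble,
                                                 seed = seed))
  results <- screen_library(model, references, library_set)
  truth <- intersect(world$ground_truth, library_set$compound_id)
  metrics <- evaluate_enrichment(results, truth)
  tani <- tanimoto_matrix(library_set$fp, references$fp)
  baseline_scores <- apply(tani, 1L, max)
  baseline_auroc <- auroc_scores(baseline_scores,
                                 library_set$compound_id %in% truth)
  list(model = model, results = results, references = references,
       truth = truth, metrics = metrics, baseline_auroc = baseline_auroc,
       graph = graph)
}
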