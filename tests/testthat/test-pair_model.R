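# ERCP enumeration, pair featurization, training, scoring.

three_target_world <- function() {
  # T1-T2 homologous, T3 unrelated; ligands {c1,c2}->T1, {c3}->T2, {c4}->T3
  ident <- data.frame(target_a = c("T1", "T1", "T2"),
                      target_b = c("T2", "T3", "T3"),
                      identity = c(0.8, 0.1, 0.1))
  list(graph = build_homology_graph(target_set(c("T1", "T2", "T3")),
                                    "identity_table", threshold = 0.5,
                                    identity_table = ident),
       activities = activity_table(c("c1", "c2", "c3", "c4"),
                                   c("T1", "T1", "T2", "T3")))
}

test_that("ERCP positives pool ligands of the focal target and its homologs", {
  w <- three_target_world()
  pairs <- enumerate_ercps(w$activities, w$graph, "T1", negative_ratio = 0,
                           seed = 1)
  pos <- pairs[pairs$label == "positive", ]
  expect_setequal(pair_keys(pos), c("c1|c2", "c1|c3", "c2|c3"))
  expect_equal(attr(pairs, "universe"), c("c1", "c2", "c3"))
})

test_that("negatives come from the eligible set, deterministically per seed", {
  w <- three_target_world()
  p1 <- enumerate_ercps(w$activities, w$graph, "T1", negative_ratio = 1,
                        seed = 99)
  neg <- p1[p1$label == "negative", ]
  expect_equal(nrow(neg), 3L)
  expect_true(all(pair_keys(neg) %in% c("c1|c4", "c2|c4", "c3|c4")))
  p2 <- enumerate_ercps(w$activities, w$graph, "T1", negative_ratio = 1,
                        seed = 99)
  expect_identical(p1, p2)

  expect_error(enumerate_ercps(w$activities, w$graph, "T3", seed = 1),
               "insufficient ligands for focal target 'T3'")
  # asking for more negatives than exist: warn and return all available
  expect_warning(p3 <- enumerate_ercps(w$activities, w$graph, "T1",
                                       negative_ratio = 5, seed = 1),
                 "eligible negative")
  expect_equal(sum(p3$label == "negative"), 3L)
})

test_that("ERCP enumeration agrees with the brute-force oracle", {
  n_checked <- 0
  for (seed in 1:24) {
    w <- random_small_world(seed)
    if (is.null(w$activities)) next
    graph <- build_homology_graph(w$targets, "identity_table",
                                  threshold = w$threshold,
                                  identity_table = w$identity_table)
    for (focal in w$targets$target_id) {
      oracle <- brute_force_ercps(w$activities, w$identity, w$threshold,
                                  focal, w$compounds)
      if (length(oracle$universe) < 2) {
        expect_error(enumerate_ercps(w$activities, graph, focal, seed = seed,
                                     compounds = w$compounds),
                     "insufficient ligands")
        next
      }
      pairs <- suppressWarnings(
        enumerate_ercps(w$activities, graph, focal, negative_ratio = 1e6,
                        seed = seed, compounds = w$compounds))
      expect_setequal(pair_keys(pairs[pairs$label == "positive", ]),
                      oracle$positives)
      # negative_ratio is huge, so sampling returns the whole eligible set
      expect_setequal(pair_keys(pairs[pairs$label == "negative", ]),
                      oracle$eligible_negatives)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("pair featurization is symmetric with the documented blocks", {
  set.seed(5)
  L <- 32L
  for (trial in 1:10) {
    a <- runif(L) < 0.3
    b <- runif(L) < 0.3
    fab <- featurize_pair(a, b)
    expect_identical(fab, featurize_pair(b, a))
    expect_length(fab, 2L * L + 4L)
    expect_equal(fab[2L * L + 1L], tanimoto(a, b))      # scalar block leads
    expect_equal(fab[2L * L + 4L], sum(a & b))
  }
  faa <- featurize_pair(a, a)
  expect_true(all(faa[(L + 1):(2 * L)] == 0))           # XOR block zero
  expect_error(featurize_pair(a, a[1:10]), "length mismatch")
})

test_that("training validates labels and compound resolution", {
  fx <- fixture_model()
  pairs <- enumerate_ercps(fx$world$activities,
                           build_homology_graph(fx$world$targets,
                                                "identity_table",
                                                threshold = 0.4,
                                                identity_table = fx$world$identity),
                           fx$world$focal_target, seed = 1,
                           compounds = fx$world$compounds)
  only_pos <- pairs[pairs$label == "positive", ]
  expect_error(train_ecbs_model(only_pos, fx$world$compounds),
               "both positive and negative")
  renamed <- pairs
  renamed$compound_a[1] <- "ghost_compound"
  expect_error(train_ecbs_model(renamed, fx$world$compounds),
               "ghost_compound")
})

test_that("separable worlds train to high held-out AUROC, permuted labels to ~0.5", {
  w <- generate_world(world_config(seed = 8, actives_per_target = 8,
                                   n_decoys = 60, fingerprint_length = 256L))
  graph <- build_homology_graph(w$targets, "identity_table", threshold = 0.4,
                                identity_table = w$identity)
  pairs <- enumerate_ercps(w$activities, graph, w$focal_target, seed = 8,
                           compounds = w$compounds)
  model <- suppressWarnings(
    train_ecbs_model(pairs, w$compounds,
                     ecbs_training_config(n_ensemble = 5, seed = 8)))
  expect_gte(model$cv_auroc, 0.95)

  null_aurocs <- vapply(1:5, function(s) {
    perm <- pairs
    set.seed(100 + s)
    perm$label <- sample(perm$label)
    suppressWarnings(
      train_ecbs_model(perm, w$compounds,
                       ecbs_training_config(n_ensemble = 3, seed = s)))$cv_auroc
  }, numeric(1))
  expect_lt(abs(mean(null_aurocs) - 0.5), 0.1)
})

test_that("scores are symmetric, bounded, and stable across serialization", {
  fx <- fixture_model()
  model <- fx$model
  L <- model$fp_config$n_bits
  set.seed(21)
  probe <- random_fp_matrix(12, L, density = 0.1)
  for (trial in 1:10) {
    i <- sample(12, 1); j <- sample(12, 1)
    s_ij <- ecbs_score(model, probe[i, ], probe[j, ])
    expect_equal(s_ij, ecbs_score(model, probe[j, ], probe[i, ]))
    expect_true(s_ij >= 0 && s_ij <= 1)
  }
  path <- withr::local_tempfile(fileext = ".rds")
  save_ecbs_model(model, path)
  reloaded <- load_ecbs_model(path)
  before <- ecbs_score_matrix(model, probe, probe)
  after <- ecbs_score_matrix(reloaded, probe, probe)
  expect_lt(max(abs(before - after)), 1e-12)

  expect_error(ecbs_score(model, probe[1, 1:16], probe[2, 1:16]),
               "length mismatch")
})

test_that("an ensemble of one scores as its single member", {
  fx <- fixture_model()
  w <- fx$world
  graph <- build_homology_graph(w$targets, "identity_table", threshold = 0.4,
                                identity_table = w$identity)
  pairs <- enumerate_ercps(w$activities, graph, w$focal_target, seed = 3,
                           compounds = w$compounds)
  m1 <- suppressWarnings(
    train_ecbs_model(pairs, w$compounds,
                     ecbs_training_config(n_ensemble = 1, seed = 3)))
  expect_length(m1$members, 1L)
  a <- w$compounds$fp[1, ]; b <- w$compounds$fp[2, ]
  x <- ecbscreen:::featurize_pairs(rbind(a, b), 1L, 2L)
  expect_equal(ecbs_score(m1, a, b),
               ecbscreen:::predict_member(m1$members[[1]], x))
})

test_that("the learned score is not materially worse than its Tanimoto input", {
  fx <- fixture_model()
  expect_gte(fx$run$metrics$auroc, fx$run$baseline_auroc - 0.02)
})
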