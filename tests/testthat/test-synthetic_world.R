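# Synthetic world generation and enrichment metrics.

test_that("world sizes and determinism follow the config", {
  cfg <- world_config(n_target_families = 2, targets_per_family = 2,
                      actives_per_target = 3, n_decoys = 20,
                      fingerprint_length = 128, motif_size = 16, seed = 5)
  w1 <- generate_world(cfg)
  expect_equal(length(w1$compounds), 2 * 2 * 3 + 20)
  expect_equal(nrow(w1$targets), 4L)
  expect_equal(length(w1$ground_truth), 6L)

  w2 <- generate_world(cfg)
  expect_identical(w1$compounds$fp, w2$compounds$fp)
  expect_identical(w1$identity, w2$identity)
  expect_identical(w1$activities, w2$activities)

  w3 <- generate_world(world_config(seed = 6, fingerprint_length = 128,
                                    motif_size = 16, actives_per_target = 3,
                                    n_decoys = 20))
  expect_false(identical(w1$compounds$fp, w3$compounds$fp))
})

test_that("identity table is symmetric-by-construction and config-consistent", {
  w <- generate_world(world_config(seed = 2, fingerprint_length = 128,
                                   motif_size = 8))
  fam <- w$targets$family[match(w$identity$target_a, w$targets$target_id)]
  fam_b <- w$targets$family[match(w$identity$target_b, w$targets$target_id)]
  expect_equal(w$identity$identity,
               ifelse(fam == fam_b, 0.6, 0.1))
})

test_that("full-strength motifs separate actives from decoys in Tanimoto", {
  cfg <- world_config(seed = 9, motif_strength = 1, background_density = 0,
                      actives_per_target = 3, n_decoys = 10,
                      fingerprint_length = 128, motif_size = 16)
  w <- generate_world(cfg)
  focal_actives <- w$ground_truth
  motif <- w$motifs[[w$focal_family]]
  for (id in focal_actives)
    expect_true(all(w$compounds$fp[id, motif]))
  # brute force over all pairs: active-active similarity dominates
  decoys <- setdiff(w$compounds$compound_id, w$activities$compound_id)
  worst_aa <- min(tanimoto_matrix(w$compounds$fp[focal_actives, ],
                                  w$compounds$fp[focal_actives, ]))
  best_ad <- max(tanimoto_matrix(w$compounds$fp[focal_actives, ],
                                 w$compounds$fp[decoys, ]))
  expect_gte(worst_aa, best_ad)
})

test_that("invalid world configs are rejected", {
  expect_error(world_config(within_family_identity = 0.2,
                            across_family_identity = 0.4), "must exceed")
  expect_error(world_config(n_target_families = 8, motif_size = 100,
                            fingerprint_length = 512), "disjoint")
  expect_error(world_config(actives_per_target = 0), ">= 1")
})

test_that("fragment mode emits parseable SMILES carrying the family motif", {
  w <- generate_world(world_config(seed = 4, actives_per_target = 3,
                                   n_decoys = 10, smiles_mode = "fragment",
                                   fingerprint_length = 512))
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(paste(w$compounds$smiles, w$compounds$compound_id), smi)
  reread <- read_compounds(smi, "smi",
                           fp_config = fingerprint_config(n_bits = 512))
  expect_equal(attr(reread, "ingestion")$n_skipped, 0)
  expect_equal(length(reread), length(w$compounds))
  # fingerprints recomputed from the written SMILES match the stored ones
  expect_equal(unname(reread$fp), unname(w$compounds$fp))
})

test_that("AUROC matches exhaustive concordance counting", {
  # worked examples first
  perfect <- fake_results(c(0.9, 0.8, 0.3, 0.2))
  expect_equal(evaluate_enrichment(perfect, c("x01", "x02"))$auroc, 1.0)
  # actives at ranks 1 and 3, decoys at 2 and 4 -> 3 of 4 concordant
  interleaved <- fake_results(c(0.9, 0.8, 0.7, 0.6))
  expect_equal(evaluate_enrichment(interleaved, c("x01", "x03"))$auroc, 0.75)

  set.seed(17)
  for (trial in 1:12) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- runif(n) < 0.3
    if (!any(labels) || all(labels)) next
    res <- fake_results(scores)
    truth <- sprintf("x%02d", which(labels))
    expect_equal(evaluate_enrichment(res, truth)$auroc,
                 brute_force_auroc(scores, labels))
  }
})

test_that("enrichment factor and recall follow their definitions", {
  # 2 actives among 10, both in top 2, f = 0.2 -> EF = (2/2)/(2/10) = 5
  res <- fake_results(seq(0.95, 0.05, by = -0.1))
  top2 <- res$compound_id[res$rank <= 2]
  m <- evaluate_enrichment(res, top2, ef_fraction = 0.2)
  expect_equal(m$enrichment_factor, 5.0)
  expect_equal(m$recall_at_k, 1.0)

  bottom <- res$compound_id[res$rank > 8]
  m2 <- evaluate_enrichment(res, bottom, ef_fraction = 0.2, k = 2)
  expect_equal(m2$enrichment_factor, 0)
  expect_equal(m2$recall_at_k, 0)

  expect_error(evaluate_enrichment(res, character(0)), "empty")
  expect_error(evaluate_enrichment(res, res$compound_id), "undefined")
  expect_error(evaluate_enrichment(res, "ghost"), "absent")
})

test_that("screen AUROC responds to motif strength", {
  strong <- suppressWarnings(screen_synthetic_world(generate_world(
    world_config(seed = 12, actives_per_target = 8, n_decoys = 60,
                 fingerprint_length = 256, motif_strength = 1)),
    n_ensemble = 3))
  null <- suppressWarnings(screen_synthetic_world(generate_world(
    world_config(seed = 12, actives_per_target = 8, n_decoys = 60,
                 fingerprint_length = 256, motif_strength = 0)),
    n_ensemble = 3))
  expect_gte(strong$metrics$auroc, 0.95)
  expect_lt(null$metrics$auroc, 0.85)
})
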