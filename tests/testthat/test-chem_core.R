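# Compound ingestion, canonicalization, fingerprints, Tanimoto.

write_smi_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".smi",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("smi ingestion preserves count, order and skips bad records", {
  path <- write_smi_file(c("# a comment", "CCO mol1", "c1ccccc1 mol2",
                           "CC(=O)O mol3"))
  cs <- read_compounds(path, "smi")
  expect_s3_class(cs, "compound_set")
  expect_equal(cs$compound_id, c("mol1", "mol2", "mol3"))
  expect_equal(attr(cs, "ingestion")$n_skipped, 0)

  # one unparsable SMILES among 5: skipped with its line number, run continues
  path2 <- write_smi_file(c("CCO m1", "CCN m2", "xyz)( bad", "CCC m3",
                            "CCCC m4", "CCCCC m5"))
  expect_warning(cs2 <- read_compounds(path2, "smi"), "line\\(s\\) 3")
  expect_equal(length(cs2), 5L)
  expect_equal(attr(cs2, "ingestion")$n_skipped, 1)
  expect_equal(attr(cs2, "ingestion")$skipped_records, 3L)

  # reference-ligand contract: invalid records abort instead of skipping
  expect_error(read_compounds(path2, "smi", on_invalid = "error"),
               "invalid record")

  # idempotence: re-reading yields an element-wise identical collection
  again <- read_compounds(path, "smi")
  expect_identical(cs$smiles, again$smiles)
  expect_identical(cs$fp, again$fp)
})

test_that("SMILES canonicalize on ingest: CCO and OCC collide", {
  # canonicalization oracle (verified against RDKit): both forms of
  # ethanol canonicalize to "CCO", so fingerprints must be identical
  path <- write_smi_file(c("CCO ethanol", "OCC ethanol2"))
  cs <- read_compounds(path, "smi")
  expect_equal(unique(cs$smiles), "CCO")
  expect_identical(cs$fp["ethanol", ], cs$fp["ethanol2", ])
})

test_that("compute_fingerprint is deterministic and validates input", {
  cfg <- fingerprint_config(radius = 2, n_bits = 2048)
  f1 <- compute_fingerprint("CCO", cfg)
  f2 <- compute_fingerprint("CCO", cfg)
  expect_identical(f1, f2)
  expect_length(f1, 2048L)

  # frozen reference values (RDKit Morgan radius 2 / 2048 bits):
  # methane sets exactly bit 1264 (0-based); ethane sets {1057, 1275}
  expect_equal(which(compute_fingerprint("C", cfg)) - 1L, 1264L)
  eth <- which(compute_fingerprint("CC", cfg)) - 1L
  expect_equal(eth, c(1057L, 1275L))
  expect_false(identical(compute_fingerprint("C", cfg),
                         compute_fingerprint("CC", cfg)))

  expect_error(compute_fingerprint("", cfg), "cannot parse SMILES")
  expect_error(compute_fingerprint("not_a_smiles", cfg),
               "cannot parse SMILES: 'not_a_smiles'")
})

test_that("SDF ingestion takes ids from a property field with title fallback", {
  # build a 2-record SDF with RDKit itself (fixture, not the code under test)
  smi <- withr::local_tempfile(fileext = ".smi")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("CCO eth", "c1ccccc1 benz"), smi)
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "sup = Chem.SmilesMolSupplier(sys.argv[1], titleLine=False)",
    "w = Chem.SDWriter(sys.argv[2])",
    "for i, m in enumerate(sup):",
    "    m.SetProp('COMPOUND_ID', f'sdf{i + 1}')",
    "    w.write(m)",
    "w.close()", sep = "\n")
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  res <- system2(Sys.which("python"), c(py, smi, sdf))
  expect_equal(res, 0L)

  by_prop <- read_compounds(sdf, "sdf", id_property = "COMPOUND_ID")
  expect_equal(by_prop$compound_id, c("sdf1", "sdf2"))
  by_title <- read_compounds(sdf, "sdf")
  expect_equal(by_title$compound_id, c("eth", "benz"))
  expect_equal(by_prop$smiles, c("CCO", "c1ccccc1"))
})

test_that("tanimoto matches its definition and contracts", {
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(tanimoto(a, a), 1)                      # identical nonzero
  expect_equal(tanimoto(a, b), 0.5)                    # {1,2,3} vs {2,3,4}
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)  # disjoint
  expect_equal(tanimoto(logical(4), logical(4)), 0)    # 0/0 convention
  expect_error(tanimoto(a, b[1:3]), "length mismatch")
})

test_that("tanimoto is symmetric, bounded, and matrix form agrees", {
  set.seed(11)
  fp <- random_fp_matrix(12, 64)
  tm <- tanimoto_matrix(fp, fp)
  for (trial in 1:25) {
    i <- sample(12, 1); j <- sample(12, 1)
    tij <- tanimoto(fp[i, ], fp[j, ])
    expect_identical(tij, tanimoto(fp[j, ], fp[i, ]))
    expect_true(tij >= 0 && tij <= 1)
    expect_equal(tm[i, j], tij)
  }
  expect_equal(diag(tm)[rowSums(fp) > 0],
               rep(1, sum(rowSums(fp) > 0)), ignore_attr = TRUE)
})

test_that("compound_set enforces unique ids and consistent width", {
  fp <- random_fp_matrix(2, 16)
  expect_error(compound_set(c("a", "a"), c("C", "C"), fp), "duplicate")
  expect_error(compound_set(c("a", "b"), c("C", "C"), fp,
                            fp_config = fingerprint_config(n_bits = 32)),
               "declares 32 bits")
  cs <- compound_set(c("a", "b"), c("C", "CC"), fp)
  expect_equal(cs["b"]$compound_id, "b")
  expect_error(cs["zz"], "unknown compound_id")
})
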