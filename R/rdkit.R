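# Bridge to the RDKit chemistry toolkit (via the `python` interpreter on
# PATH). R has no maintained circular-fingerprint implementation in this
# stack, so canonicalization and Morgan fingerprints are delegated to a
# small vendored script; everything downstream of ingestion is pure R.

python_binary <- function() {
  py <- Sys.getenv("ECBSCREEN_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py))
    stop("no 'python' interpreter found on PATH; RDKit is required for ",
         "SMILES/SDF ingestion (set ECBSCREEN_PYTHON to override)")
  py
}

# Run the bridge on a compound file; returns a data.frame with columns
# record (int, input line / record number), compound_id, status, smiles,
# and a list-column `bits` of 0-based on-bit integer vectors.
rdkit_fingerprint_file <- function(path, format, fp_config, id_property = NULL) {
  if (!file.exists(path)) stop("cannot read compound file: ", path)
  script <- system.file("python", "rdkit_bridge.py", package = "ecbscreen",
                        mustWork = TRUE)
  args <- c(script, "--input", path, "--format", format,
            "--radius", fp_config$radius, "--n-bits", fp_config$n_bits)
  if (!is.null(id_property)) args <- c(args, "--id-property", id_property)
  err_file <- tempfile("rdkit_err_")
  on.exit(unlink(err_file), add = TRUE)
  out <- suppressWarnings(
    system2(python_binary(), args, stdout = TRUE, stderr = err_file)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    err <- tryCatch(readLines(err_file, warn = FALSE), error = function(e) "")
    stop("RDKit bridge failed (exit ", status, "): ",
         paste(utils::tail(err, 5L), collapse = " | "))
  }
  if (length(out) == 0L) {
    return(data.frame(record = integer(), compound_id = character(),
                      status = character(), smiles = character()))
  }
  fields <- strsplit(out, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "",
                            character(1))
  res <- data.frame(record = as.integer(get(1L)),
                    compound_id = get(2L),
                    status = get(3L),
                    smiles = get(4L),
                    stringsAsFactors = FALSE)
  res$bits <- lapply(get(5L), function(s) {
    if (!nzchar(s)) integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  res
}

rdkit_fingerprint_smiles <- function(smiles, fp_config) {
  tmp <- tempfile("smiles_", fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  ids <- sprintf("Q%06d", seq_along(smiles))
  writeLines(paste(smiles, ids, sep = "\t"), tmp)
  rdkit_fingerprint_file(tmp, "tsv", fp_config)
}

bits_to_matrix <- function(bits, n_bits, ids) {
  fp <- matrix(FALSE, nrow = length(bits), ncol = n_bits,
               dimnames = list(ids, NULL))
  for (i in seq_along(bits)) fp[i, bits[[i]] + 1L] <- TRUE
  fp
}
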