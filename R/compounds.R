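#' Compound collection
#'
#' A set of compounds with identifiers, SMILES and fixed-length binary
#' substructure fingerprints. All fingerprints in one collection share a
#' single [fingerprint_config()].
#'
#' @param compound_id Character vector of unique identifiers.
#' @param smiles Character vector of SMILES strings (assumed canonical when
#'   built directly; [read_compounds()] canonicalizes on ingest).
#' @param fingerprints Logical (or 0/1) matrix, one fingerprint per row.
#' @param source Single tag or per-compound character vector
#'   (e.g. "library", "reference", "synthetic").
#' @param fp_config A [fingerprint_config()]; defaults to a Morgan radius-2
#'   configuration with `n_bits = ncol(fingerprints)`.
#' @return An object of class `compound_set`.
#' @export
compound_set <- function(compound_id, smiles, fingerprints,
                         source = "library", fp_config = NULL) {
  compound_id <- as.character(compound_id)
  smiles <- as.character(smiles)
  if (anyDuplicated(compound_id)) {
    dup <- unique(compound_id[duplicated(compound_id)])
    stop("duplicate compound_id: ", paste(dup, collapse = ", "))
  }
  if (!is.matrix(fingerprints))
    fingerprints <- matrix(fingerprints, nrow = length(compound_id), byrow = TRUE)
  storage.mode(fingerprints) <- "logical"
  if (nrow(fingerprints) != length(compound_id) ||
      length(smiles) != length(compound_id))
    stop("compound_id, smiles and fingerprint rows must have equal length")
  if (is.null(fp_config)) fp_config <- fingerprint_config(n_bits = ncol(fingerprints))
  if (ncol(fingerprints) != fp_config$n_bits)
    stop("fingerprint matrix has ", ncol(fingerprints),
         " columns but fp_config declares ", fp_config$n_bits, " bits")
  rownames(fingerprints) <- compound_id
  source <- rep_len(as.character(source), length(compound_id))
  structure(list(compound_id = compound_id, smiles = smiles,
                 fp = fingerprints, source = source, fp_config = fp_config),
            class = "compound_set")
}

#' @export
length.compound_set <- function(x) length(x$compound_id)

#' Subset a compound collection
#'
#' @param x A `compound_set`.
#' @param i Integer/logical index or character vector of compound ids.
#' @param ... Ignored.
#' @export
`[.compound_set` <- function(x, i, ...) {
  if (is.character(i)) {
    miss <- setdiff(i, x$compound_id)
    if (length(miss))
      stop("unknown compound_id: ", paste(miss, collapse = ", "))
    i <- match(i, x$compound_id)
  }
  compound_set(x$compound_id[i], x$smiles[i], x$fp[i, , drop = FALSE],
               x$source[i], x$fp_config)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds, %d-bit %s fingerprints (radius %d)\n",
              length(x), x$fp_config$n_bits, x$fp_config$type, x$fp_config$radius))
  if (length(x)) {
    n <- min(length(x), 5L)
    cat(paste0("  ", x$compound_id[seq_len(n)], "  ", x$smiles[seq_len(n)],
               collapse = "\n"), "\n")
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Combine two compound collections
#'
#' @param x,y `compound_set` objects with identical fingerprint
#'   configurations and disjoint identifiers.
#' @return A `compound_set` containing the rows of both, in order.
#' @export
combine_compounds <- function(x, y) {
  stopifnot(inherits(x, "compound_set"), inherits(y, "compound_set"))
  if (!same_fp_config(x$fp_config, y$fp_config))
    stop("cannot combine compound sets with different fingerprint configs")
  compound_set(c(x$compound_id, y$compound_id), c(x$smiles, y$smiles),
               rbind(x$fp, y$fp), c(x$source, y$source), x$fp_config)
}

#' Read compounds from a SMILES or SD file
#'
#' Each record is parsed and canonicalized with RDKit and fingerprinted
#' under `fp_config`. Two records whose SMILES canonicalize identically get
#' identical fingerprints. Record order is preserved.
#'
#' For `.smi` input the expected layout is one record per line,
#' `SMILES<whitespace>identifier`; lines starting with `#` and blank lines
#' are ignored. For SDF input the identifier is taken from `id_property`
#' when given, falling back to the molecule title line.
#'
#' @param path Path to the input file.
#' @param format `"smi"` or `"sdf"`.
#' @param fp_config A [fingerprint_config()].
#' @param source Source tag stored on every compound.
#' @param id_property SDF property field holding the identifier (SDF only).
#' @param on_invalid `"skip"` (default): unparsable records are dropped
#'   with a warning naming their line numbers and the run continues —
#'   appropriate for large screening libraries. `"error"`: any unparsable
#'   record aborts — use for reference-ligand files, where one bad record
#'   corrupts the whole model.
#' @return A `compound_set`; attribute `"ingestion"` holds counts of
#'   valid/skipped records and the offending record numbers.
#' @export
read_compounds <- function(path, format = c("smi", "sdf"),
                           fp_config = fingerprint_config(),
                           source = "library", id_property = NULL,
                           on_invalid = c("skip", "error")) {
  format <- match.arg(format)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("cannot read compound file: ", path)
  parsed <- rdkit_fingerprint_file(path, format, fp_config, id_property)
  bad <- parsed$status != "ok"
  if (any(bad)) {
    msg <- sprintf("%d invalid record(s) in %s at line(s) %s", sum(bad),
                   basename(path), paste(parsed$record[bad], collapse = ", "))
    if (on_invalid == "error") stop(msg)
    warning(msg, call. = FALSE)
  }
  ok <- parsed[!bad, , drop = FALSE]
  res <- compound_set(ok$compound_id, ok$smiles,
                      bits_to_matrix(ok$bits, fp_config$n_bits, ok$compound_id),
                      source = source, fp_config = fp_config)
  attr(res, "ingestion") <- list(n_records = nrow(parsed), n_valid = nrow(ok),
                                 n_skipped = sum(bad),
                                 skipped_records = parsed$record[bad])
  res
}

#' Compute Morgan fingerprints for SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @param fp_config A [fingerprint_config()].
#' @return For a single SMILES, a logical bit vector of length
#'   `fp_config$n_bits`; for several, a logical matrix with one row per
#'   input (rows named by input position). Deterministic: the same SMILES
#'   and configuration always give the same bits.
#' @export
compute_fingerprint <- function(smiles, fp_config = fingerprint_config()) {
  smiles <- as.character(smiles)
  if (length(smiles) == 0L) stop("'smiles' is empty")
  parsed <- rdkit_fingerprint_smiles(smiles, fp_config)
  bad <- parsed$status != "ok"
  if (any(bad))
    stop("cannot parse SMILES: ",
         paste(sprintf("'%s'", smiles[parsed$record[bad]]), collapse = ", "))
  fp <- bits_to_matrix(parsed$bits, fp_config$n_bits, NULL)
  if (length(smiles) == 1L) fp[1L, ] else fp
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of RDKit-canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  parsed <- rdkit_fingerprint_smiles(as.character(smiles), fingerprint_config(n_bits = 8L))
  bad <- parsed$status != "ok"
  if (any(bad))
    stop("cannot parse SMILES: ",
         paste(sprintf("'%s'", smiles[parsed$record[bad]]), collapse = ", "))
  parsed$smiles
}
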