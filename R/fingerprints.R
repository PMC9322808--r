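#' Fingerprint configuration
#'
#' Parameters of the hashed circular (Morgan/ECFP-like) substructure
#' fingerprint used throughout a run. Every compound collection, trained
#' model and screen must share one configuration; scoring refuses to mix
#' fingerprints of different lengths.
#'
#' @param radius Circular neighbourhood radius (bond steps); default 2,
#'   the ECFP4-equivalent de-facto standard.
#' @param n_bits Folded bit-vector length L; default 2048.
#' @return An object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(radius = 2L, n_bits = 2048L) {
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  if (length(radius) != 1L || is.na(radius) || radius < 0L)
    stop("'radius' must be a single non-negative integer")
  if (length(n_bits) != 1L || is.na(n_bits) || n_bits < 8L)
    stop("'n_bits' must be a single integer >= 8")
  structure(list(type = "morgan", radius = radius, n_bits = n_bits),
            class = "fingerprint_config")
}

#' @export
print.fingerprint_config <- function(x, ...) {
  cat(sprintf("<fingerprint_config> %s, radius %d, %d bits\n",
              x$type, x$radius, x$n_bits))
  invisible(x)
}

same_fp_config <- function(a, b) {
  identical(a$type, b$type) && identical(a$radius, b$radius) &&
    identical(a$n_bits, b$n_bits)
}

as_fp_logical <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 1L) stop("expected a single fingerprint vector")
    x <- x[1L, ]
  }
  x <- as.logical(x)
  if (anyNA(x)) stop("fingerprint contains NA values")
  x
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over the on-bits, the standard unlearned baseline
#' for chemical similarity. The degenerate all-zero / all-zero case is
#' defined as 0 (avoids 0/0).
#'
#' @param a,b Bit vectors (logical or 0/1) of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as_fp_logical(a)
  b <- as_fp_logical(b)
  if (length(a) != length(b))
    stop(sprintf("fingerprint length mismatch: %d vs %d", length(a), length(b)))
  union_n <- sum(a | b)
  if (union_n == 0L) return(0)
  sum(a & b) / union_n
}

#' Pairwise Tanimoto similarity matrix
#'
#' All-against-all Tanimoto between the rows of two fingerprint matrices,
#' computed by cross-product (fast enough for 10^5 x 10^2 screens).
#'
#' @param fp_a,fp_b Logical (or 0/1) matrices with one fingerprint per row
#'   and the same number of columns.
#' @return A `nrow(fp_a) x nrow(fp_b)` numeric matrix of similarities.
#' @export
tanimoto_matrix <- function(fp_a, fp_b) {
  fp_a <- fp_a * 1L
  fp_b <- fp_b * 1L
  if (ncol(fp_a) != ncol(fp_b))
    stop(sprintf("fingerprint length mismatch: %d vs %d", ncol(fp_a), ncol(fp_b)))
  common <- tcrossprod(fp_a, fp_b)
  union_n <- outer(rowSums(fp_a), rowSums(fp_b), "+") - common
  sim <- common / union_n
  sim[union_n == 0] <- 0
  sim
}
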