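#' Target protein collection
#'
#' @param target_id Character vector of unique target identifiers.
#' @param sequence Optional amino-acid sequences (for alignment-based
#'   homology).
#' @param family Optional family labels (synthetic / label-based homology).
#' @return A data frame of class `target_set`.
#' @export
target_set <- function(target_id, sequence = NULL, family = NULL) {
  target_id <- as.character(target_id)
  if (anyDuplicated(target_id))
    stop("duplicate target_id: ",
         paste(unique(target_id[duplicated(target_id)]), collapse = ", "))
  df <- data.frame(target_id = target_id,
                   sequence = if (is.null(sequence)) NA_character_ else as.character(sequence),
                   family = if (is.null(family)) NA_character_ else as.character(family),
                   stringsAsFactors = FALSE)
  class(df) <- c("target_set", "data.frame")
  df
}

#' Read target sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A `target_set` with sequences.
#' @export
read_targets_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required to read FASTA target files")
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  target_set(ids, sequence = as.character(seqs))
}

#' Read a pairwise identity table
#'
#' Tab-separated with a header; columns `target_a`, `target_b`,
#' `identity` (fractional identity in \[0, 1\]).
#'
#' @param path TSV file path.
#' @return A data frame with the three columns, validated.
#' @export
read_identity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_a", "target_b", "identity")
  if (!all(need %in% names(df)))
    stop("identity table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$identity <- as.numeric(df$identity)
  if (anyNA(df$identity) || any(df$identity < 0 | df$identity > 1))
    stop("identities must be fractions in [0, 1]")
  df
}

#' Compound-target activity table
#'
#' @param compound_id,target_id Character vectors of equal length.
#' @param active Logical vector: TRUE for a binding/active record.
#' @return A data frame of class `activity_table` with no duplicate
#'   (compound, target) rows.
#' @export
activity_table <- function(compound_id, target_id, active = TRUE) {
  df <- data.frame(compound_id = as.character(compound_id),
                   target_id = as.character(target_id),
                   active = rep_len(as.logical(active), length(compound_id)),
                   stringsAsFactors = FALSE)
  key <- paste(df$compound_id, df$target_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (compound_id, target_id) rows: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (anyNA(df$active)) stop("'active' must be TRUE/FALSE with no NA")
  class(df) <- c("activity_table", "data.frame")
  df
}

#' Read an activity table from TSV
#'
#' Expects a header with columns `compound_id`, `target_id`, `active`
#' (logical, or 0/1).
#'
#' @param path TSV file path.
#' @return An `activity_table`.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_id", "active")
  if (!all(need %in% names(df)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  active <- df$active
  if (!is.logical(active)) active <- as.logical(as.numeric(active))
  activity_table(df$compound_id, df$target_id, active)
}

pairwise_identity_alignment <- function(targets) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required for alignment-based homology")
  if (anyNA(targets$sequence))
    stop("alignment-based homology needs a sequence for every target")
  n <- nrow(targets)
  ident <- matrix(1, n, n, dimnames = list(targets$target_id, targets$target_id))
  if (n < 2L) return(ident)
  seqs <- Biostrings::AAStringSet(targets$sequence)
  names(seqs) <- targets$target_id
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]],
                                           type = "global",
                                           substitutionMatrix = "BLOSUM62",
                                           gapOpening = 10, gapExtension = 0.5)
      # identity = matches / alignment length (PID1, incl. internal gaps);
      # an all-gap alignment has no aligned positions -> identity 0
      p <- Biostrings::pid(aln, type = "PID1") / 100
      ident[i, j] <- ident[j, i] <- if (is.nan(p)) 0 else p
    }
  }
  ident
}

identity_matrix_from_table <- function(targets, tab) {
  ids <- targets$target_id
  n <- length(ids)
  ident <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ident) <- 1
  known <- tab$target_a %in% ids & tab$target_b %in% ids
  tab <- tab[known, , drop = FALSE]
  ident[cbind(tab$target_a, tab$target_b)] <- tab$identity
  ident[cbind(tab$target_b, tab$target_a)] <- tab$identity
  if (anyNA(ident)) {
    miss <- which(is.na(ident) & upper.tri(ident), arr.ind = TRUE)
    stop("identity table is missing pair(s): ",
         paste(sprintf("%s-%s", ids[miss[, 1]], ids[miss[, 2]]), collapse = ", "))
  }
  ident
}

#' Build the target homology graph
#'
#' Targets are nodes; an undirected edge connects two targets whose
#' fractional sequence identity is at least `threshold`. This graph
#' operationalizes "evolutionarily related": a target's homologs are its
#' direct neighbours (one hop), and every target is related to itself.
#'
#' @param targets A `target_set`.
#' @param identity_source How pairwise identity is obtained:
#'   `"pairwise_alignment"` (global alignment of the stored sequences,
#'   identity = matches / alignment length), `"identity_table"` (a
#'   precomputed table, see [read_identity_table()]; every pair must be
#'   present), or `"family_label"` (identity 1 within a family, 0 across).
#' @param threshold Fractional identity cutoff declaring relatedness;
#'   default 0.4, a conventional homology heuristic.
#' @param identity_table Data frame (`target_a`, `target_b`, `identity`)
#'   when `identity_source = "identity_table"`.
#' @param transitive If TRUE, [related_targets()] returns the whole
#'   connected component instead of direct neighbours only.
#' @return An object of class `homology_graph`.
#' @export
build_homology_graph <- function(targets,
                                 identity_source = c("pairwise_alignment",
                                                     "identity_table",
                                                     "family_label"),
                                 threshold = 0.4, identity_table = NULL,
                                 transitive = FALSE) {
  identity_source <- match.arg(identity_source)
  stopifnot(inherits(targets, "data.frame"), nrow(targets) >= 1L)
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  ident <- switch(identity_source,
    pairwise_alignment = pairwise_identity_alignment(targets),
    identity_table = {
      if (is.null(identity_table))
        stop("identity_source = 'identity_table' requires 'identity_table'")
      identity_matrix_from_table(targets, identity_table)
    },
    family_label = {
      if (anyNA(targets$family))
        stop("family-label homology needs a family for every target")
      outer(targets$family, targets$family, "==") * 1
    })
  dimnames(ident) <- list(targets$target_id, targets$target_id)
  up <- which(upper.tri(ident) & ident >= threshold, arr.ind = TRUE)
  edges <- data.frame(target_a = targets$target_id[up[, 1]],
                      target_b = targets$target_id[up[, 2]],
                      identity = ident[up],
                      stringsAsFactors = FALSE)
  swap <- edges$target_a > edges$target_b
  tmp <- edges$target_a[swap]
  edges$target_a[swap] <- edges$target_b[swap]
  edges$target_b[swap] <- tmp
  edges <- edges[order(edges$target_a, edges$target_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = targets$target_id, edges = edges,
                 threshold = threshold, identity = ident,
                 transitive = isTRUE(transitive)),
            class = "homology_graph")
}

#' @export
print.homology_graph <- function(x, ...) {
  cat(sprintf("<homology_graph> %d targets, %d edges at identity >= %g%s\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              if (x$transitive) " (transitive closure)" else ""))
  invisible(x)
}

graph_neighbors <- function(graph, target) {
  e <- graph$edges
  c(e$target_b[e$target_a == target], e$target_a[e$target_b == target])
}

#' Targets evolutionarily related to a focal target
#'
#' Returns the focal target itself ("identical" clause) plus its direct
#' homologs — one hop in the homology graph, no transitive closure unless
#' the graph was built with `transitive = TRUE`.
#'
#' @param graph A `homology_graph`.
#' @param target Focal target id (must be a node).
#' @return Sorted character vector of related target ids, including
#'   `target`.
#' @export
related_targets <- function(graph, target) {
  stopifnot(inherits(graph, "homology_graph"))
  if (!target %in% graph$nodes)
    stop("unknown target '", target, "' (not a node of the homology graph)")
  if (!graph$transitive)
    return(sort(unique(c(target, graph_neighbors(graph, target)))))
  comp <- target
  frontier <- target
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, graph_neighbors, graph = graph))),
                   comp)
    comp <- c(comp, nxt)
    frontier <- nxt
  }
  sort(unique(comp))
}
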