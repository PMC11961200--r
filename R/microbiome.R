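#' Read and write abundance tables and taxonomy maps
#'
#' Abundance tables are TSV files with taxa as rows and samples as columns;
#' the first column holds the taxon name. Values are non-negative (relative)
#' abundances. Taxonomy maps are two-column TSV files `taxon<TAB>phylum`
#' with no header.
#'
#' @param path file path.
#' @return `read_abundance` returns a numeric matrix with taxon rownames and
#'   sample colnames; `read_taxonomy` a named character vector (taxon ->
#'   phylum).
#' @export
read_abundance <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1L)
  m <- as.matrix(tab)
  if (any(m < 0)) stop("abundance values must be non-negative")
  if (anyDuplicated(rownames(m))) stop("taxon names must be unique")
  m
}

#' @rdname read_abundance
#' @param mat abundance matrix (taxa-by-samples) with rownames.
#' @export
write_abundance <- function(mat, path) {
  df <- data.frame(taxon = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_abundance
#' @export
read_taxonomy <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("taxon", "phylum"),
                    colClasses = "character")
  setNames(tab$phylum, tab$taxon)
}

#' Aggregate an abundance table to the phylum level
#'
#' Sums the abundances of all taxa mapped to the same phylum, sample by
#' sample; per-sample totals are preserved. Every taxon must be mapped.
#'
#' @param table taxa-by-samples abundance matrix with taxon rownames.
#' @param taxonomy named character vector mapping taxon -> phylum.
#' @return a phylum-by-samples matrix (rows in first-appearance order of the
#'   phyla).
#' @export
aggregate_to_phylum <- function(table, taxonomy) {
  table <- as.matrix(table)
  missing <- setdiff(rownames(table), names(taxonomy))
  if (length(missing))
    stop("unmapped taxa: ", paste(missing, collapse = ", "))
  phyla <- unname(taxonomy[rownames(table)])
  out <- rowsum(table, group = phyla, reorder = FALSE)
  out
}

#' Binarize an abundance table into a pattern (attractor) set
#'
#' Turns abundances into presence/absence (`1` where abundance exceeds
#' `threshold`), transposes to samples-by-taxa, and collapses duplicate
#' sample patterns: the unique binary abundance vectors are interpreted as
#' the attractors of the underlying interaction network. Patterns are
#' returned in canonical ascending integer-encoding order (first taxon row =
#' node 0 = least significant bit).
#'
#' @param table taxa-by-samples abundance matrix.
#' @param threshold presence threshold (default 0: any positive abundance
#'   counts as present).
#' @return a 0/1 matrix with one unique pattern per row and one column per
#'   taxon (named after the taxa); may have zero rows, in which case a
#'   warning is raised.
#' @export
binarize_to_attractors <- function(table, threshold = 0) {
  stopifnot(threshold >= 0)
  table <- as.matrix(table)
  bin <- t(table > threshold) * 1L
  if (!nrow(bin)) {
    warning("no samples in table; empty pattern set")
    return(matrix(integer(), 0L, nrow(table),
                  dimnames = list(NULL, rownames(table))))
  }
  codes <- apply(bin, 1L, encode_state)
  keep <- !duplicated(codes)
  out <- bin[keep, , drop = FALSE][order(codes[keep]), , drop = FALSE]
  rownames(out) <- NULL
  colnames(out) <- rownames(table)
  out
}

#' JI-weighted summary network of a cohort
#'
#' Superimposes the networks inferred from the studies of one cohort into a
#' single weighted signed network: the weight of edge (i, j) is the sum over
#' studies of the edge's sign (-1/0/+1) multiplied by the study's attractor
#' Jaccard score at EDAME termination. Strong consistent interactions across
#' studies accumulate large absolute weights; disagreements cancel.
#'
#' @param networks list of [signed_network()]s on a common node set.
#' @param ji_scores numeric vector of attractor JI scores, one per network.
#' @return a data frame with columns `i`, `j`, `weight` (non-zero weights
#'   only, sorted by `(i, j)`), with attribute `n_nodes`.
#' @export
summary_network <- function(networks, ji_scores) {
  stopifnot(length(networks) == length(ji_scores),
            all(ji_scores >= 0 & ji_scores <= 1))
  n <- unique(vapply(networks, function(x) x$n_nodes, integer(1L)))
  if (length(n) != 1L) stop("networks must share a common node set")
  W <- matrix(0, n, n)
  for (s in seq_along(networks)) {
    W <- W + interaction_matrix(networks[[s]]) * ji_scores[s]
  }
  up <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  out <- data.frame(i = up[, 1L] - 1L, j = up[, 2L] - 1L, weight = W[up])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nodes") <- n
  out
}

#' @rdname summary_network
#' @param summary a data frame from `summary_network`.
#' @param path output file; written as TSV `i<TAB>j<TAB>weight`.
#' @export
write_weighted_network <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality index of a cohort assignment
#'
#' Ratio of the mean pairwise signed-edge Jaccard similarity of networks
#' within the same cohort to the mean pairwise similarity of networks across
#' different cohorts. QI > 1 means networks from the same cohort are more
#' similar to each other than to networks from other cohorts, i.e. the
#' inference method separates the cohorts.
#'
#' @param cohorts a named list; each element is a list of
#'   [signed_network()]s belonging to one cohort (at least 2 cohorts with at
#'   least 2 networks each).
#' @param cap value reported when the across-cohort similarity is exactly 0
#'   (default `Inf`); flagged via the `degenerate` field.
#' @return a list with `qi`, `within` and `across` mean similarities, and a
#'   `degenerate` flag.
#' @export
quality_index <- function(cohorts, cap = Inf) {
  if (length(cohorts) < 2L) stop("at least 2 cohorts are required")
  if (any(lengths(cohorts) < 2L))
    stop("each cohort needs at least 2 networks")
  nets <- unlist(cohorts, recursive = FALSE)
  labels <- rep(names(cohorts) %||% seq_along(cohorts), lengths(cohorts))
  n <- length(nets)
  within <- c(); across <- c()
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      ji <- edge_jaccard(nets[[a]], nets[[b]])
      if (labels[a] == labels[b]) within <- c(within, ji)
      else across <- c(across, ji)
    }
  }
  w <- mean(within); x <- mean(across)
  if (x == 0) {
    warning("across-cohort similarity is 0; QI is degenerate")
    return(list(qi = cap, within = w, across = x, degenerate = TRUE))
  }
  list(qi = w / x, within = w, across = x, degenerate = FALSE)
}

#' Correlation baseline network on abundance data
#'
#' Thin comparison baseline operating on the non-binarized abundances:
#' node pairs with a significant rank correlation (p below `p_cutoff`)
#' whose absolute coefficient exceeds `threshold` become edges signed by
#' the correlation's sign.
#'
#' @param table taxa-by-samples abundance matrix.
#' @param threshold absolute correlation threshold (typical values
#'   0.1-0.4).
#' @param p_cutoff significance cutoff (default 0.05).
#' @param method correlation type passed to [stats::cor.test()] (default
#'   `"spearman"`).
#' @return a [signed_network()] on `nrow(table)` nodes (taxa in row order).
#' @export
correlation_network <- function(table, threshold = 0.2, p_cutoff = 0.05,
                                method = "spearman") {
  table <- as.matrix(table)
  N <- nrow(table)
  edges <- list()
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      x <- table[i, ]; y <- table[j, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                             exact = FALSE))
      if (is.na(ct$p.value) || ct$p.value >= p_cutoff) next
      if (abs(ct$estimate) <= threshold) next
      edges[[length(edges) + 1L]] <-
        data.frame(i = i - 1L, j = j - 1L,
                   sign = as.integer(sign(ct$estimate)))
    }
  }
  signed_network(N, do.call(rbind, edges))
}
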