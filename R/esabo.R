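# Shannon entropy (bits) of a binary vector with a ones-fraction f.
binary_entropy <- function(f) {
  ifelse(f <= 0 | f >= 1, 0,
         -(f * log2(f) + (1 - f) * log2(1 - f)))
}

# Exact null moments of H(AND(x, y)) for independently shuffled binary
# columns with fixed margins: with k1 = sum(x), k2 = sum(y) ones out of n
# samples, the AND-count k under a random relative permutation is
# hypergeometric, and H = binary_entropy(k / n); mean and sd follow by
# direct summation. This is the analytical form of the column-permutation
# null.
esabo_null_moments <- function(k1, k2, n) {
  k <- max(0L, k1 + k2 - n):min(k1, k2)
  w <- stats::dhyper(k, k1, n - k1, k2)
  hv <- binary_entropy(k / n)
  mu <- sum(w * hv)
  v <- sum(w * hv^2) - mu^2
  c(mu = mu, sigma = sqrt(max(v, 0)))
}

#' ESABO entropy-shift edge scores
#'
#' Scores every node pair of a binary pattern matrix by the entropy shift of
#' the AND-combined columns relative to an independence null (Entropy Shifts
#' of Abundance Vectors under Boolean Operations). For a pair (i, j), the
#' AND vector `z = x_i & x_j` across samples has Shannon entropy `H(z)`; the
#' score is the z-statistic `(H(z) - mu0) / sigma0`, where `mu0`, `sigma0`
#' are the exact null mean and standard deviation of `H` under independent
#' relative shuffling of the two columns with their observed margins (the
#' AND-count is then hypergeometric; moments are summed exactly). This is
#' the analytical counterpart of scoring against column permutations.
#' Positive scores indicate co-presence above chance (synergy), negative
#' scores co-exclusion (competition).
#'
#' Pairs involving a constant column (density 0 or 1), for which the null is
#' degenerate, get `NA` scores and are excluded from edge selection.
#'
#' @param patterns a samples-by-nodes 0/1 matrix (at least 2 samples and 2
#'   node columns); attractor matrices from [compute_attractors()] /
#'   [states_matrix] order are used directly.
#' @return an N-by-N symmetric matrix of scores with `NA` diagonal, of class
#'   `matrix`.
#' @export
esabo_scores <- function(patterns) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  n <- nrow(patterns); N <- ncol(patterns)
  if (n < 2L) stop("at least 2 samples (rows) are required")
  if (N < 2L) stop("at least 2 nodes (columns) are required")
  if (!all(patterns %in% c(0L, 1L))) stop("patterns must be 0/1")
  ones <- colSums(patterns)
  scores <- matrix(NA_real_, N, N)
  for (i in seq_len(N - 1L)) {
    if (ones[i] %in% c(0L, n)) next
    for (j in (i + 1L):N) {
      if (ones[j] %in% c(0L, n)) next
      null <- esabo_null_moments(ones[i], ones[j], n)
      if (null[["sigma"]] <= 0) next
      k <- sum(patterns[, i] & patterns[, j])
      H <- binary_entropy(k / n)
      scores[i, j] <- scores[j, i] <- (H - null[["mu"]]) / null[["sigma"]]
    }
  }
  scores
}

# Enumerate node pairs i < j (0-based) in ascending (i, j) order together
# with their scores; the pair index is the tie-breaking order.
pair_table <- function(scores) {
  N <- nrow(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
             score = scores[idx], pair = seq_len(nrow(idx)))
}

# Shared count-mode edge selection for score matrices: the n_pos
# highest-scoring pairs become +1 edges, the n_neg lowest-scoring pairs -1
# edges. NA scores are excluded; boundary ties are broken by ascending pair
# index; the two selections must not overlap.
select_edges_by_count <- function(scores, n_pos, n_neg, allow_fewer = FALSE) {
  tab <- pair_table(scores)
  tab <- tab[is.finite(tab$score), , drop = FALSE]
  avail <- nrow(tab)
  if (n_pos + n_neg > avail) {
    if (!allow_fewer)
      stop(sprintf("requested %d edges but only %d scored pairs available",
                   n_pos + n_neg, avail))
    scale <- avail / (n_pos + n_neg)
    n_pos <- floor(n_pos * scale); n_neg <- min(avail - n_pos, n_neg)
  }
  pos <- tab[order(-tab$score, tab$pair), , drop = FALSE][seq_len(n_pos), ,
                                                          drop = FALSE]
  neg <- tab[order(tab$score, tab$pair), , drop = FALSE][seq_len(n_neg), ,
                                                         drop = FALSE]
  if (length(intersect(pos$pair, neg$pair)))
    stop("positive and negative selections overlap; reduce edge counts")
  edges <- rbind(
    if (n_pos) data.frame(i = pos$i, j = pos$j, sign = 1L),
    if (n_neg) data.frame(i = neg$i, j = neg$j, sign = -1L))
  edges
}

#' Build a signed network from ESABO (or baseline) scores
#'
#' Converts a symmetric pair-score matrix into a signed network, either by
#' edge counts (the `n_pos` highest-scoring pairs become positive edges, the
#' `n_neg` lowest-scoring pairs negative edges) or by thresholds (scores
#' above `theta_pos` positive, below `theta_neg` negative). `"random"`
#' counts are drawn uniformly from `pos_range` / `neg_range`, emulating edge
#' selection when the true edge counts are unknown.
#'
#' @param scores symmetric score matrix (e.g. from [esabo_scores()]).
#' @param n_pos,n_neg positive / negative edge counts, or `"random"`.
#' @param thresholds optional numeric `c(theta_pos, theta_neg)`; when given,
#'   threshold mode is used and the counts are ignored.
#' @param pos_range,neg_range inclusive ranges for `"random"` counts.
#' @param seed optional seed for `"random"` counts.
#' @param allow_fewer if `TRUE`, silently selects fewer edges when not
#'   enough finitely scored pairs exist (instead of erroring).
#' @return a [signed_network()] on `nrow(scores)` nodes.
#' @export
esabo_network <- function(scores, n_pos = 10L, n_neg = 10L,
                          thresholds = NULL,
                          pos_range = c(1L, nrow(scores)),
                          neg_range = c(1L, nrow(scores)),
                          seed = NULL, allow_fewer = FALSE) {
  N <- nrow(scores)
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2L, thresholds[1L] >= thresholds[2L])
    tab <- pair_table(scores)
    tab <- tab[is.finite(tab$score), , drop = FALSE]
    edges <- rbind(
      data.frame(i = tab$i[tab$score > thresholds[1L]],
                 j = tab$j[tab$score > thresholds[1L]], sign = 1L),
      data.frame(i = tab$i[tab$score < thresholds[2L]],
                 j = tab$j[tab$score < thresholds[2L]], sign = -1L))
    return(signed_network(N, edges))
  }
  with_seed(seed, {
    if (identical(n_pos, "random"))
      n_pos <- sample(pos_range[1L]:pos_range[2L], 1L)
    if (identical(n_neg, "random"))
      n_neg <- sample(neg_range[1L]:neg_range[2L], 1L)
    n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
    edges <- select_edges_by_count(scores, n_pos, n_neg, allow_fewer)
    signed_network(N, edges)
  })
}
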