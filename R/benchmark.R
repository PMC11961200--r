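# Pairwise phi coefficient of two binary vectors from the 2x2 contingency
# table; equals the Pearson correlation of 0/1 variables.
phi_coefficient <- function(x, y) {
  n11 <- sum(x & y); n10 <- sum(x & !y)
  n01 <- sum(!x & y); n00 <- sum(!x & !y)
  den <- sqrt(prod(c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

# Mutual information (bits) of two binary vectors from empirical joint
# frequencies.
binary_mutual_information <- function(x, y) {
  n <- length(x)
  p <- c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)) / n
  px <- mean(x); py <- mean(y)
  q <- c(px * py, px * (1 - py), (1 - px) * py, (1 - px) * (1 - py))
  keep <- p > 0 & q > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}

#' Baseline pairwise association scores on binary patterns
#'
#' General-purpose association statistics used as comparison baselines for
#' network inference from binary attractor matrices: mutual information (in
#' bits, non-negative), Pearson correlation, and the phi coefficient (both
#' signed, in `[-1, 1]`; on binary data they coincide numerically but are
#' reported as separate methods). Pairs involving a constant column are
#' `NA`.
#'
#' @param patterns samples-by-nodes 0/1 matrix (at least 2 samples).
#' @param method one of `"mutual_information"`, `"pearson"`, `"phi"`.
#' @return an N-by-N symmetric score matrix with `NA` diagonal. For mutual
#'   information, the attribute `"sign"` carries the sign of the phi
#'   coefficient, used for edge-sign calls.
#' @export
baseline_scores <- function(patterns,
                            method = c("mutual_information", "pearson",
                                       "phi")) {
  method <- match.arg(method)
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  if (nrow(patterns) < 2L) stop("at least 2 samples (rows) are required")
  N <- ncol(patterns)
  p <- colMeans(patterns)
  scores <- matrix(NA_real_, N, N)
  signs <- matrix(NA_real_, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      if (p[i] %in% c(0, 1) || p[j] %in% c(0, 1)) next
      x <- patterns[, i]; y <- patterns[, j]
      ph <- phi_coefficient(x, y)
      v <- switch(method,
                  mutual_information = binary_mutual_information(x, y),
                  pearson = cor(x, y),
                  phi = ph)
      scores[i, j] <- scores[j, i] <- v
      signs[i, j] <- signs[j, i] <- sign(ph)
    }
  }
  if (method == "mutual_information") attr(scores, "sign") <- signs
  scores
}

#' Infer a signed network from a baseline score matrix
#'
#' Applies the same count-mode edge selection as [esabo_network()] so that
#' every method answers the same question. For mutual information, which is
#' unsigned, pairs are ranked by `MI * sign(phi)` so that strongly
#' associated co-present pairs rank highest and strongly associated
#' co-excluded pairs lowest.
#'
#' @inheritParams baseline_scores
#' @param n_pos,n_neg positive / negative edge counts.
#' @param allow_fewer see [esabo_network()].
#' @return a [signed_network()].
#' @export
baseline_network <- function(patterns, method, n_pos = 10L, n_neg = 10L,
                             allow_fewer = FALSE) {
  scores <- baseline_scores(patterns, method)
  if (method == "mutual_information")
    scores <- scores * attr(scores, "sign")
  signed_network(ncol(patterns),
                 select_edges_by_count(scores, as.integer(n_pos),
                                       as.integer(n_neg), allow_fewer))
}

#' Method comparison on simulated attractor data
#'
#' Reproduces the inference benchmark: random connected signed networks are
#' generated, their full Boolean attractor sets enumerated, and each
#' inference method is applied to the attractor matrix. Methods compared:
#' ESABO (entropy-shift scores, count-mode selection), EDAME (ESABO seed
#' refined against the attractor set), and the mutual-information, Pearson
#' and phi baselines with the same count-mode selection. Accuracy is the
#' signed-edge Jaccard index against the generating network.
#'
#' @param n_networks ensemble size (the reference experiment uses 100).
#' @param n_nodes,m_pos,m_neg network parameters (defaults 10 / 10 / 10).
#' @param lit,lfa EDAME limits.
#' @param seed integer seed for the whole comparison.
#' @param methods character vector of methods to run; subset of
#'   `c("edame", "esabo", "mutual_information", "pearson", "phi")`.
#' @return a data frame with columns `method`, `replicate`, `ji`. Use
#'   [comparison_medians()] for per-method medians.
#' @export
run_method_comparison <- function(n_networks, n_nodes = 10L, m_pos = 10L,
                                  m_neg = 10L, lit = 20L, lfa = 20L,
                                  seed = 1L,
                                  methods = c("edame", "esabo",
                                              "mutual_information",
                                              "pearson", "phi")) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (rep in seq_len(n_networks)) {
    s <- derive_seed(seed, rep)
    G <- generate_random_network(n_nodes, m_pos, m_neg,
                                 seed = derive_seed(s, 1))
    A <- compute_attractors(G)
    patterns <- states_matrix(A)
    esabo_net <- NULL
    if (any(c("esabo", "edame") %in% methods)) {
      esabo_net <- esabo_network(esabo_scores(patterns),
                                 n_pos = m_pos, n_neg = m_neg,
                                 allow_fewer = TRUE)
    }
    for (method in methods) {
      net <- switch(method,
        esabo = esabo_net,
        edame = edame_refine(esabo_net, A, lit = lit, lfa = lfa,
                             seed = derive_seed(s, 2),
                             truth = G)$final_network,
        baseline_network(patterns, method, n_pos = m_pos, n_neg = m_neg,
                         allow_fewer = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, replicate = rep, ji = edge_jaccard(G, net))
    }
  }
  do.call(rbind, rows)
}

#' @rdname run_method_comparison
#' @param comparison a data frame from [run_method_comparison()].
#' @return `comparison_medians` returns a named numeric vector of per-method
#'   median Jaccard indices.
#' @export
comparison_medians <- function(comparison) {
  tapply(comparison$ji, comparison$method, median)[
    unique(comparison$method)]
}
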