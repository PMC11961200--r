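#' Hamming distance between two Boolean states
#'
#' @param a,b 0/1 vectors of equal length.
#' @return the number of positions at which the states differ.
#' @export
hamming <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("states must have equal length")
  sum(a != b)
}

#' Nearest attractors by least Hamming distance
#'
#' Finds all members of `pool` at minimal Hamming distance from `target`;
#' ties are kept, not broken, since downstream difference arrays sum over
#' every nearest attractor.
#'
#' @param target a 0/1 state vector.
#' @param pool a 0/1 matrix with one candidate state per row (non-empty).
#' @return the minimizing rows of `pool` as a matrix (one or more rows).
#' @export
nearest_attractors <- function(target, pool) {
  pool <- as.matrix(pool)
  if (!nrow(pool)) stop("pool of candidate attractors is empty")
  if (ncol(pool) != length(target)) stop("state length mismatch")
  d <- as.vector(pool %*% (1L - as.integer(target)) +
                   (1L - pool) %*% as.integer(target))
  pool[d == min(d), , drop = FALSE]
}

# Hamming distances from each row of A (na x N) to each row of B (nb x N):
# returns an na x nb matrix. Uses the identity d = a'(1-b) + (1-a)'b.
hamming_cross <- function(A, B) {
  A %*% t(1L - B) + (1L - A) %*% t(B)
}

# Sum over rows of `froms` of (from - nearest) for all nearest pool members,
# both the signed sum and the sum of absolute per-row differences.
nearest_diff_sums <- function(froms, pool, n_nodes) {
  signed <- integer(n_nodes)
  absolute <- integer(n_nodes)
  if (!nrow(froms) || !nrow(pool))
    return(list(signed = signed, absolute = absolute))
  d <- hamming_cross(froms, pool)
  for (r in seq_len(nrow(froms))) {
    ks <- which(d[r, ] == min(d[r, ]))
    for (k in ks) {
      diff <- froms[r, ] - pool[k, ]
      signed <- signed + diff
      absolute <- absolute + abs(diff)
    }
  }
  list(signed = as.integer(signed), absolute = as.integer(absolute))
}

#' Node-level difference arrays between two attractor sets
#'
#' Localizes the nodes affected by an edge change by comparing the attractor
#' set `A` of the original network with the set `A_star` of a modified one.
#' With `cD = A \ A_star` (destroyed attractors) and `cC = A_star \ A`
#' (created attractors):
#' * `D`: for each destroyed attractor, the element-wise differences to all
#'   of its Hamming-nearest attractors in `A_star`, summed over all rows;
#' * `C`: for each created attractor, the differences (nearest minus
#'   created) against its nearest attractors in `A`, summed;
#' * `B`: for each destroyed attractor, the differences to its nearest
#'   created attractors, summed.
#' Empty complements yield all-zero arrays. The signed sum `D + C + B`
#' peaks at the nodes involved in the rewired edge; [sorted_nodes()] uses
#' the absolute-value analogue.
#'
#' @param A,A_star two `attractor_set`s (or 0/1 pattern matrices) on the same
#'   node set.
#' @return a list with integer vectors `D`, `C`, `B` of length N.
#' @export
difference_arrays <- function(A, A_star) {
  A <- as_attractor_set(A); A_star <- as_attractor_set(A_star)
  if (A$n_nodes != A_star$n_nodes) stop("attractor sets differ in n_nodes")
  n <- A$n_nodes
  cD <- decode_states(setdiff(A$all_states, A_star$all_states), n)
  cC <- decode_states(setdiff(A_star$all_states, A$all_states), n)
  D <- nearest_diff_sums(cD, states_matrix(A_star), n)$signed
  Cv <- nearest_diff_sums(cC, states_matrix(A), n)$signed
  # C sums (nearest in A) - (created), i.e. the negated from-minus-pool sum
  Cv <- -Cv
  B <- nearest_diff_sums(cD, cC, n)$signed
  list(D = D, C = Cv, B = B)
}

# Absolute difference arrays |D|, |C|, |B| (absolute values taken per row
# before summing over nearest attractors) and their sum |E|.
abs_difference_arrays <- function(A, A_star) {
  A <- as_attractor_set(A); A_star <- as_attractor_set(A_star)
  if (A$n_nodes != A_star$n_nodes) stop("attractor sets differ in n_nodes")
  n <- A$n_nodes
  cD <- decode_states(setdiff(A$all_states, A_star$all_states), n)
  cC <- decode_states(setdiff(A_star$all_states, A$all_states), n)
  Dab <- nearest_diff_sums(cD, states_matrix(A_star), n)$absolute
  Cab <- nearest_diff_sums(cC, states_matrix(A), n)$absolute
  Bab <- nearest_diff_sums(cD, cC, n)$absolute
  list(D_abs = Dab, C_abs = Cab, B_abs = Bab,
       E_abs = Dab + Cab + Bab)
}

#' Sorted-nodes array SN
#'
#' Ranks nodes by their sensitivity to the attractor-set difference: the
#' absolute difference arrays |D|, |C|, |B| (per-row absolute values taken
#' before summing) are added into |E|, and node indices are returned in
#' descending |E| order. Nodes involved in the changed edges concentrate at
#' the front of SN. Ties are broken by ascending node index. When the two
#' attractor sets are identical, SN is undefined; nodes are returned in index
#' order with a warning and `identical_sets = TRUE`.
#'
#' @inheritParams difference_arrays
#' @return a list with `order` (0-based node indices, descending |E|),
#'   `E_abs` (the per-node |E| values) and `identical_sets` (logical flag).
#' @export
sorted_nodes <- function(A, A_star) {
  A <- as_attractor_set(A); A_star <- as_attractor_set(A_star)
  n <- A$n_nodes
  if (setequal(A$all_states, A_star$all_states)) {
    warning("attractor sets are identical; SN is returned in index order")
    return(list(order = 0:(n - 1L), E_abs = integer(n),
                identical_sets = TRUE))
  }
  ab <- abs_difference_arrays(A, A_star)
  ord <- order(-ab$E_abs, 0:(n - 1L)) - 1L
  list(order = as.integer(ord), E_abs = ab$E_abs, identical_sets = FALSE)
}

#' Jaccard overlap of two attractor sets
#'
#' Overlap of the full state sets (fixed points plus cycle states):
#' `|A intersect B| / |A union B|`. This is the objective the EDAME loop
#' drives to 1.
#'
#' @param A,B `attractor_set`s (or 0/1 pattern matrices) on the same node
#'   set.
#' @return a number in `[0, 1]`; two empty sets have overlap 1.
#' @export
attractor_jaccard <- function(A, B) {
  A <- as_attractor_set(A); B <- as_attractor_set(B)
  if (A$n_nodes != B$n_nodes) stop("attractor sets differ in n_nodes")
  u <- length(union(A$all_states, B$all_states))
  if (u == 0L) return(1)
  length(intersect(A$all_states, B$all_states)) / u
}

#' Dump difference arrays as a labelled table
#'
#' Diagnostic view of D, C, B, |D|, |C|, |B| and |E| per node, written as a
#' TSV when `path` is given.
#'
#' @inheritParams difference_arrays
#' @param path optional output file.
#' @return (invisibly) the table as a data frame.
#' @export
dump_difference_arrays <- function(A, A_star, path = NULL) {
  s <- difference_arrays(A, A_star)
  a <- abs_difference_arrays(A, A_star)
  tab <- data.frame(node = 0:(length(s$D) - 1L),
                    D = s$D, C = s$C, B = s$B,
                    D_abs = a$D_abs, C_abs = a$C_abs, B_abs = a$B_abs,
                    E_abs = a$E_abs)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
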