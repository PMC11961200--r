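#' Worked 8-node example network
#'
#' A fixed 8-node signed network (8 positive, 7 negative edges) used
#' throughout the documentation to illustrate the attractor-difference
#' machinery. Rewiring its edge (4,7) to (4,6) — keeping node 4 as anchor
#' and the edge's sign — perturbs the attractor set so that the sorted-nodes
#' array of the original vs. rewired attractor sets becomes
#' `[6, 7, 4, 3, 2, 5, 1, 0]`: the three nodes touched by the rewiring (6,
#' 7 and the anchor 4) lead the ranking.
#'
#' @param rewired if `TRUE`, return the variant with (4,7) replaced by
#'   (4,6).
#' @return a [signed_network()] on 8 nodes.
#' @examples
#' G <- example_network()
#' G_star <- example_network(rewired = TRUE)
#' sn <- sorted_nodes(compute_attractors(G), compute_attractors(G_star))
#' sn$order
#' @export
example_network <- function(rewired = FALSE) {
  edges <- data.frame(
    i    = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L, 4L),
    j    = c(2L, 3L, 4L, 5L, 6L, 3L, 5L, 3L, 4L, 5L, 7L, 4L, 7L, 5L, 7L),
    sign = c(1L, 1L, 1L, 1L, 1L, -1L, 1L, -1L, -1L, -1L, 1L, 1L, -1L,
             -1L, -1L))
  if (rewired) {
    at <- which(edges$i == 4L & edges$j == 7L)
    edges$j[at] <- 6L
  }
  signed_network(8L, edges)
}
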