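#' Signed undirected interaction networks
#'
#' A `signed_network` represents an undirected graph on `n_nodes` nodes whose
#' edges carry a sign: `+1` for a synergistic (co-presence promoting)
#' interaction, `-1` for a competitive one. Nodes are labelled by 0-based
#' integers `0..n_nodes-1`, matching the bit positions used to encode Boolean
#' states (node 0 is the least significant bit). The network is equivalently a
#' symmetric interaction matrix with entries in \{-1, 0, +1\} and zero
#' diagonal.
#'
#' @param n_nodes number of nodes (positive integer).
#' @param edges a data frame (or matrix) with columns `i`, `j`, `sign`;
#'   node indices 0-based, `sign` in \{-1, +1\}. Each unordered pair may
#'   appear at most once; self-loops are not allowed.
#' @return an object of class `signed_network` with elements `n_nodes` and
#'   `edges` (a data frame with `i < j`, sorted by `(i, j)`).
#' @examples
#' net <- signed_network(3, data.frame(i = c(0, 1), j = c(1, 2),
#'                                     sign = c(1, -1)))
#' interaction_matrix(net)
#' @export
signed_network <- function(n_nodes, edges = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L)
    stop("n_nodes must be a positive integer")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(i = integer(), j = integer(), sign = integer())
  } else {
    edges <- as.data.frame(edges)[, c("i", "j", "sign")]
    edges$i <- as.integer(edges$i)
    edges$j <- as.integer(edges$j)
    edges$sign <- as.integer(edges$sign)
    if (any(edges$i == edges$j)) stop("self-loops are not allowed")
    if (any(edges$i < 0L) || any(edges$j < 0L) ||
        any(edges$i >= n_nodes) || any(edges$j >= n_nodes))
      stop("node indices must lie in 0..n_nodes-1")
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge signs must be -1 or +1")
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    if (anyDuplicated(edges[, c("i", "j")]))
      stop("multi-edges are not allowed (duplicate node pair)")
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(n_nodes = n_nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d positive / %d negative edges\n",
              x$n_nodes, sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' @rdname signed_network
#' @param net a `signed_network`.
#' @export
interaction_matrix <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  I <- matrix(0L, net$n_nodes, net$n_nodes)
  if (nrow(net$edges)) {
    idx <- cbind(net$edges$i + 1L, net$edges$j + 1L)
    I[idx] <- net$edges$sign
    I[idx[, 2:1, drop = FALSE]] <- net$edges$sign
  }
  I
}

#' @rdname signed_network
#' @param I a symmetric integer matrix with entries in \{-1, 0, +1\} and zero
#'   diagonal.
#' @export
network_from_matrix <- function(I) {
  I <- as.matrix(I)
  if (nrow(I) != ncol(I) || !isTRUE(all.equal(unname(I), unname(t(I)))))
    stop("interaction matrix must be square and symmetric")
  if (any(diag(I) != 0)) stop("interaction matrix must have zero diagonal")
  up <- which(upper.tri(I) & I != 0, arr.ind = TRUE)
  signed_network(nrow(I),
                 data.frame(i = up[, 1] - 1L, j = up[, 2] - 1L,
                            sign = I[up]))
}

# Signed-edge keys "i:j:sign" for set arithmetic on edges.
edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character())
  paste(net$edges$i, net$edges$j, net$edges$sign, sep = ":")
}

is_connected_net <- function(net) {
  if (net$n_nodes == 1L) return(TRUE)
  if (!nrow(net$edges)) return(FALSE)
  g <- igraph::make_graph(t(cbind(net$edges$i, net$edges$j) + 1L),
                          n = net$n_nodes, directed = FALSE)
  igraph::is_connected(g)
}

#' Generate a connected random signed network
#'
#' Draws a uniform random simple graph with exactly `m_pos` positive and
#' `m_neg` negative undirected edges on `n_nodes` nodes, rejecting draws that
#' are not connected (single component). This is the network ensemble used
#' throughout the simulation studies (typical scale `n_nodes = 10`,
#' `m_pos = m_neg = 10`).
#'
#' @param n_nodes number of nodes.
#' @param m_pos,m_neg number of positive / negative edges.
#' @param seed optional integer seed; identical seeds give identical networks.
#' @param max_tries rejection-sampling bound for the connectivity constraint.
#' @return a connected [signed_network()].
#' @export
generate_random_network <- function(n_nodes, m_pos, m_neg, seed = NULL,
                                    max_tries = 10000L) {
  n_nodes <- as.integer(n_nodes)
  m_pos <- as.integer(m_pos); m_neg <- as.integer(m_neg)
  m <- m_pos + m_neg
  max_edges <- n_nodes * (n_nodes - 1L) / 2L
  if (m_pos < 0L || m_neg < 0L) stop("edge counts must be non-negative")
  if (m > max_edges)
    stop(sprintf("too many edges: %d requested, at most %d on %d nodes",
                 m, max_edges, n_nodes))
  if (m < n_nodes - 1L)
    stop(sprintf(
      "too few edges to connect %d nodes: %d requested, at least %d needed",
      n_nodes, m, n_nodes - 1L))
  pairs <- if (n_nodes >= 2L) t(combn(0:(n_nodes - 1L), 2L)) else
    matrix(integer(), 0L, 2L)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      pick <- sample.int(nrow(pairs), m)
      signs <- sample(c(rep(1L, m_pos), rep(-1L, m_neg)))
      net <- signed_network(n_nodes,
                            data.frame(i = pairs[pick, 1L],
                                       j = pairs[pick, 2L], sign = signs))
      if (is_connected_net(net)) return(net)
    }
    stop("failed to draw a connected network within max_tries")
  })
}

#' Rewire edges of a signed network
#'
#' Performs `n_rewires` constrained single-edge rewires: each move picks an
#' edge `(n0, n_minus)`, keeps the anchor endpoint `n0`, and reattaches the
#' edge to a new endpoint `n_plus`, preserving its sign. The result is kept
#' connected, simple (no multi-edges), and differs from the input by exactly
#' `n_rewires` removed and `n_rewires` added signed edges (a later rewire
#' never restores an earlier removal).
#'
#' @param net a connected [signed_network()].
#' @param n_rewires number of edges to rewire (at least 1).
#' @param seed optional integer seed.
#' @param max_tries retry bound per rewire.
#' @return a list with elements `network` (the rewired `signed_network`) and
#'   `records` (a data frame with columns `n0`, `n_minus`, `n_plus`, `sign`,
#'   one row per rewire).
#' @export
rewire_edges <- function(net, n_rewires, seed = NULL, max_tries = 10000L) {
  stopifnot(inherits(net, "signed_network"))
  n_rewires <- as.integer(n_rewires)
  if (n_rewires < 1L) stop("n_rewires must be at least 1")
  orig_pairs <- paste(net$edges$i, net$edges$j, sep = ":")
  with_seed(seed, {
    cur <- net
    recs <- vector("list", n_rewires)
    removed_orig <- character()
    for (r in seq_len(n_rewires)) {
      done <- FALSE
      for (try in seq_len(max_tries)) {
        ne <- nrow(cur$edges)
        e <- sample.int(ne, 1L)
        ends <- c(cur$edges$i[e], cur$edges$j[e])
        pair_key <- paste(ends[1L], ends[2L], sep = ":")
        # only original, not-yet-touched edges may be rewired so that the
        # total difference count is exactly 2 * n_rewires
        if (!(pair_key %in% orig_pairs) || pair_key %in% removed_orig) next
        a <- sample.int(2L, 1L)
        n0 <- ends[a]; n_minus <- ends[3L - a]
        sgn <- cur$edges$sign[e]
        cur_pairs <- paste(cur$edges$i, cur$edges$j, sep = ":")
        cand <- setdiff(0:(net$n_nodes - 1L), c(n0, n_minus))
        # exclude multi-edges and edges of the original network
        keep <- vapply(cand, function(np) {
          k <- paste(min(n0, np), max(n0, np), sep = ":")
          !(k %in% cur_pairs) && !(k %in% orig_pairs)
        }, logical(1L))
        cand <- cand[keep]
        if (!length(cand)) next
        n_plus <- if (length(cand) == 1L) cand else sample(cand, 1L)
        new_edges <- cur$edges[-e, , drop = FALSE]
        new_edges <- rbind(new_edges,
                           data.frame(i = min(n0, n_plus),
                                      j = max(n0, n_plus), sign = sgn))
        trial <- signed_network(net$n_nodes, new_edges)
        if (!is_connected_net(trial)) next
        cur <- trial
        removed_orig <- c(removed_orig, pair_key)
        recs[[r]] <- data.frame(n0 = n0, n_minus = n_minus,
                                n_plus = n_plus, sign = sgn)
        done <- TRUE
        break
      }
      if (!done) stop("no legal rewire found within max_tries")
    }
    list(network = cur, records = do.call(rbind, recs))
  })
}

#' Signed-edge Jaccard index of two networks
#'
#' Overlap of the signed edge sets: an edge counts as shared only when both
#' endpoints and the sign agree. Used as the accuracy measure when comparing
#' an inferred network with its ground truth.
#'
#' @param net_a,net_b two `signed_network`s on the same node set.
#' @return `|intersection| / |union|` in `[0, 1]`; 1 when both edge sets are
#'   empty.
#' @export
edge_jaccard <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "signed_network"),
            inherits(net_b, "signed_network"))
  if (net_a$n_nodes != net_b$n_nodes)
    stop("networks must have the same number of nodes")
  a <- edge_keys(net_a); b <- edge_keys(net_b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Read / write a signed network as an edge list
#'
#' Plain-text edge-list format: a header line `# n_nodes=<N>` followed by one
#' edge per line, `i<TAB>j<TAB>sign` with 0-based node indices and sign
#' `+1`/`-1`. Reading and writing round-trip exactly.
#'
#' @param net a `signed_network`.
#' @param path file path.
#' @return `read_network` returns a `signed_network`; `write_network`
#'   (invisibly) returns `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  lines <- sprintf("# n_nodes=%d", net$n_nodes)
  if (nrow(net$edges)) {
    lines <- c(lines, sprintf("%d\t%d\t%+d", net$edges$i, net$edges$j,
                              net$edges$sign))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*n_nodes=", lines, value = TRUE)
  if (!length(hdr)) stop("missing '# n_nodes=<N>' header line")
  n <- as.integer(sub("^#\\s*n_nodes=", "", hdr[1L]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) return(signed_network(n))
  parts <- do.call(rbind, strsplit(body, "\\s+"))
  signed_network(n, data.frame(i = as.integer(parts[, 1L]),
                               j = as.integer(parts[, 2L]),
                               sign = as.integer(parts[, 3L])))
}
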