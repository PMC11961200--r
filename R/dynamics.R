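#' Encode and decode Boolean states
#'
#' A Boolean state of an N-node network is a 0/1 vector of length N
#' (presence/absence of each node). States are canonically encoded as
#' integers with node 0 as the least significant bit, which is the ordering
#' used for exhaustive enumeration and attractor serialization.
#'
#' @param bits 0/1 vector of length `n_nodes`.
#' @param code integer encoding (0 .. 2^N - 1).
#' @param n_nodes number of nodes.
#' @return `encode_state` returns an integer; `decode_state` a 0/1 integer
#'   vector; `decode_states` a matrix with one state per row.
#' @export
encode_state <- function(bits) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("state bits must be 0 or 1")
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' @rdname encode_state
#' @export
decode_state <- function(code, n_nodes) {
  as.integer(bitwAnd(bitwShiftR(as.integer(code), 0:(n_nodes - 1L)), 1L))
}

#' @rdname encode_state
#' @param codes integer vector of state encodings.
#' @export
decode_states <- function(codes, n_nodes) {
  if (!length(codes)) return(matrix(integer(), 0L, n_nodes))
  m <- t(vapply(as.integer(codes), decode_state, integer(n_nodes),
                n_nodes = n_nodes))
  dimnames(m) <- NULL
  m
}

check_capacity <- function(n_nodes, max_nodes) {
  if (n_nodes > max_nodes)
    stop(sprintf(paste0("exhaustive enumeration over 2^%d states exceeds ",
                        "the cap of %d nodes; raise max_nodes explicitly ",
                        "if this is intended"), n_nodes, max_nodes))
}

#' Synchronous threshold update
#'
#' Applies the majority-vote rule once: every node i computes its signed
#' input field `h_i = sum_j I_ij s_j` from the same input state and becomes 1
#' if `h_i > 0`, 0 if `h_i < 0`, and keeps its state when `h_i = 0`.
#'
#' @param net a [signed_network()] (or an interaction matrix).
#' @param s a 0/1 state vector of length `n_nodes`.
#' @return the successor state as a 0/1 integer vector.
#' @examples
#' net <- signed_network(2, data.frame(i = 0, j = 1, sign = 1))
#' update_state(net, c(1, 0))  # the present node switches its partner on
#' @export
update_state <- function(net, s) {
  I <- if (inherits(net, "signed_network")) interaction_matrix(net)
       else as.matrix(net)
  s <- as.integer(s)
  if (length(s) != nrow(I))
    stop("state length does not match the number of nodes")
  if (!all(s %in% c(0L, 1L))) stop("state bits must be 0 or 1")
  h <- as.vector(I %*% s)
  as.integer(ifelse(h > 0, 1L, ifelse(h < 0, 0L, s)))
}

#' Exhaustive attractor-set computation
#'
#' Updates each of the 2^N states exactly once, forming the functional graph
#' s -> update(s); its fixed points (states with update(s) = s) and cycles
#' are the attractor set of the dynamics. All 2^N states are enumerated, so
#' the network size is capped (default 20 nodes).
#'
#' @param net a [signed_network()].
#' @param max_nodes enumeration cap; exceeding it is an error.
#' @param drop_empty if `TRUE`, the all-zeros fixed point (the empty
#'   community, always an attractor) is removed from the returned set. Off by
#'   default; useful for real-data comparisons where the empty community is
#'   unobservable.
#' @return an object of class `attractor_set`: a list with `n_nodes`,
#'   `fixed_points` (integer state codes), `cycles` (list of integer code
#'   vectors, each ordered along the dynamics), and `all_states` (ascending
#'   codes of all fixed points and cycle states).
#' @export
compute_attractors <- function(net, max_nodes = 20L, drop_empty = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  check_capacity(net$n_nodes, max_nodes)
  ana <- bn_analyze(interaction_matrix(net))
  lens <- lengths(ana$orbits)
  fps <- unlist(ana$orbits[lens == 1L], use.names = FALSE) %||% integer()
  cycles <- ana$orbits[lens > 1L]
  all_states <- sort(unlist(ana$orbits, use.names = FALSE))
  if (drop_empty) {
    fps <- setdiff(fps, 0L)
    all_states <- setdiff(all_states, 0L)
  }
  structure(list(n_nodes = net$n_nodes,
                 fixed_points = as.integer(sort(fps)),
                 cycles = cycles,
                 all_states = as.integer(all_states)),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("attractor_set: %d fixed points, %d cycles (%d states total)\n",
              length(x$fixed_points), length(x$cycles),
              length(x$all_states)))
  invisible(x)
}

# Build an attractor_set-like container from raw patterns: either a 0/1
# matrix (one state per row) or a vector of integer codes. Used for
# empirically observed pattern sets whose fixed-point/cycle split is unknown.
as_attractor_set <- function(x, n_nodes = NULL) {
  if (inherits(x, "attractor_set")) return(x)
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    n_nodes <- n_nodes %||% ncol(x)
    codes <- apply(x, 1L, encode_state)
  } else {
    if (is.null(n_nodes)) stop("n_nodes is required for code vectors")
    codes <- as.integer(x)
  }
  codes <- sort(unique(as.integer(codes)))
  structure(list(n_nodes = as.integer(n_nodes),
                 fixed_points = codes, cycles = list(),
                 all_states = codes),
            class = "attractor_set")
}

# All attractor states as a 0/1 matrix, rows in ascending code order.
states_matrix <- function(aset) {
  decode_states(aset$all_states, aset$n_nodes)
}

#' Basin sizes of the attractors
#'
#' Counts, for every attractor, the number of initial states whose
#' trajectories reach it. The counts always partition the state space:
#' they sum to 2^N.
#'
#' @inheritParams compute_attractors
#' @return a data frame with one row per attractor: `states` (the attractor's
#'   state codes, "/"-separated in orbit order), `n_states` (1 for fixed
#'   points) and `basin_size`.
#' @export
basin_sizes <- function(net, max_nodes = 20L) {
  stopifnot(inherits(net, "signed_network"))
  check_capacity(net$n_nodes, max_nodes)
  ana <- bn_analyze(interaction_matrix(net))
  counts <- tabulate(ana$attractor_id, nbins = length(ana$orbits))
  data.frame(
    states = vapply(ana$orbits, function(o) paste(o, collapse = "/"), ""),
    n_states = lengths(ana$orbits),
    basin_size = counts)
}

#' Read / write attractor sets as text matrices
#'
#' One row per state, N whitespace-separated 0/1 columns, rows in ascending
#' integer-encoding order (node 0 = least significant bit = first column).
#'
#' @param aset an `attractor_set` or a 0/1 pattern matrix.
#' @param path file path.
#' @return `read_attractors` returns the patterns as a 0/1 matrix (one state
#'   per row) carrying no fixed-point/cycle annotation.
#' @export
write_attractors <- function(aset, path) {
  m <- if (inherits(aset, "attractor_set")) states_matrix(aset)
       else as.matrix(aset)
  writeLines(apply(m, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_attractors
#' @export
read_attractors <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("attractor matrix entries must be 0/1")
  m
}
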