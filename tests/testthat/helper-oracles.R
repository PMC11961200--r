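# Independent oracles, coded naively and separately from the package
# internals, for cross-checking the fast implementations.

# Attractor states by trajectory following: iterate every initial state until
# a repeat; the repeated suffix is the attractor orbit.
oracle_attractor_states <- function(net) {
  n <- net$n_nodes
  on_cycle <- logical(2^n)
  for (s in 0:(2^n - 1L)) {
    traj <- integer()
    x <- s
    while (!(x %in% traj)) {
      traj <- c(traj, x)
      x <- encode_state(update_state(net, decode_state(x, n)))
    }
    cyc <- traj[which(traj == x):length(traj)]
    on_cycle[cyc + 1L] <- TRUE
  }
  which(on_cycle) - 1L
}

# Basin sizes by trajectory following: map every state to the smallest state
# of its attractor orbit and tabulate.
oracle_basins <- function(net) {
  n <- net$n_nodes
  reps <- integer(2^n)
  for (s in 0:(2^n - 1L)) {
    traj <- integer()
    x <- s
    while (!(x %in% traj)) {
      traj <- c(traj, x)
      x <- encode_state(update_state(net, decode_state(x, n)))
    }
    cyc <- traj[which(traj == x):length(traj)]
    reps[s + 1L] <- min(cyc)
  }
  table(reps)
}

# Brute-force D, C, B arrays written directly from the procedure's prose:
# stack the per-nearest-attractor difference rows into explicit matrices and
# sum over rows. Independent of the package's vectorized path.
oracle_difference_arrays <- function(A_states, Astar_states, n) {
  to_mat <- function(codes) {
    if (!length(codes)) return(matrix(integer(), 0L, n))
    do.call(rbind, lapply(codes, decode_state, n_nodes = n))
  }
  ham <- function(u, v) sum(u != v)
  stack_diffs <- function(from_codes, pool_codes, flip = FALSE) {
    rows <- list()
    pool <- to_mat(pool_codes)
    for (code in from_codes) {
      a <- decode_state(code, n)
      if (!nrow(pool)) next
      d <- apply(pool, 1L, ham, u = a)
      for (k in which(d == min(d))) {
        rows[[length(rows) + 1L]] <- if (flip) pool[k, ] - a else
          a - pool[k, ]
      }
    }
    if (!length(rows)) return(list(signed = integer(n), absolute = integer(n)))
    m <- do.call(rbind, rows)
    list(signed = as.integer(colSums(m)),
         absolute = as.integer(colSums(abs(m))))
  }
  cD <- setdiff(A_states, Astar_states)
  cC <- setdiff(Astar_states, A_states)
  list(D = stack_diffs(cD, Astar_states),
       C = stack_diffs(cC, A_states, flip = TRUE),
       B = stack_diffs(cD, cC))
}

# Null moments of H(AND) by exhaustive enumeration of all relative shuffles:
# for margins k1, k2 out of n, every permutation of the second column gives
# an AND-count; enumerate over the exact distribution of counts by full
# permutation when n is tiny.
oracle_esabo_null <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  hs <- vapply(perms(y), function(yp) {
    f <- mean(x & yp)
    if (f <= 0 || f >= 1) 0 else -(f * log2(f) + (1 - f) * log2(1 - f))
  }, numeric(1L))
  c(mu = mean(hs), sigma = sqrt(mean(hs^2) - mean(hs)^2))
}

# Small convenience: random connected network drawn with feasible edge counts.
random_feasible_net <- function(n_nodes, seed) {
  max_e <- n_nodes * (n_nodes - 1L) / 2L
  set.seed(seed)
  m <- sample(max(1L, n_nodes - 1L):max_e, 1L)
  mp <- sample(0:m, 1L)
  generate_random_network(n_nodes, mp, m - mp, seed = seed + 1L)
}
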