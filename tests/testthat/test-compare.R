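test_that("hamming and nearest_attractors behave as defined", {
  expect_equal(hamming(c(0, 1, 1), c(1, 1, 0)), 2L)
  expect_equal(hamming(c(0, 0), c(0, 0)), 0L)
  expect_error(hamming(c(0, 1), c(0, 1, 1)), "equal length")

  pool <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 1, 1))
  # distance 1 to both 000 and 110: ties are kept
  near <- nearest_attractors(c(1, 0, 0), pool)
  expect_equal(near, rbind(c(0L, 0L, 0L), c(1L, 1L, 0L)))
  # ties are kept: two pool rows at distance 1
  near2 <- nearest_attractors(c(1, 1, 1), rbind(c(0, 1, 1), c(1, 1, 0)))
  expect_equal(nrow(near2), 2L)
  expect_error(nearest_attractors(c(1, 0), matrix(integer(), 0, 2)),
               "empty")
})

test_that("difference arrays match the brute-force oracle on rewire pairs", {
  set.seed(501)
  n_checked <- 0L
  for (s in 1:120) {
    if (n_checked >= 50L) break
    n <- sample(5:8, 1)
    G <- tryCatch(generate_random_network(n, sample(3:8, 1), sample(2:5, 1),
                                          seed = 3000 + s),
                  error = function(e) NULL)
    if (is.null(G)) next
    Gs <- tryCatch(rewire_edges(G, 1, seed = 4000 + s)$network,
                   error = function(e) NULL)
    if (is.null(Gs)) next
    A <- compute_attractors(G)
    As <- compute_attractors(Gs)
    if (setequal(A$all_states, As$all_states)) next
    got <- difference_arrays(A, As)
    gota <- edame:::abs_difference_arrays(A, As)
    orc <- oracle_difference_arrays(A$all_states, As$all_states, n)
    expect_equal(got$D, orc$D$signed, info = sprintf("seed %d", s))
    expect_equal(got$C, orc$C$signed, info = sprintf("seed %d", s))
    expect_equal(got$B, orc$B$signed, info = sprintf("seed %d", s))
    expect_equal(gota$D_abs, orc$D$absolute)
    expect_equal(gota$C_abs, orc$C$absolute)
    expect_equal(gota$B_abs, orc$B$absolute)
    expect_equal(gota$E_abs,
                 orc$D$absolute + orc$C$absolute + orc$B$absolute)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 50L)
})

test_that("empty complements give all-zero arrays", {
  net <- generate_random_network(5, 4, 2, seed = 9)
  A <- compute_attractors(net)
  d <- difference_arrays(A, A)
  expect_equal(d$D, integer(5))
  expect_equal(d$C, integer(5))
  expect_equal(d$B, integer(5))
})

test_that("sorted_nodes ranks rewired-edge nodes first and breaks ties by index", {
  # hand-checkable case: descending E with a tie
  # build attractor-set stand-ins directly from code vectors
  A <- edame:::as_attractor_set(c(0L, 3L), n_nodes = 3L)
  B <- edame:::as_attractor_set(c(0L, 5L), n_nodes = 3L)
  # cD = {3} (011), cC = {5} (101); nearest computations touch nodes 1, 2
  sn <- sorted_nodes(A, B)
  expect_equal(sort(sn$order), 0:2)
  expect_equal(sn$order[3], 0L)      # node 0 has the smallest |E|
  expect_false(sn$identical_sets)
  # ties broken by ascending node index
  ab <- edame:::abs_difference_arrays(A, B)
  expect_equal(sn$order, order(-ab$E_abs, 0:2) - 1L)

  expect_warning(res <- sorted_nodes(A, A), "identical")
  expect_true(res$identical_sets)
  expect_equal(res$order, 0:2)
})

test_that("rewired-edge endpoints concentrate at the front of SN", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    G <- generate_random_network(10, 10, 10, seed = 600 + s)
    rw <- rewire_edges(G, 1, seed = 700 + s)
    A <- compute_attractors(G)
    As <- compute_attractors(rw$network)
    if (setequal(A$all_states, As$all_states)) next
    sn <- sorted_nodes(A, As)$order
    touched <- unique(c(rw$records$n0, rw$records$n_minus,
                        rw$records$n_plus))
    total <- total + 1L
    if (any(touched %in% sn[1:3])) hits <- hits + 1L
  }
  expect_gte(total, 10L)
  expect_gte(hits / total, 0.8)
})

test_that("attractor_jaccard is a set overlap on states", {
  A <- edame:::as_attractor_set(c(0L, 1L, 6L), n_nodes = 3L)
  B <- edame:::as_attractor_set(c(0L, 6L, 7L), n_nodes = 3L)
  expect_equal(attractor_jaccard(A, B), 2 / 4)
  expect_equal(attractor_jaccard(A, A), 1)
  # matrices are accepted directly
  expect_equal(attractor_jaccard(decode_states(c(0L, 1L, 6L), 3),
                                 decode_states(c(0L, 6L, 7L), 3)), 0.5)
})

test_that("dump_difference_arrays writes a labelled table", {
  A <- edame:::as_attractor_set(c(0L, 3L), n_nodes = 3L)
  B <- edame:::as_attractor_set(c(0L, 5L), n_nodes = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- dump_difference_arrays(A, B, path)
  expect_equal(names(tab),
               c("node", "D", "C", "B", "D_abs", "C_abs", "B_abs", "E_abs"))
  expect_true(file.exists(path))
  back <- read.delim(path)
  expect_equal(back$E_abs, tab$E_abs)
})

test_that("per-node |E| dominates each absolute component and each signed array", {
  for (s in 1:10) {
    G <- generate_random_network(8, 7, 4, seed = 1200 + s)
    Gs <- rewire_edges(G, 1, seed = 1300 + s)$network
    A <- compute_attractors(G); As <- compute_attractors(Gs)
    if (setequal(A$all_states, As$all_states)) next
    sg <- difference_arrays(A, As)
    ab <- edame:::abs_difference_arrays(A, As)
    expect_equal(ab$E_abs, ab$D_abs + ab$C_abs + ab$B_abs)
    expect_true(all(ab$E_abs >= pmax(ab$D_abs, ab$C_abs, ab$B_abs)))
    expect_true(all(ab$D_abs >= abs(sg$D)))
    expect_true(all(ab$C_abs >= abs(sg$C)))
    expect_true(all(ab$B_abs >= abs(sg$B)))
  }
})

test_that("sorted_nodes is invariant under node relabeling", {
  relabel <- function(net, perm) {
    # perm[k+1] is the new label of node k
    e <- net$edges
    ni <- perm[e$i + 1L]; nj <- perm[e$j + 1L]
    signed_network(net$n_nodes,
                   data.frame(i = pmin(ni, nj), j = pmax(ni, nj),
                              sign = e$sign))
  }
  set.seed(1400)
  for (s in 1:8) {
    n <- 8L
    G <- generate_random_network(n, 7, 4, seed = 1500 + s)
    Gs <- rewire_edges(G, 1, seed = 1600 + s)$network
    A <- compute_attractors(G); As <- compute_attractors(Gs)
    if (setequal(A$all_states, As$all_states)) next
    perm <- sample.int(n) - 1L
    Ap <- compute_attractors(relabel(G, perm))
    Asp <- compute_attractors(relabel(Gs, perm))
    r <- suppressWarnings(sorted_nodes(A, As))
    rp <- suppressWarnings(sorted_nodes(Ap, Asp))
    # |E| permutes with the labels
    expect_equal(rp$E_abs[perm + 1L], r$E_abs)
    # and when the |E| values are all distinct, SN permutes identically
    if (!anyDuplicated(r$E_abs)) {
      expect_equal(rp$order, perm[r$order + 1L])
    }
  }
})
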