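test_that("state encoding uses node 0 as least significant bit", {
  expect_equal(encode_state(c(1, 0, 0)), 1L)
  expect_equal(encode_state(c(0, 0, 1)), 4L)
  expect_equal(encode_state(c(1, 1, 0, 1)), 11L)
  expect_equal(decode_state(11, 4), c(1L, 1L, 0L, 1L))
  for (code in 0:15) expect_equal(encode_state(decode_state(code, 4)), code)
  m <- decode_states(c(0, 5, 7), 3)
  expect_equal(m, rbind(c(0L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 1L)))
  expect_equal(dim(decode_states(integer(), 3)), c(0L, 3L))
  expect_error(encode_state(c(0, 2)), "0 or 1")
})

test_that("update_state implements the threshold rule with ties frozen", {
  # single positive edge: a present node switches its partner on
  pos <- signed_network(2, data.frame(i = 0, j = 1, sign = 1))
  expect_equal(update_state(pos, c(1, 0)), c(1L, 1L))
  expect_equal(update_state(pos, c(1, 1)), c(1L, 1L))
  expect_equal(update_state(pos, c(0, 0)), c(0L, 0L))
  # single negative edge: a present node switches its partner off
  neg <- signed_network(2, data.frame(i = 0, j = 1, sign = -1))
  expect_equal(update_state(neg, c(1, 1)), c(0L, 0L))
  # (1, 0) is a fixed point: the absent node exerts no field
  expect_equal(update_state(neg, c(1, 0)), c(1L, 0L))
  # zero field keeps the previous state: +1 and -1 inputs cancel
  mix <- signed_network(3, data.frame(i = c(0, 1), j = c(2, 2),
                                      sign = c(1, -1)))
  expect_equal(update_state(mix, c(1, 1, 0))[3], 0L)
  expect_equal(update_state(mix, c(1, 1, 1))[3], 1L)
  expect_error(update_state(pos, c(1, 0, 0)), "length")
})

test_that("compute_attractors matches the trajectory-following oracle", {
  for (s in 1:12) {
    net <- random_feasible_net(n_nodes = sample(2:6, 1), seed = 900 + s)
    aset <- compute_attractors(net)
    expect_equal(aset$all_states, oracle_attractor_states(net),
                 info = sprintf("seed %d", 900 + s))
    # fixed points really are fixed; cycle states really cycle
    for (fp in aset$fixed_points) {
      x <- decode_state(fp, net$n_nodes)
      expect_equal(update_state(net, x), x)
    }
    for (cyc in aset$cycles) {
      expect_gt(length(cyc), 1L)
      for (k in seq_along(cyc)) {
        nxt <- cyc[if (k == length(cyc)) 1L else k + 1L]
        x <- decode_state(cyc[k], net$n_nodes)
        expect_equal(encode_state(update_state(net, x)), nxt)
      }
    }
  }
})

test_that("known tiny systems have the expected attractors", {
  pos <- signed_network(2, data.frame(i = 0, j = 1, sign = 1))
  a <- compute_attractors(pos)
  expect_equal(a$fixed_points, c(0L, 3L))
  expect_length(a$cycles, 0L)
  neg <- signed_network(2, data.frame(i = 0, j = 1, sign = -1))
  b <- compute_attractors(neg)
  # empty state plus each single-present state are fixed
  expect_equal(b$fixed_points, c(0L, 1L, 2L))
  # the empty community is always a fixed point
  for (s in 1:5) {
    net <- random_feasible_net(6, seed = 40 + s)
    expect_true(0L %in% compute_attractors(net)$fixed_points)
  }
})

test_that("drop_empty removes the all-zeros fixed point only", {
  net <- generate_random_network(6, 5, 3, seed = 3)
  full <- compute_attractors(net)
  drop <- compute_attractors(net, drop_empty = TRUE)
  expect_false(0L %in% drop$all_states)
  expect_equal(drop$all_states, setdiff(full$all_states, 0L))
})

test_that("basin sizes partition the state space and match the oracle", {
  for (s in 1:6) {
    net <- random_feasible_net(5, seed = 700 + s)
    bs <- basin_sizes(net)
    expect_equal(sum(bs$basin_size), 2L^net$n_nodes)
    orc <- oracle_basins(net)
    smallest <- vapply(strsplit(bs$states, "/"),
                       function(x) min(as.integer(x)), integer(1L))
    expect_equal(bs$basin_size[order(smallest)],
                 as.integer(orc[order(as.integer(names(orc)))]))
  }
})

test_that("the enumeration cap is enforced", {
  big <- signed_network(25, data.frame(i = 0:23, j = 1:24,
                                       sign = rep(1L, 24)))
  expect_error(compute_attractors(big), "max_nodes")
  expect_error(basin_sizes(big), "max_nodes")
})

test_that("attractor files round-trip", {
  net <- generate_random_network(6, 5, 3, seed = 11)
  aset <- compute_attractors(net)
  path <- withr::local_tempfile(fileext = ".txt")
  write_attractors(aset, path)
  m <- read_attractors(path)
  expect_equal(m, edame:::states_matrix(aset))
  expect_equal(apply(m, 1L, encode_state), aset$all_states)
})

test_that("fixed points dominate cyclic states on the standard ensemble", {
  n_fixed <- 0L; n_cyclic <- 0L
  for (s in 1:100) {
    A <- compute_attractors(generate_random_network(10, 10, 10,
                                                    seed = 5000 + s))
    n_fixed <- n_fixed + length(A$fixed_points)
    n_cyclic <- n_cyclic + sum(lengths(A$cycles))
  }
  expect_gt(n_fixed, n_cyclic)
})
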