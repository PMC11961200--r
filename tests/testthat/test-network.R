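test_that("signed_network validates and canonicalizes edges", {
  net <- signed_network(4, data.frame(i = c(2, 0), j = c(1, 3),
                                      sign = c(-1, 1)))
  expect_s3_class(net, "signed_network")
  # edges stored with i < j, sorted by (i, j)
  expect_equal(net$edges$i, c(0L, 1L))
  expect_equal(net$edges$j, c(3L, 2L))
  expect_equal(net$edges$sign, c(1L, -1L))

  expect_error(signed_network(0), "positive integer")
  expect_error(signed_network(3, data.frame(i = 1, j = 1, sign = 1)),
               "self-loops")
  expect_error(signed_network(3, data.frame(i = 0, j = 3, sign = 1)),
               "indices")
  expect_error(signed_network(3, data.frame(i = 0, j = 1, sign = 2)),
               "signs")
  expect_error(signed_network(3, data.frame(i = c(0, 1), j = c(1, 0),
                                            sign = c(1, -1))),
               "multi-edges")
})

test_that("interaction_matrix and network_from_matrix are inverse", {
  net <- signed_network(5, data.frame(i = c(0, 1, 2), j = c(4, 2, 3),
                                      sign = c(1, -1, -1)))
  I <- interaction_matrix(net)
  expect_true(isSymmetric(I))
  expect_equal(diag(I), rep(0L, 5))
  expect_equal(I[1, 5], 1L)
  expect_equal(I[3, 2], -1L)
  back <- network_from_matrix(I)
  expect_equal(back$edges, net$edges)

  expect_error(network_from_matrix(matrix(1, 2, 2)), "zero diagonal")
  bad <- matrix(0L, 3, 3); bad[1, 2] <- 1L
  expect_error(network_from_matrix(bad), "symmetric")
})

test_that("generate_random_network honors counts, connectivity and seed", {
  net <- generate_random_network(10, 10, 10, seed = 42)
  expect_equal(sum(net$edges$sign == 1L), 10L)
  expect_equal(sum(net$edges$sign == -1L), 10L)
  expect_true(edame:::is_connected_net(net))
  net2 <- generate_random_network(10, 10, 10, seed = 42)
  expect_equal(net$edges, net2$edges)
  net3 <- generate_random_network(10, 10, 10, seed = 43)
  expect_false(identical(net$edges, net3$edges))

  expect_error(generate_random_network(4, 5, 3), "too many edges")
  expect_error(generate_random_network(10, 2, 2), "too few edges")
})

test_that("rewire_edges differs by exactly 2 signed edges per rewire", {
  for (s in 1:5) {
    G <- generate_random_network(10, 10, 10, seed = s)
    for (r in 1:3) {
      rw <- rewire_edges(G, r, seed = 100 + s)
      Gs <- rw$network
      expect_true(edame:::is_connected_net(Gs))
      a <- edame:::edge_keys(G); b <- edame:::edge_keys(Gs)
      expect_length(setdiff(a, b), r)
      expect_length(setdiff(b, a), r)
      # sign balance preserved
      expect_equal(sum(Gs$edges$sign == 1L), sum(G$edges$sign == 1L))
      expect_equal(nrow(rw$records), r)
      # each record is consistent: (n0, n_minus) removed, (n0, n_plus) added
      for (k in seq_len(r)) {
        rec <- rw$records[k, ]
        rem <- paste(min(rec$n0, rec$n_minus), max(rec$n0, rec$n_minus),
                     rec$sign, sep = ":")
        add <- paste(min(rec$n0, rec$n_plus), max(rec$n0, rec$n_plus),
                     rec$sign, sep = ":")
        expect_true(rem %in% setdiff(a, b))
        expect_true(add %in% setdiff(b, a))
      }
    }
  }
})

test_that("edge_jaccard counts signed edges", {
  a <- signed_network(4, data.frame(i = c(0, 1), j = c(1, 2),
                                    sign = c(1, -1)))
  b <- signed_network(4, data.frame(i = c(0, 1), j = c(1, 2),
                                    sign = c(1, 1)))
  # (0,1,+) shared; (1,2,-) and (1,2,+) differ by sign only -> union 3
  expect_equal(edge_jaccard(a, b), 1 / 3)
  expect_equal(edge_jaccard(a, a), 1)
  expect_equal(edge_jaccard(signed_network(3), signed_network(3)), 1)
  expect_error(edge_jaccard(a, signed_network(5)), "same number of nodes")
})

test_that("network files round-trip", {
  net <- generate_random_network(8, 6, 4, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$n_nodes, net$n_nodes)
  expect_equal(back$edges, net$edges)
  # empty network round-trips too
  write_network(signed_network(5), path)
  expect_equal(read_network(path)$n_nodes, 5L)
  expect_equal(nrow(read_network(path)$edges), 0L)
})

test_that("reversing a rewire record recovers the input network exactly", {
  for (s in 1:10) {
    G <- generate_random_network(10, 10, 10, seed = 30 + s)
    rw <- rewire_edges(G, 1, seed = 130 + s)
    rec <- rw$records[1, ]
    e <- rw$network$edges
    drop <- which(e$i == min(rec$n0, rec$n_plus) &
                  e$j == max(rec$n0, rec$n_plus))
    e <- rbind(e[-drop, , drop = FALSE],
               data.frame(i = min(rec$n0, rec$n_minus),
                          j = max(rec$n0, rec$n_minus), sign = rec$sign))
    restored <- signed_network(G$n_nodes, e)
    expect_setequal(edame:::edge_keys(restored), edame:::edge_keys(G))
    expect_equal(interaction_matrix(restored), interaction_matrix(G))
  }
})

test_that("rewiring a triangle with a pendant node never disconnects it", {
  tri <- signed_network(4, data.frame(i = c(0, 0, 1, 2),
                                      j = c(1, 2, 2, 3),
                                      sign = c(1, 1, -1, 1)))
  for (s in 1:25) {
    rw <- rewire_edges(tri, 1, seed = s)
    expect_true(edame:::is_connected_net(rw$network))
  }
})
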