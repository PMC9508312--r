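test_that("strengths match hand counts and explicit loops", {
  # uniform off-diagonals
  K <- 5; c0 <- 0.2
  W <- matrix(c0, K, K); diag(W) <- 0
  st <- strengths(W)
  expect_true(all(st$in_strength == c0 * (K - 1)))
  expect_true(all(st$out_strength == c0 * (K - 1)))
  expect_true(all(st$strength == 2 * c0 * (K - 1)))

  # single edge j -> i
  W <- matrix(0, 4, 4); W[2, 3] <- 0.4   # 3 -> 2
  st <- strengths(W)
  expect_equal(st$out_strength, c(0, 0, 0.4, 0))
  expect_equal(st$in_strength, c(0, 0.4, 0, 0))

  # random 30x30 against loops
  W <- random_digraph(30, 0.6, seed = 51)
  st <- strengths(W)
  o <- oracle_strengths(W)
  expect_equal(st$in_strength, o$in_strength, tolerance = 1e-14)
  expect_equal(st$out_strength, o$out_strength, tolerance = 1e-14)
  expect_equal(st$strength, o$in_strength + o$out_strength,
               tolerance = 1e-14)

  expect_error(strengths(matrix(c(0, -1, 1, 0), 2, 2)), "non-negative")
})

test_that("clustering reproduces hand-computed cases", {
  # complete 3-node digraph, all weights 1: C_i = 1
  W <- matrix(1, 3, 3); diag(W) <- 0
  cl <- clustering(W)
  expect_equal(unname(cl$per_node), rep(1, 3), tolerance = 1e-12)
  expect_equal(cl$global, 1, tolerance = 1e-12)

  # two-node reciprocal pair: no triangles, C = 0
  W <- matrix(0, 3, 3); W[1, 2] <- 0.5; W[2, 1] <- 0.5
  expect_equal(clustering(W)$global, 0)

  expect_error(clustering(matrix(c(0, 2, 1, 0), 2, 2)), "\\[0, 1\\]")
})

test_that("shortest paths follow the 1/w length map on hand cases", {
  # single directed edge of weight 0.5: distance 2 one way, Inf back
  W <- matrix(0, 2, 2); W[2, 1] <- 0.5   # 1 -> 2
  D <- shortest_path_lengths(W)
  expect_equal(D[1, 2], 2, ignore_attr = TRUE)
  expect_equal(D[2, 1], Inf, ignore_attr = TRUE)

  # chain a -> b -> c with weights 0.5, 0.25: d(a, c) = 2 + 4
  W <- matrix(0, 3, 3); W[2, 1] <- 0.5; W[3, 2] <- 0.25
  D <- shortest_path_lengths(W)
  expect_equal(D[1, 3], 6, ignore_attr = TRUE)
})

test_that("global and local efficiency handle complete, star, empty graphs", {
  # complete unit-weight digraph: everything is 1
  W <- matrix(1, 4, 4); diag(W) <- 0
  D <- shortest_path_lengths(W)
  expect_equal(as.numeric(char_path_length(D)), 1)
  expect_equal(global_efficiency(D), 1)
  expect_equal(unname(local_efficiency(W)), rep(1, 4))

  # two-node reciprocal weights 0.5: L = 2
  W <- matrix(0, 2, 2); W[1, 2] <- 0.5; W[2, 1] <- 0.5
  expect_equal(as.numeric(char_path_length(shortest_path_lengths(W))), 2)

  # star: hub <-> leaves, no leaf-leaf edges; hub neighbours have no edges
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- 0.5; W[2:5, 1] <- 0.5
  expect_equal(unname(local_efficiency(W))[1], 0)

  # fully disconnected
  W0 <- matrix(0, 4, 4)
  D0 <- shortest_path_lengths(W0)
  expect_equal(global_efficiency(D0), 0)
  L <- char_path_length(D0)
  expect_true(is.infinite(L))
  expect_true(attr(L, "disconnected"))
})

test_that("all metrics agree with brute-force oracles on random digraphs", {
  seeds <- 1:100
  for (s in seeds) {
    K <- 3 + (s %% 6)          # 3..8 nodes
    W <- random_digraph(K, density = 0.3 + 0.5 * (s %% 3) / 2, seed = 1000 + s)
    D <- shortest_path_lengths(W)
    Do <- oracle_distances(W)
    expect_equal(D, Do, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(global_efficiency(D), oracle_global_efficiency(Do),
                 tolerance = 1e-12)
    off <- Do[row(Do) != col(Do)]
    if (all(is.finite(off))) {
      expect_equal(as.numeric(char_path_length(D)), mean(off),
                   tolerance = 1e-12)
    }
    cl <- clustering(W)
    clo <- oracle_clustering(W)
    expect_equal(unname(cl$per_node), clo$per_node, tolerance = 1e-12)
    expect_equal(cl$global, clo$global, tolerance = 1e-12)
    expect_equal(unname(local_efficiency(W)), oracle_local_efficiency(W),
                 tolerance = 1e-12)
    st <- strengths(W)
    o <- oracle_strengths(W)
    expect_equal(st$in_strength, o$in_strength, tolerance = 1e-12)
    expect_equal(st$out_strength, o$out_strength, tolerance = 1e-12)
  }
})

test_that("uniform weight scaling acts as expected on every metric", {
  W <- random_digraph(7, 0.6, seed = 60)
  for (s in c(0.2, 0.5, 0.9)) {
    Ws <- s * W
    expect_equal(strengths(Ws)$strength, s * strengths(W)$strength,
                 tolerance = 1e-12)
    expect_equal(shortest_path_lengths(Ws),
                 shortest_path_lengths(W) / s, tolerance = 1e-12)
    expect_equal(global_efficiency(shortest_path_lengths(Ws)),
                 s * global_efficiency(shortest_path_lengths(W)),
                 tolerance = 1e-12)
    # binary denominator makes C exactly proportional to s
    expect_equal(clustering(Ws)$global, s * clustering(W)$global,
                 tolerance = 1e-12)
  }
})

test_that("increasing a single weight never decreases global efficiency", {
  W <- random_digraph(8, 0.5, seed = 61)
  ge0 <- global_efficiency(shortest_path_lengths(W))
  idx <- which(W > 0 & W < 0.9)
  set.seed(62)
  for (k in sample(idx, 10)) {
    W2 <- W
    W2[k] <- min(1, W2[k] + 0.1)
    ge2 <- global_efficiency(shortest_path_lengths(W2))
    expect_gte(ge2, ge0 - 1e-12)
  }
})
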