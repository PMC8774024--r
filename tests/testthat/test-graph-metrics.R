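test_that("edge lengths follow the reciprocal convention", {
  m <- path3() * 0.5
  len <- edge_lengths(m)
  expect_equal(len[1, 2], 2)
  expect_equal(len[1, 3], Inf)
  expect_equal(diag(len), rep(0, 3), ignore_attr = TRUE)
  expect_equal(edge_lengths(path3())[1, 2], 1)  # binary edge -> unit length
  expect_equal(edge_lengths(m, convention = "direct")[1, 2], 0.5)
})

test_that("shortest paths match hand computations", {
  d <- shortest_path_lengths(edge_lengths(path3()))
  expect_equal(d[1, 3], 2)

  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 1
  tri[1, 3] <- tri[3, 1] <- 0.25
  d2 <- shortest_path_lengths(edge_lengths(tri))
  expect_equal(d2[1, 3], 2)  # min(1/0.25, 1 + 1)

  two_comp <- matrix(0, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- 1
  two_comp[3, 4] <- two_comp[4, 3] <- 1
  d3 <- shortest_path_lengths(edge_lengths(two_comp))
  expect_equal(d3[1, 3], Inf)

  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(shortest_path_lengths(neg), "non-negative")
})

test_that("efficiency and path-length closed forms on canonical graphs", {
  d_p3 <- shortest_path_lengths(edge_lengths(path3()))
  expect_equal(global_efficiency(d_p3), 5 / 6)
  expect_equal(characteristic_path_length(d_p3), 4 / 3)

  d_k4 <- shortest_path_lengths(edge_lengths(complete_graph(4)))
  expect_equal(global_efficiency(d_k4), 1)
  expect_equal(characteristic_path_length(d_k4), 1)

  single <- matrix(0, 3, 3); single[1, 2] <- single[2, 1] <- 1
  d_s <- shortest_path_lengths(edge_lengths(single))
  expect_equal(global_efficiency(d_s), 1 / 3)

  edgeless <- matrix(0, 3, 3)
  d_e <- shortest_path_lengths(edge_lengths(edgeless))
  expect_equal(characteristic_path_length(d_e), Inf)
  expect_equal(unreachable_fraction(d_e), 1)
  expect_equal(characteristic_path_length(d_e, "harmonic"), Inf)
})

test_that("nodal efficiency, degree and betweenness on path/star/complete graphs", {
  d_p3 <- shortest_path_lengths(edge_lengths(path3()))
  en <- nodal_efficiency(d_p3)
  expect_equal(unname(en), c(0.75, 1, 0.75))
  expect_equal(nodal_efficiency(d_p3, 2), 1)

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(nodal_efficiency(shortest_path_lengths(edge_lengths(iso)), 3), 0)

  expect_equal(unname(degree_centrality(path3())), c(1, 2, 1))
  wm <- matrix(0, 3, 3); wm[1, 2] <- wm[2, 1] <- 0.2; wm[1, 3] <- wm[3, 1] <- 0.3
  expect_equal(degree_centrality(wm, 1), 0.5)
  expect_equal(degree_centrality(wm, 2), 0.2)

  bc_p3 <- betweenness_centrality(path3())
  expect_equal(unname(bc_p3), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(complete_graph(4))), rep(0, 4))
  expect_equal(unname(betweenness_centrality(star_graph(5))), c(1, 0, 0, 0, 0))

  lp <- nodal_path_length(d_p3)
  expect_equal(unname(lp), c(1.5, 1, 1.5))
})

test_that("clustering and local efficiency closed forms", {
  expect_equal(unname(clustering_coefficient(complete_graph(3))), rep(1, 3))
  expect_equal(unname(clustering_coefficient(path3())), rep(0, 3))
  expect_equal(mean(clustering_coefficient(complete_graph(4))), 1)

  expect_equal(unname(local_efficiency(complete_graph(4))), rep(1, 4))
  expect_equal(unname(local_efficiency(star_graph(5))), rep(0, 5))

  tri_pend <- matrix(0, 4, 4)
  tri_pend[1, 2] <- tri_pend[2, 1] <- 1
  tri_pend[2, 3] <- tri_pend[3, 2] <- 1
  tri_pend[1, 3] <- tri_pend[3, 1] <- 1
  tri_pend[3, 4] <- tri_pend[4, 3] <- 1
  expect_equal(local_efficiency(tri_pend)[[4]], 0)

  # weighted clustering: uniform weights equal the binary value
  expect_equal(unname(clustering_coefficient(complete_graph(4) * 0.5)),
               rep(1, 4))
})

test_that("metrics are invariant under node permutation", {
  set.seed(31)
  for (rep in 1:10) {
    w <- er_graph(9, 0.4, seed = 100 + rep) * runif(81, 0.5, 1.5)
    w <- (w + t(w)) / 2
    perm <- sample(9)
    wp <- w[perm, perm]
    d <- shortest_path_lengths(edge_lengths(w))
    dp <- shortest_path_lengths(edge_lengths(wp))
    expect_equal(global_efficiency(d), global_efficiency(dp))
    expect_equal(characteristic_path_length(d), characteristic_path_length(dp))
    expect_equal(unname(nodal_efficiency(dp)), unname(nodal_efficiency(d))[perm])
    expect_equal(unname(degree_centrality(wp)), unname(degree_centrality(w))[perm])
    expect_equal(unname(clustering_coefficient(wp)),
                 unname(clustering_coefficient(w))[perm])
    expect_equal(unname(betweenness_centrality(wp)),
                 unname(betweenness_centrality(w))[perm])
  }
})

test_that("removing edges weakly decreases efficiency and increases reachable path length", {
  set.seed(17)
  for (rep in 1:10) {
    w <- er_graph(10, 0.6, seed = 200 + rep)
    d_full <- shortest_path_lengths(edge_lengths(w))
    e <- which(upper.tri(w) & w > 0)
    drop <- sample(e, 1)
    w2 <- w
    w2[drop] <- 0
    w2 <- pmin(w2, t(w2))
    d_less <- shortest_path_lengths(edge_lengths(w2))
    expect_lte(global_efficiency(d_less), global_efficiency(d_full) + 1e-12)
    expect_true(all(d_less >= d_full - 1e-12))
    if (unreachable_fraction(d_less) == unreachable_fraction(d_full)) {
      expect_gte(characteristic_path_length(d_less),
                 characteristic_path_length(d_full) - 1e-12)
    }
  }
})
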