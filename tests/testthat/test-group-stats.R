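test_that("z_transform standardises and flags constants", {
  z <- z_transform(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)

  zc <- z_transform(rep(4, 5))
  expect_equal(as.numeric(zc), rep(0, 5))
  expect_true(isTRUE(attr(zc, "zero_variance")))
  expect_error(z_transform(1), ">= 2")
})

test_that("oneway_anova matches the lm oracle and handles edge cases", {
  set.seed(6)
  v <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- oneway_anova(v, g)
  orc <- anova_oracle(v, g)
  expect_equal(res$F_stat, orc$f, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 12)

  ident <- oneway_anova(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(ident$F_stat, 0)
  expect_equal(ident$p, 1)

  sep <- oneway_anova(c(0, 0.01, 10, 10.01, 20, 20.01),
                      rep(c("a", "b", "c"), each = 2))
  expect_lt(sep$p, 1e-6)

  # two groups: F = t^2 (pooled-variance t)
  v2 <- rnorm(10); g2 <- rep(c("a", "b"), each = 5)
  tt <- t.test(v2[g2 == "a"], v2[g2 == "b"], var.equal = TRUE)
  expect_equal(oneway_anova(v2, g2)$F_stat, unname(tt$statistic)^2,
               tolerance = 1e-10)
})

test_that("bh_fdr matches p.adjust semantics and the hand oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 3)), rep(1, 3))
  set.seed(12)
  pr <- runif(25)
  q <- bh_fdr(pr)
  expect_equal(q, bh_oracle(pr))
  expect_true(all(q >= pr))
  expect_true(all(q <= 1))
  # idempotent on ranks: adjusting preserves p-value ordering
  expect_equal(order(q[order(pr)]), seq_along(pr))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("posthoc_pairwise covers all pairs, welch and tukey", {
  v <- c(1, 2, 3, 11, 12, 13, 21, 22, 23)
  g <- rep(c("a", "b", "c"), each = 3)
  ph <- posthoc_pairwise(v, g)
  expect_setequal(ph$pair, c("a-b", "a-c", "b-c"))
  expect_true(all(ph$p < 0.01))
  expect_equal(ph$estimate[ph$pair == "a-b"], -10)
  w <- t.test(v[g == "a"], v[g == "b"])
  expect_equal(ph$p[ph$pair == "a-b"], w$p.value)

  const <- posthoc_pairwise(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(const$p, 1)
  sep <- posthoc_pairwise(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_equal(sep$p, 0)

  tk <- posthoc_pairwise(v, g, method = "tukey")
  expect_setequal(tk$pair, c("a-b", "a-c", "b-c"))
  hs <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
  expect_equal(sort(unname(tk$p)), sort(unname(hs[, "p adj"])),
               ignore_attr = TRUE)
  expect_error(posthoc_pairwise(1:3, c("a", "a", "b")), ">= 2")
})

test_that("compare_groups finds planted nodal effects with BH-corrected q", {
  set.seed(77)
  groups <- rep(c("Ep", "nEp", "con"), each = 8)
  vals <- c(rnorm(8, 0.2, 0.02), rnorm(8, 0.5, 0.02), rnorm(8, 0.5, 0.02))
  co <- cohort_with_edge_values(vals, groups)
  met <- compute_metrics(co, metrics = c("global_efficiency",
                                         "nodal_efficiency",
                                         "degree_centrality"))
  gs <- compare_groups(met)
  expect_s3_class(gs, "group_stats")
  # pair column names follow the (locale-dependent) factor level order
  ph_col <- function(a, b) {
    cand <- paste0("posthoc_", c(paste(a, b, sep = "_"), paste(b, a, sep = "_")))
    intersect(cand, names(gs))[1]
  }
  hit <- gs[gs$metric == "degree_centrality" & gs$node %in% c("N1_L", "N1_R"), ]
  expect_true(all(hit$q_fdr < 0.05))
  expect_true(all(hit[[ph_col("Ep", "con")]] < 0.05))
  expect_true(all(hit[[ph_col("Ep", "nEp")]] < 0.05))
  expect_true(all(hit[[ph_col("con", "nEp")]] > 0.05))
  # untouched nodes are not significant and their posthoc is gated off
  miss <- gs[gs$metric == "degree_centrality" & gs$node %in% c("N3_L", "N3_R"), ]
  expect_true(all(miss$q_fdr > 0.05))
  expect_true(all(is.na(miss[[ph_col("Ep", "con")]])))

  # q within a family reproduces bh_fdr of that family's p-vector
  fam <- gs[gs$scope == "nodal" & gs$metric == "degree_centrality", ]
  expect_equal(fam$q_fdr, bh_fdr(fam$p))

  # z-scoring leaves the ANOVA F unchanged (affine invariance)
  gs_raw <- compare_groups(met, z_scores = FALSE, posthoc_alpha = 0)
  merged <- merge(as.data.frame(gs)[, c("scope", "metric", "node", "weighting", "F_stat")],
                  as.data.frame(gs_raw)[, c("scope", "metric", "node", "weighting", "F_stat")],
                  by = c("scope", "metric", "node", "weighting"))
  nz <- merged[merged$F_stat.y > 0, ]
  expect_equal(nz$F_stat.x, nz$F_stat.y, tolerance = 1e-8)
})

test_that("compare_groups is quiet and NA-free on an identical-subject cohort", {
  co <- identical_cohort()
  met <- compute_metrics(co, metrics = c("global_efficiency",
                                         "shortest_path_length",
                                         "degree_centrality"))
  gs <- compare_groups(met)
  expect_true(all(gs$F_stat == 0))
  expect_true(all(gs$p == 1))
  expect_true(all(gs$q_fdr == 1))
  expect_false(any(gs$degenerate))
})

test_that("ttest_from_summary reconstructs printed-table t-tests", {
  r <- ttest_from_summary(30.17, 5.15, 10, 31.25, 4.81, 10)
  expect_equal(r$df, 18)
  expect_equal(r$t, (30.17 - 31.25) / sqrt(5.15^2 + 4.81^2), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(r$t), 18), tolerance = 1e-12)

  same <- ttest_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(ttest_from_summary(1, 0, 10, 2, 1, 10), "> 0")
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 10), ">= 2")
})

test_that("fisher_exact matches closed forms and the enumeration oracle", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  extreme <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact(extreme), 2 / choose(20, 10), tolerance = 1e-10)
  tab23 <- matrix(c(6, 4, 5, 5, 5, 5), nrow = 2, byrow = TRUE)
  expect_equal(fisher_exact(tab23), fisher_oracle(tab23), tolerance = 1e-9)
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})
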