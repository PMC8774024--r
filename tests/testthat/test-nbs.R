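test_that("edgewise F matches the lm ANOVA oracle and handles degeneracies", {
  set.seed(42)
  groups <- rep(c("Ep", "nEp", "con"), each = 4)
  vals <- c(rnorm(4, 0.5, 0.05), rnorm(4, 0.4, 0.05), rnorm(4, 0.45, 0.05))
  co <- cohort_with_edge_values(vals, groups)
  fs <- edgewise_f(co, "FA")
  row <- fs[fs$node_a == "N1_L" & fs$node_b == "N1_R", ]
  expect_equal(row$F_stat, anova_oracle(vals, groups)$f, tolerance = 1e-10)
  expect_equal(row$F_stat, anova_from_summaries(vals, groups), tolerance = 1e-10)
  expect_false(row$degenerate)

  # every other edge is constant across subjects -> F = 0, not degenerate
  other <- fs[!(fs$node_a == "N1_L" & fs$node_b == "N1_R"), ]
  expect_true(all(other$F_stat == 0))
  expect_false(any(other$degenerate))

  # perfect separation: zero within-group variance, positive between
  co2 <- cohort_with_edge_values(c(1, 1, 1, 3, 3, 3), rep(c("Ep", "con"), each = 3),
                                 weighting = "FN")
  fs2 <- edgewise_f(co2, "FN")
  row2 <- fs2[fs2$node_a == "N1_L" & fs2$node_b == "N1_R", ]
  expect_equal(row2$F_stat, 1e12)
  expect_true(row2$degenerate)
})

test_that("suprathreshold components merge touching edges and split disjoint ones", {
  f1 <- tibble::tibble(node_a = c("a", "b"), node_b = c("b", "c"),
                       F_stat = c(5, 6))
  c1 <- suprathreshold_components(f1, 4)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$n_edges, 2)
  expect_equal(c1$stat_extent, 2)
  expect_equal(c1$stat_intensity, (5 - 4) + (6 - 4))

  f2 <- tibble::tibble(node_a = c("a", "c"), node_b = c("b", "d"),
                       F_stat = c(5, 6))
  c2 <- suprathreshold_components(f2, 4)
  expect_equal(nrow(c2), 2)
  expect_equal(sort(c2$stat_intensity), c(1, 2))

  expect_equal(nrow(suprathreshold_components(f2, 10)), 0)
  # threshold is strict: F exactly at the threshold does not enter
  expect_equal(nrow(suprathreshold_components(f2, 6)), 0)
  expect_equal(nrow(suprathreshold_components(f2, 5)), 1)
})

test_that("component labels are invariant to edge ordering", {
  f <- tibble::tibble(node_a = c("a", "b", "d", "e"),
                      node_b = c("b", "c", "e", "f"),
                      F_stat = c(5, 6, 7, 8))
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    cp <- suprathreshold_components(f[perm, ], 4)
    expect_equal(nrow(cp), 2)
    expect_setequal(cp$stat_intensity,
                    suprathreshold_components(f, 4)$stat_intensity)
  }
})

test_that("nbs_test is seed-deterministic and p-values use the add-one estimator", {
  set.seed(9)
  groups <- rep(c("Ep", "nEp", "con"), each = 5)
  vals <- c(rnorm(5, 0.9, 0.02), rnorm(5, 0.5, 0.02), rnorm(5, 0.5, 0.02))
  co <- cohort_with_edge_values(vals, groups)
  cfg <- nbs_config(n_perm = 200, seed = 7)
  r1 <- nbs_test(co, "FA", config = cfg)
  r2 <- nbs_test(co, "FA", config = cfg)
  expect_identical(r1$components$p_fwe, r2$components$p_fwe)
  expect_identical(r1$null_max, r2$null_max)

  expect_equal(nrow(r1$components), 1)
  ed <- r1$components$edges[[1]]
  expect_setequal(c(ed$node_a, ed$node_b), c("N1_L", "N1_R"))
  # add-one estimator bounds: p in [1/(n+1), 1]
  expect_gte(r1$components$p_fwe, 1 / 201)
  expect_lte(r1$components$p_fwe, 1)
  expect_equal(r1$components$p_fwe,
               (1 + sum(r1$null_max >= r1$components$stat)) / 201)
  expect_lt(r1$components$p_fwe, 0.05)

  # n_perm = 1 can only yield 1/2 or 1
  r3 <- nbs_test(co, "FA", config = nbs_config(n_perm = 1, seed = 3))
  expect_true(all(r3$components$p_fwe %in% c(0.5, 1)))

  # threshold equals the F quantile for (k-1, n-k)
  expect_equal(r1$threshold, qf(0.99, 2, 12))
})

test_that("tidy and glance summarise nbs results; posthoc covers all pairs", {
  groups <- rep(c("Ep", "nEp", "con"), each = 5)
  vals <- c(rnorm(5, 0.9, 0.02), rnorm(5, 0.5, 0.02), rnorm(5, 0.5, 0.02))
  set.seed(1)
  co <- cohort_with_edge_values(vals, groups)
  r <- nbs_test(co, "FA", config = nbs_config(n_perm = 99, seed = 2))
  td <- tidy(r)
  expect_true(all(c("component", "node_a", "node_b", "F_stat", "stat",
                    "p_fwe") %in% names(td)))
  expect_equal(nrow(td), sum(r$components$n_edges))
  gl <- glance(r)
  expect_equal(gl$n_components, nrow(r$components))
  expect_equal(gl$min_p_fwe, min(r$components$p_fwe))
  expect_setequal(unique(r$posthoc$pair), c("Ep-con", "Ep-nEp", "con-nEp"))

  # no suprathreshold edges -> empty but well-formed results
  co0 <- identical_cohort()
  r0 <- nbs_test(co0, "FA", config = nbs_config(n_perm = 20, seed = 2))
  expect_equal(nrow(r0$components), 0)
  expect_equal(nrow(tidy(r0)), 0)
  expect_true(is.na(glance(r0)$min_p_fwe))
  expect_output(print(r0), "no suprathreshold components")
})
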