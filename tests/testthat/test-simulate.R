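test_that("template has hub structure, shared support, and is deterministic", {
  cfg <- sim_config(seed = 11)
  t1 <- generate_template(cfg)
  t2 <- generate_template(cfg)
  expect_identical(t1, t2)
  t3 <- generate_template(sim_config(seed = 12))
  expect_false(identical(unclass(t1$FN), unclass(t3$FN)))

  supp <- unclass(t1$binary) > 0
  for (w in c("FA", "FN", "FL")) {
    expect_identical(unclass(t1[[w]]) > 0, supp)
  }
  deg <- rowSums(supp)
  hubs <- c("A6m_L", "A6m_R")
  expect_true(all(deg[hubs] >= 0.8 * (nrow(supp) - 1)))
  expect_gt(min(deg[hubs]), median(deg[setdiff(rownames(supp), hubs)]))
  # homotopic pairs always connected
  expect_true(supp["A4ul_L", "A4ul_R"])
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected")
  expect_true(igraph::is_connected(g))
})

test_that("edge_density = 1 gives a complete template support", {
  cfg <- sim_config(seed = 3, edge_density = 1, hub_density = 1)
  tpl <- generate_template(cfg)
  fn <- unclass(tpl$FN)
  expect_true(all(fn[upper.tri(fn)] > 0))
})

test_that("cohorts have 3n subjects, valid matrices, and per-subject shared support", {
  cfg <- sim_config(n_per_group = 3, seed = 8)
  co <- generate_cohort(cfg)
  subj <- cohort_subjects(co)
  expect_equal(nrow(subj), 9)
  expect_equal(unname(table(subj$group)[c("Ep", "nEp", "con")]), rep(3L, 3),
               ignore_attr = TRUE)
  for (s in subj$subject_id) {
    bin <- unclass(cohort_matrix(co, s, "binary"))
    for (w in c("FA", "FN", "FL")) {
      m <- unclass(cohort_matrix(co, s, w))
      expect_identical(m > 0, bin > 0)
      expect_true(all(m >= 0))
    }
    fa <- unclass(cohort_matrix(co, s, "FA"))
    fa_on <- fa[fa > 0]
    expect_true(all(fa_on < 0.8))
    # only edges carrying planted multipliers / hub attenuation may dip
    # below the 0.2 tracking floor, and at most by those factors
    expect_true(all(fa_on > 0.2 * 0.6 * 0.9))
  }
})

test_that("generation is deterministic under seed; n_per_group = 0 errors", {
  cfg <- sim_config(n_per_group = 2, seed = 14)
  expect_identical(generate_cohort(cfg)$matrix, generate_cohort(cfg)$matrix)
  expect_error(sim_config(n_per_group = 0), "n_per_group")
  expect_error(
    generate_cohort(sim_config(
      effects = planted_effect("A6m_L", "FOO_R", "FA", "Ep", 0.5))),
    "FOO_R")
})

test_that("planted multiplier shifts the affected group mean by that factor", {
  # no dropout or hub attenuation, many subjects: Ep mean at the planted FA
  # edge ~ 0.6 x con mean (the multiplier mechanism in isolation)
  cfg <- sim_config(n_per_group = 100, seed = 23,
                    edge_drop = c(Ep = 0, nEp = 0, con = 0),
                    hub_attenuation = numeric(0))
  co <- generate_cohort(cfg)
  vals <- vapply(cohort_subjects(co)$subject_id, function(s) {
    unclass(cohort_matrix(co, s, "FA"))["A6m_L", "A6m_R"]
  }, numeric(1))
  grp <- cohort_subjects(co)$group
  ratio_hat <- mean(vals[grp == "Ep"]) / mean(vals[grp == "con"])
  noise_sd <- cfg$subject_noise_sd
  se_ratio <- 0.6 * noise_sd * sqrt(2 / 100)
  expect_lt(abs(ratio_hat - 0.6), 3 * se_ratio)
})

test_that("hub attenuation lowers Ep hub strength by about the stated factor", {
  cfg <- sim_config(n_per_group = 50, seed = 41,
                    edge_drop = c(Ep = 0, nEp = 0, con = 0),
                    effects = default_planted_effects()[0, ])
  co <- generate_cohort(cfg)
  subj <- cohort_subjects(co)
  strength <- vapply(subj$subject_id, function(s) {
    sum(unclass(cohort_matrix(co, s, "FN"))["A6m_L", ])
  }, numeric(1))
  ratio <- mean(strength[subj$group == "Ep"]) / mean(strength[subj$group == "con"])
  expect_lt(abs(ratio - 0.9), 0.02)
  # attenuation never touches the binary support
  expect_identical(unclass(cohort_matrix(co, "Ep_01", "binary")) > 0,
                   unclass(cohort_matrix(co, "con_01", "binary")) > 0)
  expect_error(sim_config(hub_attenuation = c(Ep = 1.2)), "\\(0, 1\\]")
  expect_error(sim_config(hub_attenuation = c(XX = 0.9)), "XX")
})

test_that("null cohorts strip effects and make groups exchangeable", {
  cfg <- sim_config(n_per_group = 4, seed = 33)
  nc <- null_cohort(cfg)
  expect_equal(nrow(attr(nc, "sim_config")$effects), 0)
  # identical to generate_cohort under the effect-free, equal-dropout config
  cfg0 <- cfg
  cfg0$effects <- cfg0$effects[0, ]
  cfg0$edge_drop[] <- mean(cfg0$edge_drop)
  cfg0$hub_attenuation <- numeric(0)
  expect_identical(nc$matrix, generate_cohort(cfg0)$matrix)

  # with all effects stripped, a two-sample t on a fixed edge rejects at
  # roughly the nominal rate
  rej <- vapply(1:200, function(s) {
    co <- null_cohort(sim_config(n_per_group = 10, seed = 4000 + s,
                                 edge_drop = c(Ep = 0, nEp = 0, con = 0)))
    v <- vapply(cohort_subjects(co)$subject_id, function(ss) {
      unclass(cohort_matrix(co, ss, "FA"))["A6m_L", "A6m_R"]
    }, numeric(1))
    g <- cohort_subjects(co)$group
    t.test(v[g == "Ep"], v[g == "con"])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})
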