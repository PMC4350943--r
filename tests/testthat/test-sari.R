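test_that("pair weight favours potent, potency-conserved pairs", {
  expect_equal(pair_weight(7, 7), 49)
  expect_equal(pair_weight(5, 9), 9)
  withr::with_seed(3, {
    p <- runif(10, 5, 10); q <- runif(10, 5, 10)
    expect_identical(pair_weight(p, q), pair_weight(q, p))
  })
  expect_error(pair_weight(NaN, 5), class = "sarsvr_invalid_value")
})

test_that("raw continuity follows the weighted-similarity reading", {
  sim2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(raw_continuity(c(7, 7), sim2), 0.5)
  # all pairs maximally similar -> 0; all dissimilar -> 1
  sim_ones <- matrix(1, 4, 4)
  expect_equal(raw_continuity(c(5, 6, 7, 8), sim_ones), 0)
  sim_zero <- diag(4)
  expect_equal(raw_continuity(c(5, 6, 7, 8), sim_zero), 1)
  expect_error(raw_continuity(7, matrix(1)), "length >= 2")
})

test_that("raw discontinuity averages gap-weighted qualifying pairs", {
  sim2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(raw_discontinuity(c(5, 9), sim2, t = 0.56), 4)
  sim3 <- matrix(0.9, 3, 3); diag(sim3) <- 1
  expect_equal(raw_discontinuity(c(7, 7, 7), sim3, t = 0.56), 0)
  low_sim <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_error(raw_discontinuity(c(5, 9), low_sim, t = 0.56),
               class = "sarsvr_no_qualifying_pairs")
})

test_that("scores equal the brute-force oracle on random sets", {
  withr::with_seed(13, {
    seeds <- sample.int(10000, 5)
  })
  for (s in seeds) {
    ds <- fixture_dataset(n = 50, k = 5, cliff_fraction = 0.1, seed = s)
    sim <- pairwise_matrix(ds)
    t <- attr(ds, "tc_threshold")
    expect_equal(raw_continuity(ds$pki, sim), oracle_continuity(ds$pki, sim),
                 tolerance = 1e-10)
    expect_equal(raw_discontinuity(ds$pki, sim, t),
                 oracle_discontinuity(ds$pki, sim, t), tolerance = 1e-10)
  }
})

test_that("scores are invariant to record ordering", {
  ds <- fixture_dataset(n = 40, k = 4)
  sim <- pairwise_matrix(ds)
  withr::with_seed(8, perm <- sample(40))
  sim_p <- sim[perm, perm]
  expect_equal(raw_continuity(ds$pki[perm], sim_p), raw_continuity(ds$pki, sim),
               tolerance = 1e-12)
  expect_equal(raw_discontinuity(ds$pki[perm], sim_p, 0.56),
               raw_discontinuity(ds$pki, sim, 0.56), tolerance = 1e-12)
})

test_that("widening a qualifying pair's gap never lowers discontinuity", {
  # one qualifying pair (1,2); compound 3 is dissimilar to both
  sim <- diag(3); sim[1, 2] <- sim[2, 1] <- 0.9
  base <- raw_discontinuity(c(6, 7, 9), sim, 0.56)
  wider <- raw_discontinuity(c(6, 8, 9), sim, 0.56)
  expect_gte(wider, base)
})

test_that("panel statistics use sample mean and sd, rejecting degeneracy", {
  s <- panel_stats(tibble::tibble(cont_raw = c(0.2, 0.4), disc_raw = c(1, 2)))
  expect_equal(s$cont_mean, 0.3)
  expect_equal(s$cont_sd, sd(c(0.2, 0.4)))
  expect_equal(s$n_sets, 2)
  expect_error(panel_stats(tibble::tibble(cont_raw = c(0.3, 0.3),
                                          disc_raw = c(1, 2))),
               class = "sarsvr_degenerate_panel")
  # loop oracle on a generated panel
  panel <- fixture_panel(n_sets = 10)
  raws <- purrr::map_dfr(panel, function(ds) {
    sim <- pairwise_matrix(ds)
    tibble::tibble(cont_raw = raw_continuity(ds$pki, sim),
                   disc_raw = raw_discontinuity(ds$pki, sim, attr(ds, "tc_threshold")))
  })
  s <- panel_stats(panel)
  tot <- 0; for (v in raws$disc_raw) tot <- tot + v
  m <- tot / nrow(raws)
  ss <- 0; for (v in raws$disc_raw) ss <- ss + (v - m)^2
  expect_equal(s$disc_mean, m, tolerance = 1e-12)
  expect_equal(s$disc_sd, sqrt(ss / (nrow(raws) - 1)), tolerance = 1e-12)
})

test_that("normalization maps panel mean to 0.5 and preserves order", {
  s <- panel_stats(tibble::tibble(cont_raw = c(0.2, 0.3, 0.4),
                                  disc_raw = c(0.5, 1, 1.5)))
  expect_equal(normalize_score(s$disc_mean, s, "discontinuity"), 0.5)
  expect_equal(normalize_score(s$disc_mean + s$disc_sd, s, "discontinuity"),
               0.84134474606854293, tolerance = 1e-10)
  raws <- seq(0, 3, length.out = 7)
  expect_true(all(diff(normalize_score(raws, s, "discontinuity")) > 0))
})

test_that("score_dataset separates smooth from cliff-heavy sets", {
  panel <- fixture_panel(n_sets = 12)
  stats <- panel_stats(panel)
  smooth <- generate_dataset(synth_config(50, 5, cliff_fraction = 0,
                                          within_cluster_spread = 0.1, seed = 21))
  cliffy <- generate_dataset(synth_config(50, 5, cliff_fraction = 0.2, seed = 21))
  s_smooth <- score_dataset(smooth, stats)
  s_cliffy <- score_dataset(cliffy, stats)
  expect_lt(s_smooth$disc_norm, 0.5)
  expect_gt(s_cliffy$disc_norm, s_smooth$disc_norm)
  expect_true(all(c(s_smooth$disc_norm, s_smooth$cont_norm) >= 0))
  expect_true(all(c(s_smooth$disc_norm, s_smooth$cont_norm) <= 1))
})
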