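test_that("constant targets are fitted inside the epsilon tube", {
  ds <- fixture_dataset(n = 12, k = 2)
  ds$pki <- rep(7.3, 12)
  m <- fit_svr(ds, C = 10)
  expect_true(all(abs(predict(m, ds) - 7.3) <= 0.1 + 1e-8))
})

test_that("two-point identity-kernel fit matches the dense grid-search oracle", {
  ds <- cmpd_dataset(tibble::tibble(
    compound_id = c("a", "b"), pki = c(5, 9),
    fingerprint = list(c(1L, 2L), c(3L, 4L))  # disjoint -> kernel = identity
  ), universe = 8)
  C <- 1000; eps <- 0.1
  m <- fit_svr(ds, C = C, epsilon = eps)
  pred <- predict(m, ds)
  expect_true(all(abs(pred - c(5, 9)) <= eps + 1e-6))
  # primal objective vs dense grid search over (beta, b) with sum(beta) = 0
  objective <- function(beta, b) {
    f <- c(beta + b, -beta + b)
    beta^2 + C * sum(pmax(0, abs(c(5, 9) - f) - eps))
  }
  grid_obj <- min(outer(seq(-3, 0, by = 0.005), seq(5, 9, by = 0.005),
                        Vectorize(objective)))
  fit_obj <- objective(m$dual_coefs[1], m$intercept)
  expect_lte(fit_obj, grid_obj + 1e-3)
})

test_that("fitted duals respect the box constraint and in-tube KKT condition", {
  ds <- fixture_dataset(n = 50, k = 5, cliff_fraction = 0.1)
  for (C in c(1, 5, 50)) {
    m <- fit_svr(ds, C = C)
    expect_true(all(abs(m$dual_coefs) <= C + 1e-8))
    resid <- abs(ds$pki - predict(m, ds))
    in_tube <- resid < m$epsilon - 1e-6
    expect_true(all(abs(m$dual_coefs[in_tube]) <= 1e-6))
  }
})

test_that("prediction is the kernel expansion over support vectors", {
  # hand-built model: two support vectors with known coefficients
  fps <- list(c(1L, 2L, 3L, 4L), c(3L, 4L, 5L, 6L), c(1L, 2L, 5L, 6L))
  m <- structure(list(
    dual_coefs = c(2, -1, 0), intercept = 7, support_indices = c(1L, 2L),
    C = 10, epsilon = 0.1, train_fingerprints = fps, universe = 8L
  ), class = "svr_model")
  # K(x, x1) and K(x, x2) for x = {1,2,3,4}: 1 and 2/6
  x <- list(c(1L, 2L, 3L, 4L))
  expect_equal(predict(m, x), 2 * 1 - 1 * (2 / 6) + 7)
  # zero dual coefficients -> constant intercept
  m0 <- m; m0$dual_coefs <- rep(0, 3); m0$support_indices <- integer(0)
  expect_equal(predict(m0, fps), rep(7, 3))
  # universe mismatch
  expect_error(predict(m, list(c(1L, 99L))), class = "sarsvr_universe_mismatch")
})

test_that("predictions agree with an independent SVR implementation", {
  ds <- fixture_dataset(n = 40, k = 4, cliff_fraction = 0.1, seed = 9)
  K <- pairwise_matrix(ds)
  m <- fit_svr(ds, C = 10, epsilon = 0.1)
  ref <- kernlab::ksvm(kernlab::as.kernelMatrix(unname(K)), ds$pki,
                       type = "eps-svr", C = 10, epsilon = 0.1, scaled = FALSE)
  ref_pred <- as.numeric(kernlab::predict(
    ref, kernlab::as.kernelMatrix(unname(K)[, kernlab::SVindex(ref), drop = FALSE])))
  expect_equal(predict(m, ds), ref_pred, tolerance = 0.02)
})

test_that("epsilon-insensitive error matches hand and loop oracles", {
  expect_equal(eps_insensitive_abs_error(5.0, 5.05, 0.1), 0)
  expect_equal(eps_insensitive_abs_error(c(5, 7), c(5.5, 6.0), 0.1), 1.3)
  withr::with_seed(4, {
    y <- runif(50, 5, 10); f <- y + rnorm(50, 0, 0.5)
  })
  expect_equal(eps_insensitive_abs_error(y, f, 0.1), oracle_eps_error(y, f, 0.1),
               tolerance = 1e-12)
  expect_equal(eps_insensitive_abs_error(y, f, 0), sum(abs(y - f)),
               tolerance = 1e-12)
  expect_error(eps_insensitive_abs_error(1:3, 1:2), "equal length")
})

test_that("mean error divides by n and is duplication-invariant", {
  expect_equal(mean_abs_error(c(5, 7), c(5.5, 6.0), 0.1), 0.65)
  expect_equal(mean_abs_error(c(5, 7), c(5, 7), 0.1), 0)
  y <- c(5, 6, 7); f <- c(5.4, 6.6, 6.9)
  expect_equal(mean_abs_error(rep(y, 2), rep(f, 2), 0.1),
               mean_abs_error(y, f, 0.1), tolerance = 1e-12)
})

test_that("r_squared is one minus the residual variance ratio", {
  y <- c(5, 6, 7, 8)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(y, c(5.5, 5.5, 7.5, 7.5)), 1 - 1 / 5)
  expect_error(r_squared(rep(5, 4), c(5, 5, 5, 6)), class = "sarsvr_invalid_value")
})

test_that("trials draw reproducible disjoint half splits", {
  ds <- fixture_dataset(n = 31, k = 3)
  cfg <- svr_config(c_grid = c(1, 5), n_trials = 4, seed = 6)
  tr1 <- run_trials(ds, C = 5, cfg)
  tr2 <- run_trials(ds, C = 5, cfg)
  expect_equal(nrow(tr1), 4)
  expect_identical(tr1$train_idx, tr2$train_idx)
  expect_identical(tr1$test_pred, tr2$test_pred)
  for (k in 1:4) {
    tr <- tr1$train_idx[[k]]; te <- tr1$test_idx[[k]]
    expect_length(tr, 15)          # floor(31/2)
    expect_length(te, 16)          # ceiling(31/2)
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), 1:31)
  }
  expect_true(all(tr1$train_error >= 0) && all(tr1$test_error >= 0))
})

test_that("the sweep reuses splits across C and is deterministic", {
  ds <- fixture_dataset(n = 30, k = 3)
  cfg <- svr_config(c_grid = c(1, 10), n_trials = 3, seed = 2)
  sw <- sweep_c(ds, cfg)
  expect_equal(nrow(sw$by_c), 2)
  expect_identical(sw$trials$train_idx[sw$trials$c == 1],
                   sw$trials$train_idx[sw$trials$c == 10])
  sw2 <- sweep_c(ds, cfg)
  expect_identical(sw$by_c, sw2$by_c)
  # weaker regularization never increases the training error on a fixed split
  tr1 <- sw$trials[sw$trials$c == 1, ]
  tr10 <- sw$trials[sw$trials$c == 10, ]
  expect_true(all(tr10$train_error <= tr1$train_error + 1e-6))
})

test_that("best C selection is the test-error argmin with small-C ties", {
  tab <- tibble::tibble(c = c(1, 2, 3), mean_test_error = c(0.5, 0.4, 0.45))
  expect_equal(select_best_c(tab), 2)
  tie <- tibble::tibble(c = c(2, 1), mean_test_error = c(0.4, 0.4))
  expect_equal(select_best_c(tie), 1)
  withr::with_seed(5, {
    tab <- tibble::tibble(c = sample(1:50, 20), mean_test_error = runif(20))
  })
  best <- Inf; arg <- NA
  for (i in order(tab$c)) {
    if (tab$mean_test_error[i] < best) { best <- tab$mean_test_error[i]; arg <- tab$c[i] }
  }
  expect_equal(select_best_c(tab), arg)
})

test_that("tidy/glance/autoplot expose the sweep", {
  ds <- fixture_dataset(n = 24, k = 3)
  sw <- sweep_c(ds, svr_config(c_grid = c(1, 5), n_trials = 2, seed = 1))
  expect_identical(tidy(sw), sw$by_c)
  g <- glance(sw)
  expect_equal(g$best_c, sw$best_c)
  expect_s3_class(autoplot(sw), "ggplot")
})
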