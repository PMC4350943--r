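fake_trials <- function(rows) {
  structure(dplyr::bind_rows(rows), c = 5, epsilon = 0.1,
            class = c("svr_trials", class(tibble::tibble())))
}

test_that("prediction summaries average per-context occurrences", {
  ds <- cmpd_dataset(tibble::tibble(
    compound_id = c("a", "b", "c"), pki = c(5, 6, 7),
    fingerprint = list(1L, 2L, 3L)
  ), universe = 8)
  trials <- fake_trials(list(
    tibble::tibble(trial = 1, train_idx = list(c(2L, 3L)), test_idx = list(1L),
                   train_pred = list(c(6.1, 7.1)), test_pred = list(6.0)),
    tibble::tibble(trial = 2, train_idx = list(c(2L, 3L)), test_idx = list(1L),
                   train_pred = list(c(5.9, 6.9)), test_pred = list(7.0)),
    tibble::tibble(trial = 3, train_idx = list(c(2L, 3L)), test_idx = list(1L),
                   train_pred = list(c(6.0, 7.0)), test_pred = list(8.0))
  ))
  s <- summarize_predictions(trials, ds, "test")
  expect_equal(s$mean_prediction[s$compound_id == "a"], 7)   # mean(6, 7, 8)
  expect_equal(s$n_occurrences, c(3L, 0L, 0L))
  # b and c never in a test set -> observed potency fallback, flagged
  expect_identical(s$fallback_used, c(FALSE, TRUE, TRUE))
  expect_equal(s$mean_prediction[2:3], c(6, 7))
  # single trial: summary equals that trial's predictions
  one <- summarize_predictions(fake_trials(list(
    tibble::tibble(trial = 1, train_idx = list(c(2L, 3L)), test_idx = list(1L),
                   train_pred = list(c(6.5, 7.5)), test_pred = list(5.5))
  )), ds, "train")
  expect_equal(one$mean_prediction, c(5, 6.5, 7.5))
})

test_that("identity substitution reproduces observed scores exactly", {
  ds <- fixture_dataset(n = 40, k = 4, cliff_fraction = 0.1)
  observed <- score_dataset(ds)
  s <- tibble::tibble(compound_id = ds$compound_id, observed_pki = ds$pki,
                      mean_prediction = ds$pki, n_occurrences = 1L,
                      fallback_used = FALSE)
  expect_identical(predicted_scores(ds, s)$disc_raw, observed$disc_raw)
  expect_identical(predicted_scores(ds, s)$cont_raw, observed$cont_raw)
})

test_that("clipping cliff potencies to the mean lowers discontinuity", {
  ds <- fixture_dataset(n = 60, k = 6, cliff_fraction = 0.15)
  observed <- score_dataset(ds)
  clipped <- ifelse(ds$is_cliff, mean(ds$pki), ds$pki)
  s <- tibble::tibble(compound_id = ds$compound_id, mean_prediction = clipped)
  expect_lt(predicted_scores(ds, s)$disc_raw, observed$disc_raw)
})

test_that("continuity is robust to mild prediction noise", {
  ds <- fixture_dataset(n = 60, k = 6, cliff_fraction = 0.1)
  observed <- score_dataset(ds)
  withr::with_seed(17, noisy <- ds$pki + rnorm(60, 0, 0.2))
  s <- tibble::tibble(compound_id = ds$compound_id, mean_prediction = noisy)
  expect_lt(abs(predicted_scores(ds, s)$cont_raw - observed$cont_raw), 0.05)
})

test_that("discontinuity profiles track the grid and favour training context", {
  ds <- fixture_dataset(n = 60, k = 6, cliff_fraction = 0.15, seed = 19)
  cfg <- svr_config(c_grid = c(1, 25), n_trials = 5, seed = 3)
  prof <- discontinuity_profile(ds, cfg)
  expect_equal(nrow(prof), 2)
  expect_true(all(c("disc_raw_train", "disc_raw_test") %in% names(prof)))
  obs <- attr(prof, "observed")
  expect_s3_class(obs, "sari_scores")
  # at the largest C the model fits training cliffs better than test cliffs
  top <- prof[prof$c == 25, ]
  expect_gte(top$disc_raw_train, top$disc_raw_test)
  prof2 <- discontinuity_profile(ds, cfg)
  expect_identical(as.data.frame(prof), as.data.frame(prof2))
  expect_s3_class(autoplot(prof), "ggplot")
})

test_that("mixed-C trial tables are rejected", {
  ds <- fixture_dataset(n = 20, k = 2)
  sw <- sweep_c(ds, svr_config(c_grid = c(1, 5), n_trials = 2, seed = 1))
  expect_error(summarize_predictions(sw$trials, ds, "test"), "several C")
})

test_that("discontinuity/error correlation matches the covariance formula", {
  line <- tibble::tibble(disc = 1:5, error = 2 * (1:5) + 3)
  expect_equal(correlate_disc_vs_error(line)$r, 1, tolerance = 1e-12)
  pts <- tibble::tibble(disc = 1:5, error = c(2, 1, 3, 4, 5))
  res <- correlate_disc_vs_error(pts)
  # hand oracle: r = 9/10; p from the exact t transform with n - 2 df
  x <- pts$disc; y <- pts$error
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_hand, 0.9, tolerance = 1e-12)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(res$p_two_tailed, 2 * stats::pt(-abs(t_stat), df = 3),
               tolerance = 1e-12)
  # antisymmetry
  neg <- correlate_disc_vs_error(tibble::tibble(disc = x, error = -y))
  expect_equal(neg$r, -res$r, tolerance = 1e-12)
  expect_error(correlate_disc_vs_error(tibble::tibble(disc = c(1, 1, 1),
                                                      error = 1:3)),
               class = "sarsvr_invalid_value")
})
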