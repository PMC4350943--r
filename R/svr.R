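#' SVR sweep configuration
#'
#' Defaults follow the standard regularization-analysis protocol: a C grid of
#' `{1, ..., 50, 100, 250, 500, 1000}`, epsilon-tube half-width 0.1 pKi
#' (smaller values would be below experimental detection limits, larger ones
#' would excuse biologically relevant deviations, so epsilon is fixed rather
#' than tuned), 10 trials of random 50/50 train/test splits. The same trial
#' partitions are reused for every C, so C is the only factor varying across
#' a sweep.
#'
#' @param c_grid Ordered vector of positive regularization values.
#' @param epsilon Tube half-width in pKi units, `>= 0`.
#' @param n_trials Number of random-split trials.
#' @param split_fraction Fraction of compounds assigned to training, in (0, 1).
#' @param seed Integer seed for the split stream.
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(c_grid = c(1:50, 100, 250, 500, 1000), epsilon = 0.1,
                       n_trials = 10L, split_fraction = 0.5, seed = 1L) {
  if (!is.numeric(c_grid) || length(c_grid) == 0 || any(c_grid <= 0)) {
    stop_input("`c_grid` must be a non-empty vector of positive values.",
               class = "sarsvr_config_error")
  }
  check_number(epsilon, "epsilon")
  if (epsilon < 0) stop_input("`epsilon` must be >= 0.", class = "sarsvr_config_error")
  check_number(n_trials, "n_trials", positive = TRUE)
  check_number(split_fraction, "split_fraction")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_input("`split_fraction` must lie strictly in (0, 1).",
               class = "sarsvr_config_error")
  }
  check_number(seed, "seed")
  structure(list(
    c_grid = as.double(c_grid), epsilon = as.double(epsilon),
    n_trials = as.integer(n_trials), split_fraction = as.double(split_fraction),
    seed = as.integer(seed)
  ), class = "svr_config")
}

# Core epsilon-SVR dual solve on a precomputed kernel matrix.
#
# Dual variables x = (alpha, alpha*) with box [0, C], equality sum(alpha -
# alpha*) = 0, solved as a QP with kernlab::ipop. The prediction coefficients
# are beta = alpha - alpha*; the intercept is recovered from the KKT interval
# [lo, hi] implied by the complementary-slackness conditions, and within that
# interval b is chosen to minimize the epsilon-insensitive training loss
# exactly (piecewise-linear 1D problem; ties broken toward the interval
# midpoint). Coefficients below 1e-8 * max(1, C) are snapped to zero.
fit_svr_kernel <- function(K, y, C, epsilon, sigf = 12, maxiter = 400) {
  n <- length(y)
  if (n < 2) stop_input("Need >= 2 training compounds.")
  check_number(C, "C", positive = TRUE)
  check_number(epsilon, "epsilon")
  # If one intercept already places every target inside the tube, the zero
  # expansion with b at the target mid-range is the exact optimum (zero loss,
  # zero norm); the interior-point solver's KKT system is singular there.
  if (max(y) - min(y) <= 2 * epsilon) {
    return(structure(list(
      dual_coefs = rep(0, n), intercept = (max(y) + min(y)) / 2,
      support_indices = integer(0), C = C, epsilon = epsilon, y_train = y
    ), class = "svr_model"))
  }
  # The dual Hessian is rank-deficient by construction; a tiny ridge keeps the
  # interior-point KKT system factorizable. At the tightest significance
  # setting the iterates can approach the box boundary so closely that the
  # scaled KKT system still goes numerically singular, so precision is
  # relaxed stepwise before giving up. In-tube coefficients stay pinned at
  # zero regardless (their dual gradient is strictly positive there).
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  sol <- NULL
  failure <- NULL
  for (s in unique(c(sigf, 10, 8))) {
    sol <- tryCatch(
      kernlab::ipop(c(epsilon - y, epsilon + y), H,
                    matrix(c(rep(1, n), rep(-1, n)), 1), 0,
                    rep(0, 2 * n), rep(C, 2 * n), 0,
                    sigf = s, maxiter = maxiter),
      error = function(e) {
        failure <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(sol) && identical(kernlab::how(sol), "converged")) break
    if (!is.null(sol)) failure <- kernlab::how(sol)
    sol <- NULL
  }
  if (is.null(sol)) {
    stop_input(sprintf("SVR dual solve failed at C = %g: %s", C, failure),
               class = "sarsvr_svr_convergence", C = C, status = failure)
  }
  x <- kernlab::primal(sol)
  alpha <- x[seq_len(n)]
  alpha_star <- x[n + seq_len(n)]
  beta <- alpha - alpha_star
  beta[abs(beta) < 1e-8 * max(1, C)] <- 0
  beta <- pmin(pmax(beta, -C), C)

  g <- y - as.numeric(K %*% beta)
  tol <- 1e-6 * max(1, C)
  lo <- suppressWarnings(max(c(g[alpha_star > tol] + epsilon,
                               g[alpha < C - tol] - epsilon)))
  hi <- suppressWarnings(min(c(g[alpha > tol] - epsilon,
                               g[alpha_star < C - tol] + epsilon)))
  if (!is.finite(lo) && !is.finite(hi)) {
    lo <- hi <- mean(g)
  } else if (!is.finite(lo)) {
    lo <- hi
  } else if (!is.finite(hi)) {
    hi <- lo
  }
  if (lo > hi) lo <- hi <- (lo + hi) / 2
  b <- polish_intercept(g, epsilon, lo, hi)

  structure(list(
    dual_coefs = beta,
    intercept = b,
    support_indices = which(beta != 0),
    C = C, epsilon = epsilon,
    y_train = y
  ), class = "svr_model")
}

# Exact minimizer of sum(max(0, |g - b| - eps)) over b in [lo, hi]. The loss
# is convex piecewise linear in b with breakpoints at g +/- eps, so the
# minimum is attained at a clipped breakpoint (or anywhere on a flat stretch;
# ties go to the candidate nearest the KKT-interval midpoint).
polish_intercept <- function(g, epsilon, lo, hi) {
  mid <- (lo + hi) / 2
  cand <- unique(pmin(pmax(c(g - epsilon, g + epsilon, mid), lo), hi))
  loss <- vapply(cand, function(b) sum(pmax(0, abs(g - b) - epsilon)), numeric(1))
  best <- which(loss <= min(loss) + 1e-12)
  cand[best][which.min(abs(cand[best] - mid))]
}

#' Fit an epsilon-SVR model with the Tanimoto kernel
#'
#' Builds the training kernel matrix from the fingerprints, solves the
#' epsilon-SVR dual (box-constrained QP, delegated to [kernlab::ipop()]), and
#' returns a self-contained model: dual coefficients `alpha_i - alpha_i*`
#' (each bounded by C in magnitude), intercept, and the training fingerprints,
#' from which the kernelized prediction function
#' `f(x) = sum_i (alpha_i - alpha_i*) K(x_i, x) + b` is evaluated.
#'
#' @param data A [cmpd_dataset()] or data frame with `pki` and `fingerprint`
#'   columns; the training set.
#' @param C Regularization term, `> 0`. Larger C penalizes training errors
#'   more heavily (risking overfitting); smaller C favours low-complexity
#'   models (risking underfitting).
#' @param epsilon Tube half-width in pKi units.
#' @return An object of class `svr_model`.
#' @examples
#' ds <- generate_dataset(synth_config(40, 4, seed = 3))
#' m <- fit_svr(ds, C = 5)
#' head(predict(m, ds))
#' @export
fit_svr <- function(data, C, epsilon = 0.1) {
  data <- as_dataset_input(data)
  K <- pairwise_matrix(data)
  model <- fit_svr_kernel(K, data$pki, C, epsilon)
  model$train_fingerprints <- data$fingerprint
  model$universe <- if (is_cmpd_dataset(data)) dataset_attr(data, "universe") else NULL
  model
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> C = %g, epsilon = %g, %d/%d support vectors, intercept %.4f\n",
              x$C, x$epsilon, length(x$support_indices), length(x$dual_coefs),
              x$intercept))
  invisible(x)
}

# Prediction from a kernel block K(new, train).
predict_kernel <- function(model, K_new_train) {
  sv <- model$support_indices
  if (length(sv) == 0) {
    return(rep(model$intercept, nrow(K_new_train)))
  }
  as.numeric(K_new_train[, sv, drop = FALSE] %*% model$dual_coefs[sv]) + model$intercept
}

#' Predict potencies from a fitted SVR model
#'
#' Evaluates the kernelized prediction function over the stored support
#' vectors: `f(x) = sum_i (alpha_i - alpha_i*) K(x_i, x) + b`.
#'
#' @param object An [fit_svr()] model.
#' @param newdata A [cmpd_dataset()], a data frame with a `fingerprint`
#'   column, or a list of fingerprints.
#' @param ... Unused.
#' @return Numeric vector of predicted pKi values.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (is.null(object$train_fingerprints)) {
    stop_input("Model was fitted on a bare kernel; predict via kernel blocks instead.")
  }
  fps <- if (is.data.frame(newdata)) newdata$fingerprint else newdata
  if (is.null(fps) || !is.list(fps)) {
    stop_input("`newdata` must carry a list of fingerprints.")
  }
  if (!is.null(object$universe)) {
    mx <- max(unlist(fps))
    if (mx > object$universe) {
      stop_input(sprintf("Fingerprint universe mismatch: bit %d > %d.", mx, object$universe),
                 class = "sarsvr_universe_mismatch")
    }
  }
  K <- cross_tanimoto(fps, object$train_fingerprints,
                      object$universe %||% max(unlist(c(fps, object$train_fingerprints))))
  predict_kernel(object, K)
}

cross_tanimoto <- function(fps_a, fps_b, universe) {
  na <- length(fps_a); nb <- length(fps_b)
  sa <- lengths(fps_a); sb <- lengths(fps_b)
  xa <- matrix(0, na, universe)
  xa[cbind(rep.int(seq_len(na), sa), unlist(fps_a))] <- 1
  xb <- matrix(0, nb, universe)
  xb[cbind(rep.int(seq_len(nb), sb), unlist(fps_b))] <- 1
  inter <- tcrossprod(xa, xb)
  inter / (outer(sa, sb, "+") - inter)
}

#' Epsilon-insensitive absolute error
#'
#' `sum_i max(0, |y_i - f(x_i)| - epsilon)`: the realized slack of the SVR
#' objective. Deviations inside the epsilon tube cost nothing; this is the
#' error the sweep minimizes and reports.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param epsilon Tube half-width.
#' @return Total error, `>= 0`. With `epsilon = 0` this is the ordinary L1
#'   error.
#' @export
eps_insensitive_abs_error <- function(y_true, y_pred, epsilon = 0.1) {
  if (length(y_true) != length(y_pred)) {
    stop_input("`y_true` and `y_pred` must have equal length.")
  }
  check_number(epsilon, "epsilon")
  sum(pmax(0, abs(y_true - y_pred) - epsilon))
}

#' Mean epsilon-insensitive absolute error
#'
#' The [eps_insensitive_abs_error()] divided by the number of compounds,
#' making errors comparable across data sets of different size.
#'
#' @inheritParams eps_insensitive_abs_error
#' @param n Divisor; defaults to `length(y_true)`.
#' @return Error per compound, `>= 0`.
#' @export
mean_abs_error <- function(y_true, y_pred, epsilon = 0.1, n = length(y_true)) {
  if (n <= 0) stop_input("`n` must be > 0.")
  eps_insensitive_abs_error(y_true, y_pred, epsilon) / n
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`: the fraction of the observed potency variance
#' explained by the predictions. Can be negative for predictions worse than
#' the mean.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must have
#'   nonzero variance.
#' @return R-squared, `<= 1`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop_input("Need equal-length vectors with >= 2 values.")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop_input("`y_true` has zero variance; R^2 is undefined.",
               class = "sarsvr_invalid_value")
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

# Seeded train-index draws: n_trials subsets of size floor(n * split_fraction).
make_splits <- function(n, config) {
  n_train <- floor(n * config$split_fraction)
  if (n_train < 2 || n - n_train < 1) {
    stop_input("Data set too small for the requested split.")
  }
  withr::with_seed(config$seed, {
    purrr::map(seq_len(config$n_trials), function(i) sort(sample.int(n, n_train)))
  })
}

#' Run repeated random-split SVR trials at one C
#'
#' Draws `n_trials` random train/test partitions from the seeded stream (the
#' training half has `floor(n * split_fraction)` compounds), fits one model
#' per partition, and records predictions and epsilon-insensitive errors on
#' both halves.
#'
#' @param dataset A [cmpd_dataset()] with at least 4 compounds.
#' @param C Regularization term.
#' @param config An [svr_config()]; its `c_grid` is ignored here.
#' @param sim Optional precomputed [pairwise_matrix()].
#' @param splits Optional list of training-index vectors (one per trial),
#'   normally produced internally; supplied by [sweep_c()] so all C values
#'   share partitions.
#' @param keep_models Store the fitted `svr_model` per trial.
#' @return A tibble of class `svr_trials`: one row per trial with list-columns
#'   `train_idx`, `test_idx`, `train_pred`, `test_pred`, the scalar errors
#'   `train_error`, `test_error`, and optionally `model`. Attributes `c`,
#'   `epsilon`, `n`.
#' @export
run_trials <- function(dataset, C, config = svr_config(), sim = NULL,
                       splits = NULL, keep_models = TRUE) {
  dataset <- as_dataset_input(dataset, "dataset")
  n <- nrow(dataset)
  if (n < 4) stop_input("Need >= 4 compounds for split trials.")
  sim <- sim %||% pairwise_matrix(dataset)
  splits <- splits %||% make_splits(n, config)
  y <- dataset$pki
  rows <- purrr::map(seq_along(splits), function(k) {
    tr <- splits[[k]]
    te <- setdiff(seq_len(n), tr)
    model <- fit_svr_kernel(sim[tr, tr, drop = FALSE], y[tr], C, config$epsilon)
    pred_tr <- predict_kernel(model, sim[tr, tr, drop = FALSE])
    pred_te <- predict_kernel(model, sim[te, tr, drop = FALSE])
    tibble(
      trial = k,
      train_idx = list(tr), test_idx = list(te),
      train_pred = list(pred_tr), test_pred = list(pred_te),
      train_error = eps_insensitive_abs_error(y[tr], pred_tr, config$epsilon),
      test_error = eps_insensitive_abs_error(y[te], pred_te, config$epsilon),
      model = if (keep_models) list(model) else list(NULL)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_models) out$model <- NULL
  structure(out, c = C, epsilon = config$epsilon, n = n,
            class = c("svr_trials", class(out)))
}

#' Regularization sweep over the C grid
#'
#' For every C in the grid, runs the repeated-split protocol of
#' [run_trials()] — with the identical trial partitions reused across C
#' values — and summarizes the per-trial epsilon-insensitive errors.
#'
#' @param dataset A [cmpd_dataset()].
#' @param config An [svr_config()].
#' @param keep_trials Keep per-trial predictions (needed to recompute SAR
#'   scores from predictions afterwards).
#' @param sim Optional precomputed similarity/kernel matrix.
#' @return An object of class `svr_sweep`: list with `by_c` (per-C tibble of
#'   mean/sd train and test errors, mean test MAE and mean test R-squared),
#'   `trials` (all per-trial rows with a `c` column, or `NULL`), `best_c`,
#'   `config`, `n`.
#' @examples
#' ds <- generate_dataset(synth_config(40, 4, seed = 3))
#' sw <- sweep_c(ds, svr_config(c_grid = c(1, 5, 10), n_trials = 3, seed = 2))
#' tidy(sw)
#' select_best_c(sw)
#' @export
sweep_c <- function(dataset, config = svr_config(), keep_trials = TRUE,
                    sim = NULL) {
  dataset <- as_dataset_input(dataset, "dataset")
  n <- nrow(dataset)
  sim <- sim %||% pairwise_matrix(dataset)
  splits <- make_splits(n, config)
  y <- dataset$pki
  per_c <- purrr::map(config$c_grid, function(C) {
    tr <- run_trials(dataset, C, config, sim = sim, splits = splits,
                     keep_models = FALSE)
    test_mae <- purrr::map2_dbl(tr$test_idx, tr$test_pred, function(idx, pred) {
      mean_abs_error(y[idx], pred, config$epsilon)
    })
    test_r2 <- purrr::map2_dbl(tr$test_idx, tr$test_pred, function(idx, pred) {
      tryCatch(r_squared(y[idx], pred), error = function(e) NA_real_)
    })
    list(
      summary = tibble(
        c = C,
        mean_train_error = mean(tr$train_error), sd_train_error = sd(tr$train_error),
        mean_test_error = mean(tr$test_error), sd_test_error = sd(tr$test_error),
        mean_test_mae = mean(test_mae), mean_test_r2 = mean(test_r2)
      ),
      trials = if (keep_trials) dplyr::mutate(as_tibble(tr), c = C, .before = 1) else NULL
    )
  })
  by_c <- dplyr::bind_rows(purrr::map(per_c, "summary"))
  out <- structure(list(
    by_c = by_c,
    trials = if (keep_trials) dplyr::bind_rows(purrr::map(per_c, "trials")) else NULL,
    config = config,
    n = n
  ), class = "svr_sweep")
  out$best_c <- select_best_c(out)
  out
}

#' Select the best regularization term from a sweep
#'
#' The C with the lowest mean test error; ties are broken toward the smallest
#' C (the less complex model).
#'
#' @param sweep An [sweep_c()] result or its `by_c` tibble.
#' @return The selected C value.
#' @export
select_best_c <- function(sweep) {
  by_c <- if (inherits(sweep, "svr_sweep")) sweep$by_c else as_tibble(sweep)
  if (is.null(by_c) || nrow(by_c) == 0) stop_input("Empty sweep.")
  by_c <- dplyr::arrange(by_c, .data$c)
  by_c$c[which.min(by_c$mean_test_error)]
}

#' @export
print.svr_sweep <- function(x, ...) {
  cat(sprintf("<svr_sweep> n = %d, %d C values x %d trials, epsilon = %g, best C = %g\n",
              x$n, nrow(x$by_c), x$config$n_trials, x$config$epsilon, x$best_c))
  print(x$by_c, ...)
  invisible(x)
}

#' @rdname sweep_c
#' @param x An `svr_sweep` object.
#' @param ... Unused.
#' @export
tidy.svr_sweep <- function(x, ...) x$by_c

#' @rdname sweep_c
#' @export
glance.svr_sweep <- function(x, ...) {
  best <- x$by_c[x$by_c$c == x$best_c, ]
  tibble(
    n = x$n, n_c = nrow(x$by_c), n_trials = x$config$n_trials,
    epsilon = x$config$epsilon, best_c = x$best_c,
    best_mean_test_error = best$mean_test_error,
    best_mean_test_mae = best$mean_test_mae,
    best_mean_test_r2 = best$mean_test_r2
  )
}

#' @rdname sweep_c
#' @param object An `svr_sweep` object.
#' @export
autoplot.svr_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(object$by_c,
                           c("mean_train_error", "mean_test_error"),
                           names_to = "context", values_to = "error")
  d$context <- ifelse(d$context == "mean_train_error", "train", "test")
  d$sd <- ifelse(d$context == "train", d$sd_train_error, d$sd_test_error)
  d$c_rank <- match(d$c, sort(unique(d$c)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_rank, y = .data$error,
                                  colour = .data$context)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$error - .data$sd,
                                      ymax = .data$error + .data$sd,
                                      fill = .data$context),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq_along(sort(unique(d$c))),
                                labels = sort(unique(d$c))) +
    ggplot2::labs(x = "regularization term C (evenly spaced)",
                  y = "epsilon-insensitive absolute error",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
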