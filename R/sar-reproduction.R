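#' Per-compound mean predicted potency in train or test context
#'
#' Over the trials of one regularization setting, averages each compound's
#' predictions across the trials in which it appeared in the requested
#' context (training or test membership). Compounds that never appeared in
#' that context across the random splits fall back to their observed potency
#' and are flagged.
#'
#' @param trials An [run_trials()] result, or the `trials` tibble of a
#'   [sweep_c()] filtered to a single C.
#' @param dataset The [cmpd_dataset()] the trials were run on.
#' @param context `"test"` or `"train"`.
#' @return A tibble of class `prediction_summary`: `compound_id`,
#'   `observed_pki`, `mean_prediction`, `n_occurrences`, `fallback_used`.
#' @export
summarize_predictions <- function(trials, dataset, context = c("test", "train")) {
  context <- match.arg(context)
  dataset <- as_dataset_input(dataset, "dataset")
  trials <- as_tibble(trials)
  if (nrow(trials) == 0) stop_input("`trials` is empty.")
  if ("c" %in% names(trials) && length(unique(trials$c)) > 1) {
    stop_input("`trials` mixes several C values; filter to one C first.")
  }
  idx_col <- paste0(context, "_idx")
  pred_col <- paste0(context, "_pred")
  if (!all(c(idx_col, pred_col) %in% names(trials))) {
    stop_input("`trials` lacks the per-trial index/prediction columns.")
  }
  n <- nrow(dataset)
  total <- numeric(n)
  count <- integer(n)
  for (k in seq_len(nrow(trials))) {
    idx <- trials[[idx_col]][[k]]
    total[idx] <- total[idx] + trials[[pred_col]][[k]]
    count[idx] <- count[idx] + 1L
  }
  fallback <- count == 0L
  mean_pred <- ifelse(fallback, dataset$pki, total / pmax(count, 1L))
  out <- tibble(
    compound_id = dataset$compound_id,
    observed_pki = dataset$pki,
    mean_prediction = mean_pred,
    n_occurrences = count,
    fallback_used = fallback
  )
  structure(out, context = context,
            c = attr(trials, "c", exact = TRUE) %||%
              (if ("c" %in% names(trials)) trials$c[1] else NA_real_),
            class = c("prediction_summary", class(out)))
}

#' SAR scores recomputed from predicted potencies
#'
#' Scores the data set with its observed potencies replaced by the
#' per-compound mean predictions of a [summarize_predictions()] summary,
#' keeping the similarity matrix and threshold of the observed scoring. With
#' the observed potencies substituted, this reproduces the observed scores
#' exactly.
#'
#' @param dataset A [cmpd_dataset()].
#' @param summary A [summarize_predictions()] result covering every compound.
#' @param stats Optional [panel_stats()] for normalized scores.
#' @param sim Optional precomputed similarity matrix.
#' @return A `sari_scores` tibble (see [score_dataset()]).
#' @export
predicted_scores <- function(dataset, summary, stats = NULL, sim = NULL) {
  dataset <- as_dataset_input(dataset, "dataset")
  summary <- as_tibble(summary)
  pos <- match(dataset$compound_id, summary$compound_id)
  if (any(is.na(pos))) {
    stop_input("`summary` must cover every compound in the data set.")
  }
  score_dataset(dataset, stats = stats,
                potencies = summary$mean_prediction[pos], sim = sim)
}

#' Discontinuity profile across the regularization grid
#'
#' For each C of a sweep, summarizes predictions in training and test context
#' and recomputes the SAR scores from them, yielding the per-C profile of
#' predicted-potency discontinuity against the observed score.
#'
#' @param dataset A [cmpd_dataset()].
#' @param sweep Either an [svr_config()] (a fresh sweep is run) or an existing
#'   [sweep_c()] result with `keep_trials = TRUE`.
#' @param stats Optional [panel_stats()] for normalized columns.
#' @param sim Optional precomputed similarity matrix.
#' @return A tibble of class `disc_profile`: per C, `disc_raw_train`,
#'   `disc_raw_test`, `cont_raw_train`, `cont_raw_test` (and normalized
#'   columns when `stats` is given). The observed `sari_scores` row is
#'   attached as attribute `observed`.
#' @export
discontinuity_profile <- function(dataset, sweep = svr_config(), stats = NULL,
                                  sim = NULL) {
  dataset <- as_dataset_input(dataset, "dataset")
  sim <- sim %||% pairwise_matrix(dataset)
  if (inherits(sweep, "svr_config")) {
    sweep <- sweep_c(dataset, sweep, keep_trials = TRUE, sim = sim)
  }
  if (!inherits(sweep, "svr_sweep") || is.null(sweep$trials)) {
    stop_input("`sweep` must be an svr_config or an svr_sweep kept with trials.")
  }
  observed <- score_dataset(dataset, stats = stats, sim = sim)
  rows <- purrr::map(unique(sweep$trials$c), function(C) {
    tr <- sweep$trials[sweep$trials$c == C, ]
    sc <- purrr::map(c(train = "train", test = "test"), function(ctx) {
      predicted_scores(dataset, summarize_predictions(tr, dataset, ctx),
                       stats = stats, sim = sim)
    })
    tibble(
      c = C,
      disc_raw_train = sc$train$disc_raw, disc_raw_test = sc$test$disc_raw,
      cont_raw_train = sc$train$cont_raw, cont_raw_test = sc$test$cont_raw,
      disc_norm_train = sc$train$disc_norm, disc_norm_test = sc$test$disc_norm,
      cont_norm_train = sc$train$cont_norm, cont_norm_test = sc$test$cont_norm
    )
  })
  structure(dplyr::bind_rows(rows), observed = observed,
            class = c("disc_profile", class(tibble())))
}

#' @rdname discontinuity_profile
#' @param object A `disc_profile`.
#' @param ... Unused.
#' @export
autoplot.disc_profile <- function(object, ...) {
  obs <- attr(object, "observed", exact = TRUE)
  d <- tidyr::pivot_longer(as_tibble(object), c("disc_raw_train", "disc_raw_test"),
                           names_to = "context", values_to = "disc_raw")
  d$context <- sub("disc_raw_", "", d$context)
  d$c_rank <- match(d$c, sort(unique(d$c)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_rank, y = .data$disc_raw,
                                  colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = obs$disc_raw, colour = "black") +
    ggplot2::scale_x_continuous(breaks = seq_along(sort(unique(d$c))),
                                labels = sort(unique(d$c))) +
    ggplot2::labs(x = "regularization term C (evenly spaced)",
                  y = "raw discontinuity from predicted potencies",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Correlate data-set discontinuity with prediction error
#'
#' Pearson product-moment correlation between per-data-set SAR discontinuity
#' scores and mean test errors, with the two-tailed p-value from the exact t
#' transform with n - 2 degrees of freedom.
#'
#' @param points A data frame whose first two numeric columns are the
#'   discontinuity score and the mean test error per data set (columns named
#'   `disc` and `error` are preferred when present); n >= 3 rows with nonzero
#'   variance in both.
#' @return A one-row tibble of class `sar_correlation`: `r`, `p_two_tailed`,
#'   `n`.
#' @export
correlate_disc_vs_error <- function(points) {
  points <- as_tibble(points)
  x <- if ("disc" %in% names(points)) points$disc else points[[1]]
  y <- if ("error" %in% names(points)) points$error else points[[2]]
  if (length(x) < 3) stop_input("Need >= 3 points for a correlation p-value.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_input("Coordinates must be finite.", class = "sarsvr_invalid_value")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("Zero variance in one coordinate; correlation undefined.",
               class = "sarsvr_invalid_value")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  out <- tibble(r = unname(ct$estimate), p_two_tailed = ct$p.value, n = length(x))
  class(out) <- c("sar_correlation", class(out))
  out
}
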