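#' Pairwise potency weight for continuity scoring
#'
#' The weight `pot_i * pot_j / (1 + |pot_i - pot_j|)` upweights pairs of two
#' potent compounds with similar potency: such pairs are the carriers of SAR
#' continuity.
#'
#' @param pot_i,pot_j Potencies (pKi); finite, vectorized.
#' @return Numeric weight(s); symmetric in the two arguments.
#' @examples
#' pair_weight(7, 7) # 49
#' pair_weight(5, 9) # 9
#' @export
pair_weight <- function(pot_i, pot_j) {
  if (!is.numeric(pot_i) || !is.numeric(pot_j) ||
      any(!is.finite(pot_i)) || any(!is.finite(pot_j))) {
    stop_input("Potencies must be finite numbers.", class = "sarsvr_invalid_value")
  }
  pot_i * pot_j / (1 + abs(pot_i - pot_j))
}

#' Per-pair bookkeeping for SAR scoring
#'
#' Enumerates all compound pairs (i > j) with their similarity, continuity
#' weight, potency gap, and whether the pair qualifies for discontinuity
#' scoring (`tc >= t`).
#'
#' @param dataset A [cmpd_dataset()].
#' @param sim Optional precomputed [pairwise_matrix()].
#' @param t Similarity threshold; defaults to the data set's `tc_threshold`.
#' @return A tibble with columns `i`, `j`, `tc`, `weight`, `potency_gap`,
#'   `qualifies`.
#' @export
pair_contributions <- function(dataset, sim = NULL, t = NULL) {
  dataset <- as_dataset_input(dataset, "dataset")
  if (nrow(dataset) < 2) stop_input("Need >= 2 compounds.")
  sim <- sim %||% pairwise_matrix(dataset)
  t <- t %||% dataset_attr(dataset, "tc_threshold") %||% 0.56
  idx <- which(lower.tri(sim), arr.ind = TRUE) # row > col, i.e. i > j
  pot <- dataset$pki
  tibble(
    i = idx[, "row"],
    j = idx[, "col"],
    tc = sim[idx],
    weight = pair_weight(pot[idx[, "row"]], pot[idx[, "col"]]),
    potency_gap = abs(pot[idx[, "row"]] - pot[idx[, "col"]]),
    qualifies = sim[idx] >= t
  )
}

#' Raw SAR continuity score
#'
#' `1 - sum(w_ij * Tc(i,j)) / sum(w_ij)` over all pairs i > j, with the
#' weights of [pair_weight()]. One minus the potency-weighted mean similarity:
#' high values indicate that potency is conserved across structurally diverse
#' compounds. Lies in `[0, 1]` because Tc does.
#'
#' @param potencies Numeric pKi vector (length n >= 2).
#' @param sim_matrix n-by-n similarity matrix.
#' @return Raw continuity score in `[0, 1]`.
#' @export
raw_continuity <- function(potencies, sim_matrix) {
  check_score_inputs(potencies, sim_matrix)
  lt <- lower.tri(sim_matrix)
  w <- pair_weight(outer(potencies, rep(1, length(potencies))),
                   outer(rep(1, length(potencies)), potencies))[lt]
  1 - sum(w * sim_matrix[lt]) / sum(w)
}

#' Raw SAR discontinuity score
#'
#' Mean of `|pot(i) - pot(j)| * Tc(i,j)` over the qualifying pairs
#' (`Tc(i,j) >= t`, i > j): the average similarity-weighted potency gap among
#' structural analogs. Activity cliffs — very similar pairs with large gaps —
#' drive this score up.
#'
#' If no pair reaches the threshold the score is undefined and an error of
#' class `sarsvr_no_qualifying_pairs` is thrown; silently returning 0 would
#' be indistinguishable from a genuinely smooth data set.
#'
#' @inheritParams raw_continuity
#' @param t Similarity threshold in `(0, 1]`.
#' @return Raw discontinuity score, `>= 0`.
#' @export
raw_discontinuity <- function(potencies, sim_matrix, t) {
  check_score_inputs(potencies, sim_matrix)
  check_number(t, "t")
  if (t <= 0 || t > 1) stop_input("`t` must lie in (0, 1].")
  lt <- lower.tri(sim_matrix)
  tc <- sim_matrix[lt]
  qual <- tc >= t
  if (!any(qual)) {
    stop_input(sprintf("No compound pair reaches Tc >= %g; discontinuity is undefined.", t),
               class = "sarsvr_no_qualifying_pairs")
  }
  gap <- abs(outer(potencies, potencies, "-"))[lt]
  mean(gap[qual] * tc[qual])
}

check_score_inputs <- function(potencies, sim_matrix) {
  if (!is.numeric(potencies) || length(potencies) < 2 || any(!is.finite(potencies))) {
    stop_input("`potencies` must be a finite numeric vector of length >= 2.")
  }
  if (!is.matrix(sim_matrix) || nrow(sim_matrix) != length(potencies) ||
      ncol(sim_matrix) != length(potencies)) {
    stop_input("`sim_matrix` must be square and match `potencies` in size.")
  }
  invisible(TRUE)
}

#' Reference-panel statistics for score normalization
#'
#' Raw SARI scores are standardized against the score distribution of an
#' independent reference panel: the panel supplies the mean and sample
#' standard deviation per score type, and [normalize_score()] maps the
#' Z-score through the standard normal CDF into `[0, 1]`.
#'
#' @param panel Either a data frame with numeric columns `cont_raw` and
#'   `disc_raw` (one row per panel set) or a list of [cmpd_dataset()] objects
#'   to be scored.
#' @return An object of class `sari_panel_stats`: a list with `cont_mean`,
#'   `cont_sd`, `disc_mean`, `disc_sd`, `n_sets`.
#' @export
panel_stats <- function(panel) {
  if (is.data.frame(panel)) {
    scores <- as_tibble(panel)
    if (!all(c("cont_raw", "disc_raw") %in% names(scores))) {
      stop_input("`panel` data frame needs columns `cont_raw` and `disc_raw`.")
    }
  } else if (is.list(panel) && all(purrr::map_lgl(panel, is_cmpd_dataset))) {
    scores <- purrr::map_dfr(panel, function(ds) {
      sim <- pairwise_matrix(ds)
      tibble(cont_raw = raw_continuity(ds$pki, sim),
             disc_raw = raw_discontinuity(ds$pki, sim, dataset_attr(ds, "tc_threshold")))
    })
  } else {
    stop_input("`panel` must be a score data frame or a list of cmpd_dataset objects.")
  }
  if (nrow(scores) < 2) {
    stop_input("Need >= 2 panel sets.", class = "sarsvr_degenerate_panel")
  }
  out <- list(
    cont_mean = mean(scores$cont_raw), cont_sd = sd(scores$cont_raw),
    disc_mean = mean(scores$disc_raw), disc_sd = sd(scores$disc_raw),
    n_sets = nrow(scores)
  )
  if (out$cont_sd == 0 || out$disc_sd == 0) {
    stop_input("Panel scores are constant; Z-normalization is undefined.",
               class = "sarsvr_degenerate_panel")
  }
  structure(out, class = "sari_panel_stats")
}

#' @export
print.sari_panel_stats <- function(x, ...) {
  cat(sprintf(
    "<sari_panel_stats> %d sets | continuity %0.4f +/- %0.4f | discontinuity %0.4f +/- %0.4f\n",
    x$n_sets, x$cont_mean, x$cont_sd, x$disc_mean, x$disc_sd))
  invisible(x)
}

#' Normalize a raw score against panel statistics
#'
#' Maps `raw` to `pnorm((raw - mean) / sd)` using the panel mean/sd of the
#' requested score type; strictly increasing in `raw`, so score ordering is
#' preserved.
#'
#' @param raw Raw score value(s).
#' @param stats A [panel_stats()] object.
#' @param type `"continuity"` or `"discontinuity"`.
#' @return Normalized score(s) in `[0, 1]`.
#' @export
normalize_score <- function(raw, stats, type = c("continuity", "discontinuity")) {
  type <- match.arg(type)
  if (!inherits(stats, "sari_panel_stats")) {
    stop_input("`stats` must come from panel_stats().")
  }
  m <- if (type == "continuity") stats$cont_mean else stats$disc_mean
  s <- if (type == "continuity") stats$cont_sd else stats$disc_sd
  if (!is.finite(s) || s <= 0) {
    stop_input("Degenerate panel standard deviation.", class = "sarsvr_degenerate_panel")
  }
  pnorm((raw - m) / s)
}

#' SAR continuity/discontinuity scores of a data set
#'
#' Computes raw continuity and discontinuity plus, when panel statistics are
#' supplied, their panel-normalized counterparts. `potencies` allows scoring
#' the same structural data under substituted potency values (e.g. model
#' predictions) while keeping the similarity matrix and threshold fixed.
#'
#' @param dataset A [cmpd_dataset()].
#' @param stats Optional [panel_stats()]; without it the normalized columns
#'   are `NA`.
#' @param potencies Optional replacement potency vector aligned to the data
#'   set rows; defaults to the observed `pki`.
#' @param t Similarity threshold override.
#' @param sim Optional precomputed similarity matrix.
#' @return A one-row tibble of class `sari_scores` with columns `target_id`,
#'   `cont_raw`, `disc_raw`, `cont_norm`, `disc_norm`, `threshold_t`,
#'   `n_pairs`, `n_qualifying_pairs`.
#' @export
score_dataset <- function(dataset, stats = NULL, potencies = NULL, t = NULL,
                          sim = NULL) {
  dataset <- as_dataset_input(dataset, "dataset")
  if (nrow(dataset) < 2) stop_input("Need >= 2 compounds to score.")
  sim <- sim %||% pairwise_matrix(dataset)
  t <- t %||% dataset_attr(dataset, "tc_threshold") %||% 0.56
  pot <- potencies %||% dataset$pki
  if (length(pot) != nrow(dataset)) {
    stop_input("`potencies` must align with the data set rows.")
  }
  n <- nrow(dataset)
  cont <- raw_continuity(pot, sim)
  disc <- raw_discontinuity(pot, sim, t)
  n_qual <- sum(sim[lower.tri(sim)] >= t)
  out <- tibble(
    target_id = if (is_cmpd_dataset(dataset)) dataset_attr(dataset, "target_id") else NA_character_,
    cont_raw = cont,
    disc_raw = disc,
    cont_norm = if (is.null(stats)) NA_real_ else normalize_score(cont, stats, "continuity"),
    disc_norm = if (is.null(stats)) NA_real_ else normalize_score(disc, stats, "discontinuity"),
    threshold_t = t,
    n_pairs = n * (n - 1) / 2,
    n_qualifying_pairs = n_qual
  )
  class(out) <- c("sari_scores", class(out))
  out
}
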