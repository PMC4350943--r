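#' 2D embedding of a similarity matrix by metric MDS
#'
#' Projects compounds into the plane by minimizing the metric stress
#' `sum_(i<j) (d_ij(X) - delta_ij)^2` on the dissimilarities
#' `delta = 1 - Tc`, via SMACOF stress majorization (Guttman transform).
#' The start configuration is classical (Torgerson) scaling — which both
#' shortens the majorization path and avoids the poorer local optima a random
#' start can settle into — with a seeded random start as fallback when the
#' classical solution is degenerate. Stress decreases monotonically;
#' iteration stops when the relative stress change falls below `tol`.
#'
#' @param sim_matrix A square symmetric similarity matrix with unit diagonal.
#' @param seed Integer seed for the fallback random initial configuration.
#' @param max_iter Iteration cap; exceeding it without reaching `tol` is an
#'   error (of class `sarsvr_mds_convergence`, carrying the stress trace).
#' @param tol Relative stress-change convergence threshold.
#' @return A tibble of class `mds_embedding` with columns `compound_id` (when
#'   the matrix has dimnames), `x`, `y`; attributes `stress` (final raw
#'   stress), `n_iter`, `converged`.
#' @export
embed_mds <- function(sim_matrix, seed = 1L, max_iter = 10000L, tol = 1e-9) {
  if (!is.matrix(sim_matrix) || nrow(sim_matrix) != ncol(sim_matrix)) {
    stop_input("`sim_matrix` must be square.")
  }
  n <- nrow(sim_matrix)
  ids <- rownames(sim_matrix)
  if (n == 1) {
    out <- tibble(x = 0, y = 0)
    if (!is.null(ids)) out <- dplyr::mutate(out, compound_id = ids, .before = 1)
    return(structure(out, stress = 0, n_iter = 0L, converged = TRUE,
                     class = c("mds_embedding", class(out))))
  }
  delta <- 1 - sim_matrix
  diag(delta) <- 0
  x <- tryCatch(suppressWarnings(stats::cmdscale(delta, k = 2)),
                error = function(e) NULL)
  if (is.null(x) || !is.matrix(x) || nrow(x) != n || any(!is.finite(x))) {
    x <- withr::with_seed(seed, matrix(runif(2 * n, -0.5, 0.5), n, 2))
  } else if (ncol(x) < 2) {
    x <- cbind(x, matrix(0, n, 2 - ncol(x)))
  }
  stress_of <- function(d) sum((d[lower.tri(d)] - delta[lower.tri(delta)])^2)
  d <- as.matrix(stats::dist(x))
  s_prev <- stress_of(d)
  trace <- s_prev
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # Guttman transform: X <- (1/n) B(X) X, b_ij = -delta_ij / d_ij (0 if d = 0)
    b <- ifelse(d > 0, -delta / d, 0)
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n
    d <- as.matrix(stats::dist(x))
    s <- stress_of(d)
    trace <- c(trace, s)
    if (s_prev - s <= tol * max(s_prev, .Machine$double.eps)) {
      converged <- TRUE
      s_prev <- s
      break
    }
    s_prev <- s
  }
  if (!converged) {
    stop_input(sprintf("MDS did not converge in %d iterations (stress %.3e).",
                       max_iter, s_prev),
               class = "sarsvr_mds_convergence",
               stress_trace = tail(trace, 20))
  }
  coords <- sweep(x, 2, colMeans(x))
  out <- tibble(x = coords[, 1], y = coords[, 2])
  if (!is.null(ids)) out <- dplyr::mutate(out, compound_id = ids, .before = 1)
  structure(out, stress = s_prev, n_iter = iter, converged = TRUE,
            class = c("mds_embedding", class(out)))
}

#' Interpolate a potency surface over an embedding
#'
#' Builds a regular `resolution x resolution` grid over the embedding's
#' bounding box and interpolates potency by inverse-distance weighting
#' (Shepard interpolation, power 2, all points, no cutoff). The scheme is
#' exact at compound locations, linear in the potency vector for fixed
#' geometry, and bounded by the observed potency range — peaks in the surface
#' are potent compounds, never interpolation overshoot.
#'
#' @param embedding An [embed_mds()] result (or data frame with `x`, `y`).
#' @param potencies Potency vector aligned with the embedding rows.
#' @param resolution Grid cells per axis, `>= 2`.
#' @return An object of class `surface_grid`: list with grid axes `x`, `y`,
#'   the value matrix `z` (`z[ix, iy]` at `x[ix]`, `y[iy]`), `potency_range`,
#'   and `resolution`.
#' @export
interpolate_surface <- function(embedding, potencies, resolution = 100L) {
  emb <- as_tibble(embedding)
  if (!all(c("x", "y") %in% names(emb))) {
    stop_input("`embedding` needs `x` and `y` columns.")
  }
  if (nrow(emb) != length(potencies) || any(!is.finite(potencies))) {
    stop_input("`potencies` must be finite and aligned with the embedding.")
  }
  check_number(resolution, "resolution", positive = TRUE)
  if (resolution < 2) stop_input("`resolution` must be >= 2.")
  r <- as.integer(resolution)
  axis_seq <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo < .Machine$double.eps) { lo <- lo - 0.5; hi <- hi + 0.5 }
    seq(lo, hi, length.out = r)
  }
  xs <- axis_seq(emb$x)
  ys <- axis_seq(emb$y)
  gx <- rep(xs, times = r)
  gy <- rep(ys, each = r)
  d2 <- outer(gx, emb$x, "-")^2 + outer(gy, emb$y, "-")^2
  exact <- d2 < 1e-18
  w <- 1 / pmax(d2, 1e-300)
  vals <- as.numeric(w %*% potencies) / rowSums(w)
  hit <- which(rowSums(exact) > 0)
  for (cell in hit) {
    vals[cell] <- mean(potencies[exact[cell, ]])
  }
  structure(list(
    x = xs, y = ys,
    z = matrix(vals, nrow = r, ncol = r),
    potency_range = range(potencies),
    resolution = r
  ), class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %dx%d cells | values in [%.3f, %.3f] pKi\n",
              x$resolution, x$resolution, min(x$z), max(x$z)))
  invisible(x)
}

#' @rdname interpolate_surface
#' @param object A `surface_grid`.
#' @param ... Unused.
#' @export
autoplot.surface_grid <- function(object, ...) {
  d <- tidyr::expand_grid(ix = seq_along(object$x), iy = seq_along(object$y))
  d$x <- object$x[d$ix]
  d$y <- object$y[d$iy]
  d$potency <- object$z[cbind(d$ix, d$iy)]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$potency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "turbo", name = "pKi") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

# 8-neighborhood local maxima above a threshold; returns an (i, j) index matrix.
local_maxima <- function(z, threshold) {
  r <- nrow(z); s <- ncol(z)
  zp <- matrix(-Inf, r + 2, s + 2)
  zp[2:(r + 1), 2:(s + 1)] <- z
  ok <- z > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (z >= zp[2:(r + 1) + di, 2:(s + 1) + dj])
  }
  which(ok, arr.ind = TRUE)
}

#' Quantify the smoothing of a predicted landscape
#'
#' Compares two potency surfaces built on the identical embedding and grid
#' (observed vs model-predicted potencies) and reports: `peak_height_loss`,
#' the drop of the global surface maximum (pKi); `surface_range_ratio`, the
#' predicted surface's dynamic range relative to the observed one;
#' `disc_delta`, observed minus predicted raw discontinuity (when supplied);
#' and `n_lost_peaks`, observed local maxima above
#' `mean(observed surface) + peak_offset` that the predicted surface no
#' longer supports: a peak counts as retained only when the predicted surface
#' within `match_radius` grid cells still reaches within `peak_drop_tol` of
#' the observed peak height — a residual bump far below the original
#' elevation is a lost activity cliff, not a counterpart. Identical surfaces
#' give a loss-free report (zero losses, range ratio 1).
#'
#' @param observed,predicted [interpolate_surface()] grids on identical axes.
#' @param observed_disc,predicted_disc Optional raw discontinuity scores.
#' @param peak_offset Peak threshold above the observed surface mean, pKi.
#' @param match_radius Chebyshev matching radius in grid cells.
#' @param peak_drop_tol Maximum tolerated height drop (pKi) for a peak to
#'   count as retained.
#' @return A one-row tibble of class `smoothing_report`: `peak_height_loss`,
#'   `surface_range_ratio`, `disc_delta`, `n_lost_peaks`, `n_observed_peaks`.
#' @export
compare_surfaces <- function(observed, predicted, observed_disc = NULL,
                             predicted_disc = NULL, peak_offset = 1,
                             match_radius = 2L, peak_drop_tol = 1) {
  if (!inherits(observed, "surface_grid") || !inherits(predicted, "surface_grid")) {
    stop_input("Both surfaces must come from interpolate_surface().")
  }
  if (!isTRUE(all.equal(observed$x, predicted$x, tolerance = 1e-12)) ||
      !isTRUE(all.equal(observed$y, predicted$y, tolerance = 1e-12))) {
    stop_input("Surfaces are on different grids; build both on one embedding.",
               class = "sarsvr_grid_mismatch")
  }
  rng_obs <- diff(range(observed$z))
  rng_pred <- diff(range(predicted$z))
  threshold <- mean(observed$z) + peak_offset
  peaks_obs <- local_maxima(observed$z, threshold)
  n_lost <- 0L
  if (nrow(peaks_obs) > 0) {
    r <- nrow(observed$z)
    for (k in seq_len(nrow(peaks_obs))) {
      i <- peaks_obs[k, 1]; j <- peaks_obs[k, 2]
      win_i <- max(1, i - match_radius):min(r, i + match_radius)
      win_j <- max(1, j - match_radius):min(ncol(observed$z), j + match_radius)
      retained <- max(predicted$z[win_i, win_j]) >=
        observed$z[i, j] - peak_drop_tol
      if (!retained) n_lost <- n_lost + 1L
    }
  }
  out <- tibble(
    peak_height_loss = max(observed$z) - max(predicted$z),
    surface_range_ratio = if (rng_obs == 0) {
      if (rng_pred == 0) 1 else Inf
    } else rng_pred / rng_obs,
    disc_delta = if (is.null(observed_disc) || is.null(predicted_disc)) {
      NA_real_
    } else observed_disc - predicted_disc,
    n_lost_peaks = n_lost,
    n_observed_peaks = nrow(peaks_obs)
  )
  class(out) <- c("smoothing_report", class(out))
  out
}
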