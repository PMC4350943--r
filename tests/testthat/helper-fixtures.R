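# Shared fixtures and independent brute-force oracles.

# Standard cliff fixture: clustered analogs, 10% cliff compounds.
fixture_dataset <- function(n = 60, k = 6, cliff_fraction = 0.1, seed = 7, ...) {
  generate_dataset(synth_config(n, k, cliff_fraction = cliff_fraction,
                                seed = seed, ...))
}

# Small mixed panel for normalization in unit tests (the full-size panel is
# exercised in the acceptance suite).
fixture_panel <- function(n_sets = 20, seed = 5) {
  generate_reference_panel(panel_config(
    n_sets = n_sets, size_range = c(30L, 40L),
    cliff_fraction_range = c(0, 0.2), seed = seed
  ))
}

random_fingerprint <- function(universe = 256, n_bits = 30) {
  sort(sample.int(universe, n_bits))
}

# O(n^2) double-loop score oracles, deliberately naive.
oracle_continuity <- function(pot, sim) {
  num <- 0; den <- 0
  n <- length(pot)
  for (i in 2:n) for (j in 1:(i - 1)) {
    w <- pot[i] * pot[j] / (1 + abs(pot[i] - pot[j]))
    num <- num + w * sim[i, j]
    den <- den + w
  }
  1 - num / den
}

oracle_discontinuity <- function(pot, sim, t) {
  total <- 0; count <- 0
  n <- length(pot)
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (sim[i, j] >= t) {
      total <- total + abs(pot[i] - pot[j]) * sim[i, j]
      count <- count + 1
    }
  }
  if (count == 0) NA_real_ else total / count
}

oracle_eps_error <- function(y, f, eps) {
  total <- 0
  for (i in seq_along(y)) {
    d <- abs(y[i] - f[i]) - eps
    if (d > 0) total <- total + d
  }
  total
}
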