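#' Configuration for a synthetic fingerprint/potency data set
#'
#' The generator emulates the statistical structure that SAR analysis of
#' screening data sets assumes: clusters of structural analogs (compounds in
#' a cluster share a common core of fingerprint bits and differ in a few
#' private bits, so within-cluster Tanimoto similarity is high and
#' between-cluster similarity low), smooth potency variation within clusters
#' (a linear gradient across members plus Gaussian noise), and a controllable
#' fraction of activity-cliff compounds: cluster members whose potency is
#' boosted by `cliff_magnitude`, creating highly similar pairs with large
#' potency gaps.
#'
#' With the defaults (40 core bits, 8 private bits) two cluster siblings
#' share about 40 of ~56 on bits, i.e. Tanimoto ~0.7, comfortably above the
#' ECFP4-style qualifying threshold of 0.56, while unrelated compounds sit
#' near zero.
#'
#' @param n_compounds Number of compounds.
#' @param n_clusters Number of analog clusters (members assigned round-robin).
#' @param universe Fingerprint length in bits.
#' @param core_bits Bits shared by every member of a cluster.
#' @param private_bits Extra per-compound bits.
#' @param potency_range Length-2 numeric, baseline pKi range (low < high).
#' @param within_cluster_spread Standard deviation (pKi) of the smooth
#'   within-cluster variation; also sets the gradient half-span.
#' @param cliff_fraction Fraction of compounds promoted to cliff peaks.
#' @param cliff_magnitude pKi boost for cliff compounds; boosted values are
#'   clamped to `potency_range[2] + 2`.
#' @param seed Integer seed; the same config yields a bit-identical data set.
#' @param target_id,scheme,tc_threshold Metadata passed to [cmpd_dataset()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_compounds, n_clusters, universe = 1024L,
                         core_bits = 40L, private_bits = 8L,
                         potency_range = c(5, 10), within_cluster_spread = 0.3,
                         cliff_fraction = 0, cliff_magnitude = 3, seed = 1L,
                         target_id = NULL, scheme = "ECFP4", tc_threshold = NULL) {
  check_number(n_compounds, "n_compounds", positive = TRUE)
  check_number(n_clusters, "n_clusters", positive = TRUE)
  check_number(universe, "universe", positive = TRUE)
  check_number(core_bits, "core_bits", positive = TRUE)
  check_number(private_bits, "private_bits")
  check_number(within_cluster_spread, "within_cluster_spread")
  check_number(cliff_fraction, "cliff_fraction")
  check_number(cliff_magnitude, "cliff_magnitude")
  check_number(seed, "seed")
  if (core_bits + private_bits > universe) {
    stop_input("`core_bits + private_bits` must not exceed `universe`.",
               class = "sarsvr_config_error")
  }
  if (cliff_fraction < 0 || cliff_fraction > 1) {
    stop_input("`cliff_fraction` must lie in [0, 1].", class = "sarsvr_config_error")
  }
  if (length(potency_range) != 2 || potency_range[1] >= potency_range[2]) {
    stop_input("`potency_range` must be (low, high) with low < high.",
               class = "sarsvr_config_error")
  }
  if (within_cluster_spread < 0) {
    stop_input("`within_cluster_spread` must be >= 0.", class = "sarsvr_config_error")
  }
  structure(list(
    n_compounds = as.integer(n_compounds), n_clusters = as.integer(n_clusters),
    universe = as.integer(universe), core_bits = as.integer(core_bits),
    private_bits = as.integer(private_bits), potency_range = as.double(potency_range),
    within_cluster_spread = as.double(within_cluster_spread),
    cliff_fraction = as.double(cliff_fraction),
    cliff_magnitude = as.double(cliff_magnitude), seed = as.integer(seed),
    target_id = target_id %||% sprintf("synthetic_seed%d", as.integer(seed)),
    scheme = scheme, tc_threshold = tc_threshold
  ), class = "synth_config")
}

#' Generate a synthetic compound data set
#'
#' Sampling consumes a single seeded random stream in a fixed order (cluster
#' cores, per-compound private bits, cluster baseline potencies, within-cluster
#' noise, cliff member selection), so the same configuration reproduces the
#' same data set bit for bit.
#'
#' @param config A [synth_config()].
#' @return A [cmpd_dataset()] with `n_compounds` rows.
#' @examples
#' ds <- generate_dataset(synth_config(60, 6, cliff_fraction = 0.1, seed = 7))
#' dataset_summary(ds)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_input("`config` must be a synth_config.")
  }
  n <- config$n_compounds
  k <- config$n_clusters
  lo <- config$potency_range[1]
  hi <- config$potency_range[2]
  cluster <- rep(seq_len(k), length.out = n)
  withr::with_seed(config$seed, {
    cores <- lapply(seq_len(k), function(i) sample.int(config$universe, config$core_bits))
    fingerprints <- lapply(seq_len(n), function(i) {
      core <- cores[[cluster[i]]]
      pool <- setdiff(seq_len(config$universe), core)
      sort(c(core, sample(pool, config$private_bits)))
    })
    baseline <- runif(k, lo, hi)
    spread <- config$within_cluster_spread
    member_rank <- stats::ave(seq_len(n), cluster, FUN = seq_along)
    cluster_size <- tabulate(cluster, nbins = k)[cluster]
    gradient <- ifelse(cluster_size > 1,
                       spread * (2 * (member_rank - 1) / pmax(cluster_size - 1, 1) - 1),
                       0)
    pki <- baseline[cluster] + gradient + rnorm(n, 0, spread)
    pki <- pmin(pmax(pki, lo), hi)
    n_cliff <- ceiling(config$cliff_fraction * n)
    is_cliff <- rep(FALSE, n)
    if (n_cliff > 0) {
      eligible <- which(cluster_size >= 2)
      chosen <- if (length(eligible) <= n_cliff) eligible else sample(eligible, n_cliff)
      pki[chosen] <- pmin(pki[chosen] + config$cliff_magnitude, hi + 2)
      is_cliff[chosen] <- TRUE
    }
  })
  records <- tibble(
    compound_id = sprintf("cpd_%04d", seq_len(n)),
    pki = pki,
    fingerprint = fingerprints,
    cluster = cluster,
    is_cliff = is_cliff
  )
  ds <- cmpd_dataset(records[, c("compound_id", "pki", "fingerprint")],
                     target_id = config$target_id, scheme = config$scheme,
                     universe = config$universe, tc_threshold = config$tc_threshold)
  ds$cluster <- cluster
  ds$is_cliff <- is_cliff
  ds
}

#' Configuration for a multi-set reference panel
#'
#' The panel supplies the score distribution against which raw SARI scores of
#' an individual data set are standardized. Sets span a range of sizes and
#' cliff fractions so that the panel's raw-score distribution is non-degenerate.
#'
#' @param n_sets Number of panel data sets (>= 2).
#' @param size_range Length-2 integer range of per-set compound counts.
#' @param cliff_fraction_range Range from which each set's cliff fraction is
#'   drawn uniformly.
#' @param seed Integer seed.
#' @param universe,scheme Passed through to each set's [synth_config()].
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_sets = 120L, size_range = c(100L, 140L),
                         cliff_fraction_range = c(0, 0.2), seed = 1L,
                         universe = 1024L, scheme = "ECFP4") {
  check_number(n_sets, "n_sets", positive = TRUE)
  if (n_sets < 2) stop_input("`n_sets` must be >= 2.", class = "sarsvr_config_error")
  if (length(size_range) != 2 || size_range[1] > size_range[2] || size_range[1] < 2) {
    stop_input("`size_range` must be (min, max) with 2 <= min <= max.",
               class = "sarsvr_config_error")
  }
  if (length(cliff_fraction_range) != 2 ||
      any(cliff_fraction_range < 0) || any(cliff_fraction_range > 1) ||
      cliff_fraction_range[1] > cliff_fraction_range[2]) {
    stop_input("`cliff_fraction_range` must be an increasing range within [0, 1].",
               class = "sarsvr_config_error")
  }
  check_number(seed, "seed")
  structure(list(
    n_sets = as.integer(n_sets), size_range = as.integer(size_range),
    cliff_fraction_range = as.double(cliff_fraction_range),
    seed = as.integer(seed), universe = as.integer(universe), scheme = scheme
  ), class = "panel_config")
}

#' Generate a reference panel of synthetic data sets
#'
#' @param config A [panel_config()].
#' @return A list of [cmpd_dataset()] objects of length `n_sets`.
#' @export
generate_reference_panel <- function(config) {
  if (!inherits(config, "panel_config")) {
    stop_input("`config` must be a panel_config.")
  }
  draws <- withr::with_seed(config$seed, {
    tibble(
      n = sample(seq(config$size_range[1], config$size_range[2]),
                 config$n_sets, replace = TRUE),
      cliff_fraction = runif(config$n_sets, config$cliff_fraction_range[1],
                             config$cliff_fraction_range[2])
    )
  })
  purrr::map(seq_len(config$n_sets), function(i) {
    generate_dataset(synth_config(
      n_compounds = draws$n[i],
      n_clusters = max(2L, round(draws$n[i] / 12)),
      universe = config$universe,
      cliff_fraction = draws$cliff_fraction[i],
      seed = derive_seed(config$seed, "panel_set", i),
      target_id = sprintf("panel_%03d", i),
      scheme = config$scheme
    ))
  })
}
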