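#' Build a compound data set
#'
#' A compound data set is a tibble with one row per compound, carrying the
#' compound identifier, its potency as a pKi value, and its binary fingerprint
#' stored as a sorted integer vector of on-bit indices (a list-column).
#' Data-set-level metadata — target id, fingerprint scheme, fingerprint
#' universe size, and the Tanimoto similarity threshold used for
#' discontinuity scoring — travel as attributes.
#'
#' The similarity threshold defaults by scheme: 0.85 for MACCS keys and 0.56
#' for ECFP4, the values commonly used to declare two fingerprints
#' "structurally analogous" under each representation. Any other scheme tag
#' requires an explicit `tc_threshold`.
#'
#' @param records A data frame with columns `compound_id` (character, unique,
#'   non-empty), `pki` (finite numeric), and `fingerprint` (list of integer
#'   vectors of on-bit indices, each non-empty). An optional `smiles` column
#'   is carried through.
#' @param target_id Identifier for the target/assay the potencies refer to.
#' @param scheme Fingerprint scheme tag, e.g. `"MACCS"` or `"ECFP4"`.
#' @param universe Fingerprint length (number of addressable bits). All on-bit
#'   indices must lie in `[1, universe]`.
#' @param tc_threshold Tanimoto threshold t for qualifying pairs; defaults by
#'   scheme (0.85 MACCS, 0.56 ECFP4).
#'
#' @return A tibble of class `cmpd_dataset` with attributes `target_id`,
#'   `scheme`, `universe`, `tc_threshold`.
#' @examples
#' ds <- cmpd_dataset(
#'   tibble::tibble(
#'     compound_id = c("a", "b"),
#'     pki = c(6.5, 8.1),
#'     fingerprint = list(c(1L, 5L, 9L), c(1L, 5L, 12L))
#'   ),
#'   target_id = "demo", scheme = "ECFP4", universe = 64
#' )
#' dataset_summary(ds)
#' @export
cmpd_dataset <- function(records, target_id = "unknown", scheme = "ECFP4",
                         universe = 1024L, tc_threshold = NULL) {
  records <- as_tibble(records)
  required <- c("compound_id", "pki", "fingerprint")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_input(paste0("`records` is missing column(s): ",
                      paste(missing_cols, collapse = ", "), "."))
  }
  check_number(universe, "universe", positive = TRUE)
  universe <- as.integer(universe)
  if (is.null(tc_threshold)) {
    tc_threshold <- scheme_threshold(scheme)
  }
  check_number(tc_threshold, "tc_threshold")
  if (tc_threshold <= 0 || tc_threshold > 1) {
    stop_input("`tc_threshold` must lie in (0, 1].")
  }
  out <- records[, c(required, intersect("smiles", names(records)))]
  out$compound_id <- as.character(out$compound_id)
  out$pki <- as.double(out$pki)
  out$fingerprint <- lapply(out$fingerprint, function(fp) sort(unique(as.integer(fp))))
  validate_dataset_records(out, universe)
  structure(out,
    target_id = as.character(target_id), scheme = as.character(scheme),
    universe = universe, tc_threshold = as.double(tc_threshold),
    class = c("cmpd_dataset", class(tibble())))
}

scheme_threshold <- function(scheme) {
  switch(toupper(scheme),
    MACCS = 0.85,
    ECFP4 = 0.56,
    stop_input(sprintf(
      "No default similarity threshold for scheme '%s'; supply `tc_threshold`.",
      scheme))
  )
}

validate_dataset_records <- function(records, universe) {
  if (any(!nzchar(records$compound_id) | is.na(records$compound_id))) {
    stop_input("All `compound_id` values must be non-empty.")
  }
  dup <- records$compound_id[duplicated(records$compound_id)]
  if (length(dup) > 0) {
    stop_input(paste0("Duplicate compound_id: ", paste(unique(dup), collapse = ", "), "."),
               class = "sarsvr_duplicate_id")
  }
  if (any(!is.finite(records$pki))) {
    stop_input("All `pki` values must be finite.")
  }
  n_bits <- lengths(records$fingerprint)
  if (any(n_bits == 0)) {
    stop_input("Empty fingerprints are not allowed (Tanimoto would be undefined).",
               class = "sarsvr_empty_fingerprint")
  }
  rng <- range(unlist(records$fingerprint))
  if (rng[1] < 1 || rng[2] > universe) {
    stop_input(sprintf("Fingerprint bit indices must lie in [1, %d].", universe))
  }
  invisible(records)
}

dataset_attr <- function(dataset, what) attr(dataset, what, exact = TRUE)

is_cmpd_dataset <- function(x) inherits(x, "cmpd_dataset")

as_dataset_input <- function(data, arg = "data") {
  if (is_cmpd_dataset(data)) return(data)
  if (is.data.frame(data) && all(c("pki", "fingerprint") %in% names(data))) {
    return(data)
  }
  stop_input(sprintf(
    "`%s` must be a cmpd_dataset or a data frame with `pki` and `fingerprint` columns.",
    arg))
}

#' @export
print.cmpd_dataset <- function(x, ...) {
  cat(sprintf("<cmpd_dataset> target %s | scheme %s (t = %.2f) | universe %d bits\n",
              dataset_attr(x, "target_id"), dataset_attr(x, "scheme"),
              dataset_attr(x, "tc_threshold"), dataset_attr(x, "universe")))
  NextMethod()
}

#' Summary statistics of a compound data set
#'
#' Computes the descriptive statistics conventionally reported for a potency
#' data set: compound count and minimum, maximum and mean pKi.
#'
#' @param dataset A [cmpd_dataset()] (or any data frame with a `pki` column).
#' @return A one-row tibble with columns `target_id`, `n`, `min_pki`,
#'   `max_pki`, `mean_pki`.
#' @export
dataset_summary <- function(dataset) {
  dataset <- as_dataset_input(dataset, "dataset")
  if (nrow(dataset) == 0) {
    stop_input("`dataset` is empty.")
  }
  tibble(
    target_id = if (is_cmpd_dataset(dataset)) dataset_attr(dataset, "target_id") else NA_character_,
    n = nrow(dataset),
    min_pki = min(dataset$pki),
    max_pki = max(dataset$pki),
    mean_pki = mean(dataset$pki)
  )
}
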