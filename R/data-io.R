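#' Convert an equilibrium constant to a pKi value
#'
#' @param ki Equilibrium constant(s) K_i in molar units; must be strictly
#'   positive.
#' @return `-log10(ki)`, the potency on the pKi scale (dimensionless; higher
#'   means more potent).
#' @examples
#' pki_from_ki(1e-8) # 8
#' @export
pki_from_ki <- function(ki) {
  if (!is.numeric(ki) || length(ki) == 0) {
    stop_input("`ki` must be numeric.")
  }
  if (any(!is.finite(ki)) || any(ki <= 0)) {
    stop_input("All `ki` values must be finite and > 0.", class = "sarsvr_invalid_value")
  }
  -log10(ki)
}

#' Curate raw K_i measurements into per-compound pKi values
#'
#' Applies the standard curation rules for binding-constant data: measurements
#' at or above `max_ki` (weak or assay-limited activity) are dropped; when a
#' compound retains several measurements they are combined only if they agree
#' to within one order of magnitude (`max(Ki)/min(Ki) <= 10`), otherwise the
#' compound is discarded as irreproducible; finally compounds whose combined
#' potency falls below `pki_floor` are removed.
#'
#' Averaging happens on the pKi scale by default (equivalently, the geometric
#' mean of the K_i values) — the scale on which all downstream arithmetic
#' operates; set `average = "ki"` for the arithmetic mean on the K_i scale.
#'
#' @param records A data frame with columns `compound_id` and `ki` (molar);
#'   an optional `assay_tag` column is ignored.
#' @param max_ki Exclusive upper bound on usable K_i, molar. Default `1e-4`
#'   (100 uM).
#' @param pki_floor Minimum retained pKi. Default 5 (i.e. K_i < 10 uM); set
#'   to `-Inf` to keep everything above `max_ki`.
#' @param average `"pki"` (geometric mean of K_i; default) or `"ki"`
#'   (arithmetic mean of K_i, then converted).
#' @return A tibble with columns `compound_id`, `pki`, `n_measurements`,
#'   containing only retained compounds. May be empty.
#' @examples
#' curate_ki_records(tibble::tibble(
#'   compound_id = c("A", "A", "B", "B"),
#'   ki = c(1e-8, 2e-8, 1e-8, 5e-7)
#' ))
#' # A kept (combined pKi ~ 7.85), B discarded (50-fold spread)
#' @export
curate_ki_records <- function(records, max_ki = 1e-4, pki_floor = 5,
                              average = c("pki", "ki")) {
  average <- match.arg(average)
  records <- as_tibble(records)
  if (nrow(records) == 0 || !all(c("compound_id", "ki") %in% names(records))) {
    stop_input("`records` must be non-empty with columns `compound_id` and `ki`.")
  }
  if (any(!is.finite(records$ki)) || any(records$ki <= 0)) {
    stop_input("All `ki` values must be finite and > 0.", class = "sarsvr_invalid_value")
  }
  check_number(max_ki, "max_ki", positive = TRUE)

  records |>
    dplyr::filter(.data$ki < max_ki) |>
    dplyr::summarise(
      n_measurements = dplyr::n(),
      spread_ok = max(.data$ki) / min(.data$ki) <= 10,
      pki = if (average == "pki") mean(-log10(.data$ki)) else -log10(mean(.data$ki)),
      .by = "compound_id"
    ) |>
    dplyr::filter(.data$spread_ok, .data$pki >= pki_floor) |>
    dplyr::select("compound_id", "pki", "n_measurements")
}

#' Read / write compound data sets as TSV
#'
#' The on-disk dialect is UTF-8 tab-separated text: `#key=value` metadata
#' lines (`target_id`, `scheme`, `universe`, `tc_threshold`), then a header
#' row `compound_id  pki  fingerprint` (optionally `smiles`), then one row
#' per compound with the fingerprint as semicolon-separated ascending on-bit
#' indices. Potencies are serialized at full double precision, so
#' write-then-read reproduces a data set exactly and re-writing a read file
#' is byte-identical.
#'
#' @param path File path.
#' @return `read_dataset()` returns a [cmpd_dataset()]; `write_dataset()`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("File not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) {
      stop_input(sprintf("Line %d: malformed metadata line (expected #key=value).", i),
                 class = "sarsvr_parse_error")
    }
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    i <- i + 1L
  }
  if (i > length(lines)) {
    stop_input("File has no header row.", class = "sarsvr_parse_error")
  }
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:3], c("compound_id", "pki", "fingerprint"))) {
    stop_input(sprintf("Line %d: unexpected header (need compound_id, pki, fingerprint).", i),
               class = "sarsvr_parse_error")
  }
  has_smiles <- length(header) >= 4 && header[4] == "smiles"
  body_start <- i + 1L
  body <- lines[seq_len(length(lines) - body_start + 1L) + body_start - 1L]
  body <- body[nzchar(body)]
  rows <- purrr::imap(body, function(line, k) {
    lineno <- body_start + k - 1L
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_input(sprintf("Line %d: expected at least 3 tab-separated fields.", lineno),
                 class = "sarsvr_parse_error")
    }
    pki <- suppressWarnings(as.double(fields[2]))
    if (is.na(pki)) {
      stop_input(sprintf("Line %d: pki '%s' is not a number.", lineno, fields[2]),
                 class = "sarsvr_parse_error")
    }
    bits <- suppressWarnings(as.integer(strsplit(fields[3], ";", fixed = TRUE)[[1]]))
    if (length(bits) == 0 || any(is.na(bits))) {
      stop_input(sprintf("Line %d: malformed fingerprint field '%s'.", lineno, fields[3]),
                 class = "sarsvr_parse_error")
    }
    list(compound_id = fields[1], pki = pki, fingerprint = bits,
         smiles = if (has_smiles && length(fields) >= 4) fields[4] else NA_character_)
  })
  records <- tibble(
    compound_id = purrr::map_chr(rows, "compound_id"),
    pki = purrr::map_dbl(rows, "pki"),
    fingerprint = purrr::map(rows, "fingerprint")
  )
  if (has_smiles) records$smiles <- purrr::map_chr(rows, "smiles")
  cmpd_dataset(records,
    target_id = meta$target_id %||% "unknown",
    scheme = meta$scheme %||% "ECFP4",
    universe = as.integer(meta$universe %||% "1024"),
    tc_threshold = if (!is.null(meta$tc_threshold)) as.double(meta$tc_threshold) else NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_dataset
#' @param dataset A [cmpd_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  if (!is_cmpd_dataset(dataset)) {
    stop_input("`dataset` must be a cmpd_dataset.")
  }
  has_smiles <- "smiles" %in% names(dataset)
  meta <- c(
    sprintf("#target_id=%s", dataset_attr(dataset, "target_id")),
    sprintf("#scheme=%s", dataset_attr(dataset, "scheme")),
    sprintf("#universe=%d", dataset_attr(dataset, "universe")),
    sprintf("#tc_threshold=%s", fmt_num(dataset_attr(dataset, "tc_threshold")))
  )
  header <- paste(c("compound_id", "pki", "fingerprint", if (has_smiles) "smiles"),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(dataset)), function(i) {
    fields <- c(dataset$compound_id[i], fmt_num(dataset$pki[i]),
                paste(dataset$fingerprint[[i]], collapse = ";"),
                if (has_smiles) dataset$smiles[i])
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, body), path, useBytes = TRUE)
  invisible(path)
}
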