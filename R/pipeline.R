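#' Study configuration
#'
#' Bundles everything one end-to-end run needs: the data set sources
#' (synthetic configurations and/or TSV paths), the reference-panel source,
#' the SVR sweep settings, landscape settings, output directory and a global
#' seed. The global seed fans out deterministically to per-stage, per-dataset
#' seeds, so the whole study — and any stage re-run in isolation — is
#' reproducible bit for bit.
#'
#' @param datasets A list whose elements are [synth_config()] objects or
#'   paths to data set TSV files; at least one.
#' @param panel A [panel_config()], or a directory containing panel TSVs.
#' @param svr An [svr_config()].
#' @param landscape_resolution Grid resolution for landscape surfaces.
#' @param out_dir Output directory for the report bundle.
#' @param seed Global integer seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(datasets, panel, svr = svr_config(),
                         landscape_resolution = 60L, out_dir, seed = 1L) {
  if (missing(datasets) || !is.list(datasets) || length(datasets) == 0) {
    stop_input("`datasets` must be a non-empty list of synth_config objects or paths.",
               class = "sarsvr_config_error")
  }
  ok <- purrr::map_lgl(datasets, function(d) {
    inherits(d, "synth_config") || (is.character(d) && length(d) == 1)
  })
  if (!all(ok)) {
    stop_input("Each dataset source must be a synth_config or a file path.",
               class = "sarsvr_config_error")
  }
  if (missing(panel) || is.null(panel)) {
    stop_input("A panel source is required (panel_config or directory path).",
               class = "sarsvr_config_error")
  }
  if (!inherits(panel, "panel_config") && !(is.character(panel) && length(panel) == 1)) {
    stop_input("`panel` must be a panel_config or a directory path.",
               class = "sarsvr_config_error")
  }
  if (!inherits(svr, "svr_config")) {
    stop_input("`svr` must be an svr_config.", class = "sarsvr_config_error")
  }
  check_number(landscape_resolution, "landscape_resolution", positive = TRUE)
  if (landscape_resolution < 2) {
    stop_input("`landscape_resolution` must be >= 2.", class = "sarsvr_config_error")
  }
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1) {
    stop_input("`out_dir` must be a single path.", class = "sarsvr_config_error")
  }
  check_number(seed, "seed")
  structure(list(
    datasets = datasets, panel = panel, svr = svr,
    landscape_resolution = as.integer(landscape_resolution),
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "study_config")
}

#' Validate a study configuration from structured text
#'
#' Accepts a ready `study_config`, a YAML file path, or YAML text. Unknown
#' keys are rejected; omitted optional keys receive the package defaults
#' (e.g. `epsilon` 0.1). Synthetic data set entries without a `seed` get one
#' derived from the global seed and their position.
#'
#' @param x A `study_config`, a path to a YAML file, or YAML text.
#' @return A validated `study_config`.
#' @export
validate_config <- function(x) {
  if (inherits(x, "study_config")) {
    return(study_config(x$datasets, x$panel, x$svr, x$landscape_resolution,
                        x$out_dir, x$seed))
  }
  if (!is.character(x) || length(x) != 1) {
    stop_input("`x` must be a study_config, a YAML path, or YAML text.",
               class = "sarsvr_config_error")
  }
  raw <- if (file.exists(x)) yaml::yaml.load_file(x) else yaml::yaml.load(x)
  if (!is.list(raw)) {
    stop_input("Configuration text did not parse to a mapping.",
               class = "sarsvr_config_error")
  }
  known_top <- c("seed", "out_dir", "datasets", "panel", "svr",
                 "landscape_resolution")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    stop_input(paste0("Unknown configuration key(s): ",
                      paste(unknown, collapse = ", "), "."),
               class = "sarsvr_config_error")
  }
  for (key in c("seed", "out_dir", "datasets", "panel")) {
    if (is.null(raw[[key]])) {
      stop_input(sprintf("Missing required configuration key `%s`.", key),
                 class = "sarsvr_config_error")
    }
  }
  seed <- raw$seed
  check_number(seed, "seed")

  take <- function(lst, keys, where) {
    unknown <- setdiff(names(lst), keys)
    if (length(unknown) > 0) {
      stop_input(paste0("Unknown key(s) in `", where, "`: ",
                        paste(unknown, collapse = ", "), "."),
                 class = "sarsvr_config_error")
    }
    lst
  }

  svr_raw <- take(raw$svr %||% list(),
                  c("c_grid", "epsilon", "n_trials", "split_fraction", "seed"), "svr")
  svr <- svr_config(
    c_grid = svr_raw$c_grid %||% c(1:50, 100, 250, 500, 1000),
    epsilon = svr_raw$epsilon %||% 0.1,
    n_trials = svr_raw$n_trials %||% 10L,
    split_fraction = svr_raw$split_fraction %||% 0.5,
    seed = svr_raw$seed %||% derive_seed(seed, "svr")
  )

  synth_keys <- c("path", "n_compounds", "n_clusters", "universe", "core_bits",
                  "private_bits", "potency_range", "within_cluster_spread",
                  "cliff_fraction", "cliff_magnitude", "seed", "target_id",
                  "scheme", "tc_threshold")
  datasets <- purrr::imap(raw$datasets, function(d, i) {
    if (is.character(d)) return(d)
    d <- take(d, synth_keys, sprintf("datasets[%s]", i))
    if (!is.null(d$path)) return(d$path)
    args <- d
    args$seed <- d$seed %||% derive_seed(seed, "dataset", as.character(i))
    args$potency_range <- unlist(args$potency_range) %||% c(5, 10)
    do.call(synth_config, args)
  })

  panel <- raw$panel
  if (is.list(panel)) {
    panel <- take(panel, c("path", "n_sets", "size_range", "cliff_fraction_range",
                           "seed", "universe", "scheme"), "panel")
    if (!is.null(panel$path)) {
      panel <- panel$path
    } else {
      panel <- panel_config(
        n_sets = panel$n_sets %||% 120L,
        size_range = unlist(panel$size_range) %||% c(100L, 140L),
        cliff_fraction_range = unlist(panel$cliff_fraction_range) %||% c(0, 0.2),
        seed = panel$seed %||% derive_seed(seed, "panel"),
        universe = panel$universe %||% 1024L,
        scheme = panel$scheme %||% "ECFP4"
      )
    }
  }

  study_config(datasets = datasets, panel = panel, svr = svr,
               landscape_resolution = raw$landscape_resolution %||% 60L,
               out_dir = raw$out_dir, seed = seed)
}

# Deterministic TSV serialization: doubles via %.17g, so re-running the study
# with the same configuration reproduces every output byte.
write_tsv_plain <- function(df, path) {
  fmt_cell <- function(x) {
    if (is.double(x)) {
      out <- fmt_num(x)
      out[is.na(x)] <- "NA"
      out
    } else {
      as.character(x)
    }
  }
  cols <- lapply(df, fmt_cell)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0) do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

load_panel <- function(panel, global_seed) {
  if (inherits(panel, "panel_config")) {
    return(generate_reference_panel(panel))
  }
  files <- sort(list.files(panel, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) < 2) {
    stop_input("Panel directory must contain >= 2 data set TSVs.",
               class = "sarsvr_config_error")
  }
  purrr::map(files, read_dataset)
}

#' Run the full study
#'
#' Executes the whole analysis from one configuration: generate or load the
#' data sets and the reference panel, score observed SAR characteristics, run
#' the regularization sweep, recompute SAR scores from train/test-context
#' mean predictions at the selected C, build observed and predicted activity
#' landscapes, and correlate observed discontinuity with mean test error
#' across data sets. All stage outputs are written as TSV/YAML under
#' `out_dir`; the bundle contains no timestamps, so identical configurations
#' produce byte-identical bundles.
#'
#' @param config A `study_config`, a YAML path, or YAML text (see
#'   [validate_config()]).
#' @return Invisibly, a `study_report`: list with `summary` (per-dataset
#'   tibble), `scores` (observed/train/test score rows), `sweeps`,
#'   `smoothing`, `correlation`, and `provenance`.
#' @export
run_study <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "datasets"), showWarnings = FALSE)

  message("[sarsvr] stage panel: building reference panel")
  panel <- load_panel(config$panel, config$seed)
  stats <- panel_stats(panel)

  sources <- config$datasets
  report_rows <- list()
  score_rows <- list()
  smoothing_rows <- list()
  sweeps <- list()

  for (i in seq_along(sources)) {
    src <- sources[[i]]
    ds <- if (is.character(src)) read_dataset(src) else generate_dataset(src)
    id <- dataset_attr(ds, "target_id")
    message(sprintf("[sarsvr] stage dataset %s (%d compounds)", id, nrow(ds)))
    write_dataset(ds, file.path(config$out_dir, "datasets", paste0(id, ".tsv")))

    sim <- pairwise_matrix(ds)
    observed <- score_dataset(ds, stats = stats, sim = sim)

    svr_cfg <- config$svr
    svr_cfg$seed <- derive_seed(config$seed, "svr", id)
    sweep <- sweep_c(ds, svr_cfg, keep_trials = TRUE, sim = sim)
    sweeps[[id]] <- sweep
    write_tsv_plain(sweep$by_c, file.path(config$out_dir, paste0("sweep_", id, ".tsv")))

    best <- sweep$by_c[sweep$by_c$c == sweep$best_c, ]
    best_trials <- sweep$trials[sweep$trials$c == sweep$best_c, ]
    summaries <- purrr::map(c(train = "train", test = "test"), function(ctx) {
      summarize_predictions(best_trials, ds, ctx)
    })
    pred_scores <- purrr::map(summaries, function(s) {
      predicted_scores(ds, s, stats = stats, sim = sim)
    })
    score_rows[[id]] <- dplyr::bind_rows(
      dplyr::mutate(observed, context = "observed", .after = "target_id"),
      dplyr::mutate(pred_scores$train, context = "predicted_train", .after = "target_id"),
      dplyr::mutate(pred_scores$test, context = "predicted_test", .after = "target_id")
    )

    message(sprintf("[sarsvr] stage landscape %s", id))
    emb <- embed_mds(sim, seed = derive_seed(config$seed, "mds", id))
    obs_surface <- interpolate_surface(emb, ds$pki, config$landscape_resolution)
    pred_surface <- interpolate_surface(emb, summaries$test$mean_prediction,
                                        config$landscape_resolution)
    smoothing <- compare_surfaces(obs_surface, pred_surface,
                                  observed_disc = observed$disc_raw,
                                  predicted_disc = pred_scores$test$disc_raw)
    smoothing_rows[[id]] <- dplyr::mutate(smoothing, target_id = id, .before = 1)

    report_rows[[id]] <- tibble(
      target_id = id,
      n = nrow(ds),
      best_c = sweep$best_c,
      mean_test_error = best$mean_test_error,
      mean_test_mae = best$mean_test_mae,
      mean_test_r2 = best$mean_test_r2,
      cont_raw_observed = observed$cont_raw,
      disc_raw_observed = observed$disc_raw,
      disc_norm_observed = observed$disc_norm,
      disc_raw_predicted_train = pred_scores$train$disc_raw,
      disc_raw_predicted_test = pred_scores$test$disc_raw,
      cont_raw_predicted_test = pred_scores$test$cont_raw,
      peak_height_loss = smoothing$peak_height_loss,
      n_lost_peaks = smoothing$n_lost_peaks
    )
  }

  summary <- dplyr::bind_rows(report_rows)
  scores <- dplyr::bind_rows(score_rows)
  smoothing <- dplyr::bind_rows(smoothing_rows)

  correlation <- if (nrow(summary) >= 3 &&
                     sd(summary$disc_raw_observed) > 0 &&
                     sd(summary$mean_test_mae) > 0) {
    correlate_disc_vs_error(tibble(disc = summary$disc_raw_observed,
                                   error = summary$mean_test_mae))
  } else {
    tibble(r = NA_real_, p_two_tailed = NA_real_, n = nrow(summary))
  }

  provenance <- list(
    package = "sarsvr",
    version = as.character(utils::packageVersion("sarsvr")),
    seed = config$seed,
    config_hash = str_hash(paste(deparse(config[setdiff(names(config), "out_dir")]),
                                 collapse = "\n")),
    n_datasets = length(sources),
    n_panel_sets = length(panel)
  )

  write_tsv_plain(summary, file.path(config$out_dir, "summary.tsv"))
  write_tsv_plain(scores, file.path(config$out_dir, "scores.tsv"))
  write_tsv_plain(smoothing, file.path(config$out_dir, "smoothing.tsv"))
  write_tsv_plain(correlation, file.path(config$out_dir, "correlation.tsv"))
  yaml::write_yaml(provenance, file.path(config$out_dir, "provenance.yaml"))

  invisible(structure(list(
    summary = summary, scores = scores, smoothing = smoothing,
    correlation = correlation, sweeps = sweeps, provenance = provenance
  ), class = "study_report"))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d data set(s), panel of %d, seed %d\n",
              x$provenance$n_datasets, x$provenance$n_panel_sets,
              x$provenance$seed))
  print(x$summary, ...)
  invisible(x)
}
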