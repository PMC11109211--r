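#' Load and validate a run configuration
#'
#' Reads a YAML configuration and fills in defaults. Unknown keys anywhere in
#' the file are rejected, so typos fail loudly instead of silently running
#' with defaults. An empty (or absent-section) file yields the full default
#' configuration.
#'
#' Sections: `mode` (`simulate`, `benchmark` or `report`), `seed`, `out_dir`,
#' `synthetic` (mirrors [synthetic_spec()]), `resamplers` (method names as in
#' [resampler_spec()]), `grid` (mirrors [model_grid()]), `cv` (`n_folds`,
#' `n_repeats`), `simulation` (`B_grid`, `N_grid`, `n_repeats`).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- list(
    mode = "benchmark",
    seed = 1L,
    out_dir = "results",
    synthetic = list(n_samples = 120L, n_features = 200L, n_informative = 0L,
                     effect_size = 0, balance = 3, missing_rate = 0,
                     correlation = 0.5),
    resamplers = c("random_undersampling", "tomek_links",
                   "random_oversampling", "smote", "polyfit_smote", "mwmote",
                   "smote_tomek"),
    grid = list(scorers = c("anova", "bhattacharyya"),
                n_features = c(1L, 4L, 16L),
                classifiers = c("logistic_regression", "naive_bayes"),
                lr_C = 2^c(-5, 0, 5), svm_C = 2^c(-5, 0, 5),
                knn_k = c(1L, 3L, 5L, 7L, 9L)),
    cv = list(n_folds = 5L, n_repeats = 30L),
    simulation = list(B_grid = c(100, 50, 100 / 3, 25, 20),
                      N_grid = c(50, 100, 200), n_repeats = 100L)
  )
  .check_keys(raw, defaults, "top level")
  for (sect in c("synthetic", "grid", "cv", "simulation"))
    if (!is.null(raw[[sect]]))
      .check_keys(raw[[sect]], defaults[[sect]], sect)
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$mode %in% c("simulate", "benchmark", "report"))
    stop(sprintf("unknown mode '%s'", cfg$mode))
  for (m in cfg$resamplers) resampler_variants(m)   # validates names
  structure(cfg, class = "run_config")
}

.check_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), names(allowed))
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration key(s) at %s: %s (allowed: %s)",
                 where, paste(unknown, collapse = ", "),
                 paste(names(allowed), collapse = ", ")))
}

#' Persist run results with a reproducibility manifest
#'
#' Writes whichever tidy tables are present in `results` —
#' `bias_records`, `summary_by_dataset`, `simulation` — as CSVs, an optional
#' plain-text leakage `audit` log, and a JSON manifest carrying the
#' configuration, its hash and the seed, sufficient to re-run the exact same
#' computation.
#'
#' @param results named list of data frames (and optionally an `audit`
#'   character vector).
#' @param out_dir output directory, created if needed.
#' @param config the `run_config` (or any list) the results came from.
#' @return invisibly, the manifest list (also written to `manifest.json`).
#' @export
write_results <- function(results, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in c("bias_records", "summary_by_dataset", "simulation")) {
    if (!is.null(results[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(results[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(results$audit)) {
    f <- file.path(out_dir, "audit.log")
    writeLines(results$audit, f)
    files <- c(files, f)
  }
  manifest <- list(config = unclass(config),
                   config_hash = rlang::hash(unclass(config)),
                   seed = config$seed %||% NA,
                   files = basename(files),
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
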