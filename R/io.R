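#' Pipeline run configuration
#'
#' Validated bundle of every tunable parameter of the pipeline, with
#' documented defaults. Unknown keys are rejected rather than ignored, so a
#' typo in a config file cannot silently fall back to a default.
#'
#' @param threshold_method Segmentation threshold: `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity cut used when `threshold_method` is
#'   `"fixed"`.
#' @param erosion_radius Core-isolation opening radius in pixels, or `NA`
#'   to estimate it as 1/4 of the equivalent-circle radius of the largest
#'   component.
#' @param min_component_size Minimum connected-component size kept by
#'   segmentation, in pixels.
#' @param hull_method Total-area rule: `"convex_hull"` or
#'   `"component_union"`.
#' @param um_per_px Micron-per-pixel scale, or `NA` to report areas in
#'   pixels.
#' @param denominator Fold-change denominator over untreated replicates:
#'   `"median"` or `"mean"`.
#' @param ci_level Confidence level for exact response-rate intervals.
#' @param progressor_rule `"absolute"` (percentage points of predicted FVC)
#'   or `"relative"` (percent of baseline).
#' @param progressor_threshold FVC decline defining progression (default 5).
#' @param progressor_window_months Follow-up window for progression
#'   (default 12).
#' @param seed Integer seed for any simulation step.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(threshold_method = "otsu", fixed_threshold = NA,
                       erosion_radius = NA, min_component_size = 5,
                       hull_method = "convex_hull", um_per_px = NA,
                       denominator = "median", ci_level = 0.95,
                       progressor_rule = "absolute",
                       progressor_threshold = 5,
                       progressor_window_months = 12, seed = 1L) {
  cfg <- list(threshold_method = match.arg(threshold_method,
                                           c("otsu", "fixed")),
              fixed_threshold = fixed_threshold,
              erosion_radius = if (is.na(erosion_radius)) NULL
                               else erosion_radius,
              min_component_size = min_component_size,
              hull_method = match.arg(hull_method,
                                      c("convex_hull", "component_union")),
              um_per_px = um_per_px,
              denominator = match.arg(denominator, c("median", "mean")),
              ci_level = ci_level,
              progressor_rule = match.arg(progressor_rule,
                                          c("absolute", "relative")),
              progressor_threshold = progressor_threshold,
              progressor_window_months = progressor_window_months,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

.config_keys <- c("threshold_method", "fixed_threshold", "erosion_radius",
                  "min_component_size", "hull_method", "um_per_px",
                  "denominator", "ci_level", "progressor_rule",
                  "progressor_threshold", "progressor_window_months", "seed")

#' Read or write a run configuration as a flat key = value file
#'
#' @param path File path. The format is one `key = value` pair per line;
#'   `#` starts a comment; unknown keys are an error.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[lengths(kv) != 2]
  if (length(bad))
    abort(sprintf("malformed config line(s): %s", paste(bad, collapse = "; ")))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  unknown <- setdiff(keys, .config_keys)
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("fixed_threshold", "erosion_radius",
                    "min_component_size", "um_per_px", "ci_level",
                    "progressor_threshold", "progressor_window_months",
                    "seed")
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- if (toupper(args[[k]]) == "NA") NA else
      as.numeric(args[[k]])
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- lapply(.config_keys, function(k) config[[k]] %||% NA)
  writeLines(sprintf("%s = %s", .config_keys,
                     vapply(vals, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

# ---------------------------------------------------------------------
# tables

.measurement_cols <- c("patient_id", "group", "arm", "replicate", "H", "R",
                       "unit", "zoi_percent")

#' Read and validate a measurement table CSV
#'
#' Schema: `patient_id, group, arm, replicate, H, R, unit, zoi_percent`
#' (header required, UTF-8, dot decimals). `(patient_id, arm, replicate)`
#' must be unique, and a present `zoi_percent` must agree with `H` and `R`
#' to 1e-6. An ROI CSV without `zoi_percent` or `group` is accepted and the
#' missing columns are derived or left NA.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_measurements(df)
}

validate_measurements <- function(df) {
  assert_columns(df, c("patient_id", "arm", "replicate", "H", "R"),
                 "measurements")
  df <- tibble::as_tibble(df)
  if (!"unit" %in% names(df)) df$unit <- "px^2"
  if (!"group" %in% names(df)) df$group <- NA_character_
  key <- paste(df$patient_id, df$arm, df$replicate)
  if (anyDuplicated(key))
    abort(sprintf("duplicate (patient_id, arm, replicate): %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  expected <- zoi_percent(df$H, df$R)
  if ("zoi_percent" %in% names(df) && any(!is.na(df$zoi_percent))) {
    off <- which(abs(df$zoi_percent - expected) > 1e-6)
    if (length(off))
      abort(sprintf("zoi_percent inconsistent with H and R at row(s): %s",
                    paste(off, collapse = ", ")))
  }
  df$zoi_percent <- expected
  df[union(.measurement_cols, names(df))]
}

#' @rdname read_measurements
#' @param measurements Measurement tibble.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read and write the patient table CSV
#'
#' Columns: `patient_id, group, diagnosis, fvc_baseline, fvc_followup,
#' followup_months, fibronectin_dab, col1a1_expr` (extras preserved).
#' Missing clinical values are empty fields, never sentinel numbers.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_patients <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("patient_id", "group"), "patients")
  if (anyDuplicated(df$patient_id))
    abort("duplicate patient_id in patient table")
  tibble::as_tibble(df)
}

#' @rdname read_patients
#' @param patients Patient tibble.
#' @export
write_patients <- function(patients, path) {
  readr::write_csv(patients, path)
  invisible(path)
}

# ---------------------------------------------------------------------
# pipeline stages

#' Simulate a cohort and write it to disk
#'
#' Writes `patients.csv`, `measurements.csv`, a `manifest.json` recording
#' the generator parameters and seed, and optionally a directory of
#' synthetic 16-bit TIFF spheroid images (one per untreated baseline
#' replicate, named `<patient>_<arm>_<replicate>.tiff`).
#'
#' @param out_dir Output directory, created if needed.
#' @param spec A [cohort_spec()].
#' @param images Also render per-replicate images? Default `FALSE` (image
#'   rendering is the slow step and most analyses start from the table).
#' @param overwrite Refuse to overwrite an existing non-empty output
#'   directory unless `TRUE`.
#' @return Invisibly, the generated `pulmo_cohort`.
#' @export
pipeline_simulate <- function(out_dir, spec = cohort_spec(),
                              images = FALSE, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    abort(sprintf("output directory %s is not empty (use overwrite = TRUE)",
                  out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec)
  write_patients(cohort$patients, file.path(out_dir, "patients.csv"))
  write_measurements(cohort$measurements,
                     file.path(out_dir, "measurements.csv"))
  if (images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    base <- dplyr::filter(cohort$measurements,
                          .data$arm %in% c("untreated", "control"))
    img_seeds <- derive_seeds(spec$seed + 1L, nrow(base))
    for (i in seq_len(nrow(base))) {
      # ZOI%-matched geometry: reach and cell count grow with invasiveness
      z <- base$zoi_percent[i]
      img <- generate_pulmosphere_image(
        core_radius = 30, n_cells = max(1L, round(2 * sqrt(z) + 5)),
        reach = max(4, 30 * (sqrt(1 + z / 100) - 1)),
        noise_sd = 0.05, seed = img_seeds[i])
      write_pulmosphere_tiff(img, file.path(
        img_dir, sprintf("%s_%s_%d.tiff", base$patient_id[i], base$arm[i],
                         base$replicate[i])))
    }
  }
  manifest <- list(created = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(
                     utils::packageVersion("pulmosphere")),
                   seed = spec$seed,
                   spec = spec[setdiff(names(spec), "drug_effects")],
                   drug_effects = spec$drug_effects,
                   images = images)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

#' Quantify a directory of spheroid images, or pass through an ROI CSV
#'
#' Every readable image contributes one measurement row; per-image failures
#' (e.g. empty foreground) are collected, reported, and isolated — they
#' never abort the batch. An ROI CSV (hand-outlined `H` and `R` values)
#' bypasses segmentation entirely and only gains a recomputed `zoi_percent`
#' column.
#'
#' @param input Directory of TIFF/PNG images, or path to an ROI CSV.
#' @param config A [run_config()].
#' @return A tibble of measurements with attribute `failures`, a tibble of
#'   per-file error messages (also printed as a message when nonempty).
#' @export
pipeline_quantify <- function(input, config = run_config()) {
  if (dir.exists(input)) {
    files <- sort(list.files(input, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) abort(sprintf("no images found in %s", input))
    res <- purrr::map(files, function(f)
      tryCatch(quantify_image(f, config),
               error = function(e) conditionMessage(e)))
    ok <- purrr::map_lgl(res, is.data.frame)
    out <- dplyr::bind_rows(res[ok])
    failures <- tibble::tibble(file = basename(files[!ok]),
                               error = unlist(res[!ok]) %||% character(0))
  } else if (file.exists(input)) {
    roi <- readr::read_csv(input, show_col_types = FALSE)
    assert_columns(roi, c("patient_id", "arm", "replicate", "H", "R"),
                   "ROI CSV")
    out <- validate_measurements(roi)
    failures <- tibble::tibble(file = character(), error = character())
  } else {
    abort(sprintf("input not found: %s", input))
  }
  if (nrow(failures))
    message(sprintf("%d image(s) failed quantification; see attr(,'failures')",
                    nrow(failures)))
  attr(out, "failures") <- failures
  out
}

#' Analyze a cohort end to end and write results
#'
#' Runs ZOI scoring ([drug_response()]) and the full [cohort_panel()] on a
#' measurement and a patient table, and (optionally) writes a
#' machine-readable `results.json`, a per-patient `responses.csv`, and a
#' plain-text `report.txt` whose response-rate lines read like
#' `12/23 (52%)`.
#'
#' @param measurements Measurement tibble or CSV path.
#' @param patients Patient tibble or CSV path.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the three result files.
#' @return The `cohort_panel`, invisibly when `out_dir` is given.
#' @export
pipeline_analyze <- function(measurements, patients,
                             config = run_config(), out_dir = NULL) {
  if (is.character(measurements))
    measurements <- read_measurements(measurements)
  if (is.character(patients)) patients <- read_patients(patients)
  measurements <- validate_measurements(measurements)
  if (!nrow(measurements)) abort("no measurements")
  patients <- classify_progressors(
    patients, threshold = config$progressor_threshold,
    window_months = config$progressor_window_months,
    rule = config$progressor_rule)
  responses <- drug_response(measurements, denominator = config$denominator)
  panel <- cohort_panel(patients, measurements, responses,
                        conf_level = config$ci_level)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(dplyr::select(responses, -"fold_changes"),
                     file.path(out_dir, "responses.csv"))
    jsonlite::write_json(
      list(group_comparison = panel$group_comparison,
           group_summaries = panel$group_summaries,
           regressions = panel$regressions,
           paired_tests = panel$paired_tests,
           response_rates = panel$response_rates,
           config = unclass(config)),
      file.path(out_dir, "results.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    writeLines(c(utils::capture.output(print(panel)), "",
                 sprintf("config: %s", paste(
                   sprintf("%s=%s", .config_keys,
                           vapply(.config_keys, function(k)
                             format(config[[k]] %||% NA), "")),
                   collapse = " ")),
                 sprintf("package version: %s", as.character(
                   utils::packageVersion("pulmosphere")))),
               file.path(out_dir, "report.txt"))
    return(invisible(panel))
  }
  panel
}
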