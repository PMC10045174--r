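#' Zone-of-invasion percentage
#'
#' The invasiveness statistic of the pulmosphere assay:
#' ZOI% = (H - R) / R * 100, where H is the total invaded area and R the
#' spheroid core area, in the same unit. It is 0 exactly when nothing
#' invaded (H == R) and is invariant under any common rescaling of H and R,
#' so pixel-vs-micron calibration never changes it.
#'
#' @param H Total invaded area(s), `H >= R`.
#' @param R Core area(s), `R > 0`.
#' @return Numeric vector of ZOI percentages.
#' @examples
#' zoi_percent(H = 6162, R = 1000)  # 516.2
#' @export
zoi_percent <- function(H, R) {
  if (!is.numeric(H) || !is.numeric(R))
    abort("`H` and `R` must be numeric")
  if (any(!is.finite(H)) || any(!is.finite(R)))
    abort("`H` and `R` must be finite")
  if (any(R <= 0))
    abort("invalid measurement: core area R must be > 0")
  if (any(H < R))
    abort("invalid measurement: H < R violates geometry (hull contains core)")
  (H - R) / R * 100
}

#' Per-replicate ZOI fold changes for one patient and one drug
#'
#' The fold change of ZOI is the ratio of ZOI% with treatment to ZOI%
#' without treatment. Treated and untreated spheroids are distinct physical
#' replicates with no natural pairing, so each treated replicate is divided
#' by a single location summary of that patient's untreated replicates —
#' the median by default (robust), optionally the mean.
#'
#' @param treated_zoi Treated-arm ZOI% values, all `>= 0`.
#' @param untreated_zoi Untreated-arm ZOI% values, all `>= 0`, with a
#'   positive denominator summary.
#' @param denominator `"median"` (default) or `"mean"`.
#' @return Numeric vector of ratios, one per treated replicate.
#' @examples
#' fold_changes(c(200), c(50, 150, 100))  # 200 / 100 = 2
#' @export
fold_changes <- function(treated_zoi, untreated_zoi,
                         denominator = c("median", "mean")) {
  denominator <- match.arg(denominator)
  if (!length(treated_zoi) || !length(untreated_zoi))
    abort("both replicate lists must be nonempty")
  if (any(treated_zoi < 0) || any(untreated_zoi < 0))
    abort("ZOI% values must be >= 0")
  denom <- switch(denominator, median = median(untreated_zoi),
                  mean = mean(untreated_zoi))
  if (denom <= 0)
    abort("undefined fold change: untreated ZOI% summary is 0 for this patient")
  treated_zoi / denom
}

#' Classify a patient as drug responder from ZOI fold changes
#'
#' A patient responds to a drug when the median fold change of ZOI across
#' treated replicates is strictly below 1 (even counts use the midpoint
#' rule). A median of exactly 1 is a nonresponder: responsiveness is defined
#' strictly as "< 1", and the boundary reads as no change.
#'
#' @param fold_changes Positive fold-change ratios, nonempty.
#' @return A list with `median_fold_change` and logical `responder`.
#' @examples
#' classify_responder(c(0.5, 0.6, 0.7, 1.2, 1.3))  # median 0.7, responder
#' classify_responder(c(0.4, 1.6))                 # median 1, nonresponder
#' @export
classify_responder <- function(fold_changes) {
  if (!length(fold_changes)) abort("`fold_changes` must be nonempty")
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
    abort("`fold_changes` must be finite and > 0")
  m <- median(fold_changes)
  list(median_fold_change = m, responder = m < 1)
}

#' Response rate with exact Clopper-Pearson confidence interval
#'
#' Counts responders, expresses the rate as an integer percent by truncation
#' toward zero (so 6/11 prints as 54%, matching the convention of reporting
#' whole percents without rounding up), and attaches the exact
#' Clopper-Pearson binomial confidence bounds in beta-quantile form:
#' lower = qbeta(a/2; k, n-k+1), upper = qbeta(1-a/2; k+1, n-k), with the
#' boundary conventions lower = 0 at k = 0 and upper = 1 at k = n.
#'
#' @param responders Logical vector of per-patient responder flags, or an
#'   integer count `k` when `n` is given.
#' @param n Number of patients; required when `responders` is a count.
#' @param conf_level Confidence level in (0, 1), default 0.95.
#' @return A one-row tibble: `n_responders`, `n_patients`, `rate_percent`
#'   (integer), `rate` (proportion), `ci_low`, `ci_high` (proportions).
#' @examples
#' response_rate(12, n = 23)   # 52%, exact 95% CI
#' @export
response_rate <- function(responders, n = NULL, conf_level = 0.95) {
  assert_scalar_number(conf_level, "conf_level", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (conf_level >= 1) abort("`conf_level` must be < 1")
  if (is.logical(responders)) {
    if (!length(responders) || anyNA(responders))
      abort("`responders` must be a nonempty logical vector without NA")
    k <- sum(responders)
    n <- length(responders)
  } else {
    if (is.null(n)) abort("`n` is required when `responders` is a count")
    k <- as.integer(responders)
    n <- as.integer(n)
    if (k < 0 || n < 1 || k > n) abort("need 0 <= k <= n, n >= 1")
  }
  ci <- clopper_pearson(k, n, conf_level)
  tibble::tibble(n_responders = as.integer(k), n_patients = as.integer(n),
                 rate_percent = as.integer(trunc_percent(k, n)),
                 rate = k / n,
                 ci_low = ci[1], ci_high = ci[2])
}

# exact binomial CI, beta-quantile form
clopper_pearson <- function(k, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' Attach ZOI% to a measurement table
#'
#' @param measurements A data frame with columns `H` and `R` (same unit per
#'   row). Rows violating `H >= R > 0` raise an error.
#' @return The input as a tibble with a `zoi_percent` column (recomputed if
#'   already present).
#' @export
add_zoi <- function(measurements) {
  assert_columns(measurements, c("H", "R"), "measurements")
  dplyr::mutate(tibble::as_tibble(measurements),
                zoi_percent = zoi_percent(.data$H, .data$R))
}

#' Score per-patient drug response from a measurement table
#'
#' For every patient with both an untreated arm and at least one treated
#' arm, computes per-replicate ZOI fold changes against the patient's
#' untreated summary, the median fold change, and the responder flag
#' (median < 1, strict).
#'
#' @param measurements Measurement table with columns `patient_id`, `arm`,
#'   `replicate`, and `zoi_percent` (or `H` and `R`, from which ZOI% is
#'   computed). Arms other than `untreated`/`control` are treated arms.
#' @param denominator Passed to [fold_changes()].
#' @return A tibble, one row per patient x drug: `patient_id`, `drug`,
#'   `n_reps`, `fold_changes` (list column), `median_fold_change`,
#'   `responder`.
#' @export
drug_response <- function(measurements, denominator = c("median", "mean")) {
  denominator <- match.arg(denominator)
  assert_columns(measurements, c("patient_id", "arm", "replicate"),
                 "measurements")
  if (!"zoi_percent" %in% names(measurements))
    measurements <- add_zoi(measurements)
  meas <- tibble::as_tibble(measurements)
  untreated <- dplyr::filter(meas, .data$arm %in% c("untreated", "control"))
  treated <- dplyr::filter(meas, !.data$arm %in% c("untreated", "control"))
  if (!nrow(treated)) {
    return(tibble::tibble(patient_id = character(), drug = character(),
                          n_reps = integer(), fold_changes = list(),
                          median_fold_change = double(),
                          responder = logical()))
  }
  base <- dplyr::summarise(dplyr::group_by(untreated, .data$patient_id),
                           baseline = list(.data$zoi_percent),
                           .groups = "drop")
  out <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(treated, .data$patient_id, .data$arm),
                     treated_zoi = list(.data$zoi_percent), .groups = "drop"),
    base, by = "patient_id")
  missing <- setdiff(unique(treated$patient_id), base$patient_id)
  if (length(missing))
    abort(sprintf("no untreated replicates for patient(s): %s",
                  paste(missing, collapse = ", ")))
  out <- dplyr::mutate(
    out,
    fold_changes = purrr::map2(.data$treated_zoi, .data$baseline,
                               ~ fold_changes(.x, .y,
                                              denominator = denominator)),
    n_reps = lengths(.data$fold_changes),
    median_fold_change = purrr::map_dbl(.data$fold_changes, median),
    responder = .data$median_fold_change < 1)
  dplyr::select(dplyr::rename(out, drug = "arm"),
                "patient_id", "drug", "n_reps", "fold_changes",
                "median_fold_change", "responder")
}

#' Response rates by drug (and optional strata) with exact CIs
#'
#' @param responses Output of [drug_response()], optionally joined with
#'   stratification columns.
#' @param ... Optional grouping columns (tidy-select style by name), e.g.
#'   `diagnosis` or `progression`, in addition to `drug`.
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @param min_n Strata with fewer patients are flagged `"insufficient n"` in
#'   the `status` column rather than dropped.
#' @return A tibble with one row per drug (x stratum): counts, truncated
#'   integer percent, exact CI bounds, `status`.
#' @export
response_rates <- function(responses, ..., conf_level = 0.95, min_n = 3L) {
  assert_columns(responses, c("patient_id", "drug", "responder"), "responses")
  if (!nrow(responses)) {
    return(tibble::tibble(drug = character(), n_responders = integer(),
                          n_patients = integer(), rate_percent = integer(),
                          rate = double(), ci_low = double(),
                          ci_high = double(), status = character()))
  }
  grouped <- dplyr::group_by(tibble::as_tibble(responses), .data$drug, ...)
  out <- dplyr::reframe(grouped, response_rate(.data$responder,
                                               conf_level = conf_level))
  dplyr::mutate(out, status = dplyr::if_else(.data$n_patients < min_n,
                                             "insufficient n", "ok"))
}

#' Plot per-patient median ZOI fold changes by drug
#'
#' Dot plot of median fold change per patient, one panel per drug, with the
#' responder threshold (fold change 1) drawn as a dashed line.
#'
#' @param responses Output of [drug_response()].
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(responses) {
  assert_columns(responses, c("patient_id", "drug", "median_fold_change"),
                 "responses")
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data$patient_id,
                               y = .data$median_fold_change,
                               colour = .data$responder)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug), ncol = 1) +
    ggplot2::labs(x = "patient", y = "median ZOI fold change") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
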