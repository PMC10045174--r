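#' Run the full cohort analysis panel
#'
#' Orchestrates every cohort-level analysis of the pulmosphere workflow on
#' joined patient, measurement, and response tables:
#' \itemize{
#'   \item ILD-versus-control comparison of per-patient baseline (untreated)
#'     ZOI%, by Mann-Whitney, with group mean/SD summaries;
#'   \item simple linear regressions of baseline ZOI% against FVC decline,
#'     fibronectin DAB intensity, and Col1a1 expression;
#'   \item per-drug paired untreated-versus-treated comparisons of patient
#'     median ZOI% (Wilcoxon signed-rank);
#'   \item response rates with exact Clopper-Pearson CIs, overall, by
#'     diagnosis subgroup, and by progression label;
#'   \item regressions of per-patient drug efficacy (median ZOI fold change,
#'     the "ZOI ratio") against baseline ZOI% and against FVC decline.
#' }
#' Strata with fewer than 3 patients are reported with status
#' `"insufficient n"`; degenerate regressions (constant predictor, n < 3)
#' are reported with status `"degenerate"`, never dropped silently.
#'
#' @param patients Patient table: `patient_id`, `group`, `diagnosis`,
#'   `fvc_baseline`, `fvc_followup`, `followup_months`, and optionally
#'   `fibronectin_dab`, `col1a1_expr`.
#' @param measurements Measurement table: `patient_id`, `arm`, `replicate`,
#'   `zoi_percent` (or `H`, `R`).
#' @param responses Optional output of [drug_response()]; computed from
#'   `measurements` when `NULL`.
#' @param conf_level Confidence level used throughout, default 0.95.
#' @return A `cohort_panel` object (list of tibbles: `group_comparison`,
#'   `group_summaries`, `regressions`, `paired_tests`, `response_rates`,
#'   `patients`, `responses`) with [tidy()], [glance()], [autoplot()] and
#'   print methods.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 3))
#' panel <- cohort_panel(cohort$patients, cohort$measurements)
#' panel$response_rates
#' @export
cohort_panel <- function(patients, measurements, responses = NULL,
                         conf_level = 0.95) {
  assert_columns(patients, c("patient_id", "group"), "patients")
  assert_columns(measurements, c("patient_id", "arm", "replicate"),
                 "measurements")
  if (!nrow(measurements)) abort("no measurements")
  if (!"zoi_percent" %in% names(measurements))
    measurements <- add_zoi(measurements)
  measurements <- tibble::as_tibble(measurements)
  patients <- tibble::as_tibble(patients)
  bad <- setdiff(unique(measurements$patient_id), patients$patient_id)
  if (length(bad))
    abort(sprintf("measurements reference unknown patient_id(s): %s",
                  paste(bad, collapse = ", ")))
  if (is.null(responses)) responses <- drug_response(measurements)

  if (!"progression" %in% names(patients)) {
    patients <- if (all(c("fvc_baseline", "fvc_followup",
                          "followup_months") %in% names(patients)))
      classify_progressors(patients)
    else dplyr::mutate(patients, delta_fvc = NA_real_,
                       progression = "undetermined")
  }

  baseline <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(measurements, .data$arm %in% c("untreated", "control")),
      .data$patient_id),
    zoi_baseline = median(.data$zoi_percent), .groups = "drop")
  pt <- dplyr::left_join(patients, baseline, by = "patient_id")

  ild <- dplyr::filter(pt, .data$group == "ILD", !is.na(.data$zoi_baseline))
  ctl <- dplyr::filter(pt, .data$group == "control",
                       !is.na(.data$zoi_baseline))

  # --- ILD vs control invasiveness -----------------------------------
  if (nrow(ild) >= 3 && nrow(ctl) >= 3) {
    mw <- mann_whitney_u(ild$zoi_baseline, ctl$zoi_baseline)
    group_comparison <- dplyr::mutate(mw, comparison = "ILD vs control ZOI%",
                                      status = "ok", .before = 1)
  } else {
    group_comparison <- tibble::tibble(comparison = "ILD vs control ZOI%",
                                       statistic = NA_real_,
                                       p_value = NA_real_,
                                       method = NA_character_,
                                       n_x = nrow(ild), n_y = nrow(ctl),
                                       status = "insufficient n")
  }
  group_summaries <- dplyr::bind_rows(
    if (nrow(ild) >= 2) dplyr::mutate(summarize_group(ild$zoi_baseline,
                                                      conf_level),
                                      group = "ILD", .before = 1),
    if (nrow(ctl) >= 2) dplyr::mutate(summarize_group(ctl$zoi_baseline,
                                                      conf_level),
                                      group = "control", .before = 1))

  # --- regressions of baseline invasiveness --------------------------
  # FVC decline is baseline minus follow-up: a larger value means more
  # lung-function loss, the orientation in which invasiveness and decline
  # correlate positively
  ild$fvc_decline <- -ild$delta_fvc
  reg_specs <- list(
    list(name = "zoi_vs_fvc_decline", x = "fvc_decline", y = "zoi_baseline"),
    list(name = "zoi_vs_fibronectin", x = "fibronectin_dab",
         y = "zoi_baseline"),
    list(name = "zoi_vs_col1a1", x = "col1a1_expr", y = "zoi_baseline"))

  eff <- dplyr::left_join(responses,
                          dplyr::select(ild, "patient_id", "zoi_baseline",
                                        "fvc_decline"),
                          by = "patient_id")
  drug_regs <- purrr::flatten(purrr::map(
    unique(responses$drug),
    function(d) list(
      list(name = paste0("efficacy_", d, "_vs_zoi"), x = "zoi_baseline",
           y = "median_fold_change", data = dplyr::filter(eff,
                                                          .data$drug == d)),
      list(name = paste0("efficacy_", d, "_vs_fvc_decline"),
           x = "fvc_decline", y = "median_fold_change",
           data = dplyr::filter(eff, .data$drug == d)))))
  regressions <- dplyr::bind_rows(purrr::map(
    c(reg_specs, drug_regs),
    function(rs) run_regression_row(rs, default_data = ild)))

  # --- paired untreated vs treated, per drug -------------------------
  paired_tests <- dplyr::bind_rows(purrr::map(
    unique(responses$drug),
    function(d) {
      med <- patient_arm_medians(measurements, d)
      if (nrow(med) < 3)
        return(tibble::tibble(drug = d, statistic = NA_real_,
                              p_value = NA_real_, method = NA_character_,
                              n_pairs = nrow(med), all_zero = NA,
                              status = "insufficient n"))
      wt <- wilcoxon_signed_rank(med$untreated, med$treated)
      dplyr::mutate(wt, drug = d, status = "ok", .before = 1)
    }))

  # --- response rates: overall, by diagnosis, by progression ---------
  resp <- dplyr::left_join(responses,
                           dplyr::select(pt, "patient_id", "diagnosis",
                                         "progression"),
                           by = "patient_id")
  rates <- if (!nrow(responses)) {
    dplyr::mutate(response_rates(responses), stratum = character(),
                  level = character(), .before = 1)
  } else dplyr::bind_rows(
    dplyr::mutate(response_rates(responses, conf_level = conf_level),
                  stratum = "all", level = "all", .before = 1),
    if ("diagnosis" %in% names(resp) && !all(is.na(resp$diagnosis)))
      dplyr::mutate(response_rates(resp, .data$diagnosis,
                                   conf_level = conf_level),
                    stratum = "diagnosis", .before = 1) |>
        dplyr::rename(level = "diagnosis"),
    dplyr::mutate(response_rates(resp, .data$progression,
                                 conf_level = conf_level),
                  stratum = "progression", .before = 1) |>
      dplyr::rename(level = "progression"))

  structure(list(group_comparison = group_comparison,
                 group_summaries = group_summaries,
                 regressions = regressions,
                 paired_tests = paired_tests,
                 response_rates = rates,
                 patients = pt, responses = responses,
                 conf_level = conf_level),
            class = "cohort_panel")
}

run_regression_row <- function(rs, default_data) {
  data <- rs$data %||% default_data
  empty <- tibble::tibble(analysis = rs$name, slope = NA_real_,
                          intercept = NA_real_, r = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          n = NA_integer_, status = "degenerate")
  if (!all(c(rs$x, rs$y) %in% names(data))) {
    empty$status <- "missing covariate"
    return(empty)
  }
  res <- tryCatch(linear_regression(data[[rs$x]], data[[rs$y]]),
                  error = function(e) conditionMessage(e))
  if (is.character(res)) {
    empty$status <- if (grepl("at least 3", res)) "insufficient n"
                    else "degenerate"
    return(empty)
  }
  dplyr::mutate(tibble::as_tibble(res), analysis = rs$name, status = "ok",
                .before = 1)
}

patient_arm_medians <- function(measurements, drug) {
  med <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(measurements,
                    .data$arm %in% c("untreated", "control", drug)),
      .data$patient_id,
      side = dplyr::if_else(.data$arm == drug, "treated", "untreated")),
    zoi = median(.data$zoi_percent), .groups = "drop")
  wide <- tidyr::pivot_wider(med, names_from = "side", values_from = "zoi")
  if (!all(c("untreated", "treated") %in% names(wide)))
    return(wide[0, ])
  tidyr::drop_na(wide, "untreated", "treated")
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("== Pulmosphere cohort analysis panel ==\n\n")
  gc <- x$group_comparison
  if (identical(gc$status, "ok")) {
    gs <- x$group_summaries
    fmt <- function(g) {
      row <- gs[gs$group == g, ]
      sprintf("%.4g ± %.4g (n=%d)", row$mean, row$sd, row$n)
    }
    cat(sprintf("ILD vs control ZOI%%: %s vs %s, Mann-Whitney p = %.3g\n",
                fmt("ILD"), fmt("control"), gc$p_value))
  } else {
    cat(sprintf("ILD vs control ZOI%%: %s\n", gc$status))
  }
  cat("\nRegressions:\n")
  for (i in seq_len(nrow(x$regressions))) {
    rr <- x$regressions[i, ]
    if (rr$status == "ok")
      cat(sprintf("  %-32s r = %.4f, R^2 = %.4f, p = %.3g (n=%d)\n",
                  rr$analysis, rr$r, rr$r_squared, rr$p_value, rr$n))
    else
      cat(sprintf("  %-32s [%s]\n", rr$analysis, rr$status))
  }
  cat("\nPaired untreated vs treated (patient median ZOI%):\n")
  for (i in seq_len(nrow(x$paired_tests))) {
    pt <- x$paired_tests[i, ]
    if (identical(pt$status, "ok"))
      cat(sprintf("  %-12s Wilcoxon W = %g, p = %.3g (n=%d)\n",
                  pt$drug, pt$statistic, pt$p_value, pt$n_pairs))
    else
      cat(sprintf("  %-12s [%s]\n", pt$drug, pt$status))
  }
  cat("\nResponse rates (exact CI):\n")
  for (i in seq_len(nrow(x$response_rates))) {
    rr <- x$response_rates[i, ]
    lab <- if (rr$stratum == "all") rr$drug
           else sprintf("%s | %s", rr$drug, rr$level)
    if (rr$status == "ok")
      cat(sprintf("  %-38s %d/%d (%d%%), CI [%.3f, %.3f]\n", lab,
                  rr$n_responders, rr$n_patients, rr$rate_percent,
                  rr$ci_low, rr$ci_high))
    else
      cat(sprintf("  %-38s %d/%d [%s]\n", lab, rr$n_responders,
                  rr$n_patients, rr$status))
  }
  invisible(x)
}

#' @rdname cohort_panel
#' @param x,object A `cohort_panel`.
#' @param ... Unused.
#' @method tidy cohort_panel
#' @export
tidy.cohort_panel <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$group_comparison,
                                analysis = "comparison"),
                  section = "group_comparison"),
    dplyr::mutate(x$regressions, section = "regression"),
    dplyr::mutate(dplyr::rename(x$paired_tests,
                                analysis = "drug"),
                  section = "paired_test"),
    dplyr::mutate(x$response_rates,
                  analysis = paste(.data$drug, .data$stratum, .data$level,
                                   sep = "/"),
                  section = "response_rate"))
}

#' @rdname cohort_panel
#' @method glance cohort_panel
#' @export
glance.cohort_panel <- function(x, ...) {
  all_rates <- dplyr::filter(x$response_rates, .data$stratum == "all")
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_ild = sum(x$patients$group == "ILD"),
    n_control = sum(x$patients$group == "control"),
    n_drugs = length(unique(x$responses$drug)),
    group_p = x$group_comparison$p_value[1],
    min_rate_percent = if (nrow(all_rates)) min(all_rates$rate_percent)
                       else NA_integer_,
    max_rate_percent = if (nrow(all_rates)) max(all_rates$rate_percent)
                       else NA_integer_)
}

#' @rdname cohort_panel
#' @method autoplot cohort_panel
#' @export
autoplot.cohort_panel <- function(object, ...) {
  pt <- dplyr::filter(object$patients, !is.na(.data$zoi_baseline))
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$group,
                                   y = .data$zoi_baseline)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "baseline ZOI%",
                  title = "Pulmosphere invasiveness by group")
}

#' Scatter plot of baseline invasiveness against a patient covariate
#'
#' @param panel A [cohort_panel()] result.
#' @param covariate Column of the patient table to plot on x (default
#'   `"fvc_decline"`, i.e. baseline minus follow-up %FVC).
#' @return A ggplot object with the least-squares line.
#' @export
plot_zoi_regression <- function(panel, covariate = "fvc_decline") {
  pt <- dplyr::filter(panel$patients, .data$group == "ILD")
  pt$fvc_decline <- -pt$delta_fvc
  assert_columns(pt, c(covariate, "zoi_baseline"), "panel$patients")
  ggplot2::ggplot(pt, ggplot2::aes(x = .data[[covariate]],
                                   y = .data$zoi_baseline)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = covariate, y = "baseline ZOI%")
}
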