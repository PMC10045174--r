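#' Specify a synthetic pulmosphere cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults emulate the study conditions of an ILD pulmosphere cohort:
#' 23 ILD patients versus 9 explant-donor controls, baseline ZOI% of
#' 516.2 +/- 115.6 (ILD) versus 54.63 +/- 19.6 (controls), 5 replicate
#' spheroids per arm, nintedanib responsive in every patient and pirfenidone
#' in 12 of 23, and a baseline-invasiveness/FVC-decline correlation of 0.80.
#'
#' @param n_ild,n_control Patients per group.
#' @param zoi_mean_ild,zoi_sd_ild,zoi_mean_control,zoi_sd_control Baseline
#'   ZOI% distribution per group (normal, truncated at 0); SDs must be > 0.
#' @param drugs Treated arms to simulate (subset of the names of
#'   `drug_effects`); `character(0)` simulates untreated baselines only.
#' @param drug_effects Named list, one entry per drug, each a list with
#'   `meanlog` and `sdlog`: the lognormal distribution of the per-patient
#'   multiplicative effect on ZOI%. Defaults are centred on the treated/
#'   untreated mean ratios of the emulated study (nintedanib 192/516.9,
#'   pirfenidone 512.3/581.2).
#' @param responder_fraction Named per-drug probability in \[0, 1\] that a
#'   patient's median ZOI fold change falls below 1. Defaults: nintedanib 1
#'   (23/23), pirfenidone 12/23.
#' @param zoi_dfvc_correlation Target Pearson correlation between baseline
#'   ZOI% and FVC decline (baseline %FVC minus follow-up %FVC) among ILD
#'   patients with follow-up, in \[-1, 1\].
#' @param reps_per_arm Replicate spheroids per arm (>= 1, default 5).
#' @param rep_sdlog Lognormal sigma of multiplicative replicate noise on
#'   ZOI% (default 0.15, i.e. ~15% replicate CV).
#' @param p_lost_followup Probability an ILD patient has no follow-up
#'   spirometry (default 4/23, the emulated loss rate).
#' @param seed Master integer seed; every per-patient stream is derived
#'   from it deterministically.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_ild = 23L, n_control = 9L,
                        zoi_mean_ild = 516.2, zoi_sd_ild = 115.6,
                        zoi_mean_control = 54.63, zoi_sd_control = 19.6,
                        drugs = c("nintedanib", "pirfenidone"),
                        drug_effects = list(
                          nintedanib = list(meanlog = log(192 / 516.9),
                                            sdlog = 0.30),
                          pirfenidone = list(meanlog = log(512.3 / 581.2),
                                             sdlog = 0.30)),
                        responder_fraction = c(nintedanib = 1.0,
                                               pirfenidone = 12 / 23),
                        zoi_dfvc_correlation = 0.80,
                        reps_per_arm = 5L,
                        rep_sdlog = 0.15,
                        p_lost_followup = 4 / 23,
                        seed = 1L) {
  assert_scalar_number(n_ild, "n_ild", lower = 0)
  assert_scalar_number(n_control, "n_control", lower = 0)
  for (nm in c("zoi_sd_ild", "zoi_sd_control"))
    assert_scalar_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  assert_scalar_number(zoi_dfvc_correlation, "zoi_dfvc_correlation",
                       lower = -1, upper = 1)
  assert_scalar_number(reps_per_arm, "reps_per_arm", lower = 1)
  assert_scalar_number(rep_sdlog, "rep_sdlog", lower = 0)
  assert_scalar_number(p_lost_followup, "p_lost_followup", lower = 0,
                       upper = 1)
  drugs <- as.character(drugs)
  bad <- setdiff(drugs, names(drug_effects))
  if (length(bad))
    abort(sprintf("no `drug_effects` entry for drug(s): %s",
                  paste(bad, collapse = ", ")))
  for (d in drugs) {
    rf <- responder_fraction[[d]]
    if (is.null(rf) || !is.finite(rf) || rf < 0 || rf > 1)
      abort(sprintf("`responder_fraction[\"%s\"]` must be in [0, 1]", d))
    # realizability: the effect distribution must put usable mass on the
    # required side of 1; refuse rather than silently clamp
    p_below <- stats::plnorm(1, drug_effects[[d]]$meanlog,
                             drug_effects[[d]]$sdlog)
    if (rf > 0 && p_below < 1e-8)
      abort(sprintf(paste0("responder_fraction %.2f for %s cannot be ",
                           "realized: effect distribution has no mass ",
                           "below 1"), rf, d))
    if (rf < 1 && (1 - p_below) < 1e-8)
      abort(sprintf(paste0("responder_fraction %.2f for %s cannot be ",
                           "realized: effect distribution has no mass ",
                           "at or above 1"), rf, d))
  }
  structure(list(
    n_ild = as.integer(n_ild), n_control = as.integer(n_control),
    zoi_mean_ild = zoi_mean_ild, zoi_sd_ild = zoi_sd_ild,
    zoi_mean_control = zoi_mean_control, zoi_sd_control = zoi_sd_control,
    drugs = drugs, drug_effects = drug_effects,
    responder_fraction = responder_fraction,
    zoi_dfvc_correlation = zoi_dfvc_correlation,
    reps_per_arm = as.integer(reps_per_arm), rep_sdlog = rep_sdlog,
    p_lost_followup = p_lost_followup, seed = as.integer(seed)),
    class = "cohort_spec")
}

# ILD diagnosis mix of the emulated cohort (counts 12/6/4/1 of 23),
# allocated to any n by largest remainder so small cohorts stay faithful
.diagnosis_mix <- c("CTD-ILD" = 12, "unclassifiable" = 6,
                    "smoking-related" = 4,
                    "hypersensitivity-pneumonitis" = 1)

allocate_diagnoses <- function(n) {
  if (n == 0) return(character(0))
  q <- .diagnosis_mix / sum(.diagnosis_mix) * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(.diagnosis_mix), times = base)
}

# clinical scales of the emulated cohort; fibronectin DAB intensity and
# Col1a1 relative expression rise monotonically with baseline ZOI%, with
# slopes chosen so the group means land on the reported group values
# (fibronectin 0.075 vs 0.122; Col1a1 0.73 vs 0.97)
.clinical <- list(
  fvc_baseline_mean_ild = 65, fvc_baseline_sd_ild = 12,
  fvc_baseline_mean_control = 95, fvc_baseline_sd_control = 8,
  fvc_decline_mean = 5, fvc_decline_sd = 4,
  followup_months_mean = 7.8, followup_months_sd = 1.3,
  fib_slope = (0.122 - 0.075) / (516.2 - 54.63),
  fib_intercept = 0.075 - (0.122 - 0.075) / (516.2 - 54.63) * 54.63,
  fib_noise_sd = 0.012,
  col_slope = (0.97 - 0.73) / (516.2 - 54.63),
  col_intercept = 0.73 - (0.97 - 0.73) / (516.2 - 54.63) * 54.63,
  col_noise_sd = 0.05)

rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# lognormal draw restricted to effect < 1 (responders) or >= 1
# (nonresponders), via inverse-CDF on the allowed slice
rlnorm_side <- function(meanlog, sdlog, below_one) {
  p1 <- stats::plnorm(1, meanlog, sdlog)
  u <- if (below_one) runif(1, 0, p1) else runif(1, p1, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a synthetic patient cohort with known ground truth
#'
#' Draws a full cohort under a [cohort_spec()]: per-patient baseline ZOI%
#' from the group distribution (truncated at 0), replicate ZOI% values with
#' multiplicative lognormal noise, treated arms scaled by a per-patient drug
#' effect realised so that exactly the specified fraction of patients are
#' responders (median fold change < 1) in expectation, %FVC follow-up drawn
#' so baseline ZOI% and FVC decline correlate at the target Pearson r, and
#' fibronectin / Col1a1 covariates monotone in ZOI% plus noise. Identical
#' spec and seed reproduce the cohort exactly, and each patient's stream is
#' independently derived from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `pulmo_cohort` list of two tibbles: `patients` (one row per
#'   patient, with ground-truth baseline `zoi_truth` and per-drug truth
#'   columns `truth_responder_<drug>`) and `measurements` (one row per
#'   spheroid replicate: `patient_id`, `group`, `arm`, `replicate`, `H`,
#'   `R`, `unit`, `zoi_percent`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(cohort$measurements, arm)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  n <- spec$n_ild + spec$n_control
  groups <- rep(c("ILD", "control"), c(spec$n_ild, spec$n_control))
  ids <- sprintf("%s%02d", ifelse(groups == "ILD", "P", "C"),
                 c(seq_len(spec$n_ild), seq_len(spec$n_control)))
  diagnosis <- c(allocate_diagnoses(spec$n_ild), rep("none", spec$n_control))
  seeds <- if (n > 0) derive_seeds(spec$seed, n + 1) else integer(1)

  rows <- purrr::pmap(list(ids, groups, diagnosis, head(seeds, n)),
                      function(id, grp, dx, sd_i)
                        simulate_patient(id, grp, dx, sd_i, spec))
  patients <- dplyr::bind_rows(purrr::map(rows, "patient"))
  measurements <- dplyr::bind_rows(purrr::map(rows, "measurements"))

  # correlate FVC decline with baseline ZOI% across the ILD group:
  # decline = mu + sd * (r * z + sqrt(1-r^2) * e), z = standardised ZOI%
  if (spec$n_ild > 0) {
    with_seed(seeds[n + 1], {
      ild <- patients$group == "ILD"
      r <- spec$zoi_dfvc_correlation
      z <- (patients$zoi_truth[ild] - spec$zoi_mean_ild) / spec$zoi_sd_ild
      e <- rnorm(sum(ild))
      decline <- .clinical$fvc_decline_mean + .clinical$fvc_decline_sd *
        (r * z + sqrt(1 - r^2) * e)
      followup <- patients$fvc_baseline[ild] - decline
      lost <- runif(sum(ild)) < spec$p_lost_followup
      months <- pmin(12, pmax(6, rnorm(sum(ild),
                                       .clinical$followup_months_mean,
                                       .clinical$followup_months_sd)))
      patients$fvc_followup[ild] <- ifelse(lost, NA_real_, followup)
      patients$followup_months[ild] <- ifelse(lost, NA_real_, months)
    })
  }
  patients$delta_fvc <- patients$fvc_followup - patients$fvc_baseline

  structure(list(patients = patients, measurements = measurements,
                 spec = spec),
            class = "pulmo_cohort")
}

simulate_patient <- function(id, grp, dx, seed_i, spec) {
  with_seed(seed_i, {
    if (grp == "ILD") {
      zoi0 <- rnorm_pos(1, spec$zoi_mean_ild, spec$zoi_sd_ild)
      fvc0 <- rnorm_pos(1, .clinical$fvc_baseline_mean_ild,
                        .clinical$fvc_baseline_sd_ild)
    } else {
      zoi0 <- rnorm_pos(1, spec$zoi_mean_control, spec$zoi_sd_control)
      fvc0 <- rnorm_pos(1, .clinical$fvc_baseline_mean_control,
                        .clinical$fvc_baseline_sd_control)
    }
    fib <- max(0.001, .clinical$fib_intercept + .clinical$fib_slope * zoi0 +
                 rnorm(1, 0, .clinical$fib_noise_sd))
    col <- max(0.01, .clinical$col_intercept + .clinical$col_slope * zoi0 +
                 rnorm(1, 0, .clinical$col_noise_sd))

    reps <- spec$reps_per_arm
    untreated_zoi <- zoi0 * stats::rlnorm(reps, 0, spec$rep_sdlog)
    arms <- list(untreated = untreated_zoi)
    truth <- list()
    if (grp == "ILD") {
      for (d in spec$drugs) {
        is_resp <- runif(1) < spec$responder_fraction[[d]]
        eff <- rlnorm_side(spec$drug_effects[[d]]$meanlog,
                           spec$drug_effects[[d]]$sdlog, is_resp)
        treated <- draw_treated_reps(zoi0, eff, untreated_zoi, is_resp,
                                     reps, spec$rep_sdlog)
        arms[[d]] <- treated
        truth[[paste0("truth_responder_", d)]] <- is_resp
      }
    }
    meas <- purrr::imap(arms, function(zoi, arm) {
      R <- stats::rlnorm(length(zoi), log(5000), 0.2)
      tibble::tibble(patient_id = id, group = grp, arm = arm,
                     replicate = seq_along(zoi),
                     H = R * (1 + zoi / 100), R = R, unit = "px^2",
                     zoi_percent = zoi)
    })
    patient <- tibble::tibble(
      patient_id = id, group = grp, diagnosis = dx,
      fvc_baseline = fvc0, fvc_followup = NA_real_,
      followup_months = NA_real_,
      fibronectin_dab = fib, col1a1_expr = col, zoi_truth = zoi0,
      !!!truth)
    list(patient = patient, measurements = dplyr::bind_rows(meas))
  })
}

# treated replicates whose realised median fold change is guaranteed to sit
# on the drawn responder side of 1: rejection-sample the replicate noise a
# few times, then nudge the effect away from 1 as a last resort
draw_treated_reps <- function(zoi0, eff, untreated_zoi, is_resp, reps,
                              rep_sdlog, max_tries = 200L) {
  denom <- median(untreated_zoi)
  for (i in seq_len(max_tries)) {
    treated <- zoi0 * eff * stats::rlnorm(reps, 0, rep_sdlog)
    ok <- (median(treated) / denom < 1) == is_resp
    if (ok) return(treated)
  }
  target <- if (is_resp) 0.95 else 1.05
  treated * (target * denom / median(treated))
}

#' @export
print.pulmo_cohort <- function(x, ...) {
  cat(sprintf(
    "<pulmo_cohort> %d patients (%d ILD, %d control), %d measurements\n",
    nrow(x$patients), sum(x$patients$group == "ILD"),
    sum(x$patients$group == "control"), nrow(x$measurements)))
  invisible(x)
}
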