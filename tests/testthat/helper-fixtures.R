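# Deterministic cohort fixture that encodes the reported study counts:
# 23 ILD patients (12 CTD-ILD, 6 unclassifiable, 4 smoking-related, 1
# hypersensitivity pneumonitis), 9 controls, nintedanib responsive in all
# 23, pirfenidone in 12 of 23 (10 of the 12 CTD-ILD; 6 of 11 progressors,
# 2 of 8 non-progressors; all 4 patients lost to follow-up responsive),
# replicate ZOI% chosen so every classification is unambiguous.
make_reported_counts_fixture <- function() {
  ild_ids <- sprintf("P%02d", 1:23)
  diagnosis <- c(rep("CTD-ILD", 12), rep("unclassifiable", 6),
                 rep("smoking-related", 4), "hypersensitivity-pneumonitis")
  # progression: P01-P06, P11, P15-P18 progressors (11); P07, P08, P12,
  # P19-P23 non-progressors (8); P09, P10, P13, P14 lost to follow-up (4)
  progressors <- c(sprintf("P%02d", 1:6), "P11", sprintf("P%02d", 15:18))
  lost <- c("P09", "P10", "P13", "P14")
  # pirfenidone responders (12): P01-P10, P13, P14
  pirf_responders <- c(sprintf("P%02d", 1:10), "P13", "P14")

  fvc_followup <- ifelse(ild_ids %in% lost, NA_real_,
                         ifelse(ild_ids %in% progressors, 54, 58))
  followup_months <- ifelse(is.na(fvc_followup), NA_real_, 10)
  patients <- tibble::tibble(
    patient_id = c(ild_ids, sprintf("C%02d", 1:9)),
    group = rep(c("ILD", "control"), c(23, 9)),
    diagnosis = c(diagnosis, rep("none", 9)),
    fvc_baseline = c(rep(60, 23), rep(95, 9)),
    fvc_followup = c(fvc_followup, rep(NA_real_, 9)),
    followup_months = c(followup_months, rep(NA_real_, 9)),
    fibronectin_dab = c(seq(0.09, 0.16, length.out = 23) +
                          0.004 * ((1:23 %% 4) - 1.5),
                        seq(0.06, 0.09, length.out = 9)),
    col1a1_expr = c(seq(0.8, 1.2, length.out = 23) +
                      0.03 * ((1:23 %% 3) - 1),
                    seq(0.65, 0.8, length.out = 9)))

  arm_rows <- function(id, arm, zoi) {
    tibble::tibble(patient_id = id, group = if (grepl("^P", id)) "ILD"
                   else "control",
                   arm = arm, replicate = 1:5, R = 1000,
                   H = 1000 * (1 + zoi / 100), unit = "px^2",
                   zoi_percent = zoi)
  }
  # untreated baselines spread so regressions are non-degenerate
  base_zoi <- seq(420, 640, length.out = 23)
  meas <- list()
  for (i in seq_along(ild_ids)) {
    id <- ild_ids[i]
    z0 <- base_zoi[i] + c(-10, -5, 0, 5, 10)
    meas[[paste0(id, "_u")]] <- arm_rows(id, "untreated", z0)
    nint_scale <- 0.4 + 0.02 * ((i %% 5) - 2)
    meas[[paste0(id, "_n")]] <- arm_rows(id, "nintedanib",
                                         nint_scale * base_zoi[i] +
                                           c(-8, -4, 0, 4, 8))
    pirf_scale <- (if (id %in% pirf_responders) 0.8 else 1.2) +
      0.02 * ((i %% 3) - 1)
    meas[[paste0(id, "_p")]] <- arm_rows(id, "pirfenidone",
                                         pirf_scale * base_zoi[i] +
                                           c(-8, -4, 0, 4, 8))
  }
  for (i in 1:9)
    meas[[paste0("C", i)]] <- arm_rows(sprintf("C%02d", i), "untreated",
                                       50 + 2 * i + c(-2, -1, 0, 1, 2))
  list(patients = patients, measurements = dplyr::bind_rows(meas))
}
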