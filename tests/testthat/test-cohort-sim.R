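test_that("cohort generation is deterministic and schema-complete", {
  spec <- cohort_spec(seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$patients, b$patients)
  expect_identical(a$measurements, b$measurements)
  expect_identical(nrow(a$patients), 32L)
  expect_identical(sum(a$patients$group == "ILD"), 23L)
  expect_identical(sum(a$patients$group == "control"), 9L)
  # 23 ILD x 3 arms x 5 reps + 9 control x 1 arm x 5 reps
  expect_identical(nrow(a$measurements), 23L * 3L * 5L + 9L * 5L)
  expect_true(all(a$measurements$H >= a$measurements$R))
  expect_true(all(a$measurements$R > 0))
  expect_equal(a$measurements$zoi_percent,
               with(a$measurements, (H - R) / R * 100))
  # diagnosis mix reproduces the emulated cohort composition
  tab <- table(a$patients$diagnosis[a$patients$group == "ILD"])
  expect_identical(as.integer(tab[c("CTD-ILD", "unclassifiable",
                                    "smoking-related",
                                    "hypersensitivity-pneumonitis")]),
                   c(12L, 6L, 4L, 1L))
  c2 <- generate_cohort(cohort_spec(seed = 100))
  expect_false(identical(a$measurements$zoi_percent,
                         c2$measurements$zoi_percent))
})

test_that("group distributions are recovered at large n", {
  spec <- cohort_spec(n_ild = 10000, n_control = 10000,
                      drugs = character(0), reps_per_arm = 1, seed = 17)
  cohort <- generate_cohort(spec)
  z <- cohort$patients$zoi_truth
  g <- cohort$patients$group
  expect_lt(abs(mean(z[g == "ILD"]) / spec$zoi_mean_ild - 1), 0.02)
  expect_lt(abs(sd(z[g == "ILD"]) / spec$zoi_sd_ild - 1), 0.05)
  expect_lt(abs(mean(z[g == "control"]) / spec$zoi_mean_control - 1), 0.02)
  expect_lt(abs(sd(z[g == "control"]) / spec$zoi_sd_control - 1), 0.05)
  expect_true(all(z > 0))
})

test_that("responder fractions are realized exactly at the extremes", {
  all_resp <- generate_cohort(cohort_spec(
    drugs = "nintedanib", responder_fraction = c(nintedanib = 1),
    seed = 5))
  resp <- drug_response(all_resp$measurements)
  expect_identical(sum(resp$responder), 23L)
  none <- generate_cohort(cohort_spec(
    drugs = "nintedanib", responder_fraction = c(nintedanib = 0),
    seed = 5))
  expect_identical(sum(drug_response(none$measurements)$responder), 0L)
})

test_that("drawn responder labels always match the realized medians", {
  cohort <- generate_cohort(cohort_spec(seed = 23))
  resp <- drug_response(cohort$measurements)
  truth <- tidyr::pivot_longer(
    dplyr::select(cohort$patients, "patient_id",
                  dplyr::starts_with("truth_responder_")),
    -"patient_id", names_to = "drug", names_prefix = "truth_responder_",
    values_to = "truth")
  truth <- tidyr::drop_na(truth, "truth")
  joined <- dplyr::inner_join(resp, truth, by = c("patient_id", "drug"))
  expect_identical(nrow(joined), nrow(resp))
  expect_identical(joined$responder, joined$truth)
})

test_that("observed responder rate falls inside its exact CI at n = 1000", {
  spec <- cohort_spec(n_ild = 1000, n_control = 0, drugs = "pirfenidone",
                      responder_fraction = c(pirfenidone = 0.52),
                      seed = 29)
  cohort <- generate_cohort(spec)
  rate <- response_rates(drug_response(cohort$measurements))
  expect_true(rate$ci_low <= 0.52 && 0.52 <= rate$ci_high)
})

test_that("null ZOI-FVC correlation stays near zero at n = 500", {
  spec <- cohort_spec(n_ild = 500, n_control = 0, drugs = character(0),
                      reps_per_arm = 1, zoi_dfvc_correlation = 0,
                      p_lost_followup = 0, seed = 41)
  cohort <- generate_cohort(spec)
  decline <- cohort$patients$fvc_baseline - cohort$patients$fvc_followup
  expect_lt(abs(cor(cohort$patients$zoi_truth, decline)), 0.1)
})

test_that("unrealizable responder fractions are rejected, not clamped", {
  expect_error(cohort_spec(
    drugs = "nintedanib",
    drug_effects = list(nintedanib = list(meanlog = log(3), sdlog = 1e-4)),
    responder_fraction = c(nintedanib = 0.5)),
    "cannot be realized")
  expect_error(cohort_spec(
    drugs = "nintedanib",
    drug_effects = list(nintedanib = list(meanlog = log(0.3), sdlog = 1e-4)),
    responder_fraction = c(nintedanib = 0.5)),
    "cannot be realized")
  expect_error(cohort_spec(responder_fraction = c(nintedanib = 1.2,
                                                  pirfenidone = 0.5)),
               "must be in")
})

test_that("a control-only cohort is valid and scores to an empty response set", {
  cohort <- generate_cohort(cohort_spec(n_ild = 0, n_control = 9, seed = 8))
  expect_identical(nrow(cohort$patients), 9L)
  expect_identical(nrow(cohort$measurements), 45L)
  expect_identical(nrow(drug_response(cohort$measurements)), 0L)
})
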