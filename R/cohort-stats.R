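#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. Ties receive midranks.
#' When both samples have at most 8 observations and there are no ties, the
#' p-value is exact, from full enumeration of all group labelings; otherwise
#' it comes from the normal approximation with the tie-corrected variance.
#'
#' @param x,y Numeric samples, each nonempty.
#' @return A one-row tibble: `statistic` (U for sample `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be nonempty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) abort("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))  # midranks
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 <= 8 && n2 <= 8 && !ties) {
    p <- mw_exact_p(c(x, y), n1, U)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                                (N * (N - 1)))
    if (sigma2 <= 0) return(tibble::tibble(statistic = U, p_value = 1,
                                           method = "normal",
                                           n_x = n1, n_y = n2))
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(statistic = U, p_value = p, method = method,
                 n_x = n1, n_y = n2)
}

# exact two-sided p: proportion of labelings whose U is at least as far
# from the null mean n1*n2/2 as the observed U
mw_exact_p <- function(pooled, n1, U_obs) {
  N <- length(pooled)
  ranks <- rank(pooled)
  combs <- utils::combn(N, n1)
  mu <- n1 * (N - n1) / 2
  U_all <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

#' Wilcoxon signed-rank test (two-sided, paired)
#'
#' Paired comparison; zero differences are dropped before ranking, ties among
#' absolute differences receive midranks. With at most 12 nonzero pairs the
#' p-value is exact, from enumeration of all sign assignments on the observed
#' absolute ranks; otherwise the tie-corrected normal approximation is used.
#'
#' @param before,after Paired numeric samples of equal length.
#' @return A one-row tibble: `statistic` (W, sum of positive-difference
#'   ranks, for `after - before`), `p_value`, `method`, `n_pairs` (nonzero),
#'   `all_zero` flag (when every difference is zero, p is 1 with a warning).
#' @examples
#' wilcoxon_signed_rank(c(0, 0, 0, 0), c(1, 2, 3, 4))  # exact p = 0.125
#' @export
wilcoxon_signed_rank <- function(before, after) {
  if (length(before) != length(after) || !length(before))
    abort("`before` and `after` must be nonempty and of equal length")
  d <- as.numeric(after) - as.numeric(before)
  if (anyNA(d)) abort("samples must not contain NA")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p-value is 1")
    return(tibble::tibble(statistic = 0, p_value = 1, method = "exact",
                          n_pairs = 0L, all_zero = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12) {
    # all 2^n sign patterns on the observed midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% r)
    p <- mean(abs(W_all - mu) >= abs(W - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(statistic = W, p_value = p, method = method,
                 n_pairs = n, all_zero = FALSE)
}

#' Simple linear regression with Pearson correlation
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' Pearson r, r squared, and the two-sided p-value of the slope from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x Predictor, non-constant, length >= 3 after pairwise NA removal.
#' @param y Response, same length as `x`.
#' @return A `zoi_regression` tibble row: `slope`, `intercept`, `r`,
#'   `r_squared`, `p_value`, `n`.
#' @examples
#' linear_regression(1:10, 2 * (1:10) + 1)  # r = 1
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete (x, y) pairs")
  if (sd(x) == 0) abort("degenerate predictor: x is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r <- cor(x, y)
  out <- tibble::tibble(slope = unname(coef(fit)[2]),
                        intercept = unname(coef(fit)[1]),
                        r = r, r_squared = r^2,
                        p_value = unname(sm$coefficients[2, 4]),
                        n = n)
  class(out) <- c("zoi_regression", class(out))
  out
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' expression = 2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)):
#' the target gene's qPCR threshold cycle, normalised to a reference gene
#' and expressed relative to a calibrator sample. One extra cycle of the
#' normalised target halves the reported expression.
#'
#' @param ct_target,ct_ref Threshold cycles of target and reference gene in
#'   the sample of interest.
#' @param ct_target_cal,ct_ref_cal The same in the calibrator sample.
#' @return Relative expression (arbitrary units), vectorised.
#' @examples
#' ddct_expression(24, 18, 25, 20)  # ddCt = 1 -> 0.5
#' @export
ddct_expression <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  vals <- c(ct_target, ct_ref, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(vals))) abort("all Ct values must be finite")
  2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))
}

#' Group summary: mean, SD, and t-based confidence interval of the mean
#'
#' @param values Numeric sample, n >= 2 after NA removal.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
summarize_group <- function(values, conf_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("need at least 2 finite values")
  m <- mean(values); s <- sd(values)
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
  tibble::tibble(n = n, mean = m, sd = s,
                 ci_low = m - half, ci_high = m + half)
}

#' Label patients as progressors from FVC decline
#'
#' A progressor shows an absolute %FVC decline of at least `threshold`
#' percentage points of predicted FVC within `window_months` of follow-up.
#' Patients without follow-up spirometry are `undetermined`. Under the
#' `"relative"` rule the decline is instead measured as a percentage of the
#' baseline value.
#'
#' @param patients Data frame with `patient_id`, `fvc_baseline`,
#'   `fvc_followup`, `followup_months`.
#' @param threshold Decline threshold, percentage points (default 5);
#'   boundary inclusive (a decline of exactly 5 is progression).
#' @param window_months Follow-up window (default 12).
#' @param rule `"absolute"` (percentage points of predicted, default) or
#'   `"relative"` (percent of baseline).
#' @return The input as a tibble with `delta_fvc` (follow-up minus
#'   baseline) and `progression` in
#'   `{"progressor", "non-progressor", "undetermined"}`.
#' @export
classify_progressors <- function(patients, threshold = 5,
                                 window_months = 12,
                                 rule = c("absolute", "relative")) {
  rule <- match.arg(rule)
  assert_columns(patients, c("patient_id", "fvc_baseline", "fvc_followup",
                             "followup_months"), "patients")
  out <- tibble::as_tibble(patients)
  out$delta_fvc <- out$fvc_followup - out$fvc_baseline
  decline <- switch(rule,
    absolute = -out$delta_fvc,
    relative = -100 * out$delta_fvc / out$fvc_baseline)
  out$progression <- dplyr::case_when(
    is.na(out$fvc_followup) | is.na(out$followup_months) ~ "undetermined",
    decline >= threshold & out$followup_months <= window_months ~
      "progressor",
    TRUE ~ "non-progressor")
  out
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
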