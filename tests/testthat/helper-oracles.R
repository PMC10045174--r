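# Independent oracles used across the suite. Each recomputes the target
# quantity by brute force or enumeration, never through the package's own
# code path.

# Exact binomial (Clopper-Pearson) bounds by root-finding on the binomial
# tail: the smallest/largest p whose probability of an outcome at least as
# extreme as k still exceeds alpha/2.
cp_enumeration_oracle <- function(k, n, conf_level = 0.95) {
  a <- 1 - conf_level
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - a / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# Mann-Whitney U computed from its defining pair counts (not rank sums):
# number of (x, y) pairs with x > y, plus half the ties.
mw_u_pairs <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings,
# measuring extremeness as distance of U from its null mean.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- mw_u_pairs(x, y)
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(idx)
    mw_u_pairs(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all sign
# assignments on the observed absolute differences (zeros dropped).
wsr_enumeration_oracle <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  w_all <- vapply(seq_len(2^n) - 1, function(bits) {
    pos <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1)))
    sum(r[pos])
  }, 0)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Small literal measurement table for scoring tests: one patient, known
# untreated and treated ZOI% values.
make_measurements <- function(patient_id = "P01",
                              untreated = c(100, 100, 100, 100, 100),
                              treated = list(nintedanib = c(50, 60, 70,
                                                            80, 90))) {
  rows <- list(tibble::tibble(patient_id = patient_id, group = "ILD",
                              arm = "untreated",
                              replicate = seq_along(untreated),
                              R = 1000, H = 1000 * (1 + untreated / 100),
                              unit = "px^2", zoi_percent = untreated))
  for (drug in names(treated)) {
    z <- treated[[drug]]
    rows[[drug]] <- tibble::tibble(patient_id = patient_id, group = "ILD",
                                   arm = drug, replicate = seq_along(z),
                                   R = 1000, H = 1000 * (1 + z / 100),
                                   unit = "px^2", zoi_percent = z)
  }
  dplyr::bind_rows(rows)
}
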