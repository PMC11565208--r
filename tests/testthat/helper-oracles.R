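# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers: the operating point is located by exhaustive grid
# search and the one-way ANOVA p-value by a permutation null.

# Brute-force operating point: minimise |supply - demand| over a ci grid.
brute_force_operating_ci <- function(gs_co2, ca, params, step = 0.001) {
  ci <- seq(step, ca, by = step)
  resid <- abs(gs_co2 * (ca - ci) - predict_a(ci, params))
  ci[which.min(resid)]
}

# One-way ANOVA F statistic computed from sums, no lm().
oneway_f <- function(y, g) {
  m <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  grand <- mean(y)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((y - m[as.character(g)])^2)
  (ssb / (length(m) - 1)) / (ssw / (length(y) - length(m)))
}

# Permutation p-value for the one-way F test.
perm_oneway_p <- function(y, g, n_perm = 20000) {
  f0 <- oneway_f(y, g)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (oneway_f(sample(y), g) >= f0) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Random plausible C4 parameter sets with vpmax/vmax in [lo, hi].
random_c4_params <- function(n, ratio_range = c(1.5, 4)) {
  lapply(seq_len(n), function(i) {
    vmax <- stats::runif(1, 20, 70)
    ratio <- stats::runif(1, ratio_range[1], ratio_range[2])
    c4_params(
      vpmax = vmax * ratio,
      vmax = vmax,
      kp = stats::runif(1, 50, 120),
      rd = stats::runif(1, 0.5, 4)
    )
  })
}
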