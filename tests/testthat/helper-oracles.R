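# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (enumeration, closed forms, numerical
# integration) without calling the implementation paths they check.

# Quota oracle: cumulative subtraction of percentage points per completed
# 3-day block, half-up rounding, floor at 3, freeze at the first day
# whose quota lands in {3, 4}.
oracle_quotas <- function(cpd) {
  pts <- 100
  frac <- numeric(21)
  for (d in 1:21) {
    if (d %% 3 == 1) pts <- pts - if (d <= 12) 15 else 10
    frac[d] <- pts / 100
  }
  quota <- integer(21)
  frozen_value <- NA
  for (d in 1:21) {
    if (!is.na(frozen_value)) {
      quota[d] <- frozen_value
    } else {
      cand <- as.integer(floor(frac[d] * cpd + 0.5))
      if (d >= 19L) cand <- min(cand, 4L) # endpoint cap: 3-4 before quit
      q <- max(cand, 3L)
      quota[d] <- q
      if (q <= 4L) frozen_value <- q
    }
  }
  quota
}

# Brute-force day enumerator: list every candidate time, snap each to the
# nearest point of an explicit quarter-hour grid (ties to the later
# quarter), drop times at/past bedtime, deduplicate.
oracle_day_times <- function(cpd, wake, bed, day) {
  quota <- oracle_quotas(cpd)[day]
  week <- if (day <= 7) 1 else if (day <= 14) 2 else 3
  ici <- (bed - wake) / quota
  raw <- wake + 15 * week + (seq_len(quota) - 1) * ici
  grid <- seq(0, 1536, by = 15)
  snapped <- vapply(raw, function(t) {
    d <- abs(grid - t)
    cand <- grid[d == min(d)]
    max(cand) # tie -> later quarter
  }, 0)
  unique(snapped[snapped < bed])
}

random_profile <- function() {
  wake <- sample(seq(240, 600, by = 5), 1)
  bed <- wake + sample(seq(600, 1020, by = 5), 1)
  bed <- min(bed, 1435)
  smoker_profile(sample(10:60, 1), wake, bed)
}

# 2x2 cross-product odds ratio.
oracle_or_2x2 <- function(x1, n1, x0, n0) {
  (x1 * (n0 - x0)) / ((n1 - x1) * x0)
}

# Bivariate normal CDF by one-dimensional numerical integration of the
# conditional-normal representation (independent of the quadrature used
# in the package).
oracle_pbvnorm <- function(h, k, rho) {
  if (abs(rho) == 1) {
    return(if (rho == 1) pnorm(min(h, k)) else
             max(0, pnorm(h) + pnorm(k) - 1))
  }
  stats::integrate(function(x) {
    dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2))
  }, lower = -9, upper = h, rel.tol = 1e-11)$value
}

# Minimal two-group dataset with a y_2wk outcome column, for effect fits.
two_group_data <- function(x_treat, n_treat, x_ctrl, n_ctrl,
                           labels = c("SSNP", "EUC")) {
  data.frame(
    arm = factor(rep(labels, c(n_treat, n_ctrl)),
                 levels = c("SSNP", "SS", "EUC")),
    y_2wk = c(rep(1:0, c(x_treat, n_treat - x_treat)),
              rep(1:0, c(x_ctrl, n_ctrl - x_ctrl)))
  )
}

# Small, fast trial configuration used where the full arm sizes are not
# the point of the test.
small_config <- function(...) {
  trial_config(n_per_arm = c(SSNP = 120L, SS = 110L, EUC = 130L), ...)
}

full_response <- matrix(1, 3, 4, dimnames = list(c("SSNP", "SS", "EUC"),
                                                 NULL))
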