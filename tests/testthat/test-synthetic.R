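test_that("identical config and seed give byte-identical datasets", {
  cfg <- small_config()
  d1 <- simulate_trial(cfg, seed = 99)
  d2 <- simulate_trial(cfg, seed = 99)
  expect_identical(d1, d2)
  d3 <- simulate_trial(cfg, seed = 100)
  expect_false(identical(d1$co_baseline, d3$co_baseline))
})

test_that("stratified allocation balances within strata and hits targets", {
  # one stratum, n = 6: exact balance
  set.seed(1)
  a <- stratified_allocate(rep("s", 6),
                           c(SSNP = 2L, SS = 2L, EUC = 2L))
  expect_equal(sort(unname(c(table(a)))), c(2L, 2L, 2L))

  # the trial's allocation marginals are achievable
  set.seed(2)
  strata <- sample(letters[1:12], 916, replace = TRUE)
  a <- stratified_allocate(strata, c(SSNP = 306L, SS = 309L, EUC = 301L))
  expect_equal(unname(table(a)[c("SSNP", "SS", "EUC")]),
               c(306L, 309L, 301L), ignore_attr = TRUE)
  # within-stratum balance to within 1 (repair pass can relax a stratum
  # only when no balanced swap exists, which these sizes do not trigger)
  for (s in unique(strata)) {
    cnt <- table(factor(a[strata == s], c("SSNP", "SS", "EUC")))
    expect_lte(max(cnt) - min(cnt), 1)
  }

  # determinism under a fixed seed
  expect_identical(stratified_allocate(strata, c(SSNP = 306L, SS = 309L,
                                                 EUC = 301L), seed = 7),
                   stratified_allocate(strata, c(SSNP = 306L, SS = 309L,
                                                 EUC = 301L), seed = 7))
  expect_error(stratified_allocate(character(0), c(SSNP = 0L)), "empty")
})

test_that("CO pairs always reproduce the compliance class", {
  set.seed(4)
  complier <- rep(c(TRUE, FALSE), each = 500)
  co <- simulate_co(rep(23, 1000), complier)
  expect_true(all(co$co_baseline > 0))
  expect_true(all(co$co_final > 0))
  red <- co_percent_reduction(co$co_baseline, co$co_final)
  expect_equal(classify_compliance(red)$compliant, complier)
  # determinism
  set.seed(4)
  co2 <- simulate_co(rep(23, 1000), complier)
  expect_identical(co, co2)
})

test_that("missingness masks visits at the configured rates", {
  set.seed(6)
  y <- matrix(1L, 4000, 4)
  m <- apply_missingness(y, rep(1, 4))
  expect_true(!anyNA(m))
  m <- apply_missingness(y, rep(0, 4))
  expect_true(all(is.na(m)))
  # EUC 2-week response 239/279: observed fraction within binomial error
  rate <- 239 / 279
  m <- apply_missingness(y, c(rate, 1, 1, 1))
  obs <- mean(!is.na(m[, 1]))
  expect_lt(abs(obs - rate), 4 * sqrt(rate * (1 - rate) / 4000))
})

test_that("generator marginals match the configured probabilities", {
  cfg <- trial_config()
  n <- 2e5
  set.seed(8)
  sim <- simulate_compliance_and_outcome(cfg, "SSNP", n)
  mc <- 4 / sqrt(n)
  expect_lt(abs(mean(sim$complier) - 139 / 273), mc)
  # complier abstinence matches the calibrated target per visit
  for (v in 1:4) {
    p_c <- mean(sim$abstinent[sim$complier, v])
    expect_lt(abs(p_c - cfg$complier_abstinence_prob["SSNP", v]), 3 * mc)
  }
  # control arm uses the configured control probabilities
  set.seed(9)
  sim0 <- simulate_compliance_and_outcome(cfg, "EUC", n)
  expect_true(all(!sim0$complier))
  for (v in 1:4) {
    expect_lt(abs(mean(sim0$abstinent[, v]) -
                    cfg$control_abstinence_prob[v]), 3 * mc)
  }
})

test_that("rho = 0 severs the compliance-abstinence link", {
  cfg <- trial_config(confound_rho = 0)
  set.seed(10)
  sim <- simulate_compliance_and_outcome(cfg, "SSNP", 2e4)
  # noncomplier outcomes are independent of the compliance latent:
  # correlation between u and eps among noncompliers ~ 0
  r <- cor(sim$u[!sim$complier], sim$eps[!sim$complier])
  expect_lt(abs(r), 0.03)
  # compliance_prob = 1 boundary: everyone complies
  cfg1 <- trial_config(compliance_prob = c(SSNP = 1, SS = 71 / 268,
                                           EUC = 0))
  set.seed(11)
  s1 <- simulate_compliance_and_outcome(cfg1, "SSNP", 500)
  expect_true(all(s1$complier))
})

test_that("confounding biases the naive as-treated contrast upward", {
  cfg <- trial_config(confound_rho = 0.5,
                      response_rate = full_response)
  n <- 2e5
  set.seed(12)
  trt <- simulate_compliance_and_outcome(cfg, "SSNP", n)
  ctl <- simulate_compliance_and_outcome(cfg, "EUC", n)
  naive <- mean(trt$abstinent[trt$complier, 1]) - mean(ctl$abstinent[, 1])
  true_late <- cfg$late_target["SSNP", 1]
  expect_gt(naive, true_late + 0.02)
})

test_that("exclusion restriction holds by construction", {
  # participants with identical (latent) complier status have the same
  # outcome law whichever arm they sit in
  cfg <- trial_config(response_rate = full_response)
  n <- 2e5
  tc <- qnorm(cfg$compliance_prob[["SSNP"]])
  set.seed(13)
  trt <- simulate_compliance_and_outcome(cfg, "SSNP", n)
  ctl <- simulate_compliance_and_outcome(cfg, "EUC", n)
  latent_noncomp <- ctl$u >= tc
  p_trt_nc <- mean(trt$abstinent[!trt$complier, 1])
  p_ctl_nc <- mean(ctl$abstinent[latent_noncomp, 1])
  expect_lt(abs(p_trt_nc - p_ctl_nc), 4 / sqrt(n * 0.4))
})

test_that("full dataset has the documented shape and CSV round-trips", {
  d <- simulate_trial(small_config(), seed = 21)
  expect_s3_class(d, "trial_dataset")
  expect_equal(unname(c(table(d$arm))), c(120L, 110L, 130L))
  expect_true(all(d$complier[d$arm == "EUC"] == 0))
  expect_true(all(d$cpd >= 10))
  red <- co_percent_reduction(d$co_baseline, d$co_final)
  expect_equal(classify_compliance(red)$compliant, d$complier == 1)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  back <- read_trial_csv(path)
  expect_equal(back$y_2wk, d$y_2wk)
  expect_equal(levels(back$arm), levels(d$arm))
})

test_that("complier-probability calibration embeds the target effect", {
  # analytic check: the complier effect implied by the calibrated
  # probability equals the requested difference
  for (late in c(0.1, 0.26)) for (rho in c(0, 0.3, 0.6)) {
    p <- calibrate_complier_prob(late, 0.25, 0.509, rho)
    implied <- p - pnorm_cond(qnorm(0.25), qnorm(0.509), rho)
    expect_equal(implied, late, tolerance = 1e-10)
  }
  expect_error(calibrate_complier_prob(0.9, 0.8, 0.5, 0.3), "incompatible")
})
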