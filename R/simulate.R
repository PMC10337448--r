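# Seeded synthetic three-arm trial generator.
#
# Structural model, per participant i with assignment Z (scheduled arm or
# control) and latent bivariate-normal errors (u, eps) with correlation
# `confound_rho`:
#
#   complier:   C_i = 1{ u_i < qnorm(pi_c[arm]) }   (scheduled arms only)
#   abstinent:  Y_iv = 1{ eps_i < b0_v + delta[arm, v] * C_i }
#
# The single eps shared across the four follow-up visits induces the
# within-person persistence of abstinence; the correlation between u and
# eps is the unobserved confounding between compliance and abstinence that
# the IV stage must remove. Controls have C = 0 structurally (nothing to
# comply with), and by default noncompliers' outcome threshold equals the
# control threshold b0_v, so assignment affects abstinence only through
# compliance (the exclusion restriction holds by construction).
# delta[arm, v] is calibrated so the complier-conditional causal effect
# equals the configured `late_target`.

.visits <- c("2wk", "4wk", "6mo", "12mo")
.arms <- c("SSNP", "SS", "EUC")

solve_cond_threshold <- function(p, a, rho, lower = TRUE) {
  # b such that P(eps < b | u < a) = p (or u >= a when lower = FALSE)
  vapply(seq_along(p), function(i) {
    stats::uniroot(function(b) pnorm_cond(b, a, rho, lower = lower) - p[i],
                   lower = -10, upper = 10, tol = 1e-10)$root
  }, 0)
}

#' Complier abstinence probability implied by a target complier effect
#'
#' Given the control abstinence probability, the compliance propensity and
#' the compliance-abstinence error correlation, returns the
#' complier-conditional abstinence probability whose complier causal effect
#' (abstinence probability among compliers minus their counterfactual
#' no-compliance probability) equals `late`.
#'
#' @param late target complier probability difference (vectorized).
#' @param control_prob control-arm abstinence probability (same length).
#' @param compliance_prob proportion of the arm complying.
#' @param rho latent error correlation.
#' @return complier abstinence probability.
#' @export
calibrate_complier_prob <- function(late, control_prob, compliance_prob,
                                    rho) {
  tc <- stats::qnorm(compliance_prob)
  b0 <- stats::qnorm(control_prob)
  p <- late + pnorm_cond(b0, tc, rho)
  if (any(p >= 1 | p <= 0)) {
    stop("target complier effect is incompatible with the control rate")
  }
  p
}

#' Synthetic trial configuration
#'
#' Defaults reproduce the stated design: analyzable arm sizes 273/268/279
#' (SSNP/SS/EUC), compliance propensities 139/273 and 71/268 for the two
#' scheduled arms (controls have nothing to comply with), per-visit
#' response rates taken from the reported follow-up counts, and complier
#' abstinence probabilities calibrated so that the generating complier
#' causal effects equal `late_target` at the configured confounding.
#' Control abstinence probabilities and the baseline-CO model are not
#' reported quantities; the defaults are synthetic placeholders (25% early
#' control abstinence tapering to 15%; CO roughly 25 ppm at 23 cig/day).
#'
#' @param n_per_arm named integer vector of arm sizes (SSNP, SS, EUC).
#' @param compliance_prob named per-arm probability of achieving the >=50%
#'   CO reduction; EUC must be 0.
#' @param control_abstinence_prob per-visit control abstinence probability
#'   (visits 2wk, 4wk, 6mo, 12mo).
#' @param late_target matrix (scheduled arm x visit) of complier
#'   probability differences the generator should embed.
#' @param complier_abstinence_prob optional matrix (scheduled arm x visit)
#'   of complier-conditional abstinence probabilities; when supplied it
#'   overrides `late_target`.
#' @param noncomplier_abstinence_prob optional matrix (scheduled arm x
#'   visit). `NULL` (default) means noncompliers share the control
#'   threshold, which is what the exclusion restriction requires; supply
#'   values only to deliberately break the exclusion restriction.
#' @param confound_rho correlation in (-1, 1) between the latent compliance
#'   and abstinence errors; 0 means compliance is ignorable.
#' @param response_rate matrix (arm x visit) of per-visit observation
#'   probabilities.
#' @param co_baseline_model list with `mean_per_cpd`, `sd`, `min`: baseline
#'   expired CO is normal with mean `mean_per_cpd * cpd`, truncated below
#'   at `min` ppm.
#' @return object of class `trial_config`, including the derived structural
#'   thresholds used by the generator.
#' @export
trial_config <- function(
    n_per_arm = c(SSNP = 273L, SS = 268L, EUC = 279L),
    compliance_prob = c(SSNP = 139 / 273, SS = 71 / 268, EUC = 0),
    control_abstinence_prob = c("2wk" = 0.25, "4wk" = 0.25,
                                "6mo" = 0.18, "12mo" = 0.15),
    late_target = rbind(SSNP = c(0.26, 0.29, 0.26, 0.22),
                        SS   = c(0.27, 0.33, 0.29, 0.28)),
    complier_abstinence_prob = NULL,
    noncomplier_abstinence_prob = NULL,
    confound_rho = 0.3,
    response_rate = rbind(SSNP = c(212, 192, 171, 151) / 273,
                          SS   = c(207, 196, 170, 137) / 268,
                          EUC  = c(239, 221, 186, 158) / 279),
    co_baseline_model = list(mean_per_cpd = 25 / 23, sd = 8, min = 2)) {
  stopifnot(all(.arms %in% names(n_per_arm)),
            all(n_per_arm > 0),
            all(compliance_prob >= 0 & compliance_prob <= 1),
            compliance_prob[["EUC"]] == 0,
            length(control_abstinence_prob) == 4L,
            all(control_abstinence_prob > 0 & control_abstinence_prob < 1),
            abs(confound_rho) < 1,
            all(response_rate >= 0 & response_rate <= 1))
  colnames(late_target) <- .visits
  colnames(response_rate) <- .visits
  names(control_abstinence_prob) <- .visits

  sched <- c("SSNP", "SS")
  b0 <- stats::qnorm(control_abstinence_prob)
  if (is.null(complier_abstinence_prob)) {
    complier_abstinence_prob <- late_target
    for (a in sched) {
      complier_abstinence_prob[a, ] <- calibrate_complier_prob(
        late_target[a, ], control_abstinence_prob,
        compliance_prob[[a]], confound_rho)
    }
  } else {
    colnames(complier_abstinence_prob) <- .visits
  }

  # Structural thresholds: eps < b1 for compliers, eps < b0 (control) or a
  # bespoke noncomplier threshold when the exclusion restriction is broken.
  b1 <- late_target * NA_real_
  for (a in sched) {
    b1[a, ] <- solve_cond_threshold(
      complier_abstinence_prob[a, ], stats::qnorm(compliance_prob[[a]]),
      confound_rho, lower = TRUE)
  }
  bnc <- NULL
  if (!is.null(noncomplier_abstinence_prob)) {
    colnames(noncomplier_abstinence_prob) <- .visits
    bnc <- noncomplier_abstinence_prob * NA_real_
    for (a in sched) {
      bnc[a, ] <- solve_cond_threshold(
        noncomplier_abstinence_prob[a, ], stats::qnorm(compliance_prob[[a]]),
        confound_rho, lower = FALSE)
    }
  }

  structure(
    list(n_per_arm = n_per_arm[.arms],
         compliance_prob = compliance_prob[.arms],
         control_abstinence_prob = control_abstinence_prob,
         late_target = late_target,
         complier_abstinence_prob = complier_abstinence_prob,
         noncomplier_abstinence_prob = noncomplier_abstinence_prob,
         confound_rho = confound_rho,
         response_rate = response_rate[.arms, , drop = FALSE],
         co_baseline_model = co_baseline_model,
         thresholds = list(b0 = b0, b1 = b1, bnc = bnc)),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat("  arms:", paste(sprintf("%s=%d", names(x$n_per_arm), x$n_per_arm),
                       collapse = ", "), "\n")
  cat("  compliance propensity:",
      paste(sprintf("%s=%.3f", names(x$compliance_prob), x$compliance_prob),
            collapse = ", "), "\n")
  cat(sprintf("  confounding rho: %.2f\n", x$confound_rho))
  invisible(x)
}

#' Stratified three-arm allocation
#'
#' Assigns arms within each stratum so that arm counts are balanced to
#' within one inside every stratum while the marginal arm totals match the
#' configured targets. Stratum remainders go to the arms furthest below
#' target; a final within-stratum swap pass repairs any residual marginal
#' discrepancy.
#'
#' @param strata a factor (or object coercible to one, e.g. an
#'   `interaction()` of covariates) with one element per participant.
#' @param n_per_arm named vector of target arm totals summing to
#'   `length(strata)`.
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @return character vector of arm labels, one per participant.
#' @export
stratified_allocate <- function(strata, n_per_arm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strata <- as.factor(strata)
  n <- length(strata)
  if (n == 0L) stop("empty strata table")
  if (sum(n_per_arm) != n) {
    stop("arm totals must sum to the number of participants")
  }
  arms <- names(n_per_arm)
  k <- length(arms)
  assigned <- stats::setNames(numeric(k), arms)
  out <- character(n)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    ns <- length(idx)
    base <- ns %/% k
    counts <- stats::setNames(rep(base, k), arms)
    rem <- ns %% k
    if (rem > 0) {
      deficit <- n_per_arm - (assigned + counts)
      extra <- arms[order(-deficit, stats::runif(k))][seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    labels <- sample(rep(arms, counts))
    out[idx] <- labels
    assigned <- assigned + counts
  }
  # Repair pass: swap between over- and under-target arms inside strata
  # where the swap keeps the within-stratum counts balanced to within 1.
  for (guard in seq_len(4 * n)) {
    deficit <- n_per_arm - table(factor(out, levels = arms))
    if (all(deficit == 0)) break
    a_over <- arms[which.min(deficit)]
    a_under <- arms[which.max(deficit)]
    done <- FALSE
    for (s in sample(levels(strata))) {
      idx <- which(strata == s)
      cnt <- table(factor(out[idx], levels = arms))
      if (cnt[[a_over]] > cnt[[a_under]]) {
        swap <- sample(idx[out[idx] == a_over], 1L)
        out[swap] <- a_under
        done <- TRUE
        break
      }
    }
    if (!done) {
      # No balance-preserving swap exists; relax within-stratum balance for
      # one participant rather than fail (keeps marginals exact).
      swap <- sample(which(out == a_over), 1L)
      out[swap] <- a_under
    }
  }
  out
}

#' Draw compliance and visit-wise abstinence for one arm
#'
#' Draws the latent `(u, eps)` pair and applies the structural thresholds
#' (see [trial_config()]). Uses the current RNG stream.
#'
#' @param config a [trial_config()].
#' @param arm `"SSNP"`, `"SS"` or `"EUC"`.
#' @param n number of participants to draw.
#' @return list with `complier` (logical), `abstinent` (n x 4 logical
#'   matrix, one column per visit), and the latent draws `u`, `eps`.
#' @export
simulate_compliance_and_outcome <- function(config, arm, n) {
  stopifnot(inherits(config, "trial_config"), arm %in% .arms)
  rho <- config$confound_rho
  u <- stats::rnorm(n)
  eps <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
  th <- config$thresholds
  if (arm == "EUC") {
    complier <- rep(FALSE, n)
    b <- matrix(th$b0, n, 4, byrow = TRUE)
  } else {
    pc <- config$compliance_prob[[arm]]
    complier <- u < stats::qnorm(pc)
    b_nc <- if (is.null(th$bnc)) th$b0 else th$bnc[arm, ]
    b <- matrix(b_nc, n, 4, byrow = TRUE)
    b[complier, ] <- matrix(th$b1[arm, ], sum(complier), 4, byrow = TRUE)
  }
  abstinent <- eps < b
  colnames(abstinent) <- .visits
  list(complier = complier, abstinent = abstinent, u = u, eps = eps)
}

#' Simulate baseline and final expired CO consistent with a compliance flag
#'
#' Baseline CO follows the configured (synthetic placeholder) model given
#' cigarettes/day; the final precessation CO is generated as
#' `co_baseline * (1 - r)` with the reduction fraction `r` drawn above the
#' 50% cutoff for compliers and below it for noncompliers, so the CO pair
#' always reproduces the participant's compliance class. Uses the current
#' RNG stream.
#'
#' @param baseline_cpd cigarettes/day vector.
#' @param complier logical vector.
#' @param model baseline CO model (see [trial_config()]).
#' @return data.frame with `co_baseline`, `co_final` (ppm, positive).
#' @export
simulate_co <- function(baseline_cpd, complier,
                        model = list(mean_per_cpd = 25 / 23, sd = 8,
                                     min = 2)) {
  stopifnot(all(baseline_cpd > 0), length(complier) == length(baseline_cpd))
  n <- length(baseline_cpd)
  co_baseline <- pmax(stats::rnorm(n, model$mean_per_cpd * baseline_cpd,
                                   model$sd), model$min)
  # Margins of 0.005 around the cutoff keep the classification robust to
  # floating-point round-trip through co_final.
  r <- ifelse(complier, stats::runif(n, 0.505, 0.85),
              stats::runif(n, -0.20, 0.495))
  data.frame(co_baseline = co_baseline, co_final = co_baseline * (1 - r))
}

#' Mask visit outcomes by per-visit response rates
#'
#' Each visit is observed independently with its response probability
#' (missing at random given arm); unobserved visits become `NA`. Uses the
#' current RNG stream.
#'
#' @param abstinent n x 4 logical or 0/1 matrix of true visit outcomes.
#' @param response_rate length-4 vector of observation probabilities.
#' @return integer matrix with values 0, 1 or `NA`.
#' @export
apply_missingness <- function(abstinent, response_rate) {
  stopifnot(all(response_rate >= 0 & response_rate <= 1))
  abstinent <- as.matrix(abstinent) * 1L
  n <- nrow(abstinent)
  for (v in seq_len(ncol(abstinent))) {
    observed <- stats::runif(n) < response_rate[v]
    abstinent[!observed, v] <- NA_integer_
  }
  abstinent
}

draw_covariates <- function(n) {
  data.frame(
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.495, 0.505)),
    race = sample(c("european_american", "african_american",
                    "hispanic_or_other"), n, TRUE,
                  prob = c(0.73, 0.17, 0.10)),
    education = sample(c("le_high_school", "some_college", "ge_college"),
                       n, TRUE, prob = c(0.20, 0.46, 0.34)),
    age = round(pmin(pmax(stats::rnorm(n, 43, 11), 18), 80)),
    cpd = pmax(round(stats::rnorm(n, 23, 10)), 10),
    dep_hx = stats::rbinom(n, 1, 0.25)
  )
}

#' Simulate a full three-arm trial dataset
#'
#' Draws covariates, performs stratified allocation (sex x race x
#' above/below-median cigarettes/day x depression history), generates
#' confounded compliance and visit-wise abstinence, CO pairs consistent
#' with the compliance class, and visit missingness. Bit-reproducible for
#' a fixed `(config, seed)`.
#'
#' @param config a [trial_config()].
#' @param seed integer seed.
#' @return data.frame of class `trial_dataset` with one row per
#'   participant: `id`, `arm`, covariates, `co_baseline`, `co_final`,
#'   `complier` (0/1), and `y_2wk`, `y_4wk`, `y_6mo`, `y_12mo` in
#'   \{0, 1, NA\}. The config and seed are attached as attributes.
#' @examples
#' d <- simulate_trial(trial_config(), seed = 1)
#' table(d$arm, d$complier)
#' @export
simulate_trial <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(seed)
  n <- sum(config$n_per_arm)
  cov <- draw_covariates(n)
  strata <- interaction(cov$sex, cov$race, cov$cpd >= 20, cov$dep_hx,
                        drop = TRUE)
  arm <- stratified_allocate(strata, config$n_per_arm)

  complier <- logical(n)
  y <- matrix(NA_integer_, n, 4, dimnames = list(NULL, .visits))
  for (a in .arms) {
    idx <- which(arm == a)
    sim <- simulate_compliance_and_outcome(config, a, length(idx))
    complier[idx] <- sim$complier
    y[idx, ] <- apply_missingness(sim$abstinent,
                                  config$response_rate[a, ])
  }
  co <- simulate_co(cov$cpd, complier, config$co_baseline_model)

  out <- data.frame(id = seq_len(n),
                    arm = factor(arm, levels = .arms),
                    cov, co, complier = as.integer(complier))
  out$y_2wk <- y[, "2wk"]
  out$y_4wk <- y[, "4wk"]
  out$y_6mo <- y[, "6mo"]
  out$y_12mo <- y[, "12mo"]
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("trial_dataset", "data.frame")
  out
}

#' Write / read a simulated trial as CSV
#'
#' One row per participant; visit outcomes are 0/1 with empty cells for
#' missing visits.
#'
#' @param dataset a `trial_dataset` (or compatible data.frame).
#' @param path file path.
#' @return `write_trial_csv` returns the path invisibly; `read_trial_csv`
#'   returns a data.frame with the same column types as
#'   [simulate_trial()] output.
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  d$arm <- factor(d$arm, levels = .arms)
  for (col in c("sex", "race", "education")) d[[col]] <- factor(d[[col]])
  d
}
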