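# Compliance-adjusted causal estimation.
#
# Two estimators of the complier (local) average treatment effect under
# one-sided noncompliance (controls cannot receive the scheduled-smoking
# treatment, so C = 0 is structural in the control arm):
#
#   * the Bloom estimator: ITT rate difference divided by the treated-arm
#     complier proportion, with a nonparametric bootstrap CI;
#   * a two-equation probit with endogenous binary compliance, estimated
#     by full-information maximum likelihood, whose cross-equation error
#     correlation rho absorbs the unobserved confounding between
#     compliance and abstinence. Complier probability differences are
#     averaged over the complier covariate distribution conditional on
#     complying, with delta-method CIs.

#' Bloom decomposition of an ITT effect
#'
#' The ITT abstinence rate in a scheduled arm is the mixture
#' `pi_c * rate_compliers + (1 - pi_c) * rate_noncompliers`. Under
#' one-sided noncompliance and the exclusion restriction, the complier
#' average causal effect is the ITT rate difference divided by the
#' complier proportion.
#'
#' @param itt_rate_treated ITT abstinence rate in the treated arm.
#' @param itt_rate_control ITT abstinence rate in the control arm.
#' @param prop_compliers complier proportion `pi_c` in (0, 1].
#' @return object of class `itt_decomposition` with the inputs and
#'   `late_estimate`.
#' @examples
#' bloom_late(0.20, 0.10, 0.50)$late_estimate # 0.20
#' @export
bloom_late <- function(itt_rate_treated, itt_rate_control, prop_compliers) {
  if (prop_compliers <= 0 || prop_compliers > 1) {
    stop("prop_compliers must lie in (0, 1]; the complier effect is ",
         "undefined when nobody complies")
  }
  structure(
    list(itt_rate_treated = itt_rate_treated,
         itt_rate_control = itt_rate_control,
         prop_compliers = prop_compliers,
         late_estimate = (itt_rate_treated - itt_rate_control) /
           prop_compliers),
    class = "itt_decomposition"
  )
}

#' Uncentered variant: overall ITT rate divided by the complier proportion
#'
#' Provided for fidelity with the shortcut formula that omits the
#' control-arm subtraction; [bloom_late()] (control-subtracted) is the
#' default estimator.
#'
#' @inheritParams bloom_late
#' @return the ratio `itt_rate_treated / prop_compliers`.
#' @export
bloom_late_uncentered <- function(itt_rate_treated, prop_compliers) {
  if (prop_compliers <= 0 || prop_compliers > 1) {
    stop("prop_compliers must lie in (0, 1]")
  }
  itt_rate_treated / prop_compliers
}

# Rates needed by the Bloom estimator from one treated arm + control.
bloom_components <- function(dataset, arm, control, visit, rule) {
  y <- outcome_vector(dataset, visit, rule)
  keep <- !is.na(y)
  trt <- keep & dataset$arm == arm
  ctl <- keep & dataset$arm == control
  if (!any(trt) || !any(ctl)) stop("empty arm after rule application")
  list(itt_treated = mean(y[trt]),
       itt_control = mean(y[ctl]),
       prop_compliers = mean(dataset$complier[dataset$arm == arm] == 1),
       rate_compliers = mean(y[trt & dataset$complier == 1]),
       rate_noncompliers = mean(y[trt & dataset$complier == 0]))
}

#' Bloom complier-effect estimate from a trial dataset with bootstrap CI
#'
#' Computes the ITT rates and treated-arm complier proportion from the
#' data, applies [bloom_late()], and attaches a percentile bootstrap CI
#' from participant resampling stratified by arm.
#'
#' @param dataset a trial dataset.
#' @param arm treated (scheduled) arm, `"SSNP"` or `"SS"`.
#' @param control control arm label, default `"EUC"`.
#' @param visit visit label.
#' @param rule `"ITT"` or `"RO"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed optional seed for the bootstrap.
#' @param conf_level confidence level.
#' @return object of class `late_result` with `difference`, `ci_low`,
#'   `ci_high`, `p_value` (normal approximation from the bootstrap SE),
#'   the decomposition, and bookkeeping fields.
#' @export
bloom_late_fit <- function(dataset, arm = "SSNP", control = "EUC",
                           visit = "2wk", rule = c("ITT", "RO"),
                           n_boot = 2000, seed = NULL, conf_level = 0.95) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  comp <- bloom_components(dataset, arm, control, visit, rule)
  est <- bloom_late(comp$itt_treated, comp$itt_control,
                    comp$prop_compliers)

  idx_t <- which(dataset$arm == arm)
  idx_c <- which(dataset$arm == control)
  boots <- vapply(seq_len(n_boot), function(b) {
    rows <- c(sample(idx_t, replace = TRUE), sample(idx_c, replace = TRUE))
    cb <- bloom_components(dataset[rows, , drop = FALSE], arm, control,
                           visit, rule)
    if (cb$prop_compliers == 0) return(NA_real_)
    (cb$itt_treated - cb$itt_control) / cb$prop_compliers
  }, 0)
  boots <- boots[!is.na(boots)]
  alpha <- 1 - conf_level
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  se <- stats::sd(boots)
  structure(
    list(contrast = paste(arm, "vs", control),
         difference = est$late_estimate,
         ci_low = ci[1], ci_high = ci[2],
         p_value = 2 * stats::pnorm(-abs(est$late_estimate / se)),
         population = rule, visit = visit, method = "bloom",
         decomposition = est, n_boot = length(boots), boot_se = se),
    class = "late_result"
  )
}

#' @export
print.late_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s, %s, %s]: difference %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
    x$contrast, x$population, x$visit, x$method,
    x$difference, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

# ---------------------------------------------------------------------------
# FIML bivariate probit with endogenous binary compliance.

biprobit_loglik <- function(theta, Z, C, Y, Xz, Xy) {
  pz <- ncol(Xz)
  py <- ncol(Xy)
  gamma <- theta[seq_len(pz)]
  beta <- theta[pz + seq_len(py)]
  delta <- theta[pz + py + 1]
  rho <- tanh(theta[pz + py + 2])
  zg <- drop(Xz %*% gamma)
  xb <- drop(Xy %*% beta)
  qy <- 2 * Y - 1
  ll <- numeric(length(Y))
  t1 <- Z == 1 & C == 1
  t0 <- Z == 1 & C == 0
  ct <- Z == 0
  ll[t1] <- log(pmax(pbvnorm(zg[t1], qy[t1] * (xb[t1] + delta),
                             qy[t1] * rho), 1e-300))
  ll[t0] <- log(pmax(pbvnorm(-zg[t0], qy[t0] * xb[t0],
                             -qy[t0] * rho), 1e-300))
  ll[ct] <- stats::pnorm(qy[ct] * xb[ct], log.p = TRUE)
  sum(ll)
}

#' FIML bivariate probit with endogenous binary compliance
#'
#' Joint model for one-sided noncompliance: among assigned-to-treatment
#' participants, compliance follows a probit `C = 1\{z'gamma + u > 0\}`;
#' the outcome follows `Y = 1\{x'beta + delta C + e > 0\}` for everyone;
#' and `(u, e)` are standard bivariate normal with correlation `rho`.
#' Controls have `C = 0` structurally and contribute only through the
#' outcome margin. The likelihood over the four treated `(C, Y)` cells
#' uses the bivariate normal CDF and is maximized on the `atanh(rho)`
#' scale (keeping `|rho| < 1`) by BFGS; the coefficient covariance comes
#' from the observed information at the optimum.
#'
#' @param Z binary assignment indicator (the instrument).
#' @param C binary compliance; must be 0 wherever `Z = 0`.
#' @param Y binary outcome.
#' @param X optional numeric covariate matrix (or data.frame of numeric
#'   columns / factors, expanded via [stats::model.matrix()]) entering
#'   both equations.
#' @param compute_vcov set `FALSE` to skip the observed-information
#'   covariance (faster in simulation loops).
#' @param control passed to [stats::optim()].
#' @return object of class `biprobit`: `gamma`, `beta`, `delta`, `rho`,
#'   `loglik`, `vcov` (on the internal parameter scale, last element
#'   `atanh(rho)`), convergence diagnostics, and the data needed for
#'   post-estimation.
#' @export
fit_biprobit <- function(Z, C, Y, X = NULL, compute_vcov = TRUE,
                         control = list(maxit = 500)) {
  stopifnot(all(Z %in% 0:1), all(C %in% 0:1), all(Y %in% 0:1))
  if (any(C == 1 & Z == 0)) {
    stop("one-sided noncompliance requires C = 0 whenever Z = 0")
  }
  n <- length(Y)
  if (is.null(X)) {
    Xmat <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xmat <- stats::model.matrix(~ ., data = as.data.frame(X))
  }
  Xz <- Xmat
  Xy <- Xmat
  pz <- ncol(Xz)
  py <- ncol(Xy)

  # Starting values: probit of C among treated; probit of Y on C overall.
  treated <- Z == 1
  g0 <- stats::glm.fit(Xz[treated, , drop = FALSE], C[treated],
                       family = stats::binomial("probit"))$coefficients
  b0 <- stats::glm.fit(cbind(Xy, C), Y,
                       family = stats::binomial("probit"))$coefficients
  start <- c(g0, b0[seq_len(py)], b0[py + 1], 0)
  start[!is.finite(start)] <- 0

  neg <- function(th) -biprobit_loglik(th, Z, C, Y, Xz, Xy)
  opt <- stats::optim(start, neg, method = "BFGS", control = control)
  if (opt$convergence != 0) {
    stop("biprobit FIML did not converge (optim code ", opt$convergence,
         "; negative log-likelihood ", format(opt$value), ")")
  }
  theta <- opt$par
  rho <- tanh(theta[pz + py + 2])
  vc <- NULL
  if (compute_vcov) {
    H <- stats::optimHess(theta, neg)
    vc <- tryCatch(solve(H), error = function(e) {
      warning("observed information is singular; vcov unavailable")
      NULL
    })
  }
  if (abs(rho) > 0.995) {
    warning("estimated |rho| is at the boundary (", round(rho, 4), ")")
  }
  structure(
    list(gamma = stats::setNames(theta[seq_len(pz)], colnames(Xz)),
         beta = stats::setNames(theta[pz + seq_len(py)], colnames(Xy)),
         delta = theta[pz + py + 1],
         rho = rho,
         theta = theta, vcov = vc,
         loglik = -opt$value,
         n = n, pz = pz, py = py,
         data = list(Z = Z, C = C, Y = Y, Xz = Xz, Xy = Xy)),
    class = "biprobit"
  )
}

#' @export
print.biprobit <- function(x, ...) {
  cat("Bivariate probit with endogenous compliance (FIML)\n")
  cat(sprintf("  n = %d, logLik = %.2f, rho = %.3f\n",
              x$n, x$loglik, x$rho))
  cat(sprintf("  compliance effect on outcome (probit scale): %.3f\n",
              x$delta))
  invisible(x)
}

#' @export
logLik.biprobit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

# ATT over compliers implied by parameter vector theta.
biprobit_att <- function(theta, model) {
  pz <- model$pz
  py <- model$py
  gamma <- theta[seq_len(pz)]
  beta <- theta[pz + seq_len(py)]
  delta <- theta[pz + py + 1]
  rho <- tanh(theta[pz + py + 2])
  d <- model$data
  comp <- d$Z == 1 & d$C == 1
  if (!any(comp)) stop("no compliers in the data: effect undefined")
  zg <- drop(d$Xz[comp, , drop = FALSE] %*% gamma)
  xb <- drop(d$Xy[comp, , drop = FALSE] %*% beta)
  denom <- stats::pnorm(zg)
  p1 <- pbvnorm(zg, xb + delta, rho) / denom
  p0 <- pbvnorm(zg, xb, rho) / denom
  mean(p1 - p0)
}

#' Complier abstinence probability difference from a fitted biprobit
#'
#' Averages, over the compliers' covariate distribution and conditional on
#' complying, the model-implied abstinence probability with compliance set
#' to 1 minus the probability with compliance set to 0:
#' `mean( Phi2(z'g, x'b + d, rho) / Phi(z'g)
#'      - Phi2(z'g, x'b, rho) / Phi(z'g) )`.
#' The CI is by the delta method (numerical gradient against the FIML
#' covariance).
#'
#' @param model a fitted [fit_biprobit()] object with `vcov` available.
#' @param contrast label for the result (e.g. `"SSNP vs EUC"`).
#' @param visit,population bookkeeping labels carried into the result.
#' @param conf_level confidence level.
#' @return object of class `late_result`.
#' @export
complier_effect_probabilities <- function(model, contrast = "treated vs control",
                                          visit = NA_character_,
                                          population = "ITT",
                                          conf_level = 0.95) {
  stopifnot(inherits(model, "biprobit"))
  est <- biprobit_att(model$theta, model)
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  p <- NA_real_
  if (!is.null(model$vcov)) {
    k <- length(model$theta)
    grad <- numeric(k)
    for (j in seq_len(k)) {
      h <- 1e-5 * (1 + abs(model$theta[j]))
      up <- dn <- model$theta
      up[j] <- up[j] + h
      dn[j] <- dn[j] - h
      grad[j] <- (biprobit_att(up, model) - biprobit_att(dn, model)) /
        (2 * h)
    }
    se <- sqrt(drop(t(grad) %*% model$vcov %*% grad))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- est + c(-1, 1) * z * se
    p <- 2 * stats::pnorm(-abs(est / se))
  }
  structure(
    list(contrast = contrast, difference = est,
         ci_low = ci[1], ci_high = ci[2], p_value = p, se = se,
         population = population, visit = visit, method = "biprobit"),
    class = "late_result"
  )
}

#' Fit the biprobit LATE for one scheduled arm versus control
#'
#' Convenience wrapper: subsets the dataset to `arm` and `control`, builds
#' the assignment instrument, compliance and rule-specific outcome, fits
#' [fit_biprobit()] and returns [complier_effect_probabilities()].
#'
#' @inheritParams bloom_late_fit
#' @param covariates optional covariate columns for both equations.
#' @param compute_vcov passed through (disable in tight loops).
#' @return list with elements `model` (the `biprobit`) and `result` (the
#'   `late_result`).
#' @export
biprobit_late_fit <- function(dataset, arm = "SSNP", control = "EUC",
                              visit = "2wk", rule = c("ITT", "RO"),
                              covariates = NULL, compute_vcov = TRUE) {
  rule <- match.arg(rule)
  d <- dataset[dataset$arm %in% c(arm, control), , drop = FALSE]
  y <- outcome_vector(d, visit, rule)
  keep <- !is.na(y)
  d <- d[keep, , drop = FALSE]
  y <- y[keep]
  Z <- as.integer(d$arm == arm)
  C <- as.integer(d$complier == 1 & Z == 1)
  X <- if (is.null(covariates)) NULL else d[, covariates, drop = FALSE]
  model <- fit_biprobit(Z, C, y, X, compute_vcov = compute_vcov)
  result <- complier_effect_probabilities(
    model, contrast = paste(arm, "vs", control), visit = visit,
    population = rule)
  list(model = model, result = result)
}
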