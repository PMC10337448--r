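# 7-day point-prevalence abstinence (biochemically verified) under ITT and
# respondent-only rules, plus logistic effect estimates with Bonferroni
# correction.

visit_col <- function(visit) {
  visit <- match.arg(visit, .visits)
  paste0("y_", visit)
}

#' Verified 7-day point-prevalence abstinence
#'
#' A participant is abstinent at a visit when they self-report no smoking
#' in the previous 7 days and their expired CO is strictly below 10 ppm
#' (CO = 10 counts as smoking). Under the intention-to-treat (`"ITT"`)
#' rule any missing component is imputed as smoking; under the
#' respondent-only (`"RO"`) rule missing information stays missing and the
#' participant drops out of the denominator.
#'
#' @param self_report_no_smoking_7d logical (or `"yes"`/`"no"`) vector,
#'   `NA` for missing.
#' @param co_ppm expired CO in ppm, `NA` for missing; must be
#'   non-negative.
#' @param rule `"ITT"` or `"RO"`.
#' @param co_cutoff ppm threshold, default 10 (strict `<`).
#' @return integer vector in \{0, 1, NA\} (NA only under `"RO"`).
#' @examples
#' point_prevalence(c(TRUE, TRUE, NA), c(8, 10, NA), rule = "ITT")
#' @export
point_prevalence <- function(self_report_no_smoking_7d, co_ppm,
                             rule = c("ITT", "RO"), co_cutoff = 10) {
  rule <- match.arg(rule)
  if (is.character(self_report_no_smoking_7d)) {
    self_report_no_smoking_7d <- c(yes = TRUE, no = FALSE)[
      self_report_no_smoking_7d]
  }
  if (any(co_ppm < 0, na.rm = TRUE)) stop("negative CO reading")
  abst <- self_report_no_smoking_7d & (co_ppm < co_cutoff)
  if (rule == "ITT") abst[is.na(abst)] <- FALSE
  as.integer(abst)
}

# Visit outcome vector from a trial dataset under an analysis rule.
outcome_vector <- function(dataset, visit, rule = c("ITT", "RO")) {
  rule <- match.arg(rule)
  y <- dataset[[visit_col(visit)]]
  if (is.null(y)) stop("dataset has no outcome column for visit ", visit)
  if (rule == "ITT") y[is.na(y)] <- 0L
  y
}

#' Abstinence rates by group
#'
#' @param dataset a trial dataset (see [simulate_trial()]).
#' @param visit one of `"2wk"`, `"4wk"`, `"6mo"`, `"12mo"`.
#' @param rule `"ITT"` (missing imputed as smoking) or `"RO"`
#'   (respondent-only).
#' @param group_var grouping column, default `"arm"`.
#' @return data.frame with group, `n` (denominator), `n_abstinent`, `rate`.
#' @export
abstinence_rates <- function(dataset, visit, rule = c("ITT", "RO"),
                             group_var = "arm") {
  rule <- match.arg(rule)
  y <- outcome_vector(dataset, visit, rule)
  g <- dataset[[group_var]]
  keep <- !is.na(y)
  tab <- tapply(y[keep], g[keep], function(v) c(n = length(v), x = sum(v)))
  out <- do.call(rbind, lapply(names(tab), function(lev) {
    data.frame(group = lev, n = tab[[lev]]["n"],
               n_abstinent = tab[[lev]]["x"],
               rate = tab[[lev]]["x"] / tab[[lev]]["n"])
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param m family size (number of comparisons); must be at least the
#'   number of p-values supplied.
#' @return adjusted p-values.
#' @examples
#' bonferroni(c(0.008, 0.5), m = 10)
#' @export
bonferroni <- function(p_values, m) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) {
    stop("family size m must be >= number of tests")
  }
  pmin(1, m * p_values)
}

#' Logistic effect of one group versus another on abstinence
#'
#' Fits a binary logistic regression of the visit outcome on group
#' membership (first element of `contrast` versus the second, which is the
#' reference), optionally adjusted for covariates. The odds ratio is the
#' exponentiated group coefficient with a Wald 95% CI on the log-odds
#' scale. Complete separation is flagged in the returned object rather
#' than failing silently.
#'
#' @param dataset a trial dataset.
#' @param contrast character of length 2, e.g. `c("SSNP", "EUC")`.
#' @param visit visit label.
#' @param rule `"ITT"` or `"RO"`.
#' @param covariates optional character vector of adjustment columns
#'   (e.g. `c("age", "sex", "race", "education")`).
#' @param group_var column holding the group labels (`"arm"` or
#'   `"subgroup"`).
#' @param m optional Bonferroni family size; when supplied the adjusted
#'   p-value is filled in.
#' @param conf_level confidence level for the Wald interval.
#' @return object of class `effect_estimate`.
#' @examples
#' d <- simulate_trial(trial_config(), seed = 1)
#' fit_group_effect(d, c("SSNP", "EUC"), visit = "2wk", rule = "ITT")
#' @export
fit_group_effect <- function(dataset, contrast, visit,
                             rule = c("ITT", "RO"), covariates = NULL,
                             group_var = "arm", m = NULL,
                             conf_level = 0.95) {
  rule <- match.arg(rule)
  stopifnot(length(contrast) == 2L)
  g <- dataset[[group_var]]
  keep <- g %in% contrast
  d <- dataset[keep, , drop = FALSE]
  d$.y <- outcome_vector(d, visit, rule)
  d <- d[!is.na(d$.y), , drop = FALSE]
  d$.grp <- factor(as.character(d[[group_var]]), levels = rev(contrast))
  if (any(table(d$.grp) == 0)) stop("both contrast groups must be non-empty")

  rhs <- paste(c(".grp", covariates), collapse = " + ")
  fit <- stats::glm(stats::reformulate(rhs, ".y"),
                    family = stats::binomial(), data = d)
  co <- stats::coef(fit)
  term <- grep("^\\.grp", names(co), value = TRUE)
  est <- co[[term]]
  se <- sqrt(stats::vcov(fit)[term, term])
  separation <- !fit$converged || abs(est) > 10 || se > 100 ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_raw <- 2 * stats::pnorm(-abs(est / se))
  structure(
    list(contrast = paste(contrast, collapse = " vs "),
         odds_ratio = exp(est),
         ci_low = exp(est - z * se), ci_high = exp(est + z * se),
         p_raw = p_raw,
         p_bonferroni = if (!is.null(m)) bonferroni(p_raw, m) else NA_real_,
         adjusted = !is.null(covariates), covariates = covariates,
         population = rule, visit = visit,
         n = nrow(d), separation = separation, fit = fit),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s [%s, %s%s]: OR %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
              x$contrast, x$population, x$visit,
              if (x$adjusted) ", adjusted" else "",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_raw,
              if (!is.na(x$p_bonferroni)) {
                sprintf(" (Bonferroni %.3g)", x$p_bonferroni)
              } else ""))
  if (x$separation) cat("  WARNING: possible complete separation\n")
  invisible(x)
}

#' Partition scheduled arms into compliance subgroups
#'
#' Splits the SSNP and SS arms by the >=50% CO-reduction compliance flag
#' into five analysis groups: SSNP_compliant, SSNP_noncompliant,
#' SS_compliant, SS_noncompliant and EUC. The split of each scheduled arm
#' is exhaustive and disjoint; control participants carrying a compliance
#' label are a data error.
#'
#' @param dataset a trial dataset with `arm` and `complier` columns.
#' @return the dataset with an added `subgroup` factor column.
#' @export
build_compliance_subgroups <- function(dataset) {
  if (any(dataset$arm == "EUC" & dataset$complier == 1)) {
    stop("EUC participants cannot carry a compliance label")
  }
  lab <- ifelse(dataset$arm == "EUC", "EUC",
                paste0(dataset$arm,
                       ifelse(dataset$complier == 1,
                              "_compliant", "_noncompliant")))
  levs <- c("SSNP_compliant", "SSNP_noncompliant",
            "SS_compliant", "SS_noncompliant", "EUC")
  dataset$subgroup <- factor(lab, levels = levs)
  empty <- levs[!(levs %in% lab)]
  if (length(empty)) {
    warning("empty compliance subgroup(s): ", paste(empty, collapse = ", "))
  }
  dataset
}
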