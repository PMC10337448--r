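Package: schedquit
Title: Scheduled Smoking Reduction Trials: Schedules, Compliance, and
    Compliance-Adjusted Causal Effects
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational core for three-arm smoking-cessation trials that
    use scheduled gradual reduction before the quit date. Provides a
    deterministic 21-day intercigarette-interval schedule generator,
    expired-CO compliance classification (percent reduction with a 50%
    cutoff) and prompt/event adherence summaries, biochemically verified
    7-day point-prevalence abstinence under intention-to-treat and
    respondent-only rules with logistic-regression effect estimates and
    Bonferroni correction, and compliance-adjusted causal estimation of the
    local average treatment effect by the Bloom estimator and a
    full-information maximum-likelihood bivariate probit with endogenous
    binary compliance. A seeded synthetic-trial generator with confounded
    compliance makes the whole pipeline testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
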