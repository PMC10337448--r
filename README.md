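# schedquit

Computational core for three-arm smoking-cessation trials built around
**scheduled gradual reduction**: smokers preparing to quit smoke only at
device-prompted times over a 21-day precessation period, with the
intercigarette interval stretched until only 3–4 cigarettes remain the day
before the quit date. The package is aimed at trialists and methodologists
who need (a) the schedule algorithm itself, (b) biochemically verified
abstinence analysis under intention-to-treat and respondent-only rules,
and (c) compliance-adjusted causal effect estimation when adherence to the
schedule is endogenous.

## What it computes

**Schedule engine.** For a smoker with baseline rate *b* cigarettes/day
awake *W* minutes, day *d* permits a stepped fraction *f(d)* of baseline
(85/70/55/40% over days 1–12 in 3-day blocks, then 30/20/10%), giving a
quota *q(d) = max(round(f(d)·b), 3)* frozen once it reaches 3–4. Prompts
fall at the wake time plus a cumulative 15-minute weekly delay, spaced by
the intercigarette interval *W/q(d)*, snapped to the quarter-hour grid,
and truncated at bedtime.

**Compliance.** Percent CO reduction
*100·(CO₀ − CO₁)/CO₀* with the ≥50% cutoff defining schedule compliance,
plus on-schedule adherence (events matched one-to-one to prompts within
±5 minutes).

**Outcomes.** 7-day point-prevalence abstinence = self-report of no
smoking **and** expired CO < 10 ppm; ITT imputes missing as smoking, RO
keeps observed data only. Arm and compliance-subgroup contrasts are
logistic odds ratios with Wald CIs and Bonferroni-adjusted p-values.

**Causal (LATE) estimation under one-sided noncompliance.** The Bloom
estimator Δ̂ = (ITT₁ − ITT₀)/π̂꜀ with bootstrap CI, and a two-equation
probit with endogenous binary compliance,

    C = 1{ z'γ + u > 0 },   Y = 1{ x'β + δC + ε > 0 },   corr(u, ε) = ρ,

estimated by full-information maximum likelihood (the in-package
bivariate-normal CDF uses Gauss–Legendre quadrature of the tetrachoric
integral). Complier probability differences average
Φ₂(z'γ, x'β + δ; ρ)/Φ(z'γ) − Φ₂(z'γ, x'β; ρ)/Φ(z'γ) over compliers, with
delta-method CIs.

**Synthetic trials.** A seeded generator emulating the design: stratified
allocation, per-arm compliance propensities confounded with abstinence
through ρ, CO pairs consistent with the compliance class, and per-visit
response rates — so every downstream stage is testable without
participant data.

## Worked example

```r
library(schedquit)

s <- generate_schedule(smoker_profile(23, "07:00", "23:00"))
s
#> Smoker profile: 23.0 cig/day, awake 07:00-23:00 (960 min)
#> 21-day reduction schedule; scheduled cigarettes per day:
#> 20 20 20 16 16 16 13 13 13 9 9 9 7 7 7 5 5 5 3 3 3
#> Day 21 first/last prompt: 07:45 / 18:30
```

A pack-a-day smoker starts at 20 scheduled cigarettes (85% of 23) and
finishes the day before quitting with 3, a 78% reduction by day 16 — the
program's "75% by week 3" property. On a synthetic trial:

```r
d <- simulate_trial(trial_config(), seed = 42)
abstinence_rates(d, "2wk", "ITT")
#>   group   n n_abstinent      rate
#> 1  SSNP 273          96 0.3516484
#> 2    SS 268          70 0.2611940
#> 3   EUC 279          61 0.2186380

bloom_late_fit(d, "SSNP", visit = "2wk", n_boot = 2000, seed = 1)
#> SSNP vs EUC [ITT, 2wk, bloom]: difference 0.239 (95% CI 0.106 to 0.363), p = 0.000279

biprobit_late_fit(d, "SSNP", "EUC", "2wk", "ITT")$result
#> SSNP vs EUC [ITT, 2wk, biprobit]: difference 0.239 (95% CI 0.108 to 0.370), p = 0.000365
```

Both estimators recover the complier effect this dataset was generated
with (0.26): complying with the scheduled-reduction-plus-patch program
raises a complier's 2-week abstinence probability by about 24 points in
this replicate, despite the compliance–abstinence confounding (ρ = 0.3)
built into the generator.

Command line:

```sh
Rscript inst/cli/schedquit schedule --cpd 23 --wake 07:00 --bed 23:00 --out schedule.csv
Rscript inst/cli/schedquit simulate --seed 42 --out trial.csv
Rscript inst/cli/schedquit analyze  --in trial.csv --visit 2wk --rule ITT --out effects.csv
Rscript inst/cli/schedquit late     --in trial.csv --visit 2wk --method biprobit --out late.csv
```

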