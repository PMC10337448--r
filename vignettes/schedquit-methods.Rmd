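---
title: "Methods: scheduled smoking reduction, compliance, and complier causal effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scheduled smoking reduction, compliance, and complier causal effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schedquit)
```

## The problem

Scheduled smoking is a gradual-reduction method of preparing to quit: for
three weeks before the quit date a handheld device prompts the smoker at
predetermined times, progressively stretching the intercigarette interval
so that consumption falls to 3–4 cigarettes the day before quitting.
Trials of this design face a classic analysis problem: whether a smoker
actually complies with the schedule is self-selected, so the "as treated"
comparison of compliant participants against controls confounds the
treatment effect with whatever makes people compliant. This package
implements the full computational chain — schedule generation, compliance
measurement, abstinence analysis, and compliance-adjusted causal
estimation — together with a synthetic-trial generator that embeds the
confounding the causal stage must remove.

## The schedule algorithm

For a profile with baseline rate $b$ cigarettes/day, wake time $w$ and bed
time $B$ (minutes from midnight, $B > w$, waking window $W = B - w$):

1. **Stepped fraction.** Day $d \in 1..21$ permits a fraction $f(d)$ of
   baseline: 15 percentage points are removed per 3-day block over days
   1–12 and 10 points per block over days 13–21, giving
   85/70/55/40/30/20/10% for the seven blocks. The reduction applies from
   day 1: the seven blocks exactly tile the 21 days, and a compounding
   (multiplicative) reading would leave a pack-a-day smoker near 9
   cigarettes on day 21, contradicting the 3–4 endpoint, while percentage
   points land on it.
2. **Quota.** $q(d) = \max(\mathrm{round}(f(d)\,b), 3)$ with half-up
   rounding. Once $q(d) \le 4$ the quota freezes at that value (no
   further reductions until the quit date). The final block (days 19–21)
   is additionally capped at 4: for baselines above 44/day, 10% of
   baseline rounds above 4 and the floor would never engage, so the
   program's stated endpoint — only 3–4 cigarettes the day before the
   quit date — is enforced as a ceiling there. Below 45 cigarettes/day
   the cap is inactive.
3. **Spacing.** The intercigarette interval is $W / q(d)$ minutes. The
   first (unrounded) prompt of day $d$ falls at $w + 15\,\mathrm{week}(d)$
   — the 15-minute delay to the first cigarette accumulates weekly, and
   we include week 1; only week-over-week differences are externally
   checkable, and those are unaffected. Subsequent prompts follow at
   interval increments of the *unrounded* sequence.
4. **Quarter grid and truncation.** Each time is independently snapped to
   the nearest quarter within the hour (exact midpoints round to the
   later quarter — later smoking is the conservative direction for a
   reduction program), and any prompt at or past bedtime is dropped.
   Rounding never accumulates: prompt $j$ is rounded from the exact
   arithmetic sequence, not from the rounded prompt $j-1$.

Duplicate rounded times (possible when the interval is under 15 minutes)
are collapsed, so emitted times are strictly increasing and never exceed
the quota in number. Overnight waking windows are rejected as
unsupported. Clock times are plain minutes from midnight throughout.

## Compliance measures

The primary compliance measure is the percent reduction in expired carbon
monoxide between baseline and the last precessation visit,
$100\,(CO_0 - CO_1)/CO_0$, with $\ge 50\%$ (inclusive) defining
compliance. The printed form of this formula places the $\times 100$
inside the denominator; we read it as the standard percent multiplier,
since a denominator reading would cap the score at 0.01 and make the
stated 50 cutoff unreachable.

Adherence from device logs matches each smoked-cigarette event to the
nearest unmatched prompt within a symmetric, boundary-inclusive ±5-minute
window, closest pairs first, one-to-one (no double-crediting). Missing a
scheduled cigarette is permissible, so unmatched prompts are not
violations; unmatched events are off-schedule. Whether an event may
precede the prompt it satisfies is unstated in the source design; we use
the symmetric window.

## Abstinence and effect estimates

Verified 7-day point-prevalence abstinence requires a self-report of no
smoking in the previous 7 days **and** expired CO strictly below 10 ppm
(CO = 10 counts as smoking). Under ITT, any missing component is imputed
as smoking; under RO the participant leaves the denominator. RO rates
therefore never fall below ITT rates, a property the tests assert.

Group contrasts are logistic regressions of the visit outcome on group
membership, optionally adjusted for age, sex, race and education (3-level
factors; reference levels are the control arm, European American and the
first factor level — unstated in the source, chosen once). Odds ratios
carry Wald 95% intervals on the log-odds scale (profile likelihood was
the obvious alternative; Wald matches the standard output of the era and
the covariate-free fit then reproduces the 2×2 cross-product ratio to
numerical precision, which the tests exploit as an oracle). Bonferroni
adjustment multiplies by the family size (3 for the three arm contrasts,
10 for the compliance-subgroup family) and caps at 1. Complete separation
is flagged on the returned object rather than silently tolerated.

## Complier causal effects

Compliance is one-sided: controls have no schedule, so $C = 0$ is
structural in that arm. Two estimators of the complier average causal
effect are provided.

**Bloom.** The ITT rate decomposes as
$\pi_c \cdot r_{\text{comp}} + (1 - \pi_c) r_{\text{noncomp}}$ (an exact
bookkeeping identity, asserted on every dataset), and under the exclusion
restriction the complier effect is
$(\mathrm{ITT}_1 - \mathrm{ITT}_0)/\pi_c$. CIs are percentile bootstrap
over participant resampling stratified by arm (default 2000 resamples,
seeded). The shortcut variant that divides the overall treated rate by
$\pi_c$ without control subtraction is provided as
`bloom_late_uncentered()` for fidelity with the printed decomposition
text, but the control-subtracted estimator is the default: the shortcut
omits the control-arm term that the underlying identity contains.

**FIML biprobit.** Compliance and outcome probits with correlated errors
($|\rho| < 1$ enforced by optimizing on the $\mathrm{atanh}\,\rho$
scale), likelihood over the four treated $(C, Y)$ cells via the bivariate
normal CDF, controls contributing through the outcome margin. The CDF is
computed in-package by 48-node Gauss–Legendre quadrature of the
tetrachoric single integral after the $t = \sin\theta$ substitution,
which removes the endpoint singularity as $|\rho| \to 1$; against an
independent conditional-normal integration oracle the error is below
$10^{-9}$ across the tested range. Starting values come from separate
probits; the covariance is the inverse observed information at the
optimum. The reported effect is the complier probability difference
conditional on complying,
$\mathbb{E}\big[\Phi_2(z'\gamma, x'\beta + \delta; \rho) -
\Phi_2(z'\gamma, x'\beta; \rho)\big]/\Phi(z'\gamma)$ averaged over
compliers, with delta-method CIs (numerical gradient). Conditioning on
complier status is what makes the two estimators target the same
quantity; the unconditional $\Phi(x'\beta + \delta) - \Phi(x'\beta)$
differs from it whenever $\rho \neq 0$. Which covariates entered the
source's probit equations is unstated; the wrapper defaults to none and
accepts the adjusted-model set.

## The synthetic generator: what it emulates

Per participant, one latent pair $(u, \varepsilon)$ is standard bivariate
normal with correlation $\rho$ (`confound_rho`, default 0.3 — the
confounding strength is not a reported quantity; 0.3 is a moderate value
and a config knob the tests sweep). In a scheduled arm,
$C = 1\{u < \Phi^{-1}(\pi_c)\}$ with $\pi_c$ = 139/273 (SSNP) and 71/268
(SS); abstinence at visit $v$ is
$Y_v = 1\{\varepsilon < b_{0v} + \delta_{av} C\}$. A single
$\varepsilon$ shared across the four visits induces within-person
persistence; given the compliance class, visit outcomes are comonotone
(no independent relapse shocks), which real data would not satisfy — a
deliberate simplification that keeps each visit an exact biprobit with
correlation $\rho$.

Because noncompliers and controls share the threshold $b_{0v}$, arm
assignment affects abstinence only through compliance: the exclusion
restriction holds by construction, and the "noncomplier abstinence
probability" is an implied quantity
($P(\varepsilon < b_{0v} \mid u \ge \Phi^{-1}(\pi_c))$), not a free
parameter. Supplying `noncomplier_abstinence_prob` overrides this and
deliberately breaks exclusion (useful for studying bias); observed
as-treated noncomplier-versus-control gaps are selection effects, which
is why the generator does not calibrate to them.

Calibration is threshold-level: $b_{0v} = \Phi^{-1}(p_{0v})$ from the
control probabilities, and $\delta_{av}$ solved (by `uniroot` on the
conditional probability) so the complier-conditional causal effect
equals `late_target` — default 0.26/0.29/0.26/0.22 (SSNP vs control by
visit) and 0.27/0.33/0.29/0.28 (SS vs control), the reported
complier-effect differences. Control probabilities
(0.25/0.25/0.18/0.15) and the baseline-CO model (normal, mean
$25/23 \times$ cpd ppm, sd 8, floor 2 ppm) are **synthetic
placeholders**: neither is a reported quantity, and 0.25 at two weeks is
the value the odds-ratio recovery target itself stipulates. CO pairs are
generated with the reduction fraction drawn uniformly on (0.505, 0.85)
for compliers and (−0.20, 0.495) for noncompliers — the 0.005 margins
keep the ≥50% classification exact under floating point — so
classification always reproduces the generating flag.

Covariates (≈50% female; 73/17/10% race mix; 20/46/34% education; age
$\mathcal{N}(43, 11)$; cigarettes/day $\mathcal{N}(23, 10)$ floored at
10; 25% depression history) are sampled independently — joint covariate
correlation is not modeled — and drive a stratified allocation (sex ×
race × above/below 20 cpd × depression history) balanced to within one
per stratum with exact marginal totals; a repair pass relaxes a single
stratum's balance only when no balance-preserving swap exists. Visit
missingness is independent given arm at the reported response rates
(e.g. 239/279 for the control arm at two weeks); no dropout process is
modeled because only per-visit response counts are reported.

A green test against this generator therefore establishes that the
estimators recover effects under probit-style confounding, one-sided
noncompliance, MAR-given-arm missingness and exact CO-class consistency.
It does not establish robustness to non-normal confounding, informative
dropout, exclusion-restriction violations (e.g. a precessation patch
affecting noncompliers), misclassified compliance, or correlated
covariates.

One consequence worth stating: with arm-dependent response rates, the
ITT missing-as-smoking convention scales each arm's rate by its response
probability, putting an assignment effect on the imputed scale outside
compliance. The estimator-recovery experiments therefore run the
generator with full response, isolating the causal machinery on the
scale on which the generating effect is defined; the missingness
defaults remain in force everywhere the ITT/RO denominator logic is the
thing under test.

## Numerical and runtime choices

- Half-up rounding throughout the schedule (deterministic, reproduces
  the 3–4 endpoints for common baselines).
- `uniroot` tolerance $10^{-10}$ on threshold calibration; BFGS with
  observed-information covariance for the FIML fit; non-convergence and
  $|\hat\rho|$ near 1 raise errors/warnings rather than returning
  silently.
- Bootstrap and simulation replicate counts in the test suite are scaled
  to a single-CPU budget where the statement of the property allows it
  (noted inline in the tests); acceptance-criterion replicate counts
  (200 compliance replicates, 1000 odds-ratio replicates, 500 LATE
  replicates) are as stated.

## Known limitations

- The schedule engine models a single day layout per profile; real
  devices re-confirmed wake/bed times daily.
- No EMA-level event streams, patch-wear diaries, early-quit or relapse
  flows; the patch arm is metadata only.
- The biprobit assumes bivariate-normal errors; no weak-instrument
  diagnostics beyond the first-stage coefficient are provided.
- Twelve-month economics, withdrawal/affect mixed models and
  questionnaire instruments are out of scope.
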