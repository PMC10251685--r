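---
title: "Net-benefit regression with anxiety-free days: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net-benefit regression with anxiety-free days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbreg)
```

## The problem

Trial-based economic evaluations ask whether a new intervention is worth its
cost. The incremental cost-effectiveness ratio (ICER), the cost contrast
divided by the effectiveness contrast, is awkward for inference: it is a
ratio of two noisy quantities, and it cannot easily be adjusted for
covariates or probed for subgroup differences. Net-benefit regression
linearizes the problem. For a willingness-to-pay threshold $\lambda$
(dollars per unit of effectiveness), each participant $i$ gets an
individual net benefit

$$ nb_i(\lambda) = \lambda\,E_i - C_i, $$

where $E_i$ is total effectiveness (here anxiety-free days, AFDs, over an
8-month horizon) and $C_i$ total cost over the same horizon. Because $nb_i$
is a plain per-participant outcome, ordinary least squares applies:

$$ nb_i = \alpha + \beta_1\,\mathrm{Intervention}_i + \varepsilon_i, $$

where $\beta_1$ is the incremental net benefit (INB): $\alpha$ is the mean
control-arm net benefit and $\alpha + \beta_1$ the mean intervention-arm
net benefit. At $\lambda = 0$ the INB reduces to $-\Delta C$; its slope in
$\lambda$ is $\Delta E$, so when $\Delta E > 0$ the break-even threshold
(the $\lambda$ where INB crosses zero) is exactly the classical ICER.
Covariates and arm-by-covariate interactions extend the model to adjusted
and moderated analyses,

$$ nb_i = \alpha + \beta_1\,\mathrm{Intervention}_i + \beta_2 X_i +
   \beta_3 (\mathrm{Intervention}_i \times X_i) + \varepsilon_i, $$

where $\beta_1 + \beta_{3k}$ is the INB in moderator stratum $k$. This
package implements that framework end-to-end for a two-arm trial with
costs observed per period under two perspectives (health system; limited
societal) and anxiety measured with the Beck Anxiety Inventory (BAI) at
baseline, post-treatment, and follow-up.

Since individual-level trial data of this kind are not publicly shareable,
the package also includes a seeded synthetic-trial generator with a *known*
cost and effectiveness structure. Every downstream stage is validated by
parameter recovery against that generator.

## Anxiety-free days

Effectiveness uses the symptom-free-day construction. Each BAI total maps
to a daily weight: scores at or below the minimal-anxiety cutoff (7) count
as a full anxiety-free day (weight 1); scores at or above the
severe-anxiety cutoff (26) count as a day with anxiety (weight 0). Scores
in between are weighted linearly, $w = (26 - s)/19$ — the convention of the
depression-free-days literature this outcome descends from. The weight is
interpolated linearly between assessments and integrated over each period,
giving the trapezoid $d\,(w_\text{start} + w_\text{end})/2$ for a $d$-day
period. With two 122-day periods (a 4-month spacing of assessments), the
attainable total is exactly 0 to 244 days:

```{r afd}
total_afd(5, 3, 7)     # minimal anxiety throughout
total_afd(30, 40, 26)  # severe anxiety throughout
```

Two conventions deserve a note. First, the in-between weighting is not
uniquely determined by the cutoffs; linearity is the standard choice and
the cutoffs are arguments, not constants. Second, we integrate the
interpolated weight continuously rather than summing per calendar day,
because the continuous convention with 122-day periods reproduces the
0–244 range exactly. Computing AFDs requires complete BAI data:
`bai_to_afd_weight()` refuses missing scores (imputation must come first),
and its `clip` argument exists solely for multiply imputed draws, which are
unbounded — the weight saturates at the cutoffs, so an imputed score of
$-3$ or $70$ maps to weight 1 or 0 without any editing of the imputed
value itself.

## Missing data: bootstrap-EM imputation and Rubin's rules

Follow-up assessments go missing in trials like this at roughly 20–25%,
plausibly depending on observed baseline characteristics (missing at
random, MAR). `em_bootstrap_impute()` implements multiple imputation in the
bootstrap-EM style: for each of $m$ imputations, participants are resampled
with replacement, an EM algorithm estimates the mean and covariance of the
joint variable set under a multivariate-normal working model on the
bootstrap sample (this propagates parameter uncertainty), and each missing
cell of the original data is drawn from its conditional normal distribution
given that participant's observed values. Draws are untransformed and not
range-restricted: negative imputed costs are possible, kept, and *audited*
(`audit_negative_costs()`), never clipped — editing imputations toward
"logical" ranges is a known source of bias, and the audit makes the
magnitude of the issue visible instead.

Numerical choices: EM runs on standardized (unit-variance) working data so
the convergence criterion — largest absolute change in any mean or
covariance entry below $10^{-6}$ — is scale-free; the iteration cap is 500
and hitting it is an error, not a warning. Binary covariates enter as 0/1
and stay continuous in completions, which only ever use them as regressors.
The default imputation model contains the arm indicator, every baseline
variable, and all follow-up outcome fields, a deliberate superset of
whatever actually predicts missingness.

Per-threshold regressions are fitted on each completion and combined with
`rubin_pool()`: pooled estimate = mean of estimates, total variance
$T = \bar W + (1 + 1/m)B$ with $\bar W$ the mean within-imputation variance
and $B$ the between-imputation variance, degrees of freedom by the
Barnard–Rubin small-sample formula. $m$ defaults to 20. Stratified INBs
($\beta_1 + \beta_{3k}$) are pooled as a linear combination computed per
completion, then Rubin-pooled, which is equivalent to pooling a
re-parameterized fit with stratum $k$ as the reference.

## Acceptability curves

The cost-effectiveness acceptability curve (CEAC) reports, per threshold,
the probability that the (stratified) INB is positive. We compute it as the
one-sided $t$ probability $P = F_t(\hat\beta_1/\widehat{se};\ \nu)$ — the
complement of the one-sided p-value against $\beta_1 > 0$ — so the curve
rises with favorable evidence; $\nu$ is the residual df for single fits and
the Barnard–Rubin df for pooled fits. A conventional 95% probability rule
is exposed via `ceac_threshold()`. Two grids are used by default: a coarse
table grid (\$0–\$60 by \$10, then \$80 and \$100 per AFD) for coefficient
tables, where two-sided p-values are reported, and a \$1-step grid for
curves. Both are arbitrary presentation choices and fully configurable.

## Confounder and moderator screening

Screening follows explicit operational rules, evaluated on pooled
estimates. A baseline variable is a **confounder** when all three hold:
(1) it differs between arms (pooled p of the arm coefficient in
`candidate ~ arm` below 0.05); (2) adding it to the net-benefit model moves
the intervention coefficient by at least 10%; (3) it is associated with the
outcome (pooled p of its coefficient in `nb ~ arm + candidate` below 0.05).
Criterion 1 is threshold-free; criteria 2 and 3 are evaluated at the \$0
and \$100 grid endpoints and trigger at either — the threshold at which
these criteria "should" be applied is genuinely open, and endpoints bracket
the behaviour of the affine net benefit. If the unadjusted intervention
coefficient is exactly zero, criterion 2 is indeterminate and the decision
says so rather than dividing by zero. Criterion 1 uses a pooled linear
regression of the (indicator-coded) candidate on arm even for categorical
candidates, because a regression coefficient pools naturally across
imputations where a chi-square statistic does not.

A variable is a **moderator** when the pooled two-sided p-value of its arm
interaction falls below 0.05 at *any* grid threshold (for multi-level
variables, the minimum over level-specific interaction terms). No
multiplicity correction is applied across candidates or thresholds — the
screen is explicitly exploratory, and a 9-point grid inflates the null flag
rate well above 5% by construction; the single-threshold size of the rule
is what the validation suite checks. Multi-level moderators are
indicator-coded against the lowest level as reference.

## Regression diagnostics

Each completed dataset is checked separately, and per-observation flags are
aggregated: a participant flagged (by any influence criterion) in five or
more completions is escalated for inspection — never removed. Influence
uses the standard leave-one-out closed forms with cutoffs: leverage
$> 3p/n$ (p counting the intercept), $|DFBETAS| \ge 2/\sqrt{n}$, Cook's
distance $> 4/n$ plus an absolute cutoff of 1. The $2/\sqrt{n}$ DFBETAS
cutoff is the standard size-adjusted form (a cutoff *growing* with $n$
would never flag anything at trial scale); it is an argument if another
convention is wanted. Model-level checks: residual skewness and kurtosis
as $z$-statistics (the SPSS-style $G_1$/$G_2$ estimators over their
large-sample standard errors) against $|z| > 3.29$; variance inflation
factors against 10 (generalized VIFs for factor terms are reported on the
squared df-adjusted scale, comparable to a VIF); Levene's test of
net-benefit variance homogeneity across arms, mean-centered by default with
median-centering available. Visual linearity checks are supported by an
exported standardized residual-vs-fitted table rather than an in-package
judgment, which would not be assertable.

## The synthetic generator

`generate_trial()` draws a two-arm trial whose true structure is known in
closed form (`true_inb()`), so recovery can be tested:

* **Costs** are gamma by arm × perspective × period — nonnegative and
  right-skewed, the signature of mental-health cost data. The gamma scale
  is derived from the configured mean (scale = mean/shape), so the
  configured treatment−control mean total cost contrast holds exactly in
  expectation; defaults (control means \$2,500 health-system, \$5,000
  limited-societal, shape 1.5) are order-of-magnitude choices for an
  8-month anxiety-disorder trial in a public health system, not calibrated
  values, since per-arm cost moments are not printed in this literature's
  trial reports.
* **BAI trajectories** are truncated normal on 0–63 around per-assessment
  means (control default 22 → 18 → 17, SD 10, a moderate-severity sample
  improving slightly under usual care). Because the AFD mapping is
  nonlinear, a configured AFD contrast cannot be induced by shifting BAI
  means by a fixed amount; instead the generator numerically calibrates the
  treatment-arm T1/T2 mean shift (per moderator level) so the *expected*
  AFD contrast equals the configured `true_delta_afd` plus the per-level
  interaction, exactly. This is why the configuration takes a control-arm
  trajectory plus effectiveness deltas rather than two free trajectories,
  which would over-determine the contrast.
* **The moderator** is one ordinal covariate with levels 0–3 (the
  comorbid-anxiety-count coding; default prevalences 25/40/25/10%, i.e.
  three quarters with at least one comorbidity). Its interactions shift the
  treatment-arm cost mean and expected AFD additively per level; defaults
  (−\$2,000 and +4 days per level) give a cost-dominated interaction of the
  size that moderation analyses in this setting report.
* **Covariates** are binary with configurable prevalences (defaults from a
  mostly-female, mean-age-37 anxiety-disorder sample), an optional per-arm
  prevalence shift (residual randomization imbalance), and an optional cost
  effect. A covariate with both is a true confounder, which the screening
  power checks rely on. The reference-level deltas remain exact only when
  cost effects are balanced across arms; enabling both knobs shifts the
  *marginal* contrast — that is what confounding means, and adjusted models
  recover the conditional contrast.
* **Missingness** (`impose_missingness()`) hits BAI and that period's costs
  jointly per assessment, via a logistic model on baseline variables whose
  intercept is calibrated so the marginal rate matches the configured
  ~19%/23%; the default dependence on baseline BAI makes the mechanism MAR
  rather than MCAR. One master seed feeds separate sub-streams for
  covariates, outcomes, and missingness, so the missingness stage is
  reproducible independently.

What the generator does **not** emulate: the joint dependence structure of
real baseline covariates (only marginal prevalences), service-use line
items (only per-period totals), cost–BAI correlation within participant,
and any non-normal BAI dynamics beyond truncation. Passing recovery tests
therefore shows the estimators are correct *under the stated model*, not
that the model captures every feature of real trial data.

## Validation problem sizes

The package's simulation-based checks use: 200 replicates of a
500-per-arm trial with ~20% MAR missingness at each follow-up and $m = 5$
imputations for interval coverage of the true INB (93–97% band) and for
the power of the moderator screen against a −\$2,000/level cost
interaction; and 2,000 complete-data replicates of a 150-per-arm trial
with a binary moderator at a single threshold for the screen's null size
(3.5–6.5% band; identical completions make the pooled fit equal the single
fit, isolating the decision rule). These sizes are the package's own
validation choices, balancing Monte-Carlo error against run time.

## Known limitations

* The normal working model of the imputation step is misspecified for
  gamma-like costs and truncated BAI scores; at the missingness rates
  studied, coverage stays nominal, but heavier missingness or more extreme
  skew could degrade it.
* OLS inference on net benefits leans on large-sample behaviour at low
  thresholds, where the cost distribution dominates and residuals are
  skewed — the same caveat the diagnostics battery is designed to surface.
* The screen's grid-wide "any threshold" rule is intentionally
  multiplicity-inflated; treat flags as hypotheses, not findings.
* QALY outcomes and bootstrap-based CEACs are out of scope.
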