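---
title: "Methods: testing school-level moderation of polygenic-score associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing school-level moderation of polygenic-score associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A polygenic score (PGS) for educational attainment predicts years of
schooling, credential thresholds, and occupational standing. Whether that
prediction is *stable across school contexts* is a gene–environment
interaction (GxE) question with two complications: we rarely know which
school-level environment would do the moderating, and students are not
randomly assigned to schools — the PGS itself clusters across schools
(gene–environment correlation, rGE), so naive between-school contrasts
confound composition with moderation.

`schoolgxe` implements two complementary answers and the simulation
machinery to calibrate them.

## The indirect model and its randomization test

For student $i$ in school $j$,

$$y_{ij} = \beta_0 + \mu_j + (\beta_1 + \delta_j)\,\mathrm{PGS}_{ij}
  + X'\beta + \epsilon_{ij}, \qquad
  (\mu_j, \delta_j) \sim N(0, \Omega),$$

fit by REML via `lme4::lmer`. $\sigma_\delta = \sqrt{\Omega_{22}}$
captures moderator-agnostic slope heterogeneity. The covariates $X$ are
sex and z-scored birth year. REML is the default because variance
components are the estimands; ML is available via `reml = FALSE`.
Components are bounded at zero by the estimator; boundary estimates are
reported as exact zeros with a `boundary` flag rather than hidden, because
a zero slope variance is a substantively meaningful finding here. A
`mean_centered` variant school-demeans the outcome and fits the random
slope only: it removes between-school level differences (and the
intercept–slope covariance pathway that can make $\sigma_\delta$ hard to
interpret when levels and slopes are strongly correlated).

Judging whether $\hat\sigma_\delta$ is "larger than nothing" from its
point estimate is unreliable, so inference is by randomization: students
are reassigned uniformly at random to schools of the observed sizes
(conserving the size multiset exactly), the model is refit, and the
observed component is located in the permutation distribution. The
p-value is the add-one estimator
$p = (1 + \#\{\hat\sigma^{(r)} \ge \hat\sigma^{obs}\})/(R_{ok} + 1)$,
one-sided because components are non-negative and the alternative is
"more between-school structure than chance". This equals one minus the
empirical quantile rank of the observed value up to the finite-sample
correction that keeps $p > 0$. Where "mean quantile rank" could also be
read as averaging ranks across several components of $\Omega$ or across
randomization batches, the package reports one p-value per component and
never averages; users who want a combined statement can combine the
per-component results explicitly. Failed or non-converged null refits are
dropped and counted (never imputed, which would bias the null); a result
with more than 20% failures is flagged unreliable.

The permutation unit defaults to the student. For cohorts with sibling
pairs a family-block mode keeps siblings together: blocks are placed into
remaining school slots with probability proportional to capacity, larger
families first so pairs are never stranded among single leftover slots.
This block sampler is exchangeable across schools though not exactly
uniform over all feasible block arrangements; at the pair sizes generated
here the distinction is negligible.

Inside the permutation loop, refits go through lme4's modular API (the
fixed-effect design is built once; only the random-effect terms are
rebuilt per reassignment, and the same REML deviance is optimized). The
test suite pins this fast path to `fit_indirect()` at $10^{-8}$.

## The direct model

With a standardized school environment $E_j$,

$$y_{ij} = \beta_0 + u_j + \beta_1 \mathrm{PGS}_{ij} + \beta_2 E_j
  + \beta_3\, \mathrm{PGS}_{ij} E_j + X'\beta + \epsilon_{ij}.$$

$\beta_3$ is the focal cross-level interaction. The model always includes
the guard interactions sex$\times$PGS, sex$\times E$,
birthyear$\times$PGS and birthyear$\times E$: omitted covariate
interactions are a classic source of spurious GxE, and including them is
cheap insurance. Fixed-effect p-values are two-sided Wald (normal) tests;
with at least ~100 schools and thousands of students the normal
approximation is standard, and it matches the closed-form benchmark used
by the power engine. Only schools with at least 10 observed students
enter, and $E_j$ is z-scored over the included schools; a constant
environment is rejected as a degenerate design rather than silently fit.

## School environments

Two candidate moderators are built from student microdata, not read from
a register:

* **status** — the share of students' mothers holding at least a
  high-school diploma (mean of a 0/1 indicator over non-missing values);
* **stratification** — the Gini coefficient of parental education years,
  $G = \sum_{i,j} |x_i - x_j| / (2 n^2 \bar x)$, computed with the exact
  sorted-order identity and verified against an $O(n^2)$ brute-force
  oracle. The population ($n^2$) denominator is the default (the textbook
  definition); the sample variant $n(n-1)$ is an option. $G \in
  [0, 1 - 1/n]$, is scale invariant, and is flagged missing when all
  values are zero.

Parental education is one value per student by default (the
questionnaire-level ambiguity of pooling both parents is left to the
caller, who can supply any column). Missing entries are dropped per
school; the inclusion filter counts students with data.

Gene–environment correlation descriptives: `between_school_share()` is
the intraclass correlation from a random-intercept-only REML fit (share
of a variable's variance lying between schools), and
`schoolmean_pgs_env_correlation()` is the Pearson correlation between
school-mean PGS and an environment over included schools.

## The synthetic cohort generator

The generator produces exactly the structure the models assume, plus the
structural features that make the real design hard:

* a latent continuous outcome with unit residual SD:
  $y^* = \beta_0 + \mu_j + f + (\beta_1 + \delta_j + \beta_3 E_j)
  \mathrm{PGS} + \beta_2 E_j + \gamma' X + \epsilon$;
* years of education = $14 + 2 y^*$ by default (a realistic mean/SD for
  mid-century through 1980s US cohorts), optionally floored at 12 years
  to emulate empanelment conditional on high-school graduation; the
  binary outcomes threshold years at $>12$ and $\ge 16$, so floor and
  threshold phenomena arise from one mechanism;
* predictors (PGS, SES, cognition) with configurable between-school
  variance shares (defaults 0.065 / 0.20 / 0.08, the orders of magnitude
  such cohorts display);
* rGE by construction: the true moderator is the standardized realized
  school-mean PGS mixed with an independent school factor at weight
  `rge_weight`, spanning weak to strong sorting;
* school-SES microdata (`mother_hs`, `parent_edu_years`) generated from
  school-level propensities tied to the true moderator, so the
  environment measures are *reconstructed* from microdata rather than
  copied from truth — exercising the measurement code path and its
  attenuation;
* the observed moderator $\sqrt{\alpha}\,z(E) + \sqrt{1-\alpha}\,
  \mathrm{noise}$, restandardized, with reliability $\alpha \in (0,1]$;
* sibling pairs sharing school and a family intercept (SD
  `sigma_family`), fit as a family effect nested within school (siblings
  in these designs attended the same sampled school; crossed structures
  are out of scope);
* a job-status index sharing $\mu_j, \delta_j$ at attenuation 0.6,
  supporting cross-outcome comparisons without new machinery.

One integer seed drives a single root generator; all sub-draws derive
from it, so cohorts are bit-reproducible and the caller's RNG state is
never touched. School sizes are apportioned deterministically (equal
split with remainder to the first schools, or largest-remainder from
multinomial proportions); configurations that starve a school are
rejected.

What the generator does **not** emulate: genotypes or GWAS weights (the
PGS is a column, not a computation), realistic school-size distributions
(these are free parameters, since the target studies do not publish
them), item-level questionnaire coding of parental education, non-normal
outcome shapes beyond the truncation floor, and mortality or
participation selection. Passing tests therefore demonstrate that the
estimators do what they claim under the assumed data-generating process —
not that any particular empirical cohort satisfies those assumptions.

## Power engine

For each interaction coefficient on a grid, cohorts are simulated from a
design template, the moderator is observed at reliability $\alpha$, and
either the direct Wald test or the indirect randomization test (reduced
$R = 199$ inside the loop, which is unbiased for size and tractable at
desk scale) is applied; power is the rejection proportion at the nominal
level. Two templates are provided, sized like the two cohorts this
design targets: `wls_like` (8,494 students, 300 equal schools) and
`addhealth_like` (4,915 students, 100 equal schools). School counts are
not published for these designs; fixed-effect interaction power depends
almost entirely on total $n$, so round school counts were chosen and are
overridable. Main effects default to $\beta_1 = \beta_2 = 0.2$ —
interaction power for standardized, independent predictors is insensitive
to main-effect magnitudes, so these act as realistic scenery rather than
tuning knobs. Interaction coefficients are interpreted on the
standardized-outcome scale throughout.

Monte-Carlo power is cross-checked against
$\Phi(|\beta_3|\sqrt{\alpha n}/\sigma_\epsilon - z_{1-\alpha/2})$, the
Wald approximation for standardized independent predictors, and the
incremental $r^2$ of the interaction term (which converges to
$\beta_3^2$) is tracked alongside — making concrete that detectable
interactions in designs of this size add well under half a percent of
explained variance.

## Numerical and interface choices

* Standardization uses the population-SD convention (`c(0, 2)` maps to
  `c(-1, 1)`); parameters are recorded for exact back-transformation.
  Continuous outcomes are standardized; binary outcomes stay on the 0/1
  scale as linear probability models with standardized predictors (their
  coefficients then read as probability differences per SD of predictor),
  and predicted probabilities are never clamped. Both choices are
  overridable via `standardize_outcome`.
* Birth year enters as a single z-scored continuous covariate, so the
  guard interactions are single columns.
* Empirical-Bayes (BLUP) school effects drive `school_predictions()`;
  shrinkage means per-school trajectories are attenuated relative to
  per-school OLS — rank order is preserved (tested), spread is
  compressed by design.
* Schools are processed in sorted `school_id` order everywhere, making
  reports byte-stable; pipeline stages cache to CSV keyed on an MD5 hash
  of the full configuration, so unchanged reruns perform no refits, and
  every report row carries seed, package version and config hash.
* Degenerate inputs fail loudly: zero-variance outcomes, predictors or
  environments, all-missing school measures, families larger than any
  school, and non-converged observed fits all raise or flag rather than
  return silent numbers.

## Problem sizes used by the test suite

Parameter-recovery checks run at 200–500 schools with 40–100 students
each ($n$ = 10,000–50,000), where Monte-Carlo error is comfortably inside
the asserted tolerances. The study-sized power checks run the two
templates at full $n$ with 400 replicates in the tests and 1,000 in
`scripts/acceptance.R`. Null calibration of the randomization test uses
200 outer cohorts (20 schools of 15) with $R = 199$ reassignments each;
size of the direct test under the null uses 1,000 simulated cohorts.
These sizes were chosen as the smallest at which each property is sharp;
all are plain package choices and can be scaled up by the user (the
engine exposes `n_reps` and `R` everywhere, and the full-fidelity
10,000-replicate power mode is just `n_reps = 10000`).

## Known limitations

* Linear probability models, not logistic mixed models, for the binary
  outcomes — by design, for interpretability and fidelity to the
  analysis this package operationalizes; users needing odds-ratio-scale
  moderation should look elsewhere.
* One environmental moderator per direct fit; no cross-level mediation,
  no multiple-moderator adjustment.
* The indirect randomization test is calibrated under within-school
  exchangeability of centered outcomes; heavy unmodeled family structure
  combined with student-level permutation can distort it (use the
  family-block mode).
* No asymptotic likelihood-ratio or parametric-bootstrap
  variance-component tests; the permutation test is the inferential tool
  of record here.
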