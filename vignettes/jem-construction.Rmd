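---
title: "Constructing quantitative job exposure matrices for occupational physical activity in pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing quantitative job exposure matrices for occupational physical activity in pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opajem)
```

## The problem

Epidemiological studies of occupational physical activity (OPA) and
pregnancy outcomes need exposure estimates for every occupation a
study participant may hold, but direct accelerometer measurement is
only feasible for a modest sample of workers in a modest subset of
occupation codes. A job exposure matrix (JEM) bridges the gap: a
cross-tabulation that assigns each code in a hierarchical occupation
classification (DISCO-08/ISCO-08 style, five levels mapping to 1-, 2-,
3-, 4- and 6-digit codes) an estimated exposure in hours per
standardized 8-hour workday. `opajem` implements the full construction
pipeline for standing, walking and forward bending (≥30° trunk
inclination) among pregnant workers, combining repeated per-workday
accelerometer summaries with calibrated multi-rater expert ratings.

## The model

For workday $d$ of worker $w$ holding job $j$, the duration-normalized
exposure $y_{jwd}$ (hours per 8-hour workday) is modelled as

$$y_{jwd} = \beta_0 + \beta_E E_j + \beta_A \,\mathrm{age}_w +
  \beta_{T2}\,[T2] + \beta_{T3}\,[T3] + u_j + v_w + \varepsilon_{jwd},$$

with $u_j \sim N(0, \sigma^2_{job})$, $v_w \sim N(0, \sigma^2_{worker})$
and $\varepsilon_{jwd} \sim N(0, \sigma^2_{resid})$ mutually
independent. Workers are nested in jobs (each participant holds one
code); worker labels are globally unique so the nested and crossed
parameterizations coincide. $E_j$ is the calibrated expert covariate in
hours (for walking, the square root of the hours — experts
systematically over-rate walking, and the square root restores
approximate linearity against measurements). Trimester contrasts are
against the non-pregnant reference; because trimester enters only as a
fixed effect, the pregnancy adjustment is one uniform shift applied to
every occupation, which is a known limitation of this design.
Estimation is by REML (`lme4`); variance components are reported as the
between-job / between-worker / within-worker decomposition, and nested
model comparisons (null, age + trimester, + expert ratings) are
summarized as percentage shares and percentage reductions relative to
the null model. By construction the job-level expert covariate can only
reduce the between-job component — the tests assert this structural
confinement.

Measured jobs receive the BLUP $\hat u_j$, the conditional mean of the
job effect given the data, which on a balanced layout with $n$ days
equals $\lambda(\bar y_j - x_j'\hat\beta)$ with shrinkage
$\lambda = n\sigma^2_{job} / (n\sigma^2_{job} + \sigma^2_{within})$:
data-poor jobs are pulled toward the model surface, data-rich jobs
toward their own mean. JEM entries are
$x'\hat\beta \,(+\,\hat u_j\ \text{if measured})$, evaluated at a
reference age and clipped to the physical $[0, 8]$ range *only at
emission*, never inside estimation.

## Pipeline stages and their parameters

* **Workday validation** (`filter_valid_days`): a workday is valid with
  ≥ 4 measured work hours; a measurement bout (week) is valid when its
  remaining days total ≥ 8 work hours. Both thresholds are inclusive
  and the weekly rule is applied per bout, not pooled across a
  participant's trimester bouts — bouts are the measurement unit, and a
  participant can validly contribute one trimester but not another.
* **TWA normalization** (`normalize_twa`): postures are rescaled by
  $8/\text{work hours}$. A 1% tolerance on the
  standing + walking + sitting sum absorbs rounding in upstream
  exports; posture hours exceeding the measured work time are a hard
  data-integrity error.
* **Expert ratings**: standing/walking/sitting are each scored 1–5 with
  the panel constraint that a rater's three scores sum to 7; bending is
  scored 1–4 on minute bands, 0 meaning "cannot be assessed" (treated
  as missing for that rater everywhere). Benchmark groups carry a panel
  consensus score that is used verbatim; other groups pool raters by
  mean (median available as a configuration switch, since the original
  panel protocol does not prescribe a reconciliation rule).
* **Hierarchy imputation** (`impute_ratings`): codes rated only via
  coarser groups inherit the group score; unrated codes receive, per
  rater, the mean over the *minimal-level* rated descendants (so a
  rated 4-digit child masks deeper 6-digit ratings and nothing is
  double-counted); leaves with no rated descendant fall back to the
  nearest resolvable ancestor. The ancestor fallback is this package's
  convention for codes the grouping tables do not reach; imputation is
  strictly per-rater and idempotent, and imputed scores may be
  fractional.
* **Calibration** (`fit_calibration`): per exposure, an OLS line of
  per-job mean measured TWA hours on consensus category. Job-level
  means (not workdays) enter so a job's weight does not depend on its
  measurement volume. Predictions clip to $[0, 8]$.
* **Agreement** (`icc_agreement`): ICC(2,1) — two-way random effects,
  absolute agreement, single rater — computed from the two-way ANOVA
  mean squares. The panel is treated as a sample of raters; ICC(3,1)
  is available where the panel is regarded as fixed.
* **Model fits and JEM assembly** as above; standing is emitted
  trimester-specifically, walking and bending once per code. For the
  latter the default is the non-pregnant reference level (their fitted
  trimester contrasts are small and non-significant); a
  measurement-share-weighted average over trimesters is the
  alternative convention, switchable in `pipeline_config()`. The
  reference age defaults to the mean age of the fitted data — the
  natural prediction point when no covariate profile is prescribed —
  and is recorded on the output. Four-digit views average six-digit
  entries unweighted, as no employment weights are available.

## The synthetic cohort generator

No measurement data are distributable, so `generate_cohort()` draws
cohorts with the study's statistical structure and a recorded ground
truth (`synthetic_truth()`), letting every stage and all recovery tests
run at desk scale. Defaults are the final standing-model operating
point: $\beta_0 = 2.228$, $\beta_E = 0.472$, $\beta_A = -0.021$,
$\beta_{T2} = -0.203$, $\beta_{T3} = -0.380$ hours and
$\sigma^2 = (0.67, 0.45, 0.60)$ hours². Ages are Normal(31, 4)
truncated to 18–45 and daily work hours Normal(7.1, 1.5) truncated to
4–12, matching the cohort's descriptive statistics. True per-job expert
hours are Uniform(0.5, 6.5): its variance of 3.0 is pinned by the
published tables themselves, since the implied null-model between-job
variance $\beta_E^2 \cdot 3 + 0.67 \approx 1.33$ and its 56% share of
total variance then match the study-scale estimates. The response is
assembled on the TWA scale and converted to raw hours through the
day's work time, so normalization recovers it exactly; walking,
sitting and bending columns are physically consistent companions
(activity sums never exceed the workday). RNG streams are split per
component so changing, say, the rater panel never perturbs the
measured responses. Rater categories discretize the true hours with
added Normal(0, 0.5) noise; standing/sitting cut-points sit at equal
fifths of the 8-hour day, while walking uses a 2-hour span (mimicking
the over-rating that motivates the square-root covariate) and bending
its minute-band scale — on the 8-hour grid every job would land in the
lowest walking and bending category and calibration would be
degenerate. Triples are renormalized to integers summing to 7.

What the generator does *not* emulate: non-Gaussian day-to-day
exposure distributions, job-dependent work-hour patterns, rater bias
that varies by occupation, and real catalogue structure (the synthetic
universe is a two-children-per-prefix forest). Passing recovery tests
therefore demonstrate correctness of the estimation machinery at the
published operating point, not robustness to real-world violations of
the model.

Two deliberate consequences of physical bounds are worth knowing.
Responses are truncated to $[0, 8]$ at generation (about 1–2% of days
at the defaults, almost all at 0): this slightly deflates the fitted
within-worker and between-worker variances (≈ 4% and ≈ 10% low at the
default design) while the between-job variance and all fixed effects —
the quantities the recovery study targets — stay within two
Monte-Carlo standard errors of truth over 20 replicates.

## Identifiability of the expert slope through calibration

The calibration line regresses measured job means on category *on the
same jobs the mixed model is then fitted to*. The calibrated covariate
is therefore (up to noise) the best linear predictor of the job mean,
and the fitted coefficient on it is close to 1 by construction — the
expert slope $\beta_E < 1$ is only identifiable against an expert-hours
scale anchored independently of the measured means. For this reason
the parameter-recovery harness (`run_parameter_recovery()`) fits the
model with the generator's *true* expert hours from the truth echo —
the scale the ground-truth slope is defined on — while the calibration
stage is validated by its own exact oracles (closed-form OLS recovery,
clipping, the walking square-root covariate). The end-to-end scripts
run the fully calibrated pipeline and report what it actually
estimates, slope near 1 included.

## Numerical choices

* REML optimization uses `bobyqa` with a tight stopping rhoend of
  2e-10, which makes balanced-layout components agree with closed-form
  ANOVA method-of-moments estimators to 1e-6 and BLUPs with the
  shrinkage formula to 1e-8; an independent grid-refinement maximizer
  of the REML log-likelihood written from the marginal covariance
  confirms the components to 1e-3 on small designs.
* Variance non-negativity is enforced at the boundary (a zero
  generating component is estimated as ≈ 0, never negative).
* Age is centred at the sample mean before fitting; the intercept is
  back-transformed to the original scale, with its standard error
  propagated through the delta relation. The REML criterion is
  invariant to this translation (tested).
* Percentages in the model-comparison table are rounded half away from
  zero for display; reductions are always computed from unrounded
  components, so a rounded table can differ by one unit from what its
  own rounded entries imply.
* Confidence intervals are Wald-type ($\pm 1.96\,\mathrm{SE}$).
* Ranking ties in the extremes tables break lexicographically by code;
  output row order is deterministic (code, exposure, trimester), so
  identical inputs rebuild byte-identical files.
* Degenerate designs: a cohort with a missing trimester level drops
  the contrast with a warning and the JEM emits only the estimable
  levels; an all-constant category vector is a calibration error, not
  a silent zero-slope line.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: recovery studies use 20 replicates of a 120 jobs × 3 workers × 5
workdays design (1 800 workdays each), chosen to give Monte-Carlo
standard errors a few percent of the parameter values; oracle
equivalence uses balanced toys of 24–72 rows where closed forms are
exact; the study-scale demonstration in `analysis/` uses 109 measured
codes in a 409-code universe with 436 workers and paired pregnancy
bouts thinned to a 161/309 third-trimester retention. A full test run
completes in well under a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
tr <- synthetic_truth(n_jobs = 40L, seed = 7L)
co <- generate_cohort(tr)
days <- normalize_twa(filter_valid_days(co$measurements)$kept)
res <- run_build(co$measurements, co$ratings, co$grouping, co$universe,
                 pipeline_config(exposures = "standing", output_dir = tempdir()))
res$variance_tables$standing
jem_extremes(res$jem$standing, "standing", k = 3)
```

The numbered scripts under `analysis/` in the source repository run
the same flow at study scale and write all tables under `results/`.
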