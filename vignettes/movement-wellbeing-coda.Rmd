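---
title: "Compositional analysis of 24-hour movement behaviours and adolescent wellbeing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour movement behaviours and adolescent wellbeing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24)
```

## The problem

A day has exactly 1440 minutes, and adolescents spend all of them in one of
four movement behaviours: sleep, sedentary time (SED), light physical
activity (LPA), or moderate-to-vigorous physical activity (MVPA).  Because
these minutes are exhaustive and mutually exclusive, they carry only
*relative* information — increasing one behaviour necessarily displaces the
others — so treating the four durations as independent regressors is
statistically incoherent.  `coda24` analyses such time-use data in the
Aitchison geometry of the simplex: closure, compositional geometric means,
a variation matrix of pairwise log-ratio variances, isometric log-ratio
(ILR) pivot coordinates, covariate- and cluster-adjusted linear regression
on those coordinates, and a pairwise time-reallocation (isotemporal
substitution) engine.  The outcome side is the 20-item EPOCH adolescent
wellbeing instrument, scored into five 4-item domains (engagement,
perseverance, optimism, connectedness, happiness), each the item mean on a
1–5 coding.

## The model

Let $x = (x_\text{sleep}, x_\text{SED}, x_\text{LPA}, x_\text{MVPA})$ be a
participant's daily composition, closed to 1440 minutes.  For a pivot
ordering $(x_{(1)}, \dots, x_{(4)})$, the pivot coordinates are

$$ z_k = \sqrt{\frac{D-k}{D-k+1}} \,
   \ln \frac{x_{(k)}}{\left(\prod_{j>k} x_{(j)}\right)^{1/(D-k)}},
   \qquad k = 1, \dots, D-1, $$

an orthonormal ILR basis whose first coordinate contrasts the pivot part
against the geometric mean of the rest.  Each wellbeing domain $y$ is
modelled as

$$ y_i = \beta_0 + \beta_z^\top z_i + \beta_a \,\text{age}_i
        + \beta_g \,\text{female}_i + \varepsilon_i, $$

fitted by ordinary least squares.  The model is refitted with each of the
four behaviours as the pivot ("rotation"); only the expression of the
coefficient vector changes — fitted values, $R^2$ and the joint model test
are invariant, because the basis change is an orthogonal transform of the
ILR block.  Each rotation's first coordinate gives the interpretable
"behaviour vs all others" row: positive $z_1$ means more of the pivot
behaviour relative to the geometric mean of the rest.

**Cluster adjustment.**  Participants are sampled within schools.  Rather
than a random-intercept mixed model, inference uses the cluster-robust
(CR1/"Stata") sandwich covariance by school — HC1 small-sample factor
$\tfrac{G}{G-1}\tfrac{n-1}{n-k}$ — with $t_{G-1}$ reference ($G$ = number
of schools).  This is the simplest standard correction for few clusters,
is exactly testable against a hand-built sandwich, and collapses to the
familiar heteroscedasticity-robust estimator when every cluster is a
singleton.  The naive OLS covariance is retained alongside it.  The
overall "model p" is the joint Wald test of all non-intercept coefficients
under the cluster-robust covariance, referred to $F(q, G-1)$; the
definition of a published "model p" is rarely stated, so this package fixes
one and documents it.

**Reallocation.**  For a base composition $x_0$ (by convention the sample
geometric mean), moving $\Delta$ minutes from behaviour $A$ to behaviour
$B$ yields $x_1$ with the same 1440-minute total.  The predicted outcome
difference is $\hat\delta = (z_1 - z_0)^\top \hat\beta_z$ — the covariates
cancel — with variance $(z_1 - z_0)^\top
\widehat{\mathrm{Cov}}(\hat\beta_z) (z_1 - z_0)$ and a $t_{G-1}$ CI.  The
estimate is invariant to which rotation the model was fitted in (ILR
isometry).  Because the ILR map is nonlinear in $\Delta$, the
$A \to B$ and $B \to A$ differences are only antisymmetric to first order;
the residual shrinks as $O(\Delta^2)$, which the tests verify by comparing
$\Delta = 30$ against $\Delta = 1$.  Published reallocation tables appear
both per-$\Delta$ and per-minute (they differ by a factor of
$\approx \Delta$), so `reallocation_grid()` emits both scales and treats
the per-$\Delta$ scale as primary; neither is silently corrected into the
other.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| closure constant | 1440 | min/day | a full day; descriptive shares use closure to 100 |
| ENMO cut-points | 35.6 / 201.4 / 707.0 | milli-g | adolescent wrist thresholds; intervals left-closed at the upper bound, so a value exactly at a cut-point takes the higher class |
| valid day | ≥ 16 h wear, > 0 min sleep | — | midnight-to-midnight day definition |
| inclusion | ≥ 3 valid days | — | participants under the bar are excluded and accounted in the flow |
| reallocation $\Delta$ | 30 | min | a realistic, intervention-achievable shift |
| $\alpha$ | 0.05 | — | two-sided, no multiplicity correction (a documented limitation) |

Cut-point boundary sources occasionally print the vigorous threshold as
707.7 mg; this package reads that as a typographical variant of 707.0 and
uses left-closed upper intervals throughout, so classification is a total
monotone step function of ENMO.

Zero minutes in any part are a hard error in the compositional layer — the
log-ratio machinery is undefined at zero and well-collected 24-h data
contains none.  `replace_zeros()` offers multiplicative replacement
(default 1 minute, total preserved) as an explicit opt-in pre-step; it is
never applied automatically.

The rotation rule is: pivot part first, remaining parts in canonical order
(sleep, SED, LPA, MVPA).  Only the first coordinate is interpreted, so the
tail order is a free choice fixed once for reproducibility.

EPOCH items are coded 1–5 ("Almost never" … "Almost always"); some summary
tables print a 0–5 range, but the instrument has five options and published
usage scores 1–5, so 1–5 is used.  The instrument is positively worded —
no reverse-coding.  The default item→domain mapping
(`default_epoch_mapping()`) assigns consecutive blocks of four items per
domain; it is a synthetic placeholder layout (the real instrument
interleaves items), and studies with real exports should supply their own
two-column mapping.  Any missing or out-of-range item invalidates the
participant; there is no partial imputation, matching how such exclusions
are reported in study flow charts.

## What the synthetic generator emulates

`cohort_config()` encodes the study conditions: n = 124 adolescents aged
13–17 (mean 14.8, SD 1.0) in 7 school clusters, gender sampled at
49.2/46.0/4.8% male/female/other (the "other" fraction exercises the
pre-model exclusion path), and a target geometric-mean composition of
473.0 / 680.9 / 250.7 / 35.3 minutes for sleep/SED/LPA/MVPA.

Compositions are **logistic-normal**: ILR coordinates drawn from a
multivariate normal centred at the ILR image of the target centre.  Because
the part-wise geometric mean is closure-equivariant, the closed sample
centre converges to the target exactly.  The ILR covariance is derived from
a *target variation matrix* via
$\Sigma_\text{clr} = -\tfrac12 G T G$, $G = I - J/D$, so the generated
sample reproduces $T$ in expectation.  The default $T$ uses the reported
adolescent ordering — sleep–SED 0.054, sleep–LPA 0.063, SED–LPA 0.088 —
and sets the three MVPA pairs to 0.32/0.36/0.40, chosen once as realistic
values that make MVPA the most compositionally distinct behaviour (its
implied log-SD is ≈ 0.44, consistent with the large relative spread of
adolescent MVPA).  The resulting ILR covariance is verified
positive-definite at config time.

Outcomes are linear in the centred log-ratio of the composition: each
domain has a zero-sum "part effect" vector $a$, and the true ILR
coefficient vector in any basis is $V^\top a$ — the quantity the fitted
models must recover.  The default calibration gives happiness
$a = (0, -0.6, +0.8, -0.2)$ for (sleep, SED, LPA, MVPA), i.e. a positive
LPA and negative SED effect whose implied LPA-vs-rest coefficient is
≈ 0.92, and leaves the other four domains null — reproducing the direction
of the published findings without copying their magnitudes.  Age (−0.05
per year, centred at 14.8) and gender (−0.10 female vs male) effects,
additive school random intercepts (SD 0.15), and residual noise (SD 0.70)
complete the outcome model; intercepts sit at the published domain means.
School effects act on outcomes only, not on compositions, keeping the
confounding structure simple.

Item responses are each domain score plus Gaussian noise, rounded into
1..5.  The item-noise SD is 0.25, calibrated (once, by simulation across
five seeds at n = 1000) so that re-scoring the items recovers the domain
score within 0.5 points for ≈ 99% of participants — the generator's
round-trip contract.

Everything is driven by R's default Mersenne-Twister RNG under a single
seed, so a config regenerates its cohort bit-identically; the ground truth
(school effects, noiseless outcomes, per-basis true betas) is stored with
every dataset.

**What it does not emulate.**  Raw accelerometry (autocalibration,
non-wear detection, sleep-onset algorithms) is out of scope — sleep is a
supplied per-day field.  Day-to-day variation in
`generate_day_summaries()` is symmetric logistic-normal noise; real
wear-time patterns (weekend effects, device removal) are richer.  Outcomes
are genuinely linear in clr with Gaussian noise, so passing
parameter-recovery and coverage tests shows the estimator is correct under
its own assumptions, not that real wellbeing data satisfies them.

## Numerical choices and simulation regimes

* Closure tolerance 1e-9 relative; ILR round-trips are tested to 1e-9 and
  oracle agreement to 1e-10.
* The variation matrix uses the n−1 sample-variance denominator, matching
  common CoDA software.
* Averaging order: a participant's valid days are averaged in raw minutes
  first, then closed — matching how arithmetic means are reported in raw
  minutes alongside a closed geometric-mean composition.
* Statistical calibration checks use regimes where the sandwich
  asymptotics are meaningful, chosen as the package's own test conditions:
  CI coverage over 200 replicate cohorts at n = 2000 with 20 schools
  (pooled over the three ILR coefficients, accepted within 92–98%);
  type-I error of the pivot coefficient over 1000 replicate null cohorts
  at n = 200 with 25 schools (accepted within the 99% binomial band around
  5%, i.e. 3.3–6.8%); qualitative sign reproduction at n = 500 with 10
  schools, where the calibrated effect has high power.  With only 7
  clusters — the study's own condition — CR1 inference is known to be
  approximate; that is a property of few-cluster sandwiches, not of this
  implementation, and is why the calibration regimes use more schools.
* Degenerate inputs fail loudly: single-level gender, a single school,
  rank-deficient designs (collinear columns are named), infeasible
  reallocations (Δ ≥ donor minutes), zero or negative parts.

## Known limitations

* Cluster-robust OLS, not a mixed model; with very few clusters the CR1
  t(G−1) intervals are approximate.
* No multiplicity correction across the 20 regression rows or 60
  reallocation cells, matching common practice in this literature.
* Sleep is modelled linearly; non-linear (U-shaped) sleep–wellbeing
  relationships are outside the model family.
* The reallocation engine predicts along the fitted linear model; it makes
  no causal claim about actually moving minutes.
* Cross-sectional associations only; no longitudinal structure is
  generated or modelled.
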