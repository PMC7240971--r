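---
title: "Methods: LMS reference curves and hierarchical associations for pediatric metabolite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LMS reference curves and hierarchical associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedmetref)
```

## Scope

`pedmetref` estimates age- and sex-dependent reference percentile curves
for panels of blood metabolites in children (0.25–18 years), converts
measurements to standard deviation scores (SDS), and tests associations of
those scores with BMI-SDS, pubertal (Tanner) stage, age intervals and
laboratory markers. Because individual-level pediatric cohort data are
rarely shareable, the package ships a synthetic-cohort generator that
reproduces the *statistical structure* such analyses must cope with —
age-dependent skewed distributions, repeated visits, sibling clusters,
detection-limit censoring, rare gross outliers — so every stage is testable
end to end.

## Distributions

The LMS parameterization describes a positive, right-skewed response at a
given age by the Box–Cox power $L$ (skewness), the median $M$, and the
coefficient of variation $S$. Under the Box–Cox Cole–Green (BCCG) family

$$z = \frac{(y/M)^L - 1}{L\,S} \;(L \neq 0), \qquad
  z = \frac{\ln(y/M)}{S} \;(L = 0)$$

is standard normal; the Box–Cox $t$ (BCT) family refers the same $z$ to a
Student $t$ with $\tau$ degrees of freedom, adding a kurtosis dial.
Numerical choices:

* $|L| < 10^{-5}$ switches to the log-form branch, avoiding catastrophic
  cancellation in $((y/M)^L - 1)/L$.
* Log-densities include the Jacobian $(L-1)\ln(y/M) - \ln(MS)$ **and** the
  exact truncation normalizer $F_{\mathrm{kernel}}(1/(S|L|))$ for the
  restriction to $y > 0$, so densities integrate to one to quadrature
  accuracy (the unit tests verify this to $10^{-4}$).
* Quantiles use the conventional untruncated LMS inversion
  $C_\alpha = M(1 + L S z_\alpha)^{1/L}$, which round-trips exactly with
  the z-transform; the truncation mass is negligible for the $S|L| \le 0.3$
  regime metabolite panels occupy. Quantiles outside the Box–Cox support
  ($1 + LSz_\alpha \le 0$) are rejected rather than clamped.
* BCT quantiles use $t_\tau$ quantiles directly (the convention of the
  originating GAMLSS literature), not a variance-rescaled $t$. SDS from a
  BCT reference maps $z$ through the probability integral transform,
  $\Phi^{-1}(F_{t_\tau}(z))$, so reported SDS are N(0,1)-scaled for both
  families.

## Reference-curve fitting

$L(t)$, $M(t)$, $S(t)$ are expanded over cubic B-spline bases in
$\sqrt{t}$ (age transformed so infancy, where levels move fastest, receives
more knot resolution); links are identity for $L$ and log for $M$, $S$ and
the constant $\tau$. Coefficients maximize the joint log-likelihood
$\sum_i \log f(y_i \mid L(t_i), M(t_i), S(t_i), \tau)$ by BFGS with a soft
barrier keeping the optimizer in $|L| \le 3$, $S \in (e^{-9}, 1.5]$.
Initialization is deterministic and robust: $M$ from a running median of
$\log y$ projected onto the basis, $S$ from the MAD of the residuals,
$L = 1$, $\tau = 10$. A restart schedule re-launches BFGS from the current
point; fits that still fail are *flagged*, never silently returned. The
optimizer's final likelihood is checked against its initialization in the
tests (it never decreases).

Smoothness is a basis-dimension choice. Default candidate grids are
$\{2,3,4,5\}$ basis functions for $M$ and $\{1,2,3\}$ for $L$ and $S$
($\tau$ constant), selected by BIC through a forward per-parameter search —
$M$ first with $L, S$ minimal, then $S$, then $L$. The forward search fits
roughly $|g_M| + |g_S| + |g_L|$ models instead of the full cross product;
on data simulated from the generator's smooth truth curves it selects the
same model as an exhaustive search would whenever the BIC differences are
non-marginal, and BIC rather than AIC is the selector to favor parsimony.
Ties at any stage keep the smaller dimension, and the BCCG-vs-BCT decision
returns BCT only when its BIC is *strictly* lower.

### Cluster-aware resampling

Repeated visits and sibling clusters make the pooled likelihood
overconfident and let a heavily sampled family drag the curves. The
resampling scheme draws, per iteration, one visit per *family* uniformly at
random (breaking subject- and sibling-level dependence simultaneously),
refits at the basis dimensions selected once on the pooled data, and
evaluates the parameter curves on a fixed 72-point age grid. The final
curves are the pointwise median across iterations (robust to occasional bad
iterations), projected back onto the basis by least squares on the link
scale. Iterations that fail to converge are dropped and counted; more than
20 % dropped aborts the fit. With 100 iterations (the default) the
aggregated curves are stable to the third digit on generator data; when
every family contributes a single visit the procedure reproduces the plain
fit exactly, which the tests assert.

## Quality control

* **Detection limit**: a metabolite is excluded when *strictly more* than
  5 % of its values fall below the limit; zeros always count as
  non-detects. The strict inequality matters at the boundary (5 of 100
  below keeps the metabolite, 6 of 100 drops it) and is pinned by tests.
* **Outliers**: values whose natural log deviates more than 5 SD from the
  mean of the log of the *nonzero* data are removed, once, per metabolite
  across the whole cohort (the rule is not stratified by age or sex). The
  mask is identical under any log base because deviation and SD rescale
  together. Zeros never enter the moments and are never flagged — they are
  non-detects, not biology — and are excluded later by the fitting step,
  which requires $y > 0$. The rule is deliberately not iterated:
  re-application after removal could cascade.

## Association analyses

All tests share one engine: a Gaussian random-intercept model (subject
level) fitted by REML via `lme4`, on a z-scaled response and z-scaled
continuous covariates, so coefficients are standardized; p-values are Wald
normal. The subject intercept absorbs within-child correlation — on
clustered null data the test holds its nominal 5 % size where ordinary
regression inflates it, which is both a unit test and an acceptance-level
simulation here.

* **Age-interval trends**: metabolite SDS on age within half-open intervals
  $[a, b)$ (boundary ages belong to the right-hand interval), default cuts
  at 1, 5, 9 and 13 years — the ages at which the four canonical profile
  types change character. Intervals with fewer than 30 observations are
  reported not-estimable rather than dropped.
* **BMI-SDS**: SDS ~ BMI-SDS × sex; the interaction p-values are one
  Benjamini–Yekutieli (BY) family, and metabolites with a significant
  adjusted interaction are reported per sex, otherwise pooled with a sex
  main effect.
* **Tanner stages**: per sex, stage as a categorical factor with the
  pre-pubertal stage 1 as reference; the 2–5 contrasts across metabolites
  and sexes form one BY family.
* **Lab-marker correlations**: each cell of the metabolites × markers
  matrix is the standardized random-intercept coefficient — not a raw
  Pearson r — computed on absolute values and, separately, on SDS of both
  sides (the age/sex-adjusted analysis, where marker SDS come from
  user-supplied LMS tables or an internal fit with the same machinery).
  All cells of a matrix are one BY family. Metabolite rows are clustered by
  agglomerative (average-linkage, Euclidean) clustering of their
  correlation profiles, $k = 5$ by default.
* **FDR**: the BY step-up
  $p_{(i)}^{adj} = \min_{j \ge i} \min(1, m\,c(m)\,p_{(j)}/j)$,
  $c(m) = \sum_{h=1}^m 1/h$, implemented in-package and cross-checked in
  the tests against `stats::p.adjust(method = "BY")` and a hand
  computation. BY families are per analysis block, as listed above.
  Significance always refers to adjusted p-values at level 0.05.

## The synthetic-cohort generator

Defaults emulate the target study design: 2191 subjects, mean 1.82 visits
each (≈ 3989 samples) between 0.25 and 18 years, 50 % female, 15 % of
subjects in sibling families (pairs), and a 30-metabolite panel (23 amino
acids with Leu/Ile merged, 6 acylcarnitines, free carnitine) with BCT for
the three kurtotic metabolites (Asp, Met, Tau) and BCCG otherwise. Median
curves follow four profile types: (1) elevated in infancy, dip by 1–5 y,
mild rise to 18 y; (2) strictly increasing; (3) rise then plateau from
≈ 5–9 y; (4) flat. $S = 0.15$, $L = 0.4$, $\tau = 5$, and a 5 % male level
shift are fixed, biologically plausible choices for whole-blood amino-acid
panels; they are simulation conditions, not fitted quantities.

Dependence is induced on the z-scale: each metabolite's latent
$z = \sqrt{\lambda}\,F + \sqrt{1-\lambda}\,(\sqrt{\rho}\,u_{subj} +
\sqrt{1-\rho}\,\varepsilon)$ with intraclass correlation $\rho = 0.4$ (a
free parameter — the magnitude of within- vs between-child variance is not
identified by published summaries, so it is a declared assumption) and a
shared factor loading $\lambda = 0.3$ giving realistic cross-metabolite
correlation; the marginal stays exactly N(0,1), so marginal percentiles are
undistorted, and BCT marginals are obtained through a Gaussian copula
($t_\tau$ quantile of the normal CDF). Lab markers are linear combinations
of target-metabolite z-scores plus optional age trend and noise, scaled so
the marker-vs-single-target correlation hits its configured value
(cystatin-C-like: ρ = 0.5 with ten metabolites; HbA1c-like: ρ = −0.3;
creatinine-like: age-confounded). Tanner stage follows a cumulative-ordinal
model in age with earlier female onset, missing below age 8. LOD censoring
writes zeros; injected outliers multiply by $e^7$, safely beyond any ±5 SD
log band.

What the generator does **not** emulate: analytical batch effects, real
marginal concentration levels (published appendix tables are not
reproduced), assay imprecision profiles, informative missingness, or
profile-type heterogeneity within a metabolite. Passing tests therefore
demonstrate that the *estimator and testing machinery* are correct and
calibrated under the assumed data-generating structure — not that any
specific real-world reference interval is reproduced.

## Validation problem sizes

The acceptance-level checks run at sizes chosen to make the Monte-Carlo
error small relative to each tolerance: percentile coverage is evaluated on
held-out cohorts of 4000 observations per sex (coverage tolerance ±0.7
percentage points; the binomial SE at the 2.5th percentile is ≈ 0.17
points, fit error dominates); FDR control uses 500 tests × 200 replicates;
the size of the hierarchical Wald test uses 2000 replicates of 300
subjects × 2 visits; slope recovery averages 50 seeds. All seeds are fixed
and every simulation is reproducible from them.

## Known limitations

* The exact resampling-aggregation scheme used with the LMS method in the
  cohort literature is not published in detail; one-visit-per-family with
  pointwise-median aggregation is this package's design choice, validated
  by its own identity and robustness tests.
* $\tau$ is constant in age; an age-varying kurtosis would need a richer
  basis and is rarely identified at cohort sizes.
* Wald normal p-values (no Kenward–Roger or Satterthwaite correction) are
  anti-conservative for very small group counts; with hundreds of subjects
  the size simulations show they are accurate.
* No extrapolation outside 0.25–18 years: SDS requests there are errors by
  design.
* `L` is the least identified LMS parameter; at n = 5000 its MLE has a
  sampling SD of ≈ 0.04 even for a constant-parameter model. Median and
  spread curves are recovered to a few percent at the same n.
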