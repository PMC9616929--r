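---
title: "Methods: the composite health index, its risk model, and the selection experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the composite health index, its risk model, and the selection experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthindex)
```

## The index and its two readings

The health index of an individual is a weighted sum of deviations of
predicted absolute disease risks from population lifetime risks,

$$I=\sum_{d} l_d\,(\rho_d - r_d),$$

where $l_d \ge 0$ is the life-expectancy reduction (years) attributable to
disease $d$, $\rho_d$ its lifetime risk, and $r_d$ the individual's
predicted absolute risk. The unit is estimated life years and higher values
mean lower expected burden. Two readings of the same formula are used
throughout:

* the **genetic index** $I$, with $r_d$ from the PRS via the Gaussian risk
  model below — this is what selection acts on;
* the **case/control index** $I^c$, with the recorded status $c_d \in
  \{0,1\}$ in place of $r_d$ — this is the outcome-based evaluation metric.
  It uses no genetic information. Diseases whose case definition
  substantially overlaps another included disease are excluded from $I^c$
  (in the bundled panel, heart attack, which overlaps coronary artery
  disease) to avoid double counting in evaluation; they still contribute to
  $I$.

Sex-specific diseases (breast cancer for females; prostate and testicular
cancer for males) contribute nothing — not the term $l_d\rho_d$, but no term
at all — for the non-applicable sex. This makes the raw index
systematically different between sexes, which is why a sex adjustment
exists. We chose per-sex mean centering as the minimal adjustment: it zeroes
the between-sex offset while preserving rank order within each sex, and is
isolated in `sex_adjust()` so that, e.g., per-sex standardization is a
one-line swap.

## Gaussian risk model

The PRS for one disease is modelled as a two-component normal mixture with
status-dependent means and a common SD,
$\phi(x) = (1-\pi)\,\mathcal N(\mu_0,\sigma) + \pi\,\mathcal N(\mu_1,\sigma)$,
which by Bayes' rule gives

$$r(x)=\Big(1+\tfrac{1-\pi}{\pi}
  \exp\big[\tfrac{(x-\mu_1)^2-(x-\mu_0)^2}{2\sigma^2}\big]\Big)^{-1}.$$

With equal variances the exponent is linear in $x$, so the model is
evaluated as $\operatorname{logit} r = \operatorname{logit}\pi +
\frac{\mu_1-\mu_0}{\sigma^2}(x - \frac{\mu_0+\mu_1}{2})$ through
`plogis()`. This is exact, monotone in the PRS, and returns risks that
approach 0/1 smoothly for arbitrarily extreme scores without overflow;
nothing is clamped. Two consequences worth knowing: $r$ at the midpoint of
the two means is exactly $\pi$, and the expected risk under the mixture
integrates back to $\pi$ (both are tested, the latter by quadrature to
1e-6).

Choices where the method leaves room:

* **Pooled $\sigma$.** Case and control SDs tend to be close in practice;
  we pool them as the sample-size-weighted average of group variances and
  report the case/control SD ratio as a diagnostic. An unequal-variance
  variant exists (`equal_variances = FALSE`) for diagnostics only — with
  unequal variances the risk is non-monotone in the tails, which we regard
  as an artifact.
* **Which prevalence enters the transform.** The configured model
  prevalence `specs$pi` is used by default (`risk_pi = "spec"`), not the
  in-sample case fraction, because lifetime risk and a cohort's observed
  case fraction are distinct quantities; both are retained in the fitted
  object. `pi` and `rho` are deliberately separate config fields.

## Synthetic cohorts: liability-threshold generator

Real cohorts with linked PRS and medical histories are access-gated, so the
package ships a generator that reproduces the distributional structure the
analysis assumes, making every downstream stage testable.

Mechanism, per individual: draw a PRS vector from
$\mathcal N(0, R)$ with $R$ the configured PRS correlation matrix; for each
disease form the latent liability
$L_d = a_d\,\mathrm{PRS}_d + \sqrt{1-a_d^2}\,e_d$ with $e_d$ standard
normal; declare a case iff $L_d > \Phi^{-1}(1-\pi_d)$. Sexes are
Bernoulli(1/2) and sex-specific statuses are set missing for the other sex
($\pi_d$ is then the within-applicable-sex prevalence).

**AUC calibration.** The loading $a_d$ is set from the identity
$\mathrm{AUC} = \Phi(\Delta\mu/(\sigma\sqrt2))$ with
$\Delta\mu = a\,\varphi(z)/(\pi(1-\pi))$, $z=\Phi^{-1}(1-\pi)$. The
identity treats the case/control PRS strata as Gaussian with the marginal
SD; under truncation they are only approximately so and their SDs shrink
slightly. The approximation is good in the regime of realistic predictors:
at AUC 0.616 and $\pi=0.2$ the realized AUC is high by about $+0.002$; the
bias grows toward low prevalence and high AUC (about $+0.013$ at AUC 0.686,
$\pi=0.01$). Tests therefore compare recovered separations against the
exact truncated-normal moment arithmetic, not against the naive identity.

**Comorbidity.** Phenotypic comorbidity beyond what PRS correlation induces
is injected through correlated residuals $e$: for a pair with target
case-case enrichment $t$ (observed/expected ratio), the total liability
correlation solving $P(L_a>z_a, L_b>z_b) = t\,\pi_a\pi_b$ is found by root
search over a bivariate-normal tail probability (computed by 1-D
quadrature), and the residual part is backed out. Keeping genetic and
residual channels separate lets phenotypic comorbidity exceed genetic
correlation, which is the empirically typical regime. The achievable
enrichment is bounded by $\min(\pi_a,\pi_b)/(\pi_a\pi_b)$; the bundled
default structure (`default_dependency_structure()`) respects this, using
moderate ratios (1.4–2.2) for common pairs and strong ones (2.5) only for
rare pairs, a 0.22 PRS correlation for the CAD–HCL pair, a handful of mild
PRS anti-correlations, and one mutually-exclusive-tendency pair (TC–CAD,
ratio 0.5). Pairs of diseases specific to different sexes can never
co-occur and get no target.

**Siblings.** $\mathrm{PRS}_i = s + u_i$ with a family-shared component of
variance equal to the sibling PRS correlation (default 0.5, i.e. full
siblings sharing half their genome) and an individual remainder, so
marginals match the unrelated cohort exactly. A shared-environment option
adds a family component to the residual liability the same way. Default
cohort scale mirrors a large biobank test set — 40,000 unrelated, 21,539
pairs, 969 trios — and is fully configurable.

**What the generator does *not* emulate:** age structure and censoring
(statuses are complete lifetime outcomes, so case/control-based gaps are
*larger* here than in a cohort whose follow-up is incomplete), ancestry
structure, genotype-level effects (PRS are drawn directly), and non-Gaussian
PRS shapes. Passing tests therefore demonstrate correctness of the
machinery and qualitative behaviors (attenuation among siblings,
monotone gain in group size), not the quantitative values any particular
real cohort would give.

**RNG.** A single master seed; `generate_unrelated()` seeds at
`seed`, sibling pairs at `seed + 1`, trios at `seed + 2`, and
`run_pipeline()` gives each selection experiment `seed + 100 + group size`.
Identical seeds give bit-identical cohorts.

## Selection experiments

Each replicate shuffles the cohort, partitions it into disjoint groups of
exactly `group_size` (the remainder when the cohort size is not divisible
is dropped *for that replicate* and re-randomized in the next — keeping
groups exactly sized is what makes the two forms of the gain identity
coincide), and selects the highest-index member per group; ties break
deterministically toward the lowest `individual_id`. Metrics:

$$\mathrm{RRR}_d = \frac{\pi_{\mathrm{rand},d}-\pi_{\mathrm{sel},d}}
  {\pi_{\mathrm{rand},d}}, \qquad
  \Delta I^c = \frac1{N_{\mathrm{group}}}\sum_g
  \big(I^c_{g,\mathrm{sel}} - \langle I^c\rangle_g\big)
  = \langle I^c\rangle_{\mathrm{sel}} - \langle I^c\rangle .$$

$\pi_{\mathrm{rand}}$ is computed on the full cohort including the selected
(the comparison is selected vs the total test set), restricted to the
applicable sex for sex-specific diseases — as is $\pi_{\mathrm{sel}}$.
`index_gain_identity_check()` verifies the algebraic identity above and
reports the discrepancy when a remainder was dropped. The reported
$\Delta I^c$ is the sum of per-disease components
$l_d(\pi_{\mathrm{rand},d}-\pi_{\mathrm{sel},d})$ over the $I^c$ diseases,
which makes the disease breakdown exactly additive.

The default 25 replicates reuse the same individuals under fresh groupings,
so the replicate spread estimates grouping noise only (an underestimate of
full sampling variance — there is no fresh-cohort variance in it).
Intervals are percentile intervals (2.5/97.5) across replicates. DALY
evaluation swaps the evaluation weights to $l_d + q_d\,\Delta y_d$
($q_d \in [0,1]$ a disability factor, $\Delta y_d$ the years between
average onset and death) while *selection stays on the life-year index*.

**Siblings.** Families cannot be re-grouped, so no bootstrap: the
prevalence among selected siblings gets a closed-form 95% Wilson score
interval, translated endpoint-wise to the RRR scale with
$\pi_{\mathrm{rand}}$ held fixed (the upper prevalence endpoint becomes the
lower RRR endpoint). Gain components are reported without error bars.

**Quantile profiles.** `quantile_prevalence()` bins by equal-count index
quantiles (default 25) and bootstraps the prevalence within each bin
(default 100-fold, no re-binning); bins with fewer than 5 cases trigger a
warning rather than suppression.

## Dependency characterization

For each disease pair: the Pearson PRS correlation (computed on the whole
cohort — PRS exist regardless of sex and of case status); the **χ² ratio**,
i.e. the observed/expected case-case cell of the 2×2 contingency table,
signed positive/negative for more/less coincidence than chance; and the χ²
independence-test p-value as a signed $\log_{10}$. The ratio and signed
log-p are masked for pairs not significant at $p=0.05$. The test is plain
Pearson χ² — no continuity correction — with a `correct` flag for Yates if
wanted. Disjoint-sex pairs have no jointly observed statuses and are
skipped.

Index-vs-additional-phenotype analyses run separately per sex: Welch
t-tests (the safer unequal-variance default) with the sign convention
`mean(controls) − mean(cases)` (positive = controls healthier), raw
p-values plus a Bonferroni column; per-trait Pearson correlations; and a
multivariate regression of the index on all traits, each centered and
scaled to unit L2 norm, reporting the full-fit $R^2$ with its SD across
10-fold cross-validation out-of-fold $R^2$ values (the spread quantifies
how unstable a near-zero $R^2$ is; 10 folds is the conventional choice).

## Numerical and degenerate-input choices

* Risk evaluation via log-odds; no clamping anywhere.
* Fitting requires ≥2 cases and ≥2 controls; degenerate strata raise an
  error naming the disease.
* User correlation matrices are validated (symmetry, unit diagonal, PSD to
  1e-8); a tiny diagonal bump (1e-8) guards Cholesky against roundoff at
  the PSD boundary.
* Zero reference prevalence makes RRR undefined: reported as `NA` with a
  warning, never as ±Inf.
* Zero-variance PRS columns yield `NA` correlations with a warning.
* Collinear trait predictors are handled by `lm()`'s rank-deficient least
  squares with a warning, so $R^2$ stays defined.

## Problem sizes used by the test suite

Unit tests run cohorts of 2k–100k individuals; the end-to-end validation
uses 200k individuals for calibration recovery and null-dependency checks
(three independent 200k datasets for separation recovery, whose per-dataset
sampling SD of ~0.9% would otherwise dominate a 2% comparison), 100k groups
for the order-statistic check against $E[\max(Z_1,Z_2)]=1/\sqrt\pi$, 1,000
simulated datasets for the χ² type-I rate, 3,000 for Wilson coverage at
$n=969$, and 40k/20k cohorts for the monotone-gain and sibling-attenuation
experiments. The full suite runs in well under a minute on one CPU.

## Known limitations

* The index is linear in risks with externally supplied weights; no
  interaction between diseases, no age-dependent or cause-specific
  mortality, no discounting in the DALY variant.
* The bundled 20-disease parameter file is a synthetic placeholder
  (realistic magnitudes, correct qualitative constraints such as the
  ~1.6 MDD/AD weight ratio and near-zero BCC/IBD weights); it is suitable
  for simulation studies only.
* $I^c$ treats recorded statuses as lifetime outcomes; with real,
  incompletely followed cohorts it understates lifetime burden and skews
  toward early-onset diseases.
* The generator's case-stratum PRS distributions are exactly Gaussian only
  in limits, so the AUC calibration identity carries the small bias
  quantified above.
* "Genetic correlation" here means PRS correlation as seen by the
  predictors, not an LD-score or variant-level estimate.
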