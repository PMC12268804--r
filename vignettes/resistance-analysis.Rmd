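---
title: "Quantal bioassay analysis of insecticide resistance: models, decisions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal bioassay analysis of insecticide resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistlab)
```

resistlab implements the statistical core of a laboratory resistance
characterization study: probit concentration–mortality analysis, the
genetics of resistance inheritance (dominance and number of loci), and the
population dynamics of resistance stability. This vignette explains the
models behind each function, the parameters that matter, the decisions
taken where published practice leaves the method open, and what the
simulation-based validation does and does not establish.

## The probit dose–response model

A quantal bioassay exposes groups of insects to a series of concentrations
and records deaths. The package models the probability of death at
concentration $c$ (μg a.i./mL) as

$$\Pr(\text{death}) = \Phi(\alpha + \beta \log_{10} c),$$

with $\Phi$ the standard normal distribution function. This is the classic
tolerance interpretation: individual log10 tolerances are normally
distributed, and $\beta$ (the "slope", probits per log10 unit) is inversely
proportional to the tolerance spread. `fit_probit()` obtains the maximum
likelihood estimates by iteratively reweighted least squares (the standard
binomial GLM algorithm), with the parameter covariance from the observed
information at the optimum. Replicates at the same concentration are pooled
before fitting — the likelihood is identical either way — and control rows
(concentration 0) never enter the likelihood; the dose metameter is always
$\log_{10} c$, matching the convention of the `dose.p` lineage of probit
software.

Two degenerate shapes are refused rather than fitted: a perfect 0 → 1
mortality step (complete separation: the slope diverges and no maximum
exists) and identical observed mortality at every concentration (the slope
is unidentifiable). A fitted $\beta \le 0$ is legal but attaches a warning,
since a declining mortality line usually signals a data problem.

**Goodness of fit and heterogeneity.** Lack of fit is measured by the
Pearson $\chi^2$ over the pooled concentration groups with
$\mathrm{df} = \text{groups} - 2$. When its p-value falls below 0.05, the
covariance used downstream is multiplied by the heterogeneity factor
$\chi^2/\mathrm{df}$ — the classic probit-analysis correction for
overdispersed assays — and the inflation is recorded on the fit and on
every interval that inherits it.

**Lethal concentrations.** `estimate_lc()` inverts the fitted line:
$\mathrm{LC}_p = 10^{(\Phi^{-1}(p) - \alpha)/\beta}$, with a delta-method
standard error on the log10-dose scale and a 95% interval
$10^{\log_{10}\mathrm{LC}_p \pm 1.96\,\mathrm{se}}$. We use the delta
method rather than Fieller fiducial limits because it is the behaviour of
the widely used `dose.p` convention and propagates cleanly into ratio
intervals; the choice is recorded in report metadata. The test suite
cross-checks the point estimates and standard errors against
`MASS::dose.p` on the same fits.

**Resistance ratios.** `resistance_ratio()` divides two LC estimates at
the same quantile and compound. Its interval uses the lethal-dose-ratio
method for independent fits,
$\mathrm{se} = \sqrt{\mathrm{se}_R^2 + \mathrm{se}_S^2}$ on the log10
scale. Ratios computed from bare published point values (no covariance)
are flagged `rounded_inputs`, because a ratio of rounded LC50s can differ
in the second decimal from one computed from full-precision fits — a
discrepancy that in published tables is real and visible.

**Equality and parallelism.** `compare_lines()` compares $k$ fitted lines
by likelihood ratio against the model with a separate intercept and slope
per line: the parallelism hypothesis (common slope) has $k - 1$ df, the
equality hypothesis (a single line) has $2(k-1)$ df. For reciprocal F1
crosses, failing to reject equality is the standard evidence that
resistance is autosomal rather than sex-linked or maternal. The statistic
is invariant to rescaling the concentration units, which only shifts
intercepts on the log scale.

**Abbott's correction.** `abbott_correct()` rescales treated mortality by
pooled control mortality, $(\text{obs} - c)/(1 - c)$, rejecting assays
with control mortality ≥ 20%. It is available but **off by default**:
rescaling is only appropriate when natural mortality is believed additive,
and when control deaths are negligible the correction is a no-op. Whether
to apply it is an explicit pipeline flag that is logged in every report.

**Diagnostic dose.** `diagnostic_dose()` returns the upper 95% confidence
limit of the susceptible strain's LC99 — a discriminating concentration at
which essentially all susceptible homozygotes die, used to track
resistance frequency over generations.

## Dominance of resistance

Two complementary statistics grade dominance:

* **Stone's D** from LC50s on the log scale,
  $D = (2X_F - X_R - X_S)/(X_R - X_S)$ with $X = \log_{10}\mathrm{LC}_{50}$,
  a single number per cross: $+1$ fully dominant resistance, $-1$ fully
  recessive.
* **Bourguet's dominance level** from mortalities at one concentration,
  $D = (M_{RS} - M_{SS})/(M_{RR} - M_{SS})$. This is dose-dependent:
  `dml_curve()` traces it across concentrations from three fitted lines,
  and it typically declines as dose rises — resistance that is effectively
  dominant at low field rates becomes effectively recessive at high ones,
  which is exactly why dose choice matters for resistance management.

Classification uses a small tolerance (0.005) around the ±1 endpoints, the
sign otherwise, and Bourguet values outside $[-1, 1]$ (possible with
non-monotone observed mortalities) are flagged, never clamped — clamping
would hide an internally inconsistent mortality pattern.

`functional_dominance()` compares strain mortalities assayed at a single
field-rate dose: pairwise two-proportion z-tests with a single-step
max-|z| familywise adjustment computed from the joint normal law of the
contrasts (the Tukey-style analogue for binomial proportions), a compact
letter display, and Bourguet's D at the dose. With sparse cells (< 5) the
pairwise p-values switch to Fisher mid-p exact tests with Bonferroni
adjustment, since the normal approximation is then untrustworthy.

## The backcross test of monogenic inheritance

Under a one-locus model, backcrossing F1 heterozygotes to the susceptible
parent yields 1:1 heterozygote:susceptible offspring, so expected backcross
mortality at any concentration is $p = (a + b)/2$, the mean of the two
parental-genotype mortalities. `monogenic_test()` compares observed dead
counts against this expectation per concentration with
$\chi^2 = (N_i - p n_i)^2 / (p q n_i)$, df = 1 — algebraically the squared
one-sample proportion z-statistic, which the tests verify on random
inputs. Significance is row-wise at $\alpha = 0.05$ with no multiplicity
adjustment, mirroring how such tables are conventionally presented; the
overall verdict (reject monogeny if **any** row is significant) is an
explicit, configurable policy, and with six rows its per-experiment
type-I error is $1 - 0.95^6 \approx 0.26$, not 0.05. Users who want a
family-level 5% error should adjust $\alpha$ accordingly.

Where do $a$ and $b$ come from? Published practice is ambiguous between
observed parental mortalities at the same tested concentration and values
predicted from the parental probit fits. The package supports both and
records the source; the pipeline defaults to fitted values because
observed parental proportions at n = 40 carry enough sampling noise to
inflate the test's false-rejection rate, while the simulator's calibration
experiments use the true (model) mortalities so that the test's nominal
behaviour is measured, not the noise of its inputs.

## The synthetic-data generator

The simulator is a first-class module, not a test fixture: it generates
data with exactly the structure the analyses assume, so every estimator
can be validated against a known truth.

**Tolerance architecture.** `genetic_architecture()` places log10
tolerance at $X_S$ for the fully susceptible genotype and $X_R$ for the
fully resistant one, with $k$ unlinked loci of equal additive effect
$(X_R - X_S)/2k$ per R allele and within-locus dominance $h$; mortality at
dose $c$ is $\Phi(\beta(\log_{10} c - \text{tolerance}))$ with a common
slope across genotypes (fitted slopes of related strains are typically
similar; per-genotype slopes would add a nuisance dimension the analyses
never estimate). When emulating a reported cross, the heterozygote is
placed by Stone's D via $h = (D+1)/2$ — the exact inverse of the dominance
statistic, which the suite verifies to 10⁻¹² — because studies report D,
not $h$. Polygenic alternatives keep the parental endpoints fixed, so a
monogenic and a five-locus architecture are matched head-to-head except
for the segregation pattern.

**Default conditions.** The defaults reproduce the scale of the motivating
study system: susceptible LC50 0.64 and resistant LC50 3 080.95 μg a.i./mL
(a ≈ 4 800-fold ratio), F1 placed at D = 0.13, slope ≈ 1.5, 40 insects per
concentration (five replicates of eight), seven log-spaced doses bracketing
each strain's LC50, and the six-dose backcross series 3.2–560 μg/mL.
`simulate_inheritance_experiment()` emits the eight tables of the classic
design (two parents, two reciprocal F1s, four backcrosses); reciprocal
labels are metadata only, since the simulated genetics are autosomal.

**Cage dynamics.** `simulate_stability()` propagates a one-locus cage
founded from RR and SS homozygotes (e.g. 80R:20S) through discrete,
non-overlapping generations on the standard life cycle: random mating
produces Hardy–Weinberg zygotes; viability selection acts on the zygotes
with fitness 1, $1 - h_c s$, $1 - s$ for SS, RS, RR; in stochastic mode a
Wright–Fisher multinomial draw of N (default 600, the scale of a rearing
cage of a few hundred adults) forms the next generation. Selection acting
on Hardy–Weinberg zygotes makes the deterministic allele trajectory obey
the classical recursion
$p' = p\,[1 - s(p + h_c(1-p))]\,/\,[1 - s(p^2 + 2 h_c p (1-p))]$
exactly — the founding adults themselves experience no viability cost,
having been raised in their source colonies. The fitness-cost magnitude is
deliberately **not** defaulted to a nonzero value: a cost is a hypothesis,
its published magnitude is not identifiable separately from its dominance
in a six-generation decay curve, and the simulator leaves $s$ and $h_c$ as
explicit configuration (default $s = 0$). An optional `selection_dose`
exposes each generation before mating, emulating laboratory selection
episodes. `population_lc50()` reports the mixture LC50 (root of the
frequency-weighted mortality curve), which is what a probit assay of the
cage estimates.

**What the simulator does not emulate.** Real bioassays bring
between-replicate overdispersion, day and operator effects, control
mortality, dose-preparation error, and genetic architectures with unequal
effects, linkage, or epistasis; real cages have overlapping generations,
fecundity differences, and non-random mating. Passing the validation suite
therefore shows that the estimators are correct *under the model they
assume*, with honest calibration at the study's sample sizes — it does not
certify behaviour under model violations, except where a test injects one
deliberately (e.g. polygenic data under the monogenic null).

## Numerical choices and validation scale

* GLM convergence follows the standard IRLS criterion (relative deviance
  change < 10⁻⁸, up to 100 iterations); the suite checks the fitted
  log-likelihood against a dense two-parameter grid-search oracle to
  within 10⁻³ on 50 simulated assays.
* Duplicate concentrations are pooled before the Pearson statistic so the
  heterogeneity df convention (groups − 2) is unambiguous.
* `population_lc50()` brackets its root 8 probits beyond the extreme
  genotype tolerances and solves to 10⁻¹² on the log10 scale.
* All randomness flows through explicit integer seeds (`withr::with_seed`,
  never the global RNG state), and per-table seeds are derived from a
  master seed, so every simulated object is byte-reproducible.
* Monte-Carlo validation sizes: 500 assays for LC50 interval coverage
  (target 0.92–0.975 at 40 × 6), 2 000 backcross experiments for the
  monogenic test's per-row type-I error (target 0.03–0.07), 300 paired
  experiments for its power ordering across architectures, 200 pipeline
  replicates for end-to-end dominance recovery (±0.08 around D* = 0.13),
  and 1 000 neutral cages for the drift martingale check. These sizes keep
  the full suite to a few minutes while leaving each band's Monte-Carlo
  error well inside the band.

## Known limitations

Fiducial (Fieller) limits, non-probit links, time–mortality models and
mixed-effects probit are out of scope. The monogenic test addresses only
the one-locus null; it does not estimate the number of loci. The stability
model is single-locus: polygenic decay under a cost is qualitatively
similar but not covered by the recursion oracle. Ratios formed from
rounded published LC50s can disagree with full-precision ratios in the
last printed decimal; the package flags, but cannot repair, that loss of
precision.
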