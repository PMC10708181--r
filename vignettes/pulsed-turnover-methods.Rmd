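---
title: "Estimating protein turnover from pulsed isotope labeling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein turnover from pulsed isotope labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseTurnover)
```

## The kinetic model

After a whole-animal switch to a ¹⁵N diet, every newly synthesized protein
molecule carries the heavy label. If the proteome is at steady state —
constant protein abundance, zero-order synthesis balanced by first-order
degradation — the light (¹⁴N) fraction of a protein's pool decays
exponentially:

$$\mathrm{Fraction^{14}N}(t) = e^{-K_d t}, \qquad t_{1/2} = \frac{\ln 2}{K_d}.$$

Mass spectrometry measures this decay peptide by peptide: the light-channel
intensity of a peptide is (up to a peptide-specific ionization constant and
a sample-specific loading factor) proportional to the remaining unlabeled
protein. Taking logarithms turns the problem into linear regression:
$\log \mathrm{fraction}$ against time has slope $-K_d$. Everything in this
package is built on that linearization; we never fit the exponential
directly, because the measurement noise of MS intensities is close to
multiplicative (lognormal), which the log transform renders homoskedastic
and the linear mixed model assumes.

The model's assumptions, explicitly:

* **Steady state.** Protein abundance does not change over the labeling
  course; all light-channel decay reflects degradation plus dilution by
  growth. In growing or remodeling tissue, $K_d$ is a turnover rate, not a
  pure degradation rate.
* **First-order kinetics.** A single rate per protein per condition; no
  multi-compartment pools.
* **Positivity.** Intensities and fractions are strictly positive;
  non-positive input rows are rejected at ingest.

## Normalization to a long-lived panel

Run-to-run intensity differences (loading, spray, digestion) are removed
with a panel of long-lived proteins whose abundance — and, on the study's
timescale, whose light-channel signal — can be treated as fixed. For each
sample the factor is the geometric mean, over observed panel peptides, of
the ratio between the peptide's intensity in that sample and its
geometric-mean intensity across all samples; factors are rescaled to
geometric mean 1 so they are pure relative loadings. Geometric means are
the natural operator for multiplicative errors and are exact under pure
loading shifts: multiplying every intensity of a sample by $c$ multiplies
its factor by $c$ and leaves all downstream fractions unchanged (this
invariance is asserted in the tests at near machine precision — exact
bit-equality is not attainable once $c$ has passed through floating-point
log/exp arithmetic).

After normalization, each peptide's abundance is divided by its **day-0
baseline** to give the ¹⁴N fraction. Three baseline scopes are supported:

* `condition_t0` (default): mean of the peptide's day-0 samples within the
  same organ × oxygen condition. Conditions with different pre-labeling
  abundances are never mixed.
* `explicit_t0`: day-0 samples pooled across conditions.
* `fitted_intercept`: $e^{\hat a}$ from a per-peptide OLS of log abundance
  on time, for datasets without dedicated baseline animals. Whether a real
  study's "time 0" comes from reference animals or extrapolation is a
  choice the data provider must make; the package supports both and
  asserts neither.

Fractions above 1 arise from noise at early timepoints and are retained:
truncating at 1 would censor the error distribution asymmetrically and
bias slopes near $t = 0$. Peptides with no observable baseline are dropped
and counted in the log rather than imputed.

## Rate estimation

**Peptide screen.** Each peptide × condition series is fitted by ordinary
least squares (closed form) of log fraction on time with a free intercept.
Peptides are retained when $r^2 > 0.65$ (strict) and the peptide is
detected in more than five samples (i.e. $\ge 6$) in that condition, both
evaluated within the condition. The free intercept absorbs residual
baseline mis-normalization; a through-origin option exists for users who
want to force $\mathrm{fraction}(0) = 1$.

**Protein roll-up.** The retained peptides of a protein share the protein's
rate but differ in ionization efficiency, so the natural model is a linear
mixed model with a per-peptide random intercept:

$$\log f_{ij} = a + u_i - K_d\, t_{ij} + \varepsilon_{ij}, \qquad
u_i \sim N(0, \sigma_u^2),\ \varepsilon_{ij} \sim N(0, \sigma^2).$$

We fit by REML (lme4), read $K_d$ as minus the time coefficient, and take
the two-sided Wald normal test of that coefficient as its p-value — the
convention of the mixed-model fitters commonly used for this analysis.
Records with $p < 0.20$ are flagged `reported`; the permissive threshold
reflects that a rate estimate, unlike a discovery call, is useful well
before it reaches conventional significance. A random per-peptide slope is
deliberately not the default: with a handful of peptides and seven
timepoints it is weakly identified, and the random-intercept model is the
most identifiable reading of "peptides as the random variable".

Degenerate inputs are handled explicitly rather than left to the
optimizer: a single-peptide protein reduces exactly to pooled OLS (tested
as an identity); a pooled fit with essentially zero residual variance
(noiseless data) is detected up front and returned as exact OLS, because
the mixed model's variance components are then unidentifiable; and if REML
fails to converge the fit is retried with ML, then falls back to pooled
OLS with `fit_method = "ols_fallback"`. Non-positive rate estimates (flat
or rising series — genuinely long-lived proteins or noise) are kept,
flagged `nonphysical`, with undefined half-life; `half_life()` itself
refuses non-positive rates.

Fractions are floored at $10^{-300}$ before the log transform — an
underflow guard only. A genuinely fast protein ($K_d > 0.4$/day) reaches
fractions below $10^{-6}$ by day 32, and clipping there would bias its
slope, so outlier-blunting floors are opt-in (`floor = 1e-6`) rather than
default.

## Differential turnover

To compare two oxygen tensions, each protein is fitted once with oxygen,
time and oxygen:time fixed effects plus per-peptide random intercepts. The
interaction coefficient is the slope difference, hence the rate
difference; its Wald statistic provides both the p-value and the signed
ranking used downstream. Both implied rates ($K_d^{\mathrm{ref}} = -b_t$,
$K_d^{\mathrm{alt}} = -(b_t + b_{\mathrm{int}})$) and the fold change come
from this single model rather than from two separate per-condition fits —
one internally consistent likelihood, though on balanced designs the two
agree (tested). A peptide enters the comparison if it passes the quality
screen in **either** condition (configurable to "both"); requiring both
would preferentially discard peptides whose decay changed strongly, the
very signal being tested.

p-values are Benjamini–Hochberg adjusted **within one organ × contrast**
family — each organ's volcano is its own discovery problem — and proteins
are classified `faster`/`slower` when the rate fold change exceeds 1.3 and
FDR < 0.05, both strict. Proteins with a non-positive implied rate are
reported as `ns` with a flag, never silently dropped.

## Downstream analyses

**Biophysical features.** From sequences the package computes only simple,
unambiguous features: length, fraction of charged residues (H, K, R, D,
E), fractions of negative (D, E) and positive (H, K, R) residues, and mean
Kyte–Doolittle hydropathy rescaled to $[0,1]$ via $(\mathrm{kd} + 4.5)/9$.
Predictor-based features (disorder, charge patterning) are consumed from a
user-supplied table, never computed.

**Tail enrichment.** Proteins are ranked — by degradation rate for the
baseline question, by interaction t-statistic for the oxygen question —
and each percentile tail (5% and 2% defaults, respectively) is compared
against *all other proteins* (not tail vs middle) with the two-sample
two-sided Kolmogorov–Smirnov test; the direction is the sign of the mean
difference. Tail size is $\max(1, \lfloor f n \rfloor)$ and ties in the
ranking are broken by protein id, so tails are deterministic.

**Complexes.** Membership comes from a simplified CORUM-style TSV
(complex id, name, semicolon-separated subunits). Per complex the package
counts measured, significant, faster and slower subunits and spans the
magnitude fold changes ($2^{|\log_2 \mathrm{FC}|}$) of the significant
ones; complexes with fewer than four measured subunits are excluded.

## The synthetic-data generator

There is no public desk-scale dataset for this design, so validation rests
on a generator that emulates the study: per-organ lognormal rate
distributions, oxygen-shifted subsets, peptide-level random intercepts,
per-sample loading factors, multiplicative noise, and missingness. Its
defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| organs × oxygen | lung/heart/brain × 8/21/60% FiO₂ | the experimental arms |
| timepoints | 0, 1, 2, 4, 8, 16, 32 d | harvest schedule plus explicit day-0 baselines |
| replicates | 4 | animals per point |
| median half-life | 3.9 / 7.3 / 8.0 d | observed organ medians |
| `half_life_sigma` | 0.25 | moderate lognormal spread; keeps organ medians identifiable at simulated cohort sizes (real tissue distributions are broader) |
| `peptides_per_protein` | 2–8 | typical DIA coverage; a guess, flagged here because no per-peptide count distribution is published |
| `noise_cv` | 0.10 | multiplicative CV typical of DIA peptide quantification |
| `missing_rate` | 0.05 | missing completely at random by default |
| `frac_affected`, `effect_fc_range` | 0.10, (1.5, 3) | a minority of proteins shifted by biologically plausible fold changes |
| panel | 10 proteins, half-life ≥ 60 d | the long-lived normalization standards |

Two deliberate idealizations keep recovery tests interpretable, and both
have switches that restore realism:

* **Flat panel signal** (`longlived_decay = FALSE`). The normalization
  assumes the panel's light-channel signal is fixed, but a 60-day
  half-life still decays ~30% over 32 days; if the panel decays, that mean
  rate is absorbed into every sample factor and every recovered rate is
  biased down by it (≈ 5–10% here). The default makes the estimator's
  assumption exactly true so that recovery error measures the estimator,
  not the assumption; setting `longlived_decay = TRUE` reproduces the bias
  the assumption hides on real data — worth knowing when interpreting
  absolute (not differential) rates.
* **MCAR missingness.** Real DIA missingness is intensity-censored; an
  intensity-dependent mode (`intensity_dependent_missing = TRUE`, rank
  based, same mean rate) is available, but censored missingness entangles
  recovery error with selection effects, so it is off by default.

The generator does not simulate MS1/MS2 spectra, isotope envelopes,
retention time, partial-labeling mass shifts, or protein-abundance changes
over time (steady state is assumed, as in the analysis model). Passing
recovery tests therefore demonstrates correctness of the estimation
chain under the stated noise model — not robustness to spectral
interference, protein inference errors, or abundance drift.

Determinism: the seed is mandatory; truth and abundance generation use
`seed` and `seed + 1`, and identical configurations reproduce
byte-identical tables.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles —
closed-form OLS against R's `lm`, the mixed-model rate against a
brute-force REML profile-likelihood grid, BH against the literal step-up
definition, the KS statistic against a direct ECDF supremum — and the
whole pipeline against the generator's ground truth at the design scale:
noiseless inversion (100 proteins × 3 conditions, exact to $10^{-8}$),
rate recovery at 10% noise (200 proteins × 3 organs, 5 peptides), null
calibration of the interaction test (500 proteins, no true effects), and
power/directionality at a two-fold shift (200 proteins, half affected).
These sizes were chosen to make medians and calibration fractions stable
at a fixed seed while keeping the suite quick to run; `scripts/acceptance.R`
recomputes the same quantities from scratch for any seed.

## Known limitations

* Rates are only as interpretable as the steady-state assumption; organs
  undergoing growth or atrophy during labeling violate it.
* Sample factors are estimated from a finite panel (10 proteins), so each
  carries a small shared error (roughly `noise_cv` divided by the square
  root of the number of observed panel peptides) that the per-protein
  models do not represent. This makes the interaction test mildly liberal
  — the realized type-I rate sits nearer 6% than 5% under the default
  generator — and correlates significance calls across proteins within a
  dataset. A larger panel removes it; it is a property of the design, not
  of the estimator.
* The quality screen ($r^2$, sample count) selects peptides within
  condition, which can mildly favor noise-aligned slopes; the differential
  "either" rule limits, but does not eliminate, selection asymmetry.
* Protein inference is taken as given (`protein_id` column); peptides
  shared between proteins should be resolved upstream.
* KS p-values with heavily tied features (e.g. integer lengths at small
  n) are approximate; the statistic itself is exact.
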