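# pulseTurnover

Protein turnover kinetics from pulsed metabolic isotope labeling
(pulsed SILAM) proteomics.

In a pulsed-labeling experiment, animals are switched to a ¹⁵N diet and
tissues are harvested over the following weeks (here: days 1, 2, 4, 8, 16
and 32). Newly synthesized protein carries the heavy label, so the light
(¹⁴N) channel of each peptide decays as the pre-existing protein pool is
degraded and replaced. At proteome steady state the unlabeled fraction
follows first-order kinetics,

    Fraction14N(t) = exp(-Kd · t),      t1/2 = ln(2) / Kd,

where *K*d is the degradation rate constant (per day) and *t*½ the protein
half-life. `pulseTurnover` implements the full analysis from peptide-level
light-channel intensities to per-protein rates, cross-condition
differential turnover, and downstream summaries:

1. **Normalization** — per-sample loading factors from a panel of
   long-lived proteins (assumed fixed in abundance), via geometric means;
   abundances are then divided by each peptide's day-0 baseline to give
   ¹⁴N fractions.
2. **Kinetics** — per-peptide OLS of log(fraction) on time as a quality
   screen (keep r² > 0.65 and detection in more than five samples per
   condition), then a per-protein linear mixed-effects model with
   per-peptide random intercepts; *K*d is minus the time coefficient, and
   rates with Wald p < 0.20 are flagged as reportable.
3. **Differential turnover** — per protein, a mixed model with oxygen,
   time and oxygen:time fixed effects; the interaction coefficient is the
   rate difference between oxygen tensions. Benjamini–Hochberg FDR within
   each organ × contrast, and classification at fold change > 1.3 with
   FDR < 0.05.
4. **Downstream** — percentile-tail Kolmogorov–Smirnov enrichment of
   sequence-derived biophysical features (charge fractions, Kyte–Doolittle
   hydropathy, length) over rate or t-statistic rankings, and
   protein-complex roll-ups (complexes with ≥ 4 measured subunits).
5. **Synthetic data** — a generator that emulates the study design
   (3 organs × 8/21/60% FiO₂ × 7 timepoints × 4 replicates) with known
   ground-truth rates, peptide-level random effects, loading factors,
   multiplicative noise and missingness, used throughout the tests to
   validate recovery, calibration and power.

It is aimed at proteomics analysts who have peptide-level DIA
quantifications in hand and want per-protein turnover estimates with an
auditable, tested statistical path.

## Worked example

```r
library(pulseTurnover)

cfg <- sim_config(n_proteins = 150, organs = c("lung", "heart"),
                  median_half_life_days = c(lung = 3.9, heart = 7.3),
                  seed = 20)
sim <- simulate_dataset(cfg)

factors   <- compute_sample_factors(sim$abundance, sim$design, sim$panel)
fractions <- compute_fractions(normalize_abundance(sim$abundance, factors),
                               sim$design)
kd <- fit_protein_kd(fractions)
summarize_half_lives(kd[!protein_id %in% sim$panel])
#>     organ oxygen     n median_half_life      q25      q75 n_outside_window
#> 1:  heart     21   150         7.175332 6.208570 8.316685                0
#> 2:  heart     60   150         7.272467 6.169507 8.423494                0
#> 3:  heart      8   150         7.196202 6.101517 8.345223                0
#> 4:   lung     21   150         3.863037 3.336889 4.790612                0
#> 5:   lung     60   150         3.852767 3.293719 4.769367                0
#> 6:   lung      8   150         3.902535 3.326899 4.887199                0
```

The recovered per-organ median half-lives sit on the configured medians
(3.9 days lung, 7.3 days heart); the interquartile ranges reflect the
simulated lognormal spread, and no half-life falls outside the plausible
0.5–64 day window of a 32-day labeling course.

```r
diff <- fit_differential(fractions, ref_oxygen = "21")
summarize_significant(diff)
#>     organ contrast n_tested n_faster n_slower pct_significant
#> 1:  heart    60v21      150        2        5        4.666667
#> 2:  heart     8v21      150        5        2        4.666667
#> 3:   lung    60v21      150        9        4        8.666667
#> 4:   lung     8v21      150        6        7        8.666667

diff[class != "ns"][1:3, .(protein_id, contrast, kd_ref, kd_alt, log2_fc, fdr, class)]
#>    protein_id contrast     kd_ref     kd_alt    log2_fc           fdr  class
#> 1:     P00012    60v21 0.08830077 0.03751912 -1.2348000  0.000000e+00 slower
#> 2:     P00022    60v21 0.11027583 0.04117972 -1.4211109  0.000000e+00 slower
#> 3:     P00035    60v21 0.08524252 0.04842465 -0.8158316 1.178802e-145 slower
```

With the generator's default 10% of proteins oxygen-shifted by 1.5–3×,
roughly 5–9% of proteins per contrast are called significant (fold change
> 1.3, FDR < 0.05); e.g. P00012's degradation rate drops from 0.088/day to
0.038/day in hyperoxia, a 2.4-fold slowdown.

The same stages are available as file-based pipeline steps
(`run_simulate()`, `run_fit()`, `run_diff()`, `run_enrich()`,
`run_complexes()`, or the `inst/exec/pulseturnover` script) that exchange
TSVs, emit the resolved configuration, and log every filter's row counts.

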