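# restact

Rest–activity rhythm, behavioral organization and complexity analysis for
minute-epoch actigraphy.

`restact` is an R package for analyzing activity-count time series of the
kind exported by collar- or wrist-mounted accelerometer data loggers
(counts accumulated over fixed 1-min epochs, recorded for weeks under a
12:12 light–dark schedule). It was built around the analysis workflow used
to phenotype home-cage activity in small diurnal primates — comparing an
exposure group against controls — but every stage is generic actigraphy
methodology:

- **Cosinor rhythm fitting.** Single-component
  `y(t) = M + A cos(ω₂₄ t + φ)` and double-component
  `y(t) = M + A₂₄ cos(ω₂₄ t + φ₂₄) + A₁₂ cos(ω₁₂ t + φ₁₂)` least-squares
  fits on 10-min aggregated data (periods fixed at 24 h and 12 h), fitted
  per calendar day and averaged per subject, with circular averaging of
  acrophases.
- **Behavioral organization.** Rest/active bout extraction at a threshold
  equal to the mean nonzero count; empirical survival curves `P(x ≥ a)`;
  a power-law fit `P(x ≥ a) = A a^(−γ)` to rest durations (default range
  3–30 min) and a stretched-exponential fit `P(x ≥ a) = exp(−α a^β)` to
  active durations (default range 10–100 min), both by OLS in log space.
- **Complexity.** Daytime Sample Entropy, `SampEn(m, r) = −ln(A/B)` with
  `m = 2`, `r = 0.2` on z-normalized lights-on data, computed per day and
  averaged (compiled kernel, checked against an O(N²) oracle).
- **Group statistics.** Pooled-variance Student t tests, mixed
  group × hour repeated-measures ANOVA with Bonferroni post hoc, Pearson
  correlations reported in the `F(1, n−2)` style, and three-chamber
  social-preference scoring
  (`SPI = (%stranger − %empty)/100`, transition counts).
- **Synthetic cohorts.** A seeded generator producing alternating
  rest/active bout processes (truncated-Pareto rests,
  stretched-exponential active bouts) modulated by a bimodal
  double-cosinor envelope, plus coupled cortisol values and three-chamber
  trials — so every estimator has a ground-truth parameter-recovery test
  without any external data.

## Worked example

Generate a default synthetic cohort (5 subjects per group, 22 days of
1-min epochs each) and run the whole pipeline:

```r
library(restact)
cfg <- run_config(input_mode = "synthetic",
                  synth = synth_config(seed = 42), seed = 42)
res <- run_pipeline(cfg, "out_dir")
res$group_summary[res$group_summary$parameter %in%
                    c("mean", "M", "A24", "phi24", "gamma", "sampen"), ]
```

```
 parameter   UE_mean     UE_sd  VPA_mean    VPA_sd   p_value
      mean  167.5531  31.13824  239.1831  34.49432 8.737e-03
         M 1675.5312 311.38240 2391.8307 344.94322 8.737e-03
       A24 1944.2614 345.59005 2774.3517 350.88764 5.475e-03
     phi24    2.9232   0.06091    2.9499   0.05220 4.777e-01
     gamma    1.0147   0.03540    1.1438   0.04918 1.422e-03
    sampen    0.3060   0.01416    0.4679   0.03491 1.145e-05
```

Each row is one activity parameter: `mean` is the per-epoch count mean
(counts/min, nocturnal included), `M`/`A24`/`phi24` are the double-cosinor
mesor, 24 h amplitude (counts per 10-min bin) and acrophase (rad), `gamma`
the rest-bout power-law exponent, `sampen` the mean daytime Sample
Entropy. `p_value` is the two-tailed pooled t test between groups: in this
synthetic cohort the exposure-like group has fragmented rest (higher γ)
and less regular daytime activity (higher SampEn), while acrophase does
not differ — the same qualitative pattern the generator was configured to
emulate.

```r
res$correlations
```

```
                             pair     r     F df1 df2       p  n
 cortisol_vs_mean_hourly_activity 0.777 12.19   1   8 0.00818 10
               cortisol_vs_sampen 0.451  2.04   1   8 0.19070 10
                cortisol_vs_gamma 0.507  2.77   1   8 0.13463 10
```

Correlations are reported Pearson-style with the equivalent regression F:
`F = r²(n−2)/(1−r²)` on `(1, n−2)` degrees of freedom. Here cortisol was
generated coupled to mean hourly activity at a population correlation of
0.72, and the recovered `r = 0.78` at n = 10 is within sampling error.

A command-line interface wraps the same stages
(`inst/cli/restact synth|run|cosinor|bouts|entropy|stats`); see
`?restact_main`.

## Package layout

- `R/epoch_series.R`, `R/io.R` — epoch-count container, CSV dialects,
  day/night partitioning, descriptive statistics
- `R/cosinor.R` — aggregation and cosinor estimators
- `R/bouts.R` — threshold, bout extraction, survival curves, fits
- `R/entropy.R` + `src/sampen.cpp` — Sample Entropy
- `R/stats.R` — t tests, correlation-F reporting, mixed ANOVA,
  three-chamber scoring
- `R/synthetic.R` — cohort generator
- `R/pipeline.R`, `R/cli.R` — orchestration and CLI
- `vignettes/restact-methods.Rmd` — models, assumptions, design choices
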