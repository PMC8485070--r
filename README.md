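# sedenz

Analysis tools for potential extracellular enzyme activities in marine
(especially deep subsurface) sediments, and for what those activities
imply about extracellular enzyme lifetimes.

Heterotrophic microbes in sediments deploy extracellular peptidases,
glycosyl hydrolases and phosphatases to break macromolecular organic
matter into transportable pieces. Their potential activities are
measured by incubating sediment slurries with small fluorogenic
substrate proxies (AMC- and MUB-linked substrates) and watching
fluorescence accumulate. `sedenz` covers the whole chain from raw
cuvette fluorescence to interpreted results:

- **Calibration** — matrix-matched standard curves per fluorophore,
  `F = b + mC`, inverted to product concentrations (negative values kept
  so rate regressions stay unbiased).
- **Kinetics** — initial rates `v0` as OLS slopes of concentration on
  time; per-gram unit conversion from the slurry geometry;
  detection-limit flagging; one-sided Welch tests of live vs autoclaved
  controls; Michaelis–Menten fits `v = V_max·S/(K_m + S)` by
  Levenberg–Marquardt with Jacobian-based standard errors; Q10
  temperature projection.
- **Profiles** — cell-count interpolation with locally fitted
  polynomials on log10(counts), segmented at the stratigraphic
  unconformity (51.7 mbsf by default), and cell-specific activities in
  amol cell⁻¹ h⁻¹.
- **Retention statistics** — percent of activity retained after
  autoclaving (100·killed/live) with detection-limit-based exclusions;
  medians/IQRs; Kruskal–Wallis omnibus and Conover–Iman pairwise rank
  tests with Holm adjustment.
- **Lifetimes** — the carbon-budget lower bound on enzyme turnover time,
  `tau >= E / (GE × R_c)` with `E = V_max / (SA / f_s)`, propagated by
  Monte Carlo over literature specific-activity ranges, with sensitivity
  scenarios.
- **Synthetic data** — a ground-truth generator that emulates a full
  assay campaign (twelve enzymes, eleven depths, triplicate
  live/autoclaved series, saturation designs, segmented cell counts), so
  every estimator above is testable by parameter recovery.

See the methods vignette (`vignettes/sediment-enzyme-pipeline.Rmd`) for
the models, defaults and their rationale.

## Worked example

```r
library(sedenz)

truth <- truth_spec(seed = 42)                       # known ground truth
assay <- generate_assay_dataset(truth, design = "vmax")
curves <- fit_standard_curves(generate_standard_curve_data(truth))
curves$AMC
#> <standard_curve AMC> F = 54 + 999 * C [uM]; r^2 = 1.0000 (n = 18)

rates <- estimate_rates(assay$series, curves, truth$geometry)
counts <- generate_cell_counts(truth, sort(c(seq(2, 50, 4), seq(53, 80, 3))))
prof <- cell_count_profile(counts)
cells <- data.frame(depth_mbsf = baltic_depths(),
                    cells_per_g = interpolate_cell_counts(prof, baltic_depths()))
profile <- assemble_depth_profile(rates, cells)
dplyr::filter(profile, enzyme == "clostripain", depth_mbsf < 20)
#>   depth_mbsf enzyme      killed_v0 live_v0 cells_per_g cell_specific_amol ...
#> 1        4.5 clostripain     0.574    9.63  476439945.               20.2
#> 2       11.1 clostripain     0.882   14.8   415718421.               35.6
#> 3       17.6 clostripain     0.707   11.8   360853903.               32.7
```

The recovered standard curve matches the generator's truth (slope 1000,
intercept 50) within noise; clostripain's live rate peaks at 11.1 mbsf
(14.8 nmol g⁻¹ h⁻¹ at 400 µM substrate) and the autoclaved control
retains a few percent of it, consistent with the generator's configured
retention fraction.

```r
rec <- retention_table(profile, dl = 0.0477, exclusion_k = 3)
summarize_retention(rec, by = "class")
#>   group           n median_pct q25_pct q75_pct quantile_type
#> 1 glycosylase     5       77.2   77.2     77.3             7
#> 2 peptidase      48       22.5    9.84    35.1             7
#> 3 phosphatase    11       54.0   54.0     54.1             7

inp <- lifetime_inputs(vmax_nmol_g_h = 9.63,
                       sa = dist_spec("log-uniform", lo = 1e2, hi = 1e4),
                       n_draws = 1e5, seed = 42)
monte_carlo_lifetime(inp)
#> <lifetime_estimate> 'baseline': tau >= 0.9576 days (IQR 0.3024-3.06;
#>   5-95% 0.1207-7.663; 100000 draws)
sensitivity_table(inp, list(conservative = list(f_s = 3, ge = 0.037)))
#>   label        median_days ...
#> 1 baseline           0.958
#> 2 conservative       7.76
```

Class medians recover the generator's configured retention fractions
(77 % glycosylase, 54 % phosphatase, ~25 % peptidase), and the
conservative lifetime scenario (sorption factor 3, growth efficiency
3.7 %) lengthens the median bound by exactly 3 × 0.10/0.037 ≈ 8.1.

The whole chain also runs as one orchestrated pipeline:

```r
run_pipeline(default_run_config(outdir = "sedenz_run", seed = 1))
# or from a shell:
#   Rscript inst/scripts/run_pipeline.R --outdir sedenz_run --seed 1
```

which writes CSV artifacts per stage plus a JSON manifest (config hash,
seed, row counts) and is byte-identical on rerun.

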