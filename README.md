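# attweights

Screen-time-based attentiveness weighting for careless/insufficient-effort
responding (C/IER) in computer-administered surveys.

## The problem

Long, low-stakes questionnaires (the background questionnaires of
educational large-scale assessments are the motivating case) invite
careless responding: random answers, straight-lining, or skipping whole
screens. Dropping respondents below an arbitrary time threshold throws away
information and ignores how uncertain the careless/attentive call is.
`attweights` instead treats attentiveness as graded:

1. **Decompose screen times.** Within each group × scale cell, log
   per-item screen times `x = ln(t)/J` are fitted with Gaussian mixtures
   `f(x) = Σ_c π_c φ(x; μ_c, σ_c)` for `C = 1..9` components, `C` chosen
   by BIC, with survey sampling weights as case weights. If `C ≥ 2`, the
   lowest-mean component is labelled C/IER; its mixture proportion
   `π^CIER` is the cell-level C/IER rate and each respondent gets a
   posterior probability `π_i^CIER` of belonging to it.
2. **Weight the analysis.** Attentiveness weights `w_i = 1 − π_i^CIER`,
   multiplied with sampling weights `v_i`, enter a pseudo-likelihood
   weighted marginal-maximum-likelihood fit of a multi-group generalized
   partial credit model: `ℓ = Σ_i w_i v_i log p(y_i | a, b, γ)`.

Around this core the package provides threshold-based timing indicators
(fixed 2 s / 1 s, normative NT30) and agreement statistics for validity
checks, a hierarchical random-intercept Beta regression of C/IER
proportions on scale characteristics (MCMC with split-R̂ diagnostics, or
fast marginal ML), a synthetic-data generator with known ground truth, and
a CLI covering the whole pipeline.

## Worked example

```r
library(attweights)

# 12% of sessions careless; careless respondents average 0.75 s per item
# against 2.08 s for attentive ones
cfg <- simulation_config(n_groups = 2, n_per_group = 800, n_scales = 2,
                         items_per_scale = 3, n_categories = 3,
                         cier_proportion = 0.12, cier_log_mean = log(0.75),
                         seed = 31)
sim <- simulate_cier_dataset(cfg)

res <- run_pipeline(sim$screen_records, sim$responses,
                    run_config(out_dir = "run1", max_components = 4, seed = 5))
res$decomposition$summary[, c("group_id", "scale_id", "n_components",
                              "cier_proportion", "mean_cier_time_per_item")]
#>   group_id scale_id n_components cier_proportion mean_cier_time_per_item
#> 1      G01      S01            2      0.10722254               0.7294972
#> 2      G01      S02            2      0.09267354               0.6700137
#> 3      G02      S01            2      0.09495900               0.6764358
#> 4      G02      S02            2      0.15035745               0.9370047

res$gpcm$S01$comparison
#> Adjusted vs unadjusted GPCM: median |diff mean| = 0.0079 [0.0039; 0.0118],
#>   median |diff var| = 0.0077 [0.0039; 0.0116]

head(res$validity, 4)
#>   group_id scale_id     statistic     value   n
#> 1      G01      S01   pb_fixed_2s 0.3520346 800
#> 2      G01      S01   pb_fixed_1s 0.9731185 800
#> 3      G01      S01       pb_nt30 0.5125851 800
#> 4      G01      S01 prop_fixed_2s 0.5362500 800
```

Reading: every group × scale cell selected a two-component solution whose
lowest-mean component carries 9–15% of the mass — around the generating
12% C/IER rate — with mean C/IER times of 0.67–0.94 s per item (generated:
0.75 s). The comparison line quantifies how much down-weighting those
sessions moves the estimated group trait means and variances; with 12%
contamination the shifts are small. The validity rows show the classic
threshold pathology the weighting avoids: a fixed 2-s cut flags 54% of
this cell and agrees weakly with the posteriors (r = .35), while the 1-s
cut tracks them closely (r = .97). `res$lag_table` holds the lagged
rank-order consistency of the posteriors, and all outputs are also written
as CSV/JSON under the run directory.

The prediction side of the Beta regression:

```r
# fixed effects: intercept, then slopes for screen position, number of
# items, number of options, average item length (words)
predict_cier_mean(-4.196, c(0.021, 0.006, 0.029, 0.016), c(21, 4.5, 4, 10))
#> [1] 0.03070927
predict_cier_mean(-4.196, c(0.021, 0.006, 0.029, 0.016), c(80, 4.5, 4, 10))
#> [1] 0.09858914
```

A median scale administered at screen position 21 has an expected C/IER
share of about .03; moving the same scale to position 80 more than triples
it to about .10.

## Command line

```sh
Rscript inst/cli/attweights.R simulate --out sim --n-per-group 500 --seed 4
Rscript inst/cli/attweights.R decompose --input sim/screen_records.csv --out dec --seed 4
```

Subcommands: `simulate`, `decompose`, `weights`, `fit-irt`, `checks`,
`betareg`, `report`. Exit codes: 0 success, 2 schema/input error,
3 convergence failure.

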