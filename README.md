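# seqmm

Treatment-sequencing survival simulation for transplant-ineligible (TIE)
multiple myeloma.

Patients with multiple myeloma who cannot receive a stem-cell transplant
typically move through up to four lines of therapy, each administered until
progression. Which regimen is used *first* matters: sequences cannot be
compared in head-to-head trials, so their expected outcomes must be
simulated from line-specific evidence. `seqmm` is for health-economic and
clinical-outcomes modellers who need to do that comparison reproducibly in
R.

## The model

`seqmm` implements a discrete-cycle state-transition (semi-Markov) cohort
model. A cohort of mass 1 starts progression-free in line 1; occupancy is
tracked by line and time-in-line `u` (tunnel states) over two-week cycles
(default 1044 cycles ≈ 40 years). Each line `k` carries a parametric PFS
curve `S_k` and an attrition fraction `a_k`:

- per-cycle event probability: `q_k(u) = 1 − S_k((u+1)Δ) / S_k(uΔ)`
- of the event mass, `a_k` enters line `k+1` (at `u = 0`), `1 − a_k` dies
- progression from the final line is death (default), or the final line can
  follow a partitioned-survival structure (`post-progression = S_OS − S_PFS`)

Curves come from a library of parametric fits (exponential, Weibull,
log-normal, log-logistic, Gompertz), from proportional-hazards adjustment
of a reference curve (`S_target = S_ref^HR`), or from weighted least-squares
fits to Kaplan–Meier summary points on the complementary log-log scale.
Outcomes are per-line expected progression-free years (unconditional, so OS
decomposes additively), overall survival per sequence, incremental OS
against an optimal sequence, and a national life-years projection.

## Worked example

Reproduce the reference comparison of the five Portuguese sequences: for
each sequence, calibrate per-line exponential curves to the published
per-line expected progression-free times (attrition 0.7 per line), simulate
the cohort, and summarize against the optimal sequence.

```r
library(seqmm)
library(purrr)

st   <- simulation_settings()           # two-week cycles, 40-year horizon
outs <- map(sequence_targets()$sequence, function(lab) {
  mods <- reference_sequence_models(lab, attrition = 0.7, settings = st)
  sequence_outcomes(simulate_sequence(mods, st, label = lab))
})
tbl <- summarize_sequences(outs, optimal_label = "DRd+PVd+Kd+Vd")
format_outcome_table(tbl)
#> # A tibble: 5 × 8
#>   sequence      pfs_l1 pfs_l2 pfs_l3 pfs_l4    os delta_os_vs_optimal
#>   <chr>          <dbl>  <dbl>  <dbl>  <dbl> <dbl>               <dbl>
#> 1 VMP+DRd+Pd+Kd   1.97   4.74   0.46   0.42  7.59               -2.17
#> 2 VMP+DRd+Kd+Pd   1.97   4.74   0.72   0.38  7.81               -1.95
#> 3 Rd+VCd+D+Pd     4.13   0.95   0.71   0.38  6.17               -3.59
#> 4 Rd+VCd+Pd+D     4.13   0.95   0.46   0.59  6.13               -3.63
#> 5 DRd+PVd+Kd+Vd   7.48   1.29   0.71   0.28  9.76               NA
round_half_up(attr(tbl, "mean_comparator_os"), 1)
#> [1] 6.9
```

Each row shows expected years progression-free per line and total OS; the
optimal sequence (daratumumab-based first line) gains 2.0–3.6 years of OS
over the common sequences, driven by first-line PFS. Scaling to the
national cohort:

```r
project_life_years(886, tie_share = 0.60, fourth_line_share = 0.175,
                   os_by_scenario = c(optimal = 9.76, worst_common = 6.13),
                   optimal = "optimal")
#> <ly_projection> (stepwise rounding)
#>   quantity              value
#> 1 new_cases_per_year      886
#> 2 transplant_ineligible   532
#> 3 reach_fourth_line        93
#>   scenario     os_years life_years ly_gained_vs_optimal
#> 1 optimal          9.76        908                   NA
#> 2 worst_common     6.13        570                  338
```

A thin command-line front end wraps the same functions
(`system.file("cli", "seqmm.R", package = "seqmm")`) with subcommands
`fit`, `simulate`, `compare`, `project` and `fixtures`; configurations are
YAML/JSON files (see `inst/extdata/demo_config.yaml`).

See the vignette (`vignettes/treatment-sequencing-model.Rmd`) for the model
assumptions, calibration details, and numerical choices.

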