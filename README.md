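# spinekinetics

Analysis of pure-moment spine flexibility tests in R.

When a functional spinal unit (FSU — two vertebrae and the intervening
disc) is loaded with a pure moment swept between −6 and +6 Nm, the
moment–rotation curve it traces is the standard readout of segmental
mechanics. Five measures summarise it:

- **ROM** — range of motion, `θ(+6 Nm) − θ(−6 Nm)`, in degrees;
- **NZ size** — the width of the neutral zone, the lax central region,
  bounded by the inflections of the curve, located as the local extrema of
  `d²M/dθ²` computed from the smoothed data;
- **NZ stiffness** — the least-squares slope of `M` on `θ` between those
  bounds, in Nm/°;
- **EZS₁, EZS₂** — the elastic-zone stiffnesses, least-squares slopes over
  the +4.5…+6 Nm and −4.5…−6 Nm bands.

`spinekinetics` provides, as a tidyverse-style pipeline:

1. **a parametric simulator** (`backbone_params()`, `solve_backbone()`,
   `generate_sweep()`, `generate_loop()`, `generate_cohort()`) that
   constructs moment–rotation curves whose five measures are *exactly* known
   — a five-zone piecewise-linear backbone (neutral zone, two stiffening
   transitions, two elastic zones) with smoothstep corner fillets, so the
   curvature peaks sit exactly on the true neutral-zone bounds; plus
   hysteresis loops, measurement noise, and whole paired-design cohorts
   calibrated to published ovine L4L5 values (`reference_kinetics()`);
2. **the extraction algorithm** (`process_curve()`, `extract_kinetics()`)
   implementing the measure definitions above, with Savitzky–Golay-style
   local-quadratic smoothing and scale-matched finite-difference curvature
   for the neutral-zone detection;
3. **the study statistics** (`anderson_darling()`, `levene_test()`,
   `rm_anova()`, `tukey_posthoc()`, `one_sample_t()`, `compare_groups()`,
   `significance_summary()`) — normality and variance checks, one-way
   repeated-measures ANOVA across intact/defect/treated conditions, Tukey
   HSD on the within-subjects error term, and percent-change summaries;
4. **an orchestration layer** (`study_config()`, `run_study()`,
   `recovery_audit()`, `render_report()`) that runs
   simulate → extract → compare reproducibly from a seed and audits
   parameter recovery against the simulator's ground truth.

## Worked example

Configure a backbone from the intact flexion–extension reference values
(ROM 8.15°, NZ 2.53° at 0.59 Nm/°, EZS 4.18/5.76 Nm/°), sample a noiseless
sweep, and extract the measures back:

```r
library(spinekinetics)

p <- backbone_params(rom = 8.15, nz_size = 2.53, nz_stiffness = 0.59,
                     ezs_pos = 4.18, ezs_neg = 5.76)
bb <- solve_backbone(p)
sweep <- generate_sweep(bb, resolution = 0.005)
res <- process_curve(sweep)
res
#> <kinetics_result>
#>   ROM            8.1500 deg
#>   NZ size        2.5300 deg  [-1.2633, 1.2667]
#>   NZ stiffness   0.5912 Nm/deg
#>   EZS1 / EZS2    4.1800 / 5.7600 Nm/deg
```

ROM, NZ size and both elastic-zone slopes are recovered exactly; NZ
stiffness comes back 0.2% high because the fit band includes the corner
fillets (within the documented 1% round-trip tolerance). `tidy(res)`
returns the same as a one-row tibble, `autoplot(res)` draws the curve with
the neutral-zone bounds and fitted zone slopes.

A whole paired cohort (8 specimens × 3 conditions × 3 loading planes, with
noise and specimen random effects) and its statistics:

```r
cfg <- study_config(cohort_spec(seed = 42))
out <- run_study(cfg)
out$summary                     # mean ± SD per condition/modality/measure
out$comparisons                 # RM-ANOVA, Tukey, normality/variance checks
significance_summary(out$comparisons)
recovery_audit(out)$per_cell    # estimate vs ground-truth errors
```

A thin CLI over the same functions lives in `inst/cli/spinekinetics.R`
(`simulate|extract|compare|run`, YAML config with a mandatory seed).

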