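# lasertherm

Calibrated fluorescence thermometry and exposure planning for
infrared-laser single-cell heat-shock induction.

## The problem

Focusing a 1455 nm infrared laser on one cell of a transparent embryo heats
that cell and, through heat-shock regulatory elements, switches on gene
expression in it — reporters for sparse-labelling microscopy, or any cDNA of
interest. Making this quantitative requires three things this package
provides:

1. **An in-vivo thermometer.** The fluorescence of mCherry falls linearly
   with temperature, about 1.7% per °C over 15–40 °C. A reporter-expressing
   cell sheet therefore reads out the laser's heat field: the ratio of
   fluorescence with the laser ON versus OFF converts to a temperature
   elevation through the calibrated linear law
   `F(T) = F_ref (1 − s (T − T_ref))`, inverted exactly as
   `ΔT = (1 − R)(1 − s (T_base − T_ref)) / s`.
2. **A heat-field model.** The focal elevation is linear in laser power
   (slope `k` ≈ 4 °C/mW) and decays with in-plane distance as an exponential
   that halves at `r½` ≈ 11 µm, the same shape at every power:
   `ΔT(r) = k P 2^(−r/r½)`. Heating equilibrates within 500 ms
   (first-order kinetics).
3. **A planner.** Because the decay is steep and the focal elevation is
   proportional to power, lowering the bath temperature and raising the power
   confines the heat-shock band (32–34 °C for 5 min) to a single cell; pulsed
   operation (6 Hz, 8.3 ms pulses) raises the focus above a lethal
   temperature for ablation while keeping the time-averaged dose at
   neighbours sub-threshold.

Morphometric tools (3D polyline neurite lengths, a tail-to-head stage clock,
bootstrap outgrowth comparisons, paired division-timing statistics,
power-normalised induction kinetics) quantify whether heated cells develop
normally. A synthetic-data module generates image stacks, measurement tables,
neurite tracks and division records with known ground truth, so the entire
pipeline is testable without a microscope.

Intended users: microscopists adapting laser heat-shock induction to a new
rig or organism, and developmental biologists analysing the resulting
time-lapse data.

## Worked example

```r
library(lasertherm)

# The calibrated heating model
prof <- thermal_profile(slope = 4, half_distance = 11, ambient = 20)
predict_focal_temp(3.0, prof)
#> [1] 32
predict_profile(3.5, c(0, 11, 22), prof)   # elevation at 0, r_half, 2 r_half
#> [1] 14.0  7.0  3.5

# Recover the half-distance from noisy synthetic per-cell measurements
dists <- withr::with_seed(42, runif(40, 0, 35))
binned <- gen_cell_measurements(prof, powers = c(2, 3, 4),
                                cell_distances = dists,
                                noise_sd = 0.3, seed = 42) |>
  bin_by_distance(2)
fit <- fit_spatial_profile(binned, profile = prof)
fit$half_distance
#> [1] 10.74215
tidy(fit)
#> # A tibble: 4 × 3
#>   term          estimate std_error
#>   <chr>            <dbl>     <dbl>
#> 1 half_distance    10.7      0.154
#> 2 amplitude_2mW     8.25     0.148
#> 3 amplitude_3mW    12.4      0.160
#> 4 amplitude_4mW    16.5      0.176

# Plan a single-cell induction: power range that lands the focus in 32-34 C
plan <- plan_induction(prof, threshold_band = c(32, 34), neighbor_distance = 11)
plan
#> <induction_plan> mode: induction, FEASIBLE
#>   feasible power range: [3, 3.5] mW
#>   power: 3.25 mW at ambient 20 degC
#>   predicted focal: 33 degC; at neighbour (11 um): 26.5 degC
#>   threshold band: [32, 34] degC
```

The fitted half-distance (10.7 µm against a generative truth of 11 µm under
0.3 °C measurement noise) and the amplitudes — proportional to power at
~4.1 °C/mW — reproduce the multiplicative-scaling structure of the heat
field. The plan says: at a 20 °C bath, any power between 3.0 and 3.5 mW puts
the focus inside the induction band while a neighbour one half-distance away
stays at 26.5 °C, well below threshold.

An end-to-end synthetic run (simulate → calibrate → map → fit → plan) with a
reproducibility manifest:

```r
run <- run_pipeline(pipeline_config(seed = 5))
run$calibrate$sensitivity   # recovered reporter sensitivity, per degC
#> [1] 0.01717501
run$plan$feasible
#> [1] TRUE
```

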