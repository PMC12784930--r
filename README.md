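# fowlplan

Closed-loop feed scheduling and live-weight prediction for cage-reared
native chickens.

## The problem

Small producers of native (colored-feather) chickens sell into markets that
specify a target live weight on a fixed slaughter date. Experience-based ad
libitum feeding over- or under-shoots both, wasting feed and raising the
feed conversion ratio (FCR = feed consumed / weight gained). `fowlplan`
implements a data-driven feeding program for cage-level husbandry:

1. **Daily live-weight model** `M_w`: predicts per-bird weight
   `y_i` from the feature vector
   `x_i = (Age_i, T̄_i, RH̄_i, f_i, CO_i^max, H2S_i^max, NH3_i^max)` —
   age, 24-h mean temperature and relative humidity, per-bird feed allowance
   `f_i = F_i / N_i`, and 24-h maxima of CO, H₂S, NH₃.
2. **Interval total-feed model** `M_F`: predicts the per-bird feed total
   `F̂_r` needed for an interval from `(w_start, w_target, d_remain)`.
3. **Closed-loop scheduler**: allocates `F̂_r` across days by a historical
   intake profile or an arithmetic ramp (`f_i = F̂_r · π_i / Σπ`), enforces
   daily bounds and a ±10 % day-to-day change band while conserving the
   interval total (`Σ_i f_i = F_r`), simulates the trajectory with `M_w`,
   and applies the proportional correction
   `F^(j+1) = F^(j) · w_target / ŵ_end^(j)` until
   `|ŵ_end − w_target| ≤ ε` or `J_max` iterations.
4. **Evaluation**: interval FCR (`FCR_r = Σ f_i / (w_target − w_start)`)
   and a partial budget (`ΔFeed = ΔFCR · W_g · N`,
   `Saving = ΔFeed · P_f`).

Learners (extra trees, random forest, gradient-boosted trees, a small ReLU
MLP) are implemented in-package behind one regressor contract, with
Monte-Carlo permutation Shapley attribution for interpreting environmental
effects. A seeded synthetic-data module emulates the cage-trial structure
(Gompertz growth, daily-cyclic sensor streams, monotone intake ramps) so
everything is testable without farm data.

## Worked example

```r
library(fowlplan)

# 3 batches x 77 days of synthetic Guzao cage records + hourly sensor logs
d  <- gen_dataset(synthetic_config(n_batches = 3, n_days = 77,
                                   breeds = "Guzao", seed = 1))
wm <- build_weight_matrix(d$records, d$env)     # 231 rows, 7 features + target
sp <- temporal_split(wm)                        # batch-wise 9:1 -> 207 / 24

mw <- fit_weight_model(wm[sp$train, ], preset_config("et", seed = 1))
evaluate(predict(mw, wm[sp$train, ]), wm$y_g_per_bird[sp$train])
#> MSE 96.17 g^2 | MAE 7.86 g | RMSE 9.81 g | R2 0.9997

iv <- build_interval_examples(wm[sp$train, ], min_len = 7, max_len = 60,
                              stride = 2)       # 1458 interval pairs
mf <- fit_feed_model(iv, preset_config("et", seed = 1))

res <- run_schedule(interval_spec(620, 1700, 40), mf, mw,
                    env_climatology(wm[sp$train, ], 40),
                    schedule_config(), start_age = 30)
res
#> feeding schedule: 40 days, 620.00 -> 1700.00 g target
#>   interval total 3122.11 g/bird | iterations 4 | terminal error +0.87 g (converged)
#>   planned FCR 2.89
```

The in-sample fit is near-interpolating (R² 0.9997, RMSE ~10 g), as expected
when ensemble trees memorize smooth monotone cage trajectories; the
temporal-test tail instead measures extrapolation, where depth-bounded trees
saturate — both numbers are reported by the pipeline. The scheduler converged
in 4 iterations to within 0.87 g of the 1700 g target and plans ~3.1 kg of
feed per bird (planned FCR 2.89 for this mid-growth interval).

The regimen comparison and economics reproduce the recorded contrast between
ad libitum and scheduled feeding:

```r
ct <- fcr_contrast(7506.75, 2194.75, 5578.08, 1705)
ct
#> FCR 3.42 -> 3.27 (relative reduction 4.39%)
partial_budget(1000, 1.705, ct$fcr0_2dp, ct$fcr1_2dp)
#> partial budget (N = 1000 birds, gain 1.705 kg/bird, feed 14.00 NTD/kg)
#>   dFCR = 0.1500 -> feed saved 255.75 kg, worth 3580 NTD
```

## Command line

```sh
Rscript inst/cli/fowlplan.R run-all --config inst/extdata/demo-config.json \
    --seed 1 --out fowlplan-run
```

Subcommands: `simulate-data`, `preprocess`, `train`, `explain`, `schedule`,
`economics`, `run-all`. The pipeline writes `data/`, `matrices/`, `models/`,
`schedule/`, `report/` and a `manifest.json` recording seed, config hash,
versions and metrics.

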