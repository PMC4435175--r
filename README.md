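# amevaHAR

Physical activity recognition from smartphone accelerometer data using
**discrete variables**, for researchers and engineers who need continuous
on-device activity monitoring without draining the battery. Instead of
feeding continuous per-window statistics to a costly classifier (SVM, neural
network, ...), every statistic is first discretized with the supervised
chi-squared **Ameva** criterion, and windows are then classified by a cheap
majority vote over a precomputed likelihood table. Two controllers further
cut the sensing cost: a dynamic per-activity sampling rate (32 Hz for
sedentary postures, 50 Hz for locomotion) and an escalating duty cycle that
lets the sensor sleep when the device is not being worn.

## The method

Let `X = {x_1, ..., x_n}` be the values of one per-window statistic, each
labeled with one of `l >= 2` activities `C = {C_1, ..., C_l}`. A
discretization into `k` half-open intervals `L_1 = (-inf, d_1], L_j =
(d_{j-1}, d_j]` is scored by

```
Ameva(k) = chi2(k) / (k (l - 1)),   chi2(k) = N (-1 + sum_ij n_ij^2 / (n_i. n_.j))
```

where `n_ij` counts values of class `C_i` in interval `L_j` and `n_i.`,
`n_.j` are the marginals. The greedy search adds, one at a time, the
candidate cut point (midpoints between consecutive distinct values) that
most increases the Ameva value, and stops at the first non-improving step —
favoring few, class-pure intervals.

Training then counts the **class matrix** `v_pij` (windows of activity `j`
in interval `i` of statistic `p`) and converts it into the
**activity-interval matrix**

```
u_pij = (v_pij / v_p.j) * (1/(l-1)) * sum_{q != j} (1 - v_piq / v_p.q)
```

(with ratios over a zero activity total defined as 0), whose interval rows
are normalized to unit sum. A new window is classified by the **most
probable activity**: locate each statistic's value in its interval and take
the argmax over activities of the summed likelihoods. A low mean winning
likelihood flags a **novel activity** the system was never trained on.
Cadence is estimated per window as `z = tau * 60` cycles/min, with `tau` the
dominant non-DC spectral frequency of the acceleration magnitude. The
per-statistic Ameva coefficient doubles as a feature-selection score: low
scoring statistics can be pruned before classification.

## Worked example

```r
library(amevaHAR)
fx <- har_fixtures()               # small in-memory reference tables

model <- train_ameva(fx$table2)    # 10 windows, 6 statistics, 3 classes
model
#> <ameva_model> 6 statistics (6 selected), 3 activities: C1, C2, C3
round(model$ameva_values, 3)
#>     mean       sd      max      min   energy skewness
#>    3.333    3.333    3.333    3.333    3.333    2.556

cl <- classify_window(model, fx$table2$features[1, ])
cl$activity                        # "C1" — correct label of window 1
cl$score                           # 5.833: near-unanimous 6-statistic vote

evaluate_model(model, fx$table2)$accuracy
#> [1] 100
```

The Ameva coefficients say every statistic separates the three toy classes
perfectly except skewness (2.556 < 3.333), which overlaps between classes.
The activity-interval matrix built from a real 6-activity class matrix of
the standard-deviation statistic:

```r
U <- build_activity_interval_matrix(class_matrix_from_counts(fx$table5))
round(U$u_norm$sd, 2)
#>    walking upstairs downstairs sitting standing lying
#> L1    0.00     0.00       0.00    0.42     0.48  0.10
#> L2    0.00     0.00       0.00    0.35     0.31  0.34
#> L3    0.00     0.00       0.00    0.25     0.24  0.51
#> L4    0.61     0.36       0.02    0.00     0.00  0.01
#> L5    0.30     0.49       0.21    0.00     0.00  0.00
#> L6    0.02     0.07       0.92    0.00     0.00  0.00
```

Row `L6` reads: a window whose standard deviation lands in the top interval
is downstairs-walking with likelihood 0.92. Cadence from a synthetic
walking signal (1.8 Hz generator, 4 s window, 0.25 Hz spectral resolution):

```r
sig <- generate_signal(default_activity_specs()$walking, 8, seed = 42)
cadence(segment_windows(sig, 4, 1)[[1]])$cycles_per_min
#> [1] 105    # nearest bin to the true 108 cycles/min
```

## Command line

The `exec/ameva` script wires the pipeline end to end:

```sh
ameva synth      --activity walking --duration 60 --seed 1 --out walk.csv
ameva features   --in walk.csv --label walking --out feat.txt --out-labels lab.txt
ameva train      --features feat.txt --labels lab.txt --out model.json
ameva predict    --model model.json --features feat.txt --out pred.csv
ameva evaluate   --model model.json --features feat.txt --labels lab.txt --out metrics.json
ameva simulate   --seed 7 --out sim.json
```

All subcommands accept `--config` (YAML overriding `run_config()` defaults)
and `--seed`; identical config and seed give byte-identical outputs.

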