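# tvis — time-varying information storage for non-stationary time series

Information storage (IS) measures the regularity of a dynamic process:
the mutual information between its present state and its own past, i.e.
the part of the process entropy that is predictable. Under Gaussianity it
reduces to

```
S_n = 1/2 · log( σ²_Y,n / σ²_U,n )        [nats]
```

the log-ratio of the process variance to the innovation variance of an
autoregressive (AR) model. The classical estimator assumes stationarity
and returns one number per recording. `tvis` drops that assumption and
returns one number per *sample*:

1. a time-varying AR model `Y_n = Σ_k a_{k,n} Y_{n−k} + U_n` is
   identified by **recursive least squares with exponential forgetting**
   (adaptation factor `c`, forgetting factor `1 − c`), with the
   innovation variance tracked by the convex recursion
   `σ²_n = σ²_{n−1} + c (Z_n² − σ²_{n−1})` on the a-priori error `Z_n`;
2. at each instant the frozen coefficients are embedded in companion
   form and the **discrete Lyapunov equation** `Γ0 = A Γ0 Aᵀ + Λ` is
   solved for the instantaneous process variance (its (1,1) entry);
3. the log-ratio gives the storage trajectory `S_n`, with unstable
   instants flagged missing.

The package is aimed at physiological time-series analysis — in
particular EEG regularity timed with the heartbeat (brain–heart
interactions) — but applies to any univariate non-stationary signal. It
includes the square/sine TV-AR(1) simulation benchmark with
bias/variance/rise–fall-time metrics and forgetting-factor sweeps, a
cardiac-cycle–locked analysis pipeline (R/T/P fiducials → I1/I2/I3
segmentation → per-interval MEAN/STD → paired t-tests with Bonferroni
correction and Cohen's d), synthetic multichannel fixture generators with
ground truth, CSV/JSON I/O and a command-line interface.

## Worked example

Track an AR(1) coefficient that jumps between 0.3 and 0.9 as a 0.3 Hz
square wave (theoretical IS levels 0.05 and 0.83 nats):

```r
library(tvis)

cfg   <- sim_preset("square", seed = 1)       # fs = 500 Hz, 10 s, 0.3 <-> 0.9
y     <- simulate_scenario(cfg, seed = 1)$signal
model <- rls_identify(y, p = 1, forgetting = 0.97)
traj  <- tv_is(model)
traj
#> <is_trajectory> 5000 samples @ 500 Hz; mean S = 0.417 nats (4994 valid, 5 unstable)
```

The trajectory mean (0.417 nats) sits between the two theoretical
plateaus, as it should for a 50% duty cycle; 5 of 5000 instants had a
transiently unstable coefficient estimate and are missing rather than
clamped. The estimator's bias/variance/speed trade-off as a function of
the forgetting factor:

```r
sweep <- forgetting_sweep(cfg, c(0.95, 0.97, 0.99), n_realizations = 20, seed = 1)
round(sweep[, c("forgetting", "bias_on", "bias_off", "var", "rft")], 4)
#>   forgetting bias_on bias_off    var    rft
#> 1       0.95 -0.0644    0.010 0.0512 0.0635
#> 2       0.97 -0.0498    0.006 0.0308 0.1075
#> 3       0.99 -0.0440    0.020 0.0095 0.3974
```

Higher forgetting factors estimate more smoothly (variance falls
five-fold from 0.95 to 0.99) but react more slowly (the 10–90% rise–fall
time grows from 64 ms to 0.40 s) and slightly underestimate the high
plateau (`bias_on < 0`). The heartbeat-locked pipeline runs the same
estimator per EEG channel, cuts each cardiac cycle into I1 (R-peak to
T + 80 ms), I2 (to next P − 40 ms) and I3 (remainder), and summarizes
MEAN and STD of `S_n` per interval before group statistics — see
`?cardiac_is_pipeline`, `?group_compare` and the vignette.

A command-line wrapper is installed with the package:

```sh
TVIS=$(Rscript -e 'cat(system.file("cli", "tvis", package = "tvis"))')
Rscript "$TVIS" simulate --preset square --seed 7 --out square.csv
Rscript "$TVIS" storage  --in square.csv --p 1 --forgetting 0.97 --out is.csv
Rscript "$TVIS" benchmark --grid 0.95,0.97,0.99 --reps 20 --out sweep.csv
```

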