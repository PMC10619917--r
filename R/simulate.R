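#' Sampled time-series record
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param label Free-text channel label.
#' @return An object of class `"ts_record"`.
#' @export
ts_record <- function(samples, fs, label = "") {
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop_tvis("samples must be a non-empty finite numeric vector",
              "tvis_invalid_config")
  structure(list(samples = as.numeric(samples), fs = fs, label = label),
            class = "ts_record")
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("<ts_record> %s: %d samples @ %g Hz (%.2f s)\n",
              if (nzchar(x$label)) x$label else "unnamed",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Simulate a time-varying AR process
#'
#' Runs the recursion `Y_n = sum_k a_{k,n} Y_{n-k} + U_n` with
#' `U_n ~ N(0, innovation_var)`. The first `p` samples are pure innovations
#' (no pre-history); callers who need a fully burned-in record can discard
#' the first modulation cycle.
#'
#' @param coeffs A `"coeff_trajectory"` (rows = lags, columns = time).
#' @param innovation_var Innovation variance, > 0.
#' @param seed Optional integer seed for reproducibility.
#' @param label Channel label for the returned record.
#' @return A `"ts_record"` of length `ncol(coeffs$values)`.
#' @export
simulate_tvar <- function(coeffs, innovation_var = 1, seed = NULL, label = "tvar") {
  stopifnot(inherits(coeffs, "coeff_trajectory"))
  if (!is.finite(innovation_var) || innovation_var <= 0)
    stop_tvis("`innovation_var` must be positive", "tvis_invalid_config")
  a <- coeffs$values
  p <- nrow(a)
  n <- ncol(a)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- stats::rnorm(n, mean = 0, sd = sqrt(innovation_var))
  y <- numeric(n)
  y[seq_len(min(p, n))] <- u[seq_len(min(p, n))]
  if (n > p) {
    if (p == 1L) {
      a1 <- a[1L, ]
      for (i in 2:n) y[i] <- a1[i] * y[i - 1L] + u[i]
    } else {
      for (i in (p + 1L):n) {
        y[i] <- sum(a[, i] * y[i - seq_len(p)]) + u[i]
      }
    }
  }
  ts_record(y, coeffs$fs, label)
}

#' Run a benchmark scenario end to end
#'
#' Convenience wrapper: waveform from the config, then [simulate_tvar()].
#'
#' @param cfg A `"sim_config"`.
#' @param seed Seed overriding `cfg$seed`.
#' @return List with `signal` (`ts_record`), `coeffs`
#'   (`coeff_trajectory`) and `theory` (quasi-stationary IS trajectory).
#' @export
simulate_scenario <- function(cfg, seed = cfg$seed) {
  coeffs <- coeff_waveform(cfg)
  sig <- simulate_tvar(coeffs, cfg$innovation_var, seed = seed,
                       label = cfg$waveform)
  list(signal = sig, coeffs = coeffs,
       theory = theoretical_is_trajectory(coeffs, cfg$innovation_var))
}

#' Generate a multichannel cardiac-locked TV-AR fixture
#'
#' Emits EEG-like TV-AR(1) channels whose lag-1 coefficient is stepped to
#' channel-specific levels inside each of the three within-beat windows
#' (I1: R-peak to T-peak + 80 ms; I2: up to next P-peak - 40 ms; I3:
#' remainder of the cycle), plus ground-truth R/T/P fiducials on a regular
#' (optionally jittered) beat grid. The fixture is a statistical stand-in
#' only: there is no ECG/EEG waveshape modelling. A synthetic impulse-train
#' "ecg" trace (spikes at the fiducials) is included so the convenience
#' detector can be exercised.
#'
#' @param n_channels Number of EEG-like channels.
#' @param n_beats Number of complete cardiac cycles.
#' @param fs Sampling rate in Hz.
#' @param beat_period Mean R-R interval in seconds.
#' @param baseline Baseline AR(1) coefficient common to all channels.
#' @param depths `n_channels x 3` matrix of additive coefficient
#'   modulation depths for intervals I1, I2, I3 (a scalar or length-3
#'   vector is recycled across channels).
#' @param t_frac,p_frac Position of the T-peak (fraction of the R-R
#'   interval after R) and of the P-peak (fraction before the next R).
#' @param jitter_sd Gaussian jitter SD (seconds) on beat-to-beat R times;
#'   0 gives a perfectly regular rhythm.
#' @param innovation_var Innovation variance of every channel.
#' @param seed Integer root seed; channel `ch` uses `seed + ch` so
#'   channels are independent but jointly reproducible.
#' @return List with `signals` (list of `ts_record`), `data` (N x channels
#'   matrix), `fiducials` (`fiducial_set`), `intervals`
#'   (`cycle_intervals` ground truth), `coeffs` (list of
#'   `coeff_trajectory`), `ecg` (synthetic impulse-train `ts_record`),
#'   `depths`, `fs`, `seed`.
#' @export
cardiac_fixture <- function(n_channels = 4, n_beats = 40, fs = 128,
                            beat_period = 0.8, baseline = 0.5,
                            depths = 0, t_frac = 0.30, p_frac = 0.16,
                            jitter_sd = 0, innovation_var = 1, seed = 1) {
  if (n_beats < 1L) stop_tvis("`n_beats` must be >= 1", "tvis_invalid_config")
  if (beat_period <= 0) stop_tvis("`beat_period` must be positive",
                                  "tvis_invalid_config")
  depths <- matrix(depths, nrow = n_channels, ncol = 3L,
                   byrow = is.vector(depths) && length(depths) == 3L)
  if (any(abs(baseline + depths) >= 1))
    stop_tvis("baseline + depth must keep |a| < 1", "tvis_invalid_config")

  set.seed(as.integer(seed))
  r_sec <- (0:n_beats) * beat_period
  if (jitter_sd > 0) {
    jit <- stats::rnorm(n_beats + 1L, 0, jitter_sd)
    jit[1L] <- 0
    r_sec <- r_sec + jit
    if (any(diff(r_sec) <= 0))
      stop_tvis("jitter produced non-increasing R times; reduce `jitter_sd`",
                "tvis_invalid_config")
  }
  rr <- diff(r_sec)
  t_sec <- r_sec[seq_len(n_beats)] + t_frac * rr
  p_sec <- r_sec[-1L] - p_frac * rr
  # window geometry must leave room for the 80 ms / 40 ms guard offsets
  if (any(t_sec + 0.080 >= p_sec - 0.040) || any(p_sec - 0.040 >= r_sec[-1L]))
    stop_tvis("interval windows overlap or exceed the beat period",
              "tvis_invalid_config")

  n <- as.integer(round_half_away(r_sec[n_beats + 1L] * fs)) + 1L
  fid <- fiducial_set(R = r_sec, T = t_sec, P = p_sec, fs = fs,
                      units = "seconds")
  iv <- segment_cycles(fid, n)

  # per-channel coefficient trajectory: baseline stepped inside each window
  coeffs <- vector("list", n_channels)
  signals <- vector("list", n_channels)
  data <- matrix(NA_real_, n, n_channels)
  for (ch in seq_len(n_channels)) {
    a <- rep(baseline, n)
    for (b in seq_len(nrow(iv$beats))) {
      row <- iv$beats[b, ]
      a[row$i1_start:(row$i1_end - 1L)] <- baseline + depths[ch, 1L]
      a[row$i2_start:(row$i2_end - 1L)] <- baseline + depths[ch, 2L]
      a[row$i3_start:(row$i3_end - 1L)] <- baseline + depths[ch, 3L]
    }
    coeffs[[ch]] <- coeff_trajectory(a, fs)
    signals[[ch]] <- simulate_tvar(coeffs[[ch]], innovation_var,
                                   seed = as.integer(seed) + ch,
                                   label = sprintf("ch%02d", ch))
    data[, ch] <- signals[[ch]]$samples
  }
  colnames(data) <- vapply(signals, function(s) s$label, character(1))

  # synthetic (non-physiological) impulse-train trace marking the fiducials
  ecg <- numeric(n)
  ecg[pmin(n, fid$r_idx)] <- 1
  ecg[pmin(n, fid$t_idx)] <- 0.4
  ecg[pmin(n, fid$p_idx)] <- 0.25
  list(signals = signals, data = data, fiducials = fid, intervals = iv,
       coeffs = coeffs, ecg = ts_record(ecg, fs, "ecg_synthetic"),
       depths = depths, fs = fs, seed = seed)
}
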