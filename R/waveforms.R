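#' Simulation configuration for time-varying AR benchmark signals
#'
#' Bundles and validates the parameters of a univariate TV-AR(1) benchmark
#' scenario in which the lag-1 coefficient is modulated over time by a
#' prescribed waveform.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Signal duration in seconds (`N = round(fs * duration)`).
#' @param waveform One of `"square"`, `"sine"`, `"constant"`.
#' @param mod_freq Modulation frequency of the coefficient waveform in Hz
#'   (ignored for `"constant"`).
#' @param a_low,a_high Lower and upper bounds of the AR coefficient; each
#'   must lie strictly inside (-1, 1) so the process is stable within each
#'   steady state.
#' @param duty Duty cycle of the square waveform, a fraction in (0, 1).
#' @param phase Initial phase: fraction of a period for the square waveform,
#'   radians for the sine.
#' @param innovation_var Variance of the white Gaussian innovation.
#' @param seed Integer seed used by [simulate_tvar()] when drawing
#'   innovations.
#' @return An object of class `"sim_config"`.
#' @seealso [sim_preset()] for the built-in benchmark scenarios.
#' @export
sim_config <- function(fs, duration, waveform = c("square", "sine", "constant"),
                       mod_freq = NULL, a_low, a_high, duty = 0.5, phase = 0,
                       innovation_var = 1, seed = NULL) {
  waveform <- match.arg(waveform)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_tvis("`fs` must be a positive number (Hz)", "tvis_invalid_config")
  if (!is.numeric(duration) || duration <= 0)
    stop_tvis("`duration` must be positive (seconds)", "tvis_invalid_config")
  if (waveform != "constant") {
    if (is.null(mod_freq) || !is.finite(mod_freq) || mod_freq <= 0)
      stop_tvis("`mod_freq` must be a positive frequency (Hz)",
                "tvis_invalid_config")
  }
  if (!is.finite(duty) || duty <= 0 || duty >= 1)
    stop_tvis("`duty` must lie strictly between 0 and 1", "tvis_invalid_config")
  for (a in c(a_low, a_high))
    if (!is.finite(a) || abs(a) >= 1)
      stop_tvis("coefficient bounds must satisfy |a| < 1", "tvis_invalid_config")
  if (!is.finite(innovation_var) || innovation_var <= 0)
    stop_tvis("`innovation_var` must be positive", "tvis_invalid_config")
  structure(list(fs = fs, duration = duration, waveform = waveform,
                 mod_freq = mod_freq, a_low = a_low, a_high = a_high,
                 duty = duty, phase = phase, innovation_var = innovation_var,
                 seed = seed),
            class = "sim_config")
}

#' Built-in benchmark scenario presets
#'
#' The `"square"` and `"sine"` presets reproduce the standard benchmark:
#' 500 Hz sampling, 10 s duration (5000 samples), coefficient oscillating
#' between 0.3 and 0.9 at 0.3 Hz, 50% duty cycle for the square waveform,
#' unit innovation variance.
#'
#' @param name `"square"` or `"sine"`.
#' @param seed Optional integer seed stored in the config.
#' @return A `"sim_config"` object.
#' @export
sim_preset <- function(name = c("square", "sine"), seed = NULL) {
  name <- match.arg(name)
  sim_config(fs = 500, duration = 10, waveform = name, mod_freq = 0.3,
             a_low = 0.3, a_high = 0.9, duty = 0.5, phase = 0,
             innovation_var = 1, seed = seed)
}

#' Generate a time-varying AR coefficient trajectory
#'
#' Evaluates the coefficient waveform described by a [sim_config()] on the
#' sampling grid `t_n = (n - 1) / fs`. The square waveform starts on its
#' high plateau (`phase = 0`) and switches to the low plateau after `duty`
#' of each period; the sine starts at mid-level ascending.
#'
#' @param cfg A `"sim_config"` object.
#' @return An object of class `"coeff_trajectory"`: a list with `values`
#'   (a `p x N` matrix of coefficients, here `p = 1`) and `fs`.
#' @export
coeff_waveform <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- as.integer(round(cfg$fs * cfg$duration))
  t <- (seq_len(n) - 1) / cfg$fs
  a <- switch(cfg$waveform,
    constant = rep(cfg$a_high, n),
    square = {
      frac <- (t * cfg$mod_freq + cfg$phase) %% 1
      ifelse(frac < cfg$duty, cfg$a_high, cfg$a_low)
    },
    sine = {
      mid <- (cfg$a_high + cfg$a_low) / 2
      amp <- (cfg$a_high - cfg$a_low) / 2
      mid + amp * sin(2 * pi * cfg$mod_freq * t + cfg$phase)
    })
  coeff_trajectory(matrix(a, nrow = 1L), cfg$fs)
}

#' Construct a coefficient trajectory object
#'
#' @param values Numeric `p x N` matrix, row `k` holding the lag-`k` AR
#'   coefficient at each time index (a vector is taken as `p = 1`).
#' @param fs Sampling rate in Hz.
#' @return An object of class `"coeff_trajectory"`.
#' @export
coeff_trajectory <- function(values, fs) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop_tvis("coefficient trajectory must be a non-empty matrix",
              "tvis_invalid_config")
  if (!all(is.finite(values)))
    stop_tvis("coefficient trajectory must be finite", "tvis_invalid_config")
  structure(list(values = values, fs = fs), class = "coeff_trajectory")
}

#' Theoretical information storage of a stationary AR(1) process
#'
#' Closed form `S = -0.5 * log(1 - a^2)` in nats: the storage does not
#' depend on the innovation variance because the process variance is
#' `sigma2_U / (1 - a^2)`.
#'
#' @param a AR(1) coefficient(s), each with `|a| < 1`.
#' @return Information storage in nats (vectorized over `a`).
#' @examples
#' theoretical_is_ar1(0.9)  # ~ 0.83 nats
#' theoretical_is_ar1(0.3)  # ~ 0.05 nats
#' @export
theoretical_is_ar1 <- function(a) {
  if (any(!is.finite(a)) || any(abs(a) >= 1))
    stop_tvis("|a| must be < 1 for a stationary AR(1)", "tvis_nonstationary")
  -0.5 * log1p(-a^2)
}

#' Quasi-stationary theoretical IS along a coefficient trajectory
#'
#' At each time index the instantaneous coefficient vector is treated as if
#' frozen and the stationary IS of that AR model is computed through the
#' companion-form Lyapunov solve (for `p = 1` this equals
#' `-0.5 * log(1 - a_n^2)`). Instants whose frozen model is unstable yield
#' `NA`.
#'
#' @param coeffs A `"coeff_trajectory"`.
#' @param innovation_var Innovation variance (scalar or length-`N` vector).
#' @return Numeric vector of IS values in nats, `NA` where unstable.
#' @export
theoretical_is_trajectory <- function(coeffs, innovation_var = 1) {
  stopifnot(inherits(coeffs, "coeff_trajectory"))
  a <- coeffs$values
  p <- nrow(a)
  n <- ncol(a)
  sig <- rep_len(innovation_var, n)
  if (p == 1L) {
    out <- rep(NA_real_, n)
    ok <- abs(a[1L, ]) < 1
    out[ok] <- -0.5 * log1p(-a[1L, ok]^2)
    return(out)
  }
  vapply(seq_len(n), function(i) {
    sys <- companion_system(a[, i], sig[i])
    g <- tryCatch(lyapunov_autocov(sys), tvis_instability = function(e) NULL)
    if (is.null(g)) return(NA_real_)
    information_storage(g[1L, 1L], sig[i])
  }, numeric(1))
}
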