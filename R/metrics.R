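#' Transitions of a square-modulated coefficient trajectory
#'
#' @param coeffs A `"coeff_trajectory"` with a piecewise-constant first row.
#' @return Data frame with `index` (first sample of the new plateau) and
#'   `direction` (`"up"`/`"down"`).
#' @export
coeff_transitions <- function(coeffs) {
  a <- coeffs$values[1L, ]
  d <- diff(a)
  idx <- which(d != 0) + 1L
  data.frame(index = idx,
             direction = ifelse(d[idx - 1L] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Steady-state mask for a square-wave benchmark
#'
#' Splits the sample indices into ON (high-plateau) and OFF (low-plateau)
#' sets, excluding a guard fraction at the start of each plateau so that
#' post-transition transients do not contaminate the steady-state
#' statistics.
#'
#' @param coeffs A `"coeff_trajectory"` whose first row is the
#'   square-modulated coefficient.
#' @param guard Fraction of each plateau excluded after a transition
#'   (default 0.25, beyond the longest transition time observed at high
#'   forgetting).
#' @return An object of class `"steady_state_mask"`: list with `on_idx`,
#'   `off_idx`, `guard`, `transitions`, `a_high`, `a_low`.
#' @export
steady_state_mask <- function(coeffs, guard = 0.25) {
  stopifnot(inherits(coeffs, "coeff_trajectory"))
  if (guard < 0 || guard >= 1)
    stop_tvis("`guard` must lie in [0, 1)", "tvis_invalid_config")
  a <- coeffs$values[1L, ]
  lv <- sort(unique(a))
  if (length(lv) != 2L)
    stop_tvis("steady-state mask needs a two-level (square) trajectory",
              "tvis_invalid_config")
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- integer(0)
  off_idx <- integer(0)
  for (j in seq_along(r$values)) {
    st <- starts[j] + ceiling(guard * r$lengths[j])
    if (st > ends[j]) next
    keep <- st:ends[j]
    if (r$values[j] == lv[2L]) on_idx <- c(on_idx, keep)
    else off_idx <- c(off_idx, keep)
  }
  if (length(on_idx) == 0L || length(off_idx) == 0L)
    stop_tvis("mask needs at least one full plateau of each level",
              "tvis_invalid_config")
  structure(list(on_idx = on_idx, off_idx = off_idx, guard = guard,
                 transitions = coeff_transitions(coeffs),
                 a_high = lv[2L], a_low = lv[1L]),
            class = "steady_state_mask")
}

#' Steady-state bias and variance of an IS estimate
#'
#' BIAS per condition is the mean estimated IS on the plateau minus the
#' theoretical value; VAR is the mean squared deviation from the condition
#' mean. The summary bias averages the absolute per-condition biases; the
#' summary variance is the simple average.
#'
#' @param est An `"is_trajectory"` or numeric vector of IS estimates.
#' @param theory_high,theory_low Theoretical IS on the high/low plateau.
#' @param mask A `"steady_state_mask"`.
#' @return List with `bias_on`, `bias_off`, `bias_avg`, `var_on`,
#'   `var_off`, `var_avg`, `n_on`, `n_off`.
#' @export
steady_state_metrics <- function(est, theory_high, theory_low, mask) {
  s <- if (inherits(est, "is_trajectory")) est$S else as.numeric(est)
  stopifnot(inherits(mask, "steady_state_mask"))
  if (max(mask$on_idx, mask$off_idx) > length(s))
    stop_tvis("mask indices exceed trajectory length", "tvis_invalid_config")
  on <- s[mask$on_idx]
  off <- s[mask$off_idx]
  on <- on[!is.na(on)]
  off <- off[!is.na(off)]
  if (length(on) == 0L || length(off) == 0L)
    stop_tvis("empty steady-state mask after removing missing values",
              "tvis_invalid_config")
  bias_on <- mean(on) - theory_high
  bias_off <- mean(off) - theory_low
  var_on <- mean((on - mean(on))^2)
  var_off <- mean((off - mean(off))^2)
  list(bias_on = bias_on, bias_off = bias_off,
       bias_avg = (abs(bias_on) + abs(bias_off)) / 2,
       var_on = var_on, var_off = var_off,
       var_avg = (var_on + var_off) / 2,
       n_on = length(on), n_off = length(off))
}

# first index in `idx` (ordered) where pred holds, NA_integer_ otherwise
first_where <- function(x, idx, pred) {
  for (i in idx) if (!is.na(x[i]) && pred(x[i])) return(i)
  NA_integer_
}

#' Rise and fall times of an IS estimate across coefficient transitions
#'
#' Measures the adaptation speed of the estimator. After each upward
#' transition, the rise time is the inclusive interval between the first
#' sample at or above the lower threshold and the first sample at or above
#' the upper threshold (both searched from the transition instant to the
#' end of the half-cycle); falls are measured symmetrically downwards. An
#' ideal instantaneous step therefore measures one sample period. Two
#' threshold conventions are provided:
#' \describe{
#'   \item{`"literal"`}{lower = `0.1 * theory_low`, upper =
#'     `0.9 * theory_high`.}
#'   \item{`"range"`}{10% and 90% of the way from `theory_low` to
#'     `theory_high`, the standard 10-90% convention.}
#' }
#' Under `"literal"` the lower threshold sits below the low plateau
#' itself, so a noisy estimate may never cross it and downward transitions
#' are then excluded (with a count); `"range"` is the default for this
#' reason.
#'
#' @param est An `"is_trajectory"` or numeric vector.
#' @param theory_high,theory_low Theoretical plateau IS values.
#' @param transitions Data frame from [coeff_transitions()] (or a
#'   `"steady_state_mask"`).
#' @param fs Sampling rate (taken from `est` when available).
#' @param mode `"range"` (default) or `"literal"`.
#' @return List with `rise`, `fall`, `rft` (seconds, averaged over
#'   transitions), `n_rise`, `n_fall`, `n_excluded`, `per_transition`.
#' @export
rise_fall_time <- function(est, theory_high, theory_low, transitions,
                           fs = NULL, mode = c("range", "literal")) {
  mode <- match.arg(mode)
  if (inherits(est, "is_trajectory")) {
    fs <- fs %||% est$fs
    s <- est$S
  } else s <- as.numeric(est)
  if (is.null(fs) || !is.finite(fs))
    stop_tvis("`fs` is required", "tvis_invalid_config")
  if (inherits(transitions, "steady_state_mask"))
    transitions <- transitions$transitions
  if (nrow(transitions) == 0L)
    stop_tvis("no transitions supplied", "tvis_invalid_config")
  if (mode == "literal") {
    thr_lo <- 0.1 * theory_low
    thr_hi <- 0.9 * theory_high
  } else {
    ds <- theory_high - theory_low
    thr_lo <- theory_low + 0.1 * ds
    thr_hi <- theory_low + 0.9 * ds
  }
  n <- length(s)
  bounds <- c(transitions$index, n + 1L)
  rises <- numeric(0)
  falls <- numeric(0)
  n_excluded <- 0L
  rows <- list()
  for (j in seq_len(nrow(transitions))) {
    t0 <- transitions$index[j]
    t1 <- bounds[j + 1L] - 1L # end of this half-cycle
    span <- t0:t1
    up <- transitions$direction[j] == "up"
    if (up) {
      i_lo <- first_where(s, span, function(v) v >= thr_lo)
      i_hi <- first_where(s, span, function(v) v >= thr_hi)
    } else {
      i_hi <- first_where(s, span, function(v) v <= thr_hi)
      i_lo <- first_where(s, span, function(v) v <= thr_lo)
    }
    tt <- if (up) (i_hi - i_lo + 1L) / fs else (i_lo - i_hi + 1L) / fs
    if (is.na(tt) || tt < 0) { n_excluded <- n_excluded + 1L; next }
    if (up) rises <- c(rises, tt) else falls <- c(falls, tt)
    rows[[length(rows) + 1L]] <-
      data.frame(index = t0, direction = if (up) "up" else "down", time = tt)
  }
  if (n_excluded > 0L)
    warning(sprintf("%d transition(s) excluded: threshold never crossed",
                    n_excluded), call. = FALSE)
  if (length(rises) == 0L && length(falls) == 0L)
    stop_tvis("all transitions excluded: thresholds never crossed",
              "tvis_empty_result")
  rise <- if (length(rises)) mean(rises) else NA_real_
  fall <- if (length(falls)) mean(falls) else NA_real_
  list(rise = rise, fall = fall, rft = mean(c(rise, fall), na.rm = TRUE),
       n_rise = length(rises), n_fall = length(falls),
       n_excluded = n_excluded,
       per_transition = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Run the square-wave benchmark for one forgetting factor
#'
#' Simulates `n_realizations` independent realizations of the scenario
#' (realization `r` uses seed `seed + r - 1`), identifies a TV-AR(1) model
#' with the given forgetting factor, computes the IS trajectory, and
#' averages steady-state bias/variance and rise/fall times.
#'
#' @param cfg A square-wave `"sim_config"`.
#' @param forgetting Forgetting factor in (0, 1).
#' @param n_realizations Number of seeded realizations.
#' @param seed Root seed.
#' @param p Model order used in identification (default 1).
#' @param guard Guard fraction for [steady_state_mask()].
#' @param mode Threshold mode for [rise_fall_time()].
#' @return One-row data frame with the averaged performance metrics.
#' @export
benchmark_run <- function(cfg, forgetting, n_realizations = 20, seed = 1,
                          p = 1, guard = 0.25, mode = "range") {
  coeffs <- coeff_waveform(cfg)
  mask <- steady_state_mask(coeffs, guard)
  th_hi <- theoretical_is_ar1(mask$a_high)
  th_lo <- theoretical_is_ar1(mask$a_low)
  acc <- NULL
  for (r in seq_len(n_realizations)) {
    y <- simulate_tvar(coeffs, cfg$innovation_var, seed = seed + r - 1L)
    model <- rls_identify(y, p = p, forgetting = forgetting)
    traj <- tv_is(model)
    ssm <- steady_state_metrics(traj, th_hi, th_lo, mask)
    rft <- suppressWarnings(tryCatch(
      rise_fall_time(traj, th_hi, th_lo, mask$transitions, mode = mode),
      tvis_empty_result = function(e)
        list(rise = NA_real_, fall = NA_real_, rft = NA_real_)))
    row <- c(bias_on = ssm$bias_on, bias_off = ssm$bias_off,
             bias = ssm$bias_avg, var_on = ssm$var_on,
             var_off = ssm$var_off, var = ssm$var_avg,
             rise = rft$rise, fall = rft$fall, rft = rft$rft)
    acc <- rbind(acc, row)
  }
  out <- as.data.frame(t(colMeans(acc, na.rm = TRUE)))
  out <- cbind(data.frame(forgetting = forgetting), out,
               data.frame(n_realizations = n_realizations))
  rownames(out) <- NULL
  out
}

#' Forgetting-factor sweep over the square-wave benchmark
#'
#' Runs [benchmark_run()] for each forgetting factor in `grid` and stacks
#' the results, giving the bias / variance / rise-fall-time curves as a
#' function of the forgetting factor. The value 1 is rejected: it is the
#' ordinary least-squares (stationary) solution, not an adaptive
#' estimator.
#'
#' @inheritParams benchmark_run
#' @param grid Vector of forgetting factors, each in (0, 1).
#' @return Data frame, one row per grid value.
#' @export
forgetting_sweep <- function(cfg, grid, n_realizations = 20, seed = 1,
                             p = 1, guard = 0.25, mode = "range") {
  if (any(!is.finite(grid)) || any(grid <= 0) || any(grid >= 1))
    stop_tvis(paste("forgetting grid values must lie in (0, 1);",
                    "1 is the ordinary least-squares (stationary) solution",
                    "and is excluded"), "tvis_invalid_config")
  out <- lapply(grid, function(lam)
    benchmark_run(cfg, lam, n_realizations = n_realizations, seed = seed,
                  p = p, guard = guard, mode = mode))
  do.call(rbind, out)
}
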