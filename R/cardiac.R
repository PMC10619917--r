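#' Cardiac fiducial set (R, T, P event times)
#'
#' Holds the per-cycle fiducials used to segment each cardiac cycle. With
#' `n` R-peaks there are `n - 1` complete cycles; cycle `k` needs its own
#' T-peak (`T_k`, after `R_k`) and the P-peak preceding the next R
#' (`P_k`, before `R_{k+1}`), so `T` and `P` must have `n - 1` entries
#' satisfying `R_k < T_k < P_k < R_{k+1}`.
#'
#' Times can be supplied as sample indices (1-based, converted internally
#' to seconds as `(index - 1) / fs`) or directly in seconds; interval
#' boundaries are always computed in continuous time and rounded once,
#' which keeps millisecond offsets exact regardless of the sampling grid.
#'
#' @param R,T,P Increasing event times (see Details for lengths).
#' @param fs Sampling rate in Hz.
#' @param units `"samples"` (1-based indices) or `"seconds"`.
#' @return An object of class `"fiducial_set"` with `r_sec`, `t_sec`,
#'   `p_sec` (seconds), `r_idx`, `t_idx`, `p_idx` (1-based samples), `fs`.
#' @export
fiducial_set <- function(R, T, P, fs, units = c("samples", "seconds")) {
  units <- match.arg(units)
  if (units == "samples") {
    r_sec <- (R - 1) / fs; t_sec <- (T - 1) / fs; p_sec <- (P - 1) / fs
  } else {
    r_sec <- R; t_sec <- T; p_sec <- P
  }
  nc <- length(r_sec) - 1L
  if (nc < 1L)
    stop_tvis("need at least two R-peaks (one complete cycle)",
              "tvis_invalid_config")
  t_sec <- t_sec[seq_len(min(nc, length(t_sec)))]
  p_sec <- p_sec[seq_len(min(nc, length(p_sec)))]
  if (length(t_sec) != nc || length(p_sec) != nc)
    stop_tvis("T and P must have one entry per complete cycle",
              "tvis_invalid_config")
  if (is.unsorted(r_sec, strictly = TRUE))
    stop_tvis("R times must be strictly increasing", "tvis_invalid_config")
  structure(list(r_sec = r_sec, t_sec = t_sec, p_sec = p_sec,
                 r_idx = as.integer(round_half_away(r_sec * fs)) + 1L,
                 t_idx = as.integer(round_half_away(t_sec * fs)) + 1L,
                 p_idx = as.integer(round_half_away(p_sec * fs)) + 1L,
                 fs = fs),
            class = "fiducial_set")
}

#' Segment cardiac cycles into the I1/I2/I3 intervals
#'
#' For each complete cycle `k` the three half-open intervals are:
#' I1 from the R-peak to 80 ms after the T-peak, I2 from there to 40 ms
#' before the next P-peak, and I3 the remainder of the cycle up to the
#' next R-peak. Boundaries are computed in continuous time, converted to
#' samples by round-half-away-from-zero of `t * fs`, and expressed as
#' half-open 1-based ranges `[start, end)` so adjacent intervals never
#' double-count a sample; by construction the three intervals exactly
#' partition `[R_k, R_{k+1})`. Beats whose geometry violates the ordering
#' (e.g., T + 80 ms reaching past P - 40 ms) are skipped, not truncated,
#' with a recorded reason.
#'
#' @param fid A `"fiducial_set"`.
#' @param n_samples Signal length; beats extending past it are skipped.
#' @param t_offset,p_offset Offsets in seconds added after the T-peak and
#'   subtracted before the P-peak (defaults 0.080 and 0.040).
#' @return An object of class `"cycle_intervals"`: list with `beats` (data
#'   frame: `beat`, `i1_start`, `i1_end`, `i2_start`, `i2_end`,
#'   `i3_start`, `i3_end`, half-open 1-based), `skipped` (data frame of
#'   skipped beats and reasons), `fs`.
#' @export
segment_cycles <- function(fid, n_samples, t_offset = 0.080,
                           p_offset = 0.040) {
  stopifnot(inherits(fid, "fiducial_set"))
  fs <- fid$fs
  nc <- length(fid$r_sec) - 1L
  to_idx <- function(sec) as.integer(round_half_away(sec * fs)) + 1L
  rows <- list()
  skipped <- list()
  for (k in seq_len(nc)) {
    b0 <- to_idx(fid$r_sec[k])
    b1 <- to_idx(fid$t_sec[k] + t_offset)
    b2 <- to_idx(fid$p_sec[k] - p_offset)
    b3 <- to_idx(fid$r_sec[k + 1L])
    reason <- NULL
    if (!(b0 < b1 && b1 < b2 && b2 < b3))
      reason <- "degenerate geometry: empty or inverted interval"
    else if (b3 - 1L > n_samples)
      reason <- "beat extends past end of signal"
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(beat = k, reason = reason, stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(beat = k, i1_start = b0, i1_end = b1, i2_start = b1,
                 i2_end = b2, i3_start = b2, i3_end = b3)
  }
  if (length(rows) == 0L)
    stop_tvis("no valid beats after segmentation", "tvis_empty_result")
  structure(list(beats = do.call(rbind, rows),
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else data.frame(beat = integer(0),
                                           reason = character(0)),
                 fs = fs),
            class = "cycle_intervals")
}

#' Convenience R/T/P detector for synthetic traces
#'
#' A deliberately simple threshold detector intended for the package's
#' synthetic impulse-train traces and quick sanity checks -- it is *not* a
#' faithful clinical QRS detector (annotation files are the primary input
#' path). The squared, median-centred signal is smoothed with a 150 ms
#' moving average; regions above an adaptive threshold (half of the 99th
#' percentile) separated by a 250 ms refractory period give R candidates,
#' each refined to the argmax of the squared signal. T is the maximum in
#' (R + 100 ms, R + 400 ms); P the maximum in (next R - 300 ms, next R -
#' 80 ms).
#'
#' @param ecg A `"ts_record"` sampled at >= 100 Hz.
#' @return A `"fiducial_set"`.
#' @export
detect_fiducials <- function(ecg) {
  stopifnot(inherits(ecg, "ts_record"))
  fs <- ecg$fs
  if (fs < 100) stop_tvis("detector requires fs >= 100 Hz",
                          "tvis_invalid_config")
  x <- ecg$samples
  if (stats::sd(x) == 0)
    stop_tvis("flat signal: no peaks found", "tvis_empty_result")
  e <- (x - stats::median(x))^2
  w <- max(1L, as.integer(round(0.150 * fs)))
  ma <- stats::filter(e, rep(1 / w, w), sides = 2)
  ma[is.na(ma)] <- 0
  thr <- 0.5 * stats::quantile(ma, 0.99, names = FALSE)
  if (thr <= 0) stop_tvis("flat signal: no peaks found", "tvis_empty_result")
  above <- which(ma > thr)
  if (length(above) == 0L)
    stop_tvis("no peaks found above threshold", "tvis_empty_result")
  refractory <- as.integer(round(0.250 * fs))
  gaps <- which(diff(above) > refractory)
  seg_start <- above[c(1L, gaps + 1L)]
  seg_end <- above[c(gaps, length(above))]
  # widen by the smoothing window so edge beats (where the centered moving
  # average is undefined) still refine to the true peak sample
  r_idx <- mapply(function(s, t) {
    s <- max(1L, s - w)
    t <- min(length(e), t + w)
    s - 1L + which.max(e[s:t])
  }, seg_start, seg_end)
  if (length(r_idx) < 2L)
    stop_tvis("fewer than two R-peaks found", "tvis_empty_result")
  win_max <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(length(x), hi)
    if (lo > hi) return(NA_integer_)
    lo - 1L + which.max(x[lo:hi])
  }
  nc <- length(r_idx) - 1L
  t_idx <- integer(nc)
  p_idx <- integer(nc)
  for (k in seq_len(nc)) {
    t_idx[k] <- win_max(r_idx[k] + as.integer(round(0.100 * fs)),
                        r_idx[k] + as.integer(round(0.400 * fs)))
    p_idx[k] <- win_max(r_idx[k + 1L] - as.integer(round(0.300 * fs)),
                        r_idx[k + 1L] - as.integer(round(0.080 * fs)))
  }
  fiducial_set(R = r_idx, T = t_idx, P = p_idx, fs = fs, units = "samples")
}

#' Per-interval summary of a time-varying IS trajectory
#'
#' For each retained beat and each interval (G = whole cycle, I1, I2, I3),
#' the mean and standard deviation of the IS trajectory over the
#' in-interval samples are computed (missing samples excluded; the
#' within-beat SD uses the population formula). These per-beat values are
#' then averaged, unweighted, across the first `max_beats` retained beats,
#' giving one MEAN and one STD per channel and interval.
#'
#' @param is_traj An `"is_trajectory"`, or a named list of them (one per
#'   channel).
#' @param intervals A `"cycle_intervals"`.
#' @param max_beats Maximum number of beats used (default 300, the
#'   short-term analysis convention).
#' @param strict Error (instead of warn) when fewer than `max_beats`
#'   beats are available.
#' @return An object of class `"interval_summary"`: data frame with
#'   `channel`, `interval` (`G`, `I1`, `I2`, `I3`), `mean_nats`,
#'   `std_nats`, `n_beats`.
#' @export
interval_summary <- function(is_traj, intervals, max_beats = 300,
                             strict = FALSE) {
  stopifnot(inherits(intervals, "cycle_intervals"))
  trajs <- if (inherits(is_traj, "is_trajectory")) list(ch1 = is_traj)
           else is_traj
  if (is.null(names(trajs)))
    names(trajs) <- sprintf("ch%02d", seq_along(trajs))
  beats <- intervals$beats
  nb <- min(nrow(beats), max_beats)
  if (nrow(beats) < max_beats) {
    msg <- sprintf("only %d beats available (max_beats = %d)",
                   nrow(beats), max_beats)
    if (strict) stop_tvis(msg, "tvis_insufficient_beats")
    warning(msg, call. = FALSE)
  }
  beats <- beats[seq_len(nb), , drop = FALSE]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- list()
  for (ch in names(trajs)) {
    s <- trajs[[ch]]$S
    for (iv in c("G", "I1", "I2", "I3")) {
      m <- numeric(0)
      sd_ <- numeric(0)
      for (b in seq_len(nb)) {
        rng <- switch(iv,
          G = beats$i1_start[b]:(beats$i3_end[b] - 1L),
          I1 = beats$i1_start[b]:(beats$i1_end[b] - 1L),
          I2 = beats$i2_start[b]:(beats$i2_end[b] - 1L),
          I3 = beats$i3_start[b]:(beats$i3_end[b] - 1L))
        v <- s[rng]
        v <- v[!is.na(v)]
        if (length(v) == 0L) next
        m <- c(m, mean(v))
        sd_ <- c(sd_, pop_sd(v))
      }
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, interval = iv,
        mean_nats = if (length(m)) mean(m) else NA_real_,
        std_nats = if (length(sd_)) mean(sd_) else NA_real_,
        n_beats = length(m), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("interval_summary", "data.frame"))
}

#' Cohen's d with pooled-variance denominator
#'
#' `d = (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)`: the
#' standardized mean difference between two equally sized distributions.
#' Conventionally |d| = 0.2 is a small and |d| = 0.8 a large effect.
#'
#' @param x,y Numeric vectors.
#' @return Cohen's d (NaN when both variances are zero).
#' @examples
#' cohens_d(rep(1, 5) + c(-1, 1, 0, -1, 1), rep(0, 5) + c(1, -1, 0, 1, -1))
#' @export
cohens_d <- function(x, y) {
  (mean(x) - mean(y)) / sqrt((stats::var(x) + stats::var(y)) / 2)
}

#' Paired group comparison of interval summaries across subjects
#'
#' For each channel, interval pair and metric (MEAN and STD of the
#' time-varying IS), runs a paired Student's t-test across subjects,
#' applies Bonferroni correction with `n_comparisons` (default 62, one
#' per electrode in a full-scalp montage), and reports the effect size as
#' Cohen's d of the two across-subject distributions. Pairs with zero
#' variance of the paired differences and non-zero mean difference give an
#' undefined p (flagged `NA`); identical distributions give `d = 0`,
#' corrected `p = 1`.
#'
#' @param summaries List of `"interval_summary"` objects, one per subject,
#'   with identical channels.
#' @param pairs Character vector of comparisons `"A-B"`; default the six
#'   canonical ones (G vs each interval and all interval pairs).
#' @param n_comparisons Bonferroni comparison count per pair.
#' @param alpha Family-wise significance level used for the `significant`
#'   flag.
#' @return An object of class `"group_stats"`: data frame with `channel`,
#'   `comparison`, `metric`, `t`, `p_raw`, `p_bonf`, `d`, `direction`,
#'   `significant`, `n_subjects`.
#' @export
group_compare <- function(summaries,
                          pairs = c("G-I1", "G-I2", "G-I3",
                                    "I1-I2", "I1-I3", "I2-I3"),
                          n_comparisons = 62, alpha = 0.05) {
  if (length(summaries) < 2L)
    stop_tvis("need at least two subjects", "tvis_invalid_config")
  chans <- unique(summaries[[1L]]$channel)
  for (s in summaries)
    if (!identical(unique(s$channel), chans))
      stop_tvis("subjects must share the same channels",
                "tvis_invalid_config")
  get_vals <- function(metric, ch, iv) {
    col <- if (metric == "MEAN") "mean_nats" else "std_nats"
    vapply(summaries, function(s)
      s[[col]][s$channel == ch & s$interval == iv], numeric(1))
  }
  out <- list()
  for (ch in chans) for (pr in pairs) for (metric in c("MEAN", "STD")) {
    iv <- strsplit(pr, "-", fixed = TRUE)[[1L]]
    x <- get_vals(metric, ch, iv[1L])
    y <- get_vals(metric, ch, iv[2L])
    dvec <- x - y
    if (stats::sd(dvec) == 0) {
      if (all(dvec == 0)) {
        tval <- 0; p <- 1
      } else {
        tval <- NA_real_; p <- NA_real_ # constant non-zero difference
      }
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      tval <- unname(tt$statistic)
      p <- tt$p.value
    }
    d <- cohens_d(x, y)
    if (is.nan(d)) d <- 0
    p_bonf <- if (is.na(p)) NA_real_ else min(1, p * n_comparisons)
    out[[length(out) + 1L]] <- data.frame(
      channel = ch, comparison = pr, metric = metric, t = tval,
      p_raw = p, p_bonf = p_bonf, d = d,
      direction = sign(mean(dvec)),
      significant = !is.na(p_bonf) & p_bonf < alpha,
      n_subjects = length(summaries), stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("group_stats", "data.frame"))
}

#' End-to-end heartbeat-locked storage analysis for one subject
#'
#' De-means each channel, identifies the TV-AR model, computes the IS
#' trajectory, segments the cardiac cycle and summarizes per interval.
#'
#' @param data Numeric matrix, one column per channel.
#' @param fid A `"fiducial_set"`.
#' @param fs Sampling rate in Hz.
#' @param p TV-AR model order (default 5, the EEG convention).
#' @param forgetting Forgetting factor.
#' @param max_beats Beats retained in the summary.
#' @param demean De-mean each channel before identification (default
#'   TRUE; the model has no intercept).
#' @return List with `summary` (`interval_summary`), `intervals`, `trajs`.
#' @export
cardiac_is_pipeline <- function(data, fid, fs, p = 5, forgetting = 0.99,
                                max_beats = 300, demean = TRUE) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("ch%02d", seq_len(ncol(data)))
  iv <- segment_cycles(fid, nrow(data))
  trajs <- lapply(seq_len(ncol(data)), function(j) {
    yj <- data[, j]
    if (demean) yj <- yj - mean(yj)
    tv_is(rls_identify(yj, p = p, forgetting = forgetting, fs = fs))
  })
  names(trajs) <- colnames(data)
  summ <- suppressWarnings(interval_summary(trajs, iv, max_beats = max_beats))
  list(summary = summ, intervals = iv, trajs = trajs)
}
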