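#' Recursive least-squares identification of a time-varying AR model
#'
#' Identifies `Y_n = sum_k a_{k,n} Y_{n-k} + U_n` by recursive least
#' squares with exponential forgetting. With the lag vector
#' `W_n = (Y_{n-1}, ..., Y_{n-p})` and adaptation factor `c = 1 -
#' forgetting`, the per-step updates are
#' \deqn{\Phi_n = (1-c)\Phi_{n-1} + W_n W_n', \quad K_n = \Phi_n^{-1} W_n,}
#' \deqn{Z_n = Y_n - W_n' A_{n-1}, \quad A_n = A_{n-1} + K_n Z_n,}
#' and the innovation variance is tracked by the convex recursion
#' `sigma2_n = sigma2_{n-1} + c * (Z_n^2 - sigma2_{n-1})`, which keeps it
#' non-negative. `forgetting = 1` (`c = 0`) reduces the coefficient
#' recursion to ordinary least squares (the innovation variance then stays
#' at `sigma0`; use [ols_identify()] for a stationary fit with residual
#' variance).
#'
#' The textbook initialization `Phi_p = 0` leaves the gain undefined until
#' `Phi` gains full rank, so the default regularizes with
#' `Phi_p = init_delta * I`, `init_delta = 1e-6 * var(y)`; estimates for
#' `n >> p` are insensitive to this choice, and `init = "literal"` keeps
#' the zero start (updates begin once `Phi` is numerically invertible).
#'
#' The model is zero-mean (no intercept); de-mean the input first (the CLI
#' does so by default).
#'
#' @param y A `"ts_record"` or numeric vector.
#' @param p Model order (>= 1).
#' @param forgetting Forgetting factor `1 - c` in (0, 1].
#' @param init_delta Regularization of the initial correlation matrix;
#'   default `1e-6 * var(y)`.
#' @param sigma0 Initial innovation variance (default 0; see
#'   `warm_start`).
#' @param method `"inverse"` maintains `P = Phi^{-1}` via the matrix
#'   inversion lemma (O(p^2)/step, symmetrized each step); `"direct"`
#'   re-inverts `Phi` every step (O(p^3), kept for validation).
#' @param init `"regularized"` (default) or `"literal"` (`Phi_p = 0`).
#' @param warm_start If `TRUE`, `sigma0` is replaced by the variance of
#'   the first `p + 10` a-priori errors, avoiding the downward bias of the
#'   zero start in early samples.
#' @param fs Sampling rate, taken from `y` when it is a `"ts_record"`.
#' @return An object of class `"tvar_model"`: list with `p`, `forgetting`,
#'   `c`, `coeffs` (`coeff_trajectory`, `NA` before `valid_from`),
#'   `innov_var`, `apriori_err`, `valid_from = p + 1`, `fs`, `init_delta`,
#'   `sigma0`.
#' @export
rls_identify <- function(y, p, forgetting, init_delta = NULL, sigma0 = 0,
                         method = c("inverse", "direct"),
                         init = c("regularized", "literal"),
                         warm_start = FALSE, fs = NULL) {
  method <- match.arg(method)
  init <- match.arg(init)
  if (init == "literal") method <- "direct"
  if (inherits(y, "ts_record")) {
    fs <- fs %||% y$fs
    y <- y$samples
  }
  fs <- fs %||% NA_real_
  n <- length(y)
  p <- as.integer(p)
  if (p < 1L) stop_tvis("`p` must be >= 1", "tvis_invalid_config")
  if (n <= p) stop_tvis("need more samples than the model order",
                        "tvis_invalid_config")
  if (!is.finite(forgetting) || forgetting <= 0 || forgetting > 1)
    stop_tvis("`forgetting` must lie in (0, 1]", "tvis_invalid_config")
  cc <- 1 - forgetting
  if (is.null(init_delta)) {
    v <- stats::var(y)
    init_delta <- if (is.finite(v) && v > 0) 1e-6 * v else 1e-6
  }
  if (init == "regularized" && init_delta <= 0)
    stop_tvis("`init_delta` must be positive", "tvis_invalid_config")

  coeffs <- matrix(NA_real_, p, n)
  innov <- rep(NA_real_, n)
  zs <- rep(NA_real_, n)
  a <- numeric(p)
  sig <- sigma0
  lam <- forgetting

  if (p == 1L && method == "inverse" && init == "regularized") {
    # scalar fast path (identical arithmetic to the matrix path)
    pinv <- 1 / init_delta
    for (i in 2:n) {
      w <- y[i - 1L]
      pw <- pinv * w
      denom <- lam + w * pw
      k <- pw / denom
      pinv <- (pinv - pw * pw / denom) / lam
      z <- y[i] - w * a
      a <- a + k * z
      if (cc > 0) sig <- sig + cc * (z * z - sig)
      coeffs[1L, i] <- a
      innov[i] <- sig
      zs[i] <- z
    }
  } else {
    P <- NULL
    Phi <- NULL
    started <- TRUE
    if (method == "inverse") {
      P <- diag(1 / init_delta, p)
    } else {
      Phi <- diag(if (init == "regularized") init_delta else 0, p)
      started <- init == "regularized"
    }
    av <- numeric(p)
    for (i in (p + 1L):n) {
      w <- y[i - seq_len(p)]
      if (method == "inverse") {
        pw <- P %*% w
        denom <- lam + sum(w * pw)
        k <- pw / denom
        P <- (P - tcrossprod(pw) / denom) / lam
        P <- (P + t(P)) / 2
      } else {
        Phi <- lam * Phi + tcrossprod(w)
        k <- tryCatch(solve(Phi, w), error = function(e) NULL)
        if (is.null(k)) {
          if (init == "literal") { # not yet invertible: skip update
            innov[i] <- sig
            next
          }
          stop_tvis(sprintf(
            "correlation matrix numerically singular at time index %d", i),
            "tvis_rank_deficient")
        }
      }
      z <- y[i] - sum(w * av)
      av <- av + as.numeric(k) * z
      if (cc > 0) sig <- sig + cc * (z * z - sig)
      coeffs[, i] <- av
      innov[i] <- sig
      zs[i] <- z
    }
  }

  if (warm_start) {
    idx <- which(!is.na(zs))[seq_len(min(10L + p, sum(!is.na(zs))))]
    s0 <- stats::var(zs[idx])
    sig <- s0
    innov <- rep(NA_real_, n)
    # rerun only the variance recursion with the warm start
    for (i in which(!is.na(zs))) {
      if (cc > 0) sig <- sig + cc * (zs[i]^2 - sig)
      innov[i] <- sig
    }
    sigma0 <- s0
  }

  structure(list(p = p, forgetting = forgetting, c = cc,
                 coeffs = coeff_trajectory_raw(coeffs, fs),
                 innov_var = innov, apriori_err = zs,
                 valid_from = p + 1L, fs = fs, init_delta = init_delta,
                 sigma0 = sigma0),
            class = "tvar_model")
}

# like coeff_trajectory() but tolerates the NA prefix before valid_from
coeff_trajectory_raw <- function(values, fs) {
  structure(list(values = values, fs = fs), class = "coeff_trajectory")
}

#' @export
print.tvar_model <- function(x, ...) {
  cat(sprintf(
    "<tvar_model> p = %d, forgetting = %g, %d samples (valid from %d)\n",
    x$p, x$forgetting, ncol(x$coeffs$values), x$valid_from))
  invisible(x)
}

#' One step of the recursive innovation-variance update
#'
#' `sigma2_n = sigma2_{n-1} + c * (Z_n^2 - sigma2_{n-1})`, a convex
#' combination of the previous estimate and the squared a-priori error, so
#' the result is non-negative whenever the previous estimate is.
#'
#' @param sigma2_prev Previous variance estimate.
#' @param c Adaptation factor in \[0, 1).
#' @param z A-priori prediction error `Z_n`.
#' @return Updated variance estimate.
#' @examples
#' innov_var_update(1, 0.05, 2)  # 1.15
#' @export
innov_var_update <- function(sigma2_prev, c, z) {
  sigma2_prev + c * (z^2 - sigma2_prev)
}

#' Ordinary least-squares AR fit (stationary reference)
#'
#' Solves the unweighted normal equations over all usable rows; this is the
#' `c = 0` limit of the exponentially weighted criterion and serves as the
#' stationary reference estimator and RLS oracle.
#'
#' @param y A `"ts_record"` or numeric vector.
#' @param p Model order.
#' @return List with `a` (coefficients), `innov_var` (mean squared
#'   residual), `residuals`, `p`.
#' @export
ols_identify <- function(y, p) {
  if (inherits(y, "ts_record")) y <- y$samples
  n <- length(y)
  p <- as.integer(p)
  if (n <= 2L * p) stop_tvis("need N > 2p samples", "tvis_invalid_config")
  X <- sapply(seq_len(p), function(k) y[(p + 1L - k):(n - k)])
  X <- matrix(X, ncol = p)
  yy <- y[(p + 1L):n]
  qr_x <- qr(X)
  if (qr_x$rank < p)
    stop_tvis("rank-deficient regressor matrix", "tvis_rank_deficient")
  a <- as.numeric(qr.coef(qr_x, yy))
  res <- yy - X %*% a
  list(a = a, innov_var = mean(res^2), residuals = as.numeric(res), p = p)
}

#' Direct exponentially weighted least squares at one time index
#'
#' Brute-force minimizer of `sum_{i<=at} forgetting^(at-i) * Z_i^2` by a
#' single weighted normal-equations solve; the independent oracle for
#' [rls_identify()]. With `init_delta > 0` the same ridge term the RLS
#' recursion starts from (`forgetting^(at-p) * init_delta * I`) is added,
#' making the two algebraically identical.
#'
#' @param y A `"ts_record"` or numeric vector.
#' @param p Model order.
#' @param forgetting Forgetting factor in (0, 1].
#' @param at Time index at which to solve (`at > p`).
#' @param init_delta Optional ridge matching the RLS initialization
#'   (default 0: the pure weighted LS solution).
#' @return Coefficient vector of length `p`.
#' @export
ewls_direct <- function(y, p, forgetting, at, init_delta = 0) {
  if (inherits(y, "ts_record")) y <- y$samples
  p <- as.integer(p)
  at <- as.integer(at)
  if (at <= p || at > length(y))
    stop_tvis("`at` must satisfy p < at <= N", "tvis_invalid_config")
  idx <- (p + 1L):at
  wts <- forgetting^(at - idx)
  Phi <- diag(forgetting^(at - p) * init_delta, p)
  b <- numeric(p)
  for (j in seq_along(idx)) {
    i <- idx[j]
    w <- y[i - seq_len(p)]
    Phi <- Phi + wts[j] * tcrossprod(w)
    b <- b + wts[j] * w * y[i]
  }
  out <- tryCatch(solve(Phi, b), error = function(e)
    stop_tvis("singular weighted normal matrix", "tvis_rank_deficient"))
  as.numeric(out)
}
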