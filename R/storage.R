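#' Companion-form system of an AR(p) model
#'
#' Embeds the AR(p) recursion as a first-order vector system: the top row
#' of `A` holds the coefficients `a_1 .. a_p`, the subdiagonal is the
#' identity, and the innovation covariance `Lambda` has the innovation
#' variance in entry (1, 1) and zeros elsewhere.
#'
#' @param a Coefficient vector `a_1 .. a_p`.
#' @param sigma2_u Innovation variance (>= 0).
#' @return An object of class `"companion_system"`: list with `A`,
#'   `Lambda`, `p`.
#' @export
companion_system <- function(a, sigma2_u) {
  if (!all(is.finite(a))) stop_tvis("non-finite coefficients",
                                    "tvis_invalid_config")
  p <- length(a)
  A <- matrix(0, p, p)
  A[1L, ] <- a
  if (p > 1L) A[cbind(2:p, 1:(p - 1L))] <- 1
  Lambda <- matrix(0, p, p)
  Lambda[1L, 1L] <- sigma2_u
  structure(list(A = A, Lambda = Lambda, p = p), class = "companion_system")
}

#' Spectral radius of the companion matrix
#' @param sys A `"companion_system"`.
#' @return Largest eigenvalue modulus.
#' @export
spectral_radius <- function(sys) {
  max(Mod(eigen(sys$A, only.values = TRUE)$values))
}

#' Solve the discrete Lyapunov equation for the AR autocovariance
#'
#' Returns the unique solution `G` of `G = A G A' + Lambda` for a stable
#' companion system, via the vectorized linear system
#' `(I - A \%x\% A) vec(G) = vec(Lambda)` (the model order here is small,
#' so the p^2 x p^2 solve is direct; symmetry is enforced post-solve).
#' Entry (1, 1) is the process variance; the first row holds the
#' autocovariances at lags 0 .. p-1.
#'
#' @param sys A `"companion_system"`.
#' @param stability_tol Stability margin: an error of class
#'   `"tvis_instability"` is raised when the spectral radius is
#'   `>= 1 - stability_tol`.
#' @return `p x p` symmetric autocovariance matrix.
#' @export
lyapunov_autocov <- function(sys, stability_tol = 1e-8) {
  stopifnot(inherits(sys, "companion_system"))
  p <- sys$p
  if (p == 1L) {
    a <- sys$A[1L, 1L]
    if (abs(a) >= 1 - stability_tol)
      stop_tvis("companion matrix is not stable (|a| >= 1)",
                "tvis_instability")
    return(matrix(sys$Lambda[1L, 1L] / (1 - a^2), 1L, 1L))
  }
  if (spectral_radius(sys) >= 1 - stability_tol)
    stop_tvis("companion matrix is not stable (spectral radius >= 1)",
              "tvis_instability")
  g <- solve(diag(p * p) - sys$A %x% sys$A, as.vector(sys$Lambda))
  G <- matrix(g, p, p)
  (G + t(G)) / 2
}

#' Information storage from process and innovation variance
#'
#' `S = 0.5 * log(sigma2_y / sigma2_u)` in nats (or bits with
#' `base = "bits"`): the entropy of the present minus its conditional
#' entropy given the past, under Gaussianity.
#'
#' Non-positive variances are floored at `floor_eps * ref` (warn) unless
#' `strict = TRUE`, in which case they raise an error.
#'
#' @param sigma2_y Process variance(s).
#' @param sigma2_u Innovation variance(s).
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @param strict Error instead of flooring non-positive variances.
#' @param floor_eps Relative floor applied to non-positive variances.
#' @param ref Reference scale for the floor (default the largest variance
#'   supplied).
#' @return Information storage value(s).
#' @examples
#' information_storage(5.2632, 1)  # ~ 0.83 nats
#' @export
information_storage <- function(sigma2_y, sigma2_u, base = c("nats", "bits"),
                                strict = FALSE, floor_eps = 1e-12,
                                ref = NULL) {
  base <- match.arg(base)
  bad <- !is.na(sigma2_y) & sigma2_y <= 0 | !is.na(sigma2_u) & sigma2_u <= 0
  if (any(bad, na.rm = TRUE)) {
    if (strict)
      stop_tvis("non-positive variance in information_storage()",
                "tvis_invalid_variance")
    ref <- ref %||% max(c(sigma2_y, sigma2_u, 1), na.rm = TRUE)
    flo <- floor_eps * ref
    sigma2_y <- pmax(sigma2_y, flo)
    sigma2_u <- pmax(sigma2_u, flo)
    warning(sprintf("floored %d non-positive variance value(s)",
                    sum(bad, na.rm = TRUE)), call. = FALSE)
  }
  s <- 0.5 * log(sigma2_y / sigma2_u)
  if (base == "bits") s / log(2) else s
}

#' Time-varying information storage trajectory of a TV-AR model
#'
#' For each time index from `valid_from` on: build the companion system
#' from the instantaneous coefficients and innovation variance, check
#' stability, solve the discrete Lyapunov equation for the process
#' variance, and apply `S_n = 0.5 * log(sigma2_{Y,n} / sigma2_{U,n})`.
#' Instants whose frozen model is unstable give `NA` (clamping the
#' coefficients would fabricate storage values); their count is reported.
#' Innovation variances below the relative floor are floored before the
#' log (count reported), or raise an error in strict mode.
#'
#' @param model A `"tvar_model"` from [rls_identify()].
#' @param base `"nats"` or `"bits"`.
#' @param strict Raise on floored variances instead of warning.
#' @param floor_eps Relative variance floor (times the median innovation
#'   variance).
#' @param stability_tol Stability margin for the spectral-radius check.
#' @return An object of class `"is_trajectory"`: list with `S` (nats),
#'   `proc_var`, `innov_var`, `stable` (logical), `fs`, `valid_from`,
#'   `n_unstable`, `n_floored`.
#' @export
tv_is <- function(model, base = c("nats", "bits"), strict = FALSE,
                  floor_eps = 1e-12, stability_tol = 1e-8) {
  stopifnot(inherits(model, "tvar_model"))
  base <- match.arg(base)
  a <- model$coeffs$values
  p <- model$p
  n <- ncol(a)
  su <- model$innov_var
  sy <- rep(NA_real_, n)
  stable <- rep(NA, n)
  idx <- which(colSums(is.na(a)) == 0L)

  if (p == 1L) {
    a1 <- a[1L, idx]
    ok <- abs(a1) < 1 - stability_tol
    stable[idx] <- ok
    sy[idx[ok]] <- su[idx[ok]] / (1 - a1[ok]^2)
  } else {
    for (i in idx) {
      sys <- companion_system(a[, i], su[i])
      rho <- spectral_radius(sys)
      stable[i] <- rho < 1 - stability_tol
      if (stable[i]) {
        g <- solve(diag(p * p) - sys$A %x% sys$A, as.vector(sys$Lambda))
        sy[i] <- g[1L]
      }
    }
  }
  n_unstable <- sum(!stable, na.rm = TRUE)
  if (length(idx) > 0L && n_unstable == length(idx))
    stop_tvis("all instants unstable: empty storage trajectory",
              "tvis_empty_result")

  ref <- stats::median(su[idx], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) ref <- 1
  flo <- floor_eps * ref
  comp <- !is.na(sy) & !is.na(su)
  n_floored <- sum(comp & (sy < flo | su < flo))
  if (n_floored > 0L) {
    if (strict)
      stop_tvis("non-positive variance encountered in strict mode",
                "tvis_invalid_variance")
    warning(sprintf("floored %d variance value(s) below %.3g",
                    n_floored, flo), call. = FALSE)
  }
  s <- rep(NA_real_, n)
  s[comp] <- 0.5 * log(pmax(sy[comp], flo) / pmax(su[comp], flo))
  if (base == "bits") s <- s / log(2)
  structure(list(S = s, proc_var = sy, innov_var = su, stable = stable,
                 fs = model$fs, valid_from = model$valid_from,
                 n_unstable = n_unstable, n_floored = n_floored),
            class = "is_trajectory")
}

#' @export
print.is_trajectory <- function(x, ...) {
  ok <- !is.na(x$S)
  cat(sprintf(
    "<is_trajectory> %d samples @ %s Hz; mean S = %.3f nats (%d valid, %d unstable)\n",
    length(x$S), format(x$fs), mean(x$S[ok]), sum(ok), x$n_unstable))
  invisible(x)
}
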