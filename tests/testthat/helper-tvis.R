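# shared test helpers

# construct a tvar_model directly from a coefficient matrix and innovation
# variance trajectory, bypassing identification (for engine-level tests)
make_model <- function(a, innov_var, fs = 100) {
  if (is.vector(a)) a <- matrix(a, nrow = 1L)
  n <- ncol(a)
  structure(list(p = nrow(a), forgetting = NA_real_, c = NA_real_,
                 coeffs = structure(list(values = a, fs = fs),
                                    class = "coeff_trajectory"),
                 innov_var = rep_len(innov_var, n),
                 apriori_err = rep(NA_real_, n),
                 valid_from = 1L, fs = fs, init_delta = NA_real_,
                 sigma0 = 0),
            class = "tvar_model")
}

# stationary AR(p) autocovariances gamma_0..gamma_p by brute-force solution
# of the Yule-Walker system (independent of the package's Lyapunov route)
yw_brute <- function(a, sigma2) {
  p <- length(a)
  # unknowns gamma_0 .. gamma_p
  m <- matrix(0, p + 1L, p + 1L)
  rhs <- c(sigma2, rep(0, p))
  for (k in 0:p) {
    m[k + 1L, k + 1L] <- m[k + 1L, k + 1L] + 1
    for (l in seq_len(p))
      m[k + 1L, abs(k - l) + 1L] <- m[k + 1L, abs(k - l) + 1L] - a[l]
  }
  as.numeric(solve(m, rhs))
}

# fixed-point iteration oracle for the discrete Lyapunov equation
lyap_fixed_point <- function(A, Lambda, iters = 2000) {
  G <- Lambda
  for (i in seq_len(iters)) G <- A %*% G %*% t(A) + Lambda
  G
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
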