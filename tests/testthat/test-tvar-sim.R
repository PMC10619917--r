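test_that("square waveform follows the piecewise rule with the stated duty cycle", {
  cfg <- sim_config(fs = 500, duration = 10, waveform = "square",
                    mod_freq = 0.3, a_low = 0.3, a_high = 0.9, duty = 0.5)
  co <- coeff_waveform(cfg)
  a <- co$values[1L, ]
  expect_equal(length(a), 5000L)
  expect_equal(a[1L], 0.9)                       # starts on the high plateau
  expect_equal(a[round(2.0 * 500) + 1L], 0.3)    # t = 2 s: second half of cycle
  expect_setequal(unique(a), c(0.3, 0.9))

  # integer samples-per-period: exactly half the samples are high
  cfg2 <- sim_config(fs = 100, duration = 2, waveform = "square",
                     mod_freq = 0.5, a_low = 0.2, a_high = 0.8, duty = 0.5)
  a2 <- coeff_waveform(cfg2)$values[1L, ]
  expect_equal(sum(a2 == 0.8), length(a2) / 2)
})

test_that("sine waveform respects bounds, phase and the zero-depth limit", {
  cfg <- sim_config(fs = 200, duration = 5, waveform = "sine", mod_freq = 0.5,
                    a_low = 0.3, a_high = 0.9)
  a <- coeff_waveform(cfg)$values[1L, ]
  expect_equal(a[1L], 0.6)  # starts at mid-level
  expect_true(all(a >= 0.3 - 1e-12 & a <= 0.9 + 1e-12))
  expect_gt(a[2L], a[1L])   # ascending

  flat <- sim_config(fs = 200, duration = 1, waveform = "sine",
                     mod_freq = 0.5, a_low = 0.5, a_high = 0.5)
  expect_equal(unique(coeff_waveform(flat)$values[1L, ]), 0.5)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(sim_config(fs = -1, duration = 1, waveform = "square",
                          mod_freq = 1, a_low = 0.3, a_high = 0.9),
               class = "tvis_invalid_config")
  expect_error(sim_config(fs = 100, duration = 1, waveform = "square",
                          mod_freq = 0, a_low = 0.3, a_high = 0.9),
               class = "tvis_invalid_config")
  expect_error(sim_config(fs = 100, duration = 1, waveform = "square",
                          mod_freq = 1, a_low = 0.3, a_high = 0.9, duty = 1.2),
               class = "tvis_invalid_config")
  expect_error(sim_config(fs = 100, duration = 1, waveform = "square",
                          mod_freq = 1, a_low = 0.3, a_high = 1.0),
               class = "tvis_invalid_config")
  expect_error(sim_config(fs = 100, duration = 1, waveform = "square",
                          mod_freq = 1, a_low = 0.3, a_high = 0.9,
                          innovation_var = 0),
               class = "tvis_invalid_config")
})

test_that("simulated TV-AR reproduces stationary moments and is reproducible", {
  # white-noise limit: all-zero coefficients
  co0 <- coeff_trajectory(rep(0, 50000), fs = 500)
  y0 <- simulate_tvar(co0, innovation_var = 1, seed = 42)
  expect_equal(stats::var(y0$samples), 1, tolerance = 0.02)

  # stationary AR(1): var = sigma2_U / (1 - a^2)
  co9 <- coeff_trajectory(rep(0.9, 200000), fs = 500)
  y9 <- simulate_tvar(co9, innovation_var = 1, seed = 7)
  expect_equal(stats::var(y9$samples), 1 / (1 - 0.81), tolerance = 0.05)

  # determinism
  ya <- simulate_tvar(co0, 1, seed = 3)
  yb <- simulate_tvar(co0, 1, seed = 3)
  expect_identical(ya$samples, yb$samples)
})

test_that("closed-form AR(1) storage matches the known values and properties", {
  expect_equal(round(theoretical_is_ar1(0.9), 2), 0.83)
  expect_equal(round(theoretical_is_ar1(0.3), 2), 0.05)
  expect_equal(theoretical_is_ar1(0), 0)
  # even in a, strictly increasing in |a|
  aa <- seq(0.05, 0.95, by = 0.05)
  expect_equal(theoretical_is_ar1(-aa), theoretical_is_ar1(aa))
  expect_true(all(diff(theoretical_is_ar1(aa)) > 0))
  expect_error(theoretical_is_ar1(1), class = "tvis_nonstationary")
})

test_that("quasi-stationary IS trajectory agrees with closed form and Yule-Walker", {
  cfg <- sim_preset("square")
  co <- coeff_waveform(cfg)
  th <- theoretical_is_trajectory(co)
  expect_equal(th, theoretical_is_ar1(co$values[1L, ]))  # p = 1 pointwise
  expect_setequal(round(unique(th), 2), c(0.83, 0.05))

  # p = 2: against the brute-force Yule-Walker solution
  a2 <- c(0.5, -0.3)
  co2 <- coeff_trajectory(matrix(a2, nrow = 2, ncol = 4), fs = 100)
  th2 <- theoretical_is_trajectory(co2, innovation_var = 2)
  g <- yw_brute(a2, 2)
  expect_equal(th2, rep(0.5 * log(g[1L] / 2), 4), tolerance = 1e-12)

  # instantaneous instability flagged as missing
  co_bad <- structure(list(values = matrix(c(0.5, 1.2), nrow = 1), fs = 10),
                      class = "coeff_trajectory")
  expect_equal(is.na(theoretical_is_trajectory(co_bad)), c(FALSE, TRUE))
})

test_that("cardiac fixture is reproducible with valid geometry and errors otherwise", {
  fx1 <- cardiac_fixture(n_channels = 2, n_beats = 5, seed = 9)
  fx2 <- cardiac_fixture(n_channels = 2, n_beats = 5, seed = 9)
  expect_identical(fx1$data, fx2$data)
  expect_identical(fx1$fiducials$r_idx, fx2$fiducials$r_idx)

  # intervals partition every retained beat
  b <- fx1$intervals$beats
  expect_true(all(b$i1_end == b$i2_start & b$i2_end == b$i3_start))
  expect_equal(b$i3_end - b$i1_start,
               (b$i1_end - b$i1_start) + (b$i2_end - b$i2_start) +
                 (b$i3_end - b$i3_start))

  # beat too short for the 80/40 ms offsets
  expect_error(cardiac_fixture(n_beats = 3, beat_period = 0.12),
               class = "tvis_invalid_config")
  # coefficient must stay stable
  expect_error(cardiac_fixture(baseline = 0.9, depths = c(0, 0.2, 0)),
               class = "tvis_invalid_config")
})
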