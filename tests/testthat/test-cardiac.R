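test_that("cycle segmentation reproduces the toy geometry and partitions beats", {
  fid <- fiducial_set(R = c(0, 0.8), T = 0.3, P = 0.7, fs = 128,
                      units = "seconds")
  iv <- segment_cycles(fid, n_samples = 200)
  b <- iv$beats
  # 0-based boundaries: R = 0, T + 80 ms -> 49, P - 40 ms -> 84, next R -> 102
  expect_equal(b$i1_start - 1L, 0L)
  expect_equal(b$i1_end - 1L, 49L)
  expect_equal(b$i2_end - 1L, 84L)
  expect_equal(b$i3_end - 1L, 102L)
  # exact partition of [R_k, R_{k+1})
  expect_equal(b$i1_end, b$i2_start)
  expect_equal(b$i2_end, b$i3_start)
  expect_equal((b$i1_end - b$i1_start) + (b$i2_end - b$i2_start) +
                 (b$i3_end - b$i3_start),
               b$i3_end - b$i1_start)
})

test_that("beats with degenerate geometry are skipped with a reason", {
  # T + 80 ms crosses P - 40 ms in the first beat only
  fid <- fiducial_set(R = c(0, 0.8, 1.6), T = c(0.55, 1.04),
                      P = c(0.62, 1.5), fs = 128, units = "seconds")
  iv <- segment_cycles(fid, n_samples = 300)
  expect_equal(nrow(iv$beats), 1L)
  expect_equal(iv$skipped$beat, 1L)
  expect_match(iv$skipped$reason, "degenerate")

  # all beats degenerate -> error
  fid2 <- fiducial_set(R = c(0, 0.8), T = 0.55, P = 0.62, fs = 128,
                       units = "seconds")
  expect_error(segment_cycles(fid2, 200), class = "tvis_empty_result")
})

test_that("convenience detector finds impulse-train fiducials and rejects flat input", {
  fx <- cardiac_fixture(n_channels = 1, n_beats = 10, fs = 128, seed = 3)
  det <- detect_fiducials(fx$ecg)
  truth <- fx$fiducials
  expect_equal(length(det$r_idx), length(truth$r_idx))
  expect_true(all(abs(det$r_idx - truth$r_idx) <= 1L))
  expect_true(all(abs(det$t_idx - truth$t_idx) <= 1L))
  expect_true(all(abs(det$p_idx - truth$p_idx) <= 1L))

  expect_error(detect_fiducials(ts_record(rep(1, 1000), 128)),
               class = "tvis_empty_result")
  expect_error(detect_fiducials(ts_record(rnorm(100), 50)),
               class = "tvis_invalid_config")
})

test_that("interval summary computes per-beat means and stds as defined", {
  fid <- fiducial_set(R = c(0, 0.8, 1.6), T = c(0.3, 1.1), P = c(0.7, 1.5),
                      fs = 128, units = "seconds")
  iv <- segment_cycles(fid, 300)
  n <- 300

  traj_const <- structure(list(S = rep(1.3, n), fs = 128, valid_from = 1L),
                          class = "is_trajectory")
  sm <- quiet(interval_summary(traj_const, iv, max_beats = 300))
  expect_equal(unique(sm$mean_nats), 1.3)
  expect_equal(unique(sm$std_nats), 0)

  # S = 1 inside I2 only
  s <- rep(0, n)
  for (b in seq_len(nrow(iv$beats)))
    s[iv$beats$i2_start[b]:(iv$beats$i2_end[b] - 1L)] <- 1
  traj <- structure(list(S = s, fs = 128, valid_from = 1L),
                    class = "is_trajectory")
  sm2 <- quiet(interval_summary(traj, iv, max_beats = 2))
  get <- function(ivl, col) sm2[[col]][sm2$interval == ivl]
  expect_equal(get("I2", "mean_nats"), 1)
  expect_equal(get("I1", "mean_nats"), 0)
  expect_equal(get("I3", "mean_nats"), 0)
  # G mean is the duration-weighted mixture for each beat, then averaged
  b <- iv$beats
  frac <- (b$i2_end - b$i2_start) / (b$i3_end - b$i1_start)
  expect_equal(get("G", "mean_nats"), mean(frac))

  # channel reordering commutes
  trajs <- list(a = traj, b = traj_const)
  sm_ab <- quiet(interval_summary(trajs, iv))
  sm_ba <- quiet(interval_summary(rev(trajs), iv))
  expect_equal(sm_ab[sm_ab$channel == "a", ], sm_ba[sm_ba$channel == "a", ],
               ignore_attr = TRUE)

  expect_error(interval_summary(traj, iv, max_beats = 300, strict = TRUE),
               class = "tvis_insufficient_beats")
})

test_that("Cohen's d matches its pooled-variance definition and symmetries", {
  x <- c(0, 1, 2)   # mean 1, var 1
  y <- c(-1, 0, 1)  # mean 0, var 1
  expect_equal(cohens_d(x, y), 1)
  expect_equal(cohens_d(y, x), -1)                      # antisymmetry
  expect_equal(cohens_d(3 * x, 3 * y), cohens_d(x, y))  # scale invariance
})

test_that("paired group comparison flags injected differences and not nulls", {
  fid <- fiducial_set(R = c(0, 0.8, 1.6), T = c(0.3, 1.1), P = c(0.7, 1.5),
                      fs = 128, units = "seconds")
  iv <- segment_cycles(fid, 300)
  mk_subject <- function(i2_level, noise_sd, seed) {
    set.seed(seed)
    s <- rep(0.5, 300) + rnorm(300, 0, noise_sd)
    for (b in seq_len(nrow(iv$beats)))
      s[iv$beats$i2_start[b]:(iv$beats$i2_end[b] - 1L)] <- i2_level +
        rnorm(iv$beats$i2_end[b] - iv$beats$i2_start[b], 0, noise_sd)
    quiet(interval_summary(
      structure(list(S = s, fs = 128, valid_from = 1L),
                class = "is_trajectory"), iv))
  }
  subs <- lapply(1:8, function(k) mk_subject(1.0, 0.05, seed = 400 + k))
  gs <- group_compare(subs, n_comparisons = 6)
  expect_equal(nrow(gs), 12L)  # 6 pairs x 2 metrics x 1 channel
  row <- gs[gs$comparison == "I1-I2" & gs$metric == "MEAN", ]
  expect_true(row$significant)
  expect_lt(row$d, -0.8)       # I2 higher: large negative standardized diff
  expect_equal(row$direction, -1)

  # identical distributions (every interval identical within each subject):
  # d = 0, corrected p = 1
  same <- lapply(1:5, function(k) {
    s <- rep(0.5 + 0.02 * k, 300)  # constant trajectory per subject
    quiet(interval_summary(
      structure(list(S = s, fs = 128, valid_from = 1L),
                class = "is_trajectory"), iv))
  })
  gs0 <- group_compare(same, n_comparisons = 6)
  expect_true(all(gs0$d == 0))
  expect_true(all(gs0$p_bonf == 1))
  expect_false(any(gs0$significant))

  expect_error(group_compare(subs[1]), class = "tvis_invalid_config")
})

test_that("fixture modulation in I2 is recovered end to end", {
  fx <- cardiac_fixture(n_channels = 2, n_beats = 30, fs = 128,
                        depths = c(0, 0.3, 0), baseline = 0.4, seed = 60)
  res <- cardiac_is_pipeline(fx$data, fx$fiducials, fx$fs, p = 1,
                             forgetting = 0.95, max_beats = 30)
  sm <- res$summary
  for (ch in unique(sm$channel)) {
    m <- sm[sm$channel == ch, ]
    expect_gt(m$mean_nats[m$interval == "I2"],
              m$mean_nats[m$interval == "I1"])
    expect_gt(m$mean_nats[m$interval == "I2"],
              m$mean_nats[m$interval == "I3"])
  }
})
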