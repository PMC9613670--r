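test_that("frame displacement is the per-frame Euclidean step length", {
  x <- matrix(c(0, 3, 3), 3, 1, dimnames = list(NULL, "index_tip"))
  y <- matrix(c(0, 4, 4), 3, 1, dimnames = list(NULL, "index_tip"))
  d <- frame_displacement(make_track(x, y), "index_tip")
  expect_equal(d$values, c(5, 0))
  expect_equal(d$fs, 60)
  expect_equal(d$stage, "raw_displacement")

  xs <- matrix(2, 100, 1, dimnames = list(NULL, "index_tip"))
  expect_equal(frame_displacement(make_track(xs, xs), "index_tip")$values,
               rep(0, 99))

  # random walk with unit steps: every displacement is exactly 1
  set.seed(4)
  ang <- runif(200, 0, 2 * pi)
  xw <- matrix(cumsum(c(0, cos(ang))), ncol = 1,
               dimnames = list(NULL, "index_tip"))
  yw <- matrix(cumsum(c(0, sin(ang))), ncol = 1,
               dimnames = list(NULL, "index_tip"))
  expect_equal(frame_displacement(make_track(xw, yw), "index_tip")$values,
               rep(1, 200), tolerance = 1e-12)

  expect_error(frame_displacement(make_track(x, y), "nope"),
               class = "nmmap_lookup_error")
})

test_that("low-likelihood detections propagate as absent displacements", {
  x <- matrix(1:10, 10, 1, dimnames = list(NULL, "index_tip"))
  lk <- matrix(1, 10, 1, dimnames = list(NULL, "index_tip"))
  lk[4, 1] <- 0.2
  d <- frame_displacement(make_track(x, x, lk), "index_tip",
                          likelihood_min = 0.6)
  expect_true(all(is.na(d$values[3:4])))  # steps into and out of frame 4
  expect_equal(sum(is.na(d$values)), 2)
})

test_that("artifact repair flags spikes above mean + k*SD and interpolates", {
  v <- rep(1, 30); v[15] <- 100
  # confirm the spike exceeds the epoch's own mean + 4.5 SD threshold
  expect_gt(100, mean(v) + 4.5 * sd(v))
  rep1 <- repair_artifacts(kinematic_signal(v, 60), k_sd = 4.5)
  expect_equal(rep1$values, rep(1, 30))
  expect_equal(which(rep1$flags), 15L)

  # no values above threshold and no gaps: identity
  set.seed(5)
  clean <- kinematic_signal(runif(50, 1, 2), 60)
  rep2 <- repair_artifacts(clean)
  expect_equal(rep2$values, clean$values)
  expect_false(any(rep2$flags))

  # absent run linearly interpolated between neighbours
  sig3 <- kinematic_signal(c(1, NA, NA, NA, 4, 4), 60)
  rep3 <- repair_artifacts(sig3)
  expect_equal(rep3$values[2:4], c(1.75, 2.5, 3.25))

  # edge gaps take the nearest value
  sig4 <- kinematic_signal(c(NA, NA, 3, 5, 7, 7, 7, NA), 60)
  rep4 <- repair_artifacts(sig4)
  expect_equal(rep4$values, c(3, 3, 3, 5, 7, 7, 7, 7))

  # unusable epoch: more than half the samples flagged
  expect_error(repair_artifacts(kinematic_signal(c(NA, NA, NA, 1, 2), 60)),
               class = "nmmap_quality_error")
})

test_that("repair never changes unflagged samples", {
  set.seed(6)
  for (i in 1:20) {
    v <- runif(100, 0, 3)
    v[sample(100, 5)] <- NA
    v[sample(100, 2)] <- 50  # gross spikes
    out <- repair_artifacts(kinematic_signal(v, 60))
    keep <- !out$flags
    expect_identical(out$values[keep], v[keep])
  }
})

test_that("fingertip aggregation averages then smooths", {
  set.seed(7)
  v <- runif(120, 0, 2)
  mk <- function(vals) kinematic_signal(vals, 60, stage = "raw_displacement")
  one <- repair_artifacts(mk(v))
  five <- replicate(5, one, simplify = FALSE)
  expect_equal(aggregate_fingertips(five)$values,
               aggregate_fingertips(list(one))$values)

  const <- lapply(1:5, function(i) repair_artifacts(mk(rep(2, 60))))
  expect_equal(aggregate_fingertips(const)$values, rep(2, 60))

  a <- repair_artifacts(mk(rep(c(0, 2), 30)))
  b <- repair_artifacts(mk(rep(c(2, 0), 30)))
  # antiphase signals average to a constant even before smoothing
  expect_equal(aggregate_fingertips(list(a, b), smoothing_window_s = 0)$values,
               rep(1, 60))

  short <- repair_artifacts(mk(rep(1, 30)))
  expect_error(aggregate_fingertips(list(one, short)),
               class = "nmmap_validation_error")
})

test_that("smoothing reduces or preserves total variation", {
  tv <- function(x) sum(abs(diff(x)))
  set.seed(8)
  for (i in 1:25) {
    v <- cumsum(rnorm(150))
    sm <- nmmap:::.moving_average(v, sample(2:40, 1))
    expect_lte(tv(sm), tv(v) + 1e-9)
  }
})

test_that("resampling to 1200 Hz preserves in-band content", {
  mk <- function(vals) kinematic_signal(vals, 60, stage = "smoothed")
  con <- resample_to_common(mk(rep(3.7, 60)))
  expect_equal(length(con$values), 1200)
  expect_equal(con$values, rep(3.7, 1200), tolerance = 1e-3)
  expect_equal(con$fs, 1200)

  t <- (0:599) / 60
  sig <- resample_to_common(mk(sin(2 * pi * 5 * t)))
  expect_equal(length(sig$values), 12000)
  # a 5 Hz sinusoid survives with amplitude error below 1%
  expect_lt(abs(max(abs(sig$values)) - 1), 0.01)

  expect_error(resample_to_common(mk(runif(60)), fs_out = 60 * pi),
               class = "nmmap_config_error")
})

test_that("min-max normalization hits 0 and 1 and is idempotent", {
  expect_equal(normalize_01(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_01(c(-1, 0, 3)), c(0, 0.25, 1))
  v <- normalize_01(runif(30))
  expect_equal(normalize_01(v), v)
  expect_error(normalize_01(rep(1, 10)), class = "nmmap_degenerate_error")
})

test_that("pipeline output is invariant to keypoint translation and scale", {
  cfg <- test_config()
  kt <- gen_kinematics(cfg, "active", seed = 99)
  base <- process_kinematics(kt)$values
  shift <- keypoint_table(kt$x + 137, kt$y - 42, kt$likelihood,
                          kt$frame_rate)
  expect_equal(process_kinematics(shift)$values, base, tolerance = 1e-9)
  scaled <- keypoint_table(kt$x * 2.5, kt$y * 2.5, kt$likelihood,
                           kt$frame_rate)
  expect_equal(process_kinematics(scaled)$values, base, tolerance = 1e-9)
})
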