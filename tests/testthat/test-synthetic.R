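test_that("generators are pure functions of (config, seed)", {
  cfg <- test_config(dropout_rate = 0.05)
  k1 <- gen_kinematics(cfg, "active", seed = 41)
  k2 <- gen_kinematics(cfg, "active", seed = 41)
  expect_identical(k1$x, k2$x)
  expect_identical(k1$likelihood, k2$likelihood)
  k3 <- gen_kinematics(cfg, "active", seed = 42)
  expect_false(identical(k1$x, k3$x))

  v1 <- gen_voltage(cfg, attr(k1, "envelope"), seed = 43)
  v2 <- gen_voltage(cfg, attr(k1, "envelope"), seed = 43)
  expect_identical(v1$samples, v2$samples)
  expect_identical(attr(v1, "true_spikes"), attr(v2, "true_spikes"))
})

test_that("active kinematics peak at the clench frequency", {
  cfg <- test_config(dropout_rate = 0)
  kt <- gen_kinematics(cfg, "active", seed = 44)
  expect_false(anyNA(kt$x))
  d <- frame_displacement(kt, "index_tip")$values
  sp <- Mod(fft(d - mean(d)))[2:50]
  freqs <- (1:48) / length(d) * 60
  peak_f <- freqs[which.max(sp)]
  # the speed envelope of a clench at f Hz oscillates at 2f
  drive <- attr(kt, "drive")
  zero_cross <- sum(diff(drive > mean(drive)) != 0) / 2
  f_true <- zero_cross / cfg$epoch_duration_s
  expect_equal(peak_f, 2 * f_true, tolerance = 0.35)
})

test_that("dropouts occlude approximately the configured frame fraction", {
  cfg <- test_config(epoch_duration_s = 30, dropout_rate = 0.1)
  frac <- mean(vapply(1:8, function(i) {
    kt <- gen_kinematics(cfg, "passive", seed = 100 + i)
    mean(is.na(kt$x[, 1]))
  }, 0))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.16)
})

test_that("uncoupled spiking is Poisson at the base rate", {
  cfg <- test_config(epoch_duration_s = 10, base_rate_hz = 100)
  tr <- gen_voltage(cfg, NULL, coupling_gain = 0, seed = 45)
  n_sp <- length(attr(tr, "true_spikes"))
  expect_lt(abs(n_sp - 1000), 3 * sqrt(1000))

  # chi-square goodness of fit of 200 ms bin counts against Poisson(20)
  bins <- cut(attr(tr, "true_spikes"),
              breaks = seq(0, 10 * cfg$fs_neural, by = 0.2 * cfg$fs_neural))
  counts <- as.vector(table(bins))
  lam <- mean(counts)
  br <- c(-Inf, qpois(seq(0.1, 0.9, 0.2), lam), Inf)
  obs <- table(cut(counts, br))
  expp <- diff(ppois(c(-Inf, qpois(seq(0.1, 0.9, 0.2), lam), Inf), lam)) *
    length(counts)
  chi <- sum((as.vector(obs) - expp)^2 / expp)
  expect_lt(chi, qchisq(0.99, df = length(expp) - 2))
})

test_that("noise-only traces force the detector off its start threshold", {
  cfg <- test_config(spike_amplitude_snr = 0, epoch_duration_s = 2)
  tr <- gen_voltage(cfg, NULL, coupling_gain = 0, seed = 46)
  st <- detect_spikes_adaptive(bandpass_mua(tr))
  expect_lt(st$threshold_used, 4.5)
  expect_true(st$threshold_used == 2.5 ||
                (st$mean_rate_hz > 80 && st$mean_rate_hz < 400))
})

test_that("coupled voltage yields a rate signal correlated with movement", {
  # slow clenches: the speed envelope oscillates at twice the clench
  # frequency, so the 250 ms comparison smoothing passes it intact
  cfg <- test_config(epoch_duration_s = 10, coupling_gain = 1,
                     latency_s = 0, clench_hz_range = c(0.6, 0.9))
  kt <- gen_kinematics(cfg, "active", seed = 47)
  env <- attr(kt, "envelope")
  tr <- gen_voltage(cfg, env, seed = 48)
  r <- process_mua(tr, n_samples = length(env$values))
  sm <- function(x) nmmap:::.moving_average(x, 300)
  expect_gt(cor(sm(r$values), sm(env$values)), 0.4)
})

test_that("null databases have the declared size, length, and manifest", {
  cfg <- test_config()
  db <- gen_null_database(cfg, n_recordings = 4, duration_s = 11)
  expect_s3_class(db, "mua_segment_db")
  expect_length(db$rates, 4)
  expect_equal(nrow(db$manifest), 4)
  lens <- vapply(db$rates, function(r) length(r$values), 0L)
  expect_true(all(lens == round(11 * 1200)))
  db2 <- gen_null_database(cfg, n_recordings = 4, duration_s = 11)
  expect_identical(db$rates[[2]]$values, db2$rates[[2]]$values)
})

test_that("labeled sessions tie labels to true coupling", {
  cfg <- test_config(n_epochs = 12, label_error_rate = 0)
  s <- gen_labeled_session(cfg)
  expect_length(s$epochs, 12)
  expect_equal(s$truth$clinician_label,
               ifelse(s$truth$coupling_gain > 0, "clin_plus", "clin_minus"))
  expect_true(all(vapply(s$epochs, inherits, TRUE, what = "epoch_record")))
  # movement mix and coupling mix are both represented
  expect_gt(length(unique(s$truth$movement_type)), 1)
  expect_gt(length(unique(s$truth$coupling_gain)), 1)

  cfg2 <- test_config(n_epochs = 30, label_error_rate = 0.3)
  s2 <- gen_labeled_session(cfg2)
  truth2 <- ifelse(s2$truth$coupling_gain > 0, "clin_plus", "clin_minus")
  expect_gt(sum(s2$truth$clinician_label != truth2), 0)
})
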