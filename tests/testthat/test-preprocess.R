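test_that("MBLL conversion inverts the simulator's intensity emission", {
  cfg <- sim_config(seed = 21, n_per_group = 2, emit_intensity = TRUE,
                    artifact = artifact_spec(spike_rate = 0))
  rec <- simulate_recording(cfg, "S001", "intervention", "pre")
  pc <- preproc_config()
  conv <- mbll_convert(rec, pc)
  # emission references intensities to the first 10 s mean, so conversion
  # recovers the signal re-centred on that window
  nref <- round(pc$baseline_tail_s * rec$fs)
  centred <- sweep(rec$data, 2, colMeans(rec$data[seq_len(nref), ]))
  expect_lt(max(abs(conv$data - centred)), 1e-9)
  expect_equal(conv$hbr, -pc$mbll$hbr_ratio * centred, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("MBLL conversion validates its inputs", {
  pc <- preproc_config()
  rec <- nirs_recording(matrix(0, 700, 48), fs = 5)
  expect_error(mbll_convert(rec, pc), "no dual-wavelength")
  # constant intensity at the reference level -> zero concentration change
  rec$intensity <- list(`785` = matrix(0.8, 700, 48),
                        `825` = matrix(1.2, 700, 48))
  out <- mbll_convert(rec, pc)
  expect_equal(max(abs(out$data)), 0)
  # nonpositive intensity
  rec$intensity[[1]][5, 3] <- -1
  expect_error(mbll_convert(rec, pc), "positive")
  # proportional extinction rows are singular
  expect_error(
    mbll_coefficients(extinction = matrix(c(1, 2, 2, 4), 2, byrow = TRUE)),
    "singular")
})

test_that("motion detection flags spikes and nothing else", {
  pc <- preproc_config()
  flat <- nirs_recording(matrix(5, 700, 2), fs = 5)
  expect_true(!any(detect_motion(flat, pc)))

  set.seed(31)
  x <- matrix(rnorm(700 * 2, sd = 0.05), 700, 2)
  spike_at <- 300
  x[spike_at, 1] <- x[spike_at, 1] + 20 * 0.05
  rec <- nirs_recording(x, fs = 5)
  mask <- detect_motion(rec, pc)
  expect_true(mask[spike_at, 1])
  expect_false(any(mask[, 2]))
  # infinite threshold disables detection
  expect_false(any(detect_motion(rec, preproc_config(motion_z = Inf))))
  short <- nirs_recording(matrix(rnorm(10), 10, 1), fs = 5)
  expect_error(detect_motion(short, pc), "too short")
})

test_that("interpolation repair is exact on a ramp and safe on edge cases", {
  n <- 700
  ramp <- matrix(seq(0, 10, length.out = n), n, 1)
  rec <- nirs_recording(ramp + 0, fs = 5)
  mask <- matrix(FALSE, n, 1)
  # empty mask: identity
  expect_identical(correct_motion(rec, mask)$data, rec$data)
  # spiked ramp: cubic interpolation restores the line
  spiked <- rec
  spiked$data[350:352, 1] <- spiked$data[350:352, 1] + 3
  mask[349:353, 1] <- TRUE
  fixed <- correct_motion(spiked, mask)
  expect_lt(max(abs(fixed$data - ramp)), 1e-6)
  # a fully masked channel cannot be repaired
  mask[] <- TRUE
  expect_error(correct_motion(spiked, mask), "entirely artifact")
  # method "none" passes through
  expect_identical(correct_motion(spiked, mask, "none")$data, spiked$data)
})

test_that("the low-pass filter meets its frequency-response contracts", {
  pc <- preproc_config()  # 0.1 Hz, order 4, zero phase
  fs <- 5
  n <- 3000
  tt <- (seq_len(n) - 1) / fs
  mid <- 500:2500
  amp_out <- function(f_hz) {
    rec <- nirs_recording(as.matrix(sin(2 * pi * f_hz * tt)), fs = fs)
    y <- lowpass(rec, pc)$data[, 1]
    max(abs(y[mid]))
  }
  # DC gain exactly 1
  const <- nirs_recording(matrix(3.7, 700, 3), fs = fs)
  expect_lt(max(abs(lowpass(const, pc)$data - 3.7)), 1e-8)
  # cardiac band (1.1 Hz) crushed, slow passband (0.01 Hz) untouched
  expect_lt(amp_out(1.1), 0.01)
  expect_gt(amp_out(0.01), 0.99)
  # design validation
  expect_error(lowpass(const, preproc_config(lowpass_cutoff_hz = 3)),
               "Nyquist")
})

test_that("the low-pass filter is linear", {
  pc <- preproc_config()
  set.seed(41)
  x <- matrix(rnorm(700 * 2), 700, 2)
  y <- matrix(rnorm(700 * 2), 700, 2)
  lp <- function(m) lowpass(nirs_recording(m, fs = 5), pc)$data
  expect_lt(max(abs(lp(2 * x + 3 * y) - (2 * lp(x) + 3 * lp(y)))), 1e-8)
})

test_that("baseline panning zeroes the pre-task tail minimum, idempotently", {
  p <- vft_paradigm()
  pc <- preproc_config()
  win <- 76:125  # last 10 s of the 25 s pre-task rest at 5 Hz
  # constant channel collapses to zero
  const <- nirs_recording(matrix(-2.4, p$n_samples, 2), fs = p$fs)
  expect_equal(max(abs(baseline_pan(const, p, pc)$data)), 0)
  # a window minimum of -0.3 shifts the trace up by exactly 0.3
  set.seed(51)
  x <- matrix(rnorm(p$n_samples), p$n_samples, 1)
  x[100, 1] <- min(x[win, 1]) - 1  # force a known minimum inside the window
  x[100, 1] <- -0.3
  x[win, 1] <- pmax(x[win, 1], -0.3)
  rec <- nirs_recording(x, fs = p$fs)
  panned <- baseline_pan(rec, p, pc)
  expect_equal(panned$data[, 1], x[, 1] + 0.3)
  expect_equal(min(panned$data[win, 1]), 0)
  # idempotence
  expect_equal(baseline_pan(panned, p, pc)$data, panned$data)
  # window validation
  expect_error(baseline_pan(rec, p, preproc_config(baseline_tail_s = 30)),
               "pre-task rest")
})

test_that("channel quality gating admits exactly the 36-channel boundary", {
  cfg <- sim_config(seed = 61, n_per_group = 2,
                    artifact = artifact_spec(spike_rate = 0))
  rec <- simulate_recording(cfg, "S001", "intervention", "pre")
  pc <- quiet_preproc()
  q <- assess_quality(rec, pc)
  expect_equal(attr(q, "n_good"), 48L)
  expect_true(all(q$good))

  flatten <- function(rec, k) {
    rec$data[, seq_len(k)] <- 0
    rec
  }
  q35 <- assess_quality(flatten(rec, 13), pc)
  expect_equal(attr(q35, "n_good"), 35L)
  expect_equal(sum(q35$reason == "flat"), 13L)
  q36 <- assess_quality(flatten(rec, 12), pc)
  expect_equal(attr(q36, "n_good"), 36L)

  expect_false(subject_quality_gate(q35, q36)$subject_valid)
  expect_true(subject_quality_gate(q36, q36)$subject_valid)
  expect_false(subject_quality_gate(q36, q35)$subject_valid)
  # deterministic
  expect_identical(as.data.frame(q36),
                   as.data.frame(assess_quality(flatten(rec, 12), pc)))
})

test_that("preprocessing runs in the fixed documented order", {
  cfg <- sim_config(seed = 71, n_per_group = 2, emit_intensity = TRUE)
  rec <- simulate_recording(cfg, "S001", "control", "pre")
  pp <- preprocess_recording(rec, cfg$paradigm, preproc_config())
  steps <- sub(":.*", "", pp$steps)
  expect_equal(steps, c("mbll", "motion", "detrend", "lowpass", "pan"))
  expect_s3_class(attr(pp, "quality"), "quality_report")
  expect_true(all(is.finite(pp$data)))
})

test_that("preprocessing suppresses injected spike artifacts", {
  # identical cohorts with and without spikes (artifacts are drawn after
  # the signal, so the underlying data are the same); after preprocessing,
  # the group-level activation contrast - the estimate every downstream
  # test consumes - must agree to within 10% of the true amplitude
  a <- 0.06
  n_subj <- 12
  base <- list(
    seed = 81, n_per_group = n_subj, amplitudes = flat_amplitudes(a),
    amp_subject_sd = 0, resp_sd = 0)
  cfg_clean <- do.call(sim_config, c(base, list(
    artifact = artifact_spec(spike_rate = 0, shift_rate = 0))))
  cfg_spiky <- do.call(sim_config, c(base, list(
    artifact = artifact_spec())))  # defaults: 2 spikes/min, sd 2
  pc <- preproc_config()  # motion repair on
  group_contrast <- function(cfg) {
    per_subj <- sapply(seq_len(n_subj), function(i) {
      rec <- simulate_recording(cfg, sprintf("S%03d", i), "intervention",
                                "post")
      pp <- preprocess_recording(rec, cfg$paradigm, pc)
      block_contrast(pp, cfg$paradigm)$contrast
    })
    # cohort-mean contrast per channel over good (quality-passing)
    # subject x channel observations, as the cohort analysis computes it
    rowMeans(per_subj, na.rm = TRUE)
  }
  d <- abs(group_contrast(cfg_spiky) - group_contrast(cfg_clean))
  expect_lt(mean(d), 0.1 * a)
})
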