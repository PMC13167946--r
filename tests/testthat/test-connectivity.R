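# tiny paradigm: 3-sample baseline, 3-sample task window at 5 Hz
toy_paradigm <- vft_paradigm(pre_rest_s = 0.6, task_block_s = 0.6,
                             n_blocks = 1, post_rest_s = 0.6, fs = 5)

toy_rec <- function(task_cols) {
  n <- toy_paradigm$n_samples
  X <- matrix(0.5, n, length(task_cols))
  w <- nirsvft:::paradigm_windows(toy_paradigm)$task
  for (j in seq_along(task_cols)) X[w, j] <- task_cols[[j]]
  nirs_recording(X, fs = 5)
}

test_that("Pearson FC matches hand computations on toy windows", {
  # duplicated / negated channels
  f <- fc_matrix(toy_rec(list(c(1, 2, 3), c(1, 2, 3), c(-1, -2, -3))),
                 toy_paradigm)
  expect_equal(f$r[1, 2], 1)
  expect_equal(f$r[1, 3], -1)
  # x = (1,2,3), y = (1,2,4): r = 3 / sqrt(2 * 14/3)
  f2 <- fc_matrix(toy_rec(list(c(1, 2, 3), c(1, 2, 4))), toy_paradigm)
  expect_equal(f2$r[1, 2], 0.98198, tolerance = 1e-4)
  # symmetric, unit diagonal, bounded
  expect_identical(f2$r, t(f2$r))
  expect_equal(diag(f2$r), rep(1, 2), ignore_attr = TRUE)
  expect_true(all(abs(f2$r) <= 1))
})

test_that("zero-variance channels are flagged and excluded, not zeroed", {
  f <- fc_matrix(toy_rec(list(c(1, 2, 3), c(2, 2, 2))), toy_paradigm)
  expect_false(f$good[2])
  expect_true(all(is.na(f$r[2, ])))
  expect_true(all(is.na(f$r[, 2])))
  expect_equal(f$r[1, 1], 1)
  short <- vft_paradigm(pre_rest_s = 0.2, task_block_s = 0.4, n_blocks = 1,
                        post_rest_s = 0.2, fs = 5)
  expect_error(fc_matrix(toy_rec(list(1:3)), short), "fewer than 3")
})

test_that("fc_matrix equals a brute-force per-pair Pearson loop", {
  p <- vft_paradigm(pre_rest_s = 2, task_block_s = 10, n_blocks = 1,
                    post_rest_s = 2, fs = 5)  # 50-sample task window
  set.seed(141)
  for (rep in 1:5) {
    X <- matrix(rnorm(p$n_samples * 5), p$n_samples, 5)
    rec <- nirs_recording(X, fs = p$fs)
    f <- fc_matrix(rec, p)
    w <- nirsvft:::paradigm_windows(p)$task
    for (i in 1:4) for (j in (i + 1):5) {
      xi <- X[w, i]; xj <- X[w, j]
      r_manual <- sum((xi - mean(xi)) * (xj - mean(xj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      expect_equal(f$r[i, j], r_manual, tolerance = 1e-10)
    }
  }
})

test_that("the Fisher transform round-trips and mean FC averages on z", {
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  # identity matrix -> mean FC 0; constant off-diagonal r -> that r
  mk <- function(R) structure(list(r = R, good = rep(TRUE, nrow(R)),
                                   subject = "s", group = "g",
                                   timepoint = "pre",
                                   channels = seq_len(nrow(R))),
                              class = "nirs_fc")
  R0 <- diag(3)
  expect_equal(mean_fc(mk(R0)), 0)
  R5 <- matrix(0.5, 3, 3); diag(R5) <- 1
  expect_equal(mean_fc(mk(R5)), 0.5)
  # mixed toy {0.3, 0.5, 0.4}: back-transformed mean z
  Rm <- diag(3)
  Rm[1, 2] <- Rm[2, 1] <- 0.3
  Rm[1, 3] <- Rm[3, 1] <- 0.5
  Rm[2, 3] <- Rm[3, 2] <- 0.4
  expect_equal(mean_fc(mk(Rm)),
               tanh(mean(atanh(c(0.3, 0.5, 0.4)))), tolerance = 1e-12)
  expect_equal(mean_fc(mk(Rm)), 0.40322, tolerance = 1e-3)
})

test_that("region-pair FC averages channel pairs on the z scale", {
  m <- default_montage()
  R <- matrix(0, 48, 48); diag(R) <- 1
  mk <- function(R, good = rep(TRUE, 48))
    structure(list(r = R, good = good, subject = "s", group = "g",
                   timepoint = "pre", channels = 1:48), class = "nirs_fc")
  # all zero off-diagonal -> all ROI entries 0
  rf0 <- roi_fc(mk(R), m)
  expect_equal(max(abs(rf0)), 0)
  # constant r = c everywhere -> every entry c (z-mean is exact)
  Rc <- matrix(0.35, 48, 48); diag(Rc) <- 1
  rfc <- roi_fc(mk(Rc), m)
  expect_equal(max(abs(rfc - 0.35)), 0, tolerance = 1e-12)
  # two inter-ROI pairs {0.3, 0.5}: only channels 1 (rSTC), 5 and 6
  # (rVLPFC) are good
  good <- rep(FALSE, 48); good[c(1, 5, 6)] <- TRUE
  R2 <- matrix(0, 48, 48); diag(R2) <- 1
  R2[1, 5] <- R2[5, 1] <- 0.3
  R2[1, 6] <- R2[6, 1] <- 0.5
  rf2 <- roi_fc(mk(R2, good), m)
  expect_equal(rf2["rSTC", "rVLPFC"],
               tanh((atanh(0.3) + atanh(0.5)) / 2), tolerance = 1e-12)
  expect_equal(rf2["rSTC", "rVLPFC"], 0.40483, tolerance = 1e-4)
  # an ROI with no good channel yields missing rows
  expect_true(all(is.na(rf2["mPFC", ])))
  # symmetry
  expect_identical(rf2, t(rf2))
})

test_that("pre = post connectivity gives null change statistics", {
  set.seed(151)
  base <- matrix(rnorm(300 * 6), 300, 6)
  p <- vft_paradigm(pre_rest_s = 2, task_block_s = 60, n_blocks = 1,
                    post_rest_s = 2, fs = 5)
  recs <- list()
  for (s in 1:4) for (tp in c("pre", "post")) {
    X <- matrix(rnorm(p$n_samples * 6, sd = 0.01), p$n_samples, 6)
    w <- nirsvft:::paradigm_windows(p)$task
    X[w, ] <- base + s  # identical task window pre and post
    recs[[length(recs) + 1]] <- nirs_recording(
      X, fs = p$fs, subject = sprintf("S%02d", s),
      group = if (s <= 2) "intervention" else "control", timepoint = tp)
  }
  fc <- cohort_fc(recs, p)
  res <- fc_change_tests(fc, "pair")
  within <- res[startsWith(res$comparison, "within"), ]
  expect_equal(within$statistic, rep(0, nrow(within)))
  expect_equal(within$p, rep(1, nrow(within)))
  expect_equal(within$q, rep(1, nrow(within)))
  expect_false(any(res$sig))
})

test_that("fc_change_tests agrees with explicit t-tests on Fisher z", {
  cfg <- sim_config(seed = 161, n_per_group = 6,
                    artifact = artifact_spec(spike_rate = 0))
  co <- simulate_cohort(cfg)
  pp <- lapply(co$recordings, preprocess_recording, cfg = quiet_preproc())
  fc <- cohort_fc(pp)
  res <- fc_change_tests(fc, "roi_pair")
  # cross-check one ROI pair against direct computation
  e <- fc$roi_edges
  pick <- "lSFC-lDLPFC"
  sub <- e[paste0(e$roi_a, "-", e$roi_b) == pick, ]
  wide <- tidyr::pivot_wider(sub[, c("subject", "group", "timepoint", "z")],
                             names_from = "timepoint", values_from = "z")
  g1 <- wide[wide$group == "intervention", ]
  tt <- stats::t.test(g1$post, g1$pre, paired = TRUE)
  row <- res[res$comparison == "within_intervention" & res$edge == pick, ]
  expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  # between-group two-sample on the change
  g2 <- wide[wide$group == "control", ]
  tt2 <- stats::t.test(g1$post - g1$pre, g2$post - g2$pre,
                       var.equal = TRUE)
  row2 <- res[res$comparison == "between" & res$edge == pick, ]
  expect_equal(row2$statistic, unname(tt2$statistic), tolerance = 1e-10)
  # the family: 36 ROI pairs + 9 within-ROI entries per comparison
  expect_equal(sum(res$comparison == "between"), 45)
})

test_that("brain-behaviour correlation matches its closed form", {
  d <- data.frame(dfc = c(0.1, 0.2, 0.05, 0.3), dscale = c(2, 4, 1, 6))
  d$exact <- 2 * d$dfc
  res <- correlate_outcome(d, dfc, exact)
  expect_equal(res$r, 1)
  # r, t and p agree with cor.test
  set.seed(171)
  d2 <- data.frame(x = rnorm(30), y = rnorm(30))
  res2 <- correlate_outcome(d2, x, y)
  ct <- stats::cor.test(d2$x, d2$y)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$statistic, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-10)
  expect_equal(c(res2$conf.low, res2$conf.high),
               as.numeric(ct$conf.int), tolerance = 1e-6)
  # null at n = 1000
  set.seed(172)
  d3 <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(correlate_outcome(d3, x, y)$r), 0.08)
  expect_error(correlate_outcome(d2[1:2, ], x, y), "at least 3")
  d4 <- data.frame(x = rep(1, 5), y = rnorm(5))
  expect_error(correlate_outcome(d4, x, y), "zero variance")
})

test_that("simulated FC matrices satisfy symmetry and bounds", {
  cfg <- sim_config(seed = 181, n_per_group = 3)
  co <- simulate_cohort(cfg, groups = "intervention")
  pp <- lapply(co$recordings, preprocess_recording, cfg = quiet_preproc())
  for (rec in pp) {
    f <- fc_matrix(rec, cfg$paradigm)
    expect_identical(f$r, t(f$r))
    expect_true(all(abs(f$r[!is.na(f$r)]) <= 1))
    expect_equal(diag(f$r)[f$good], rep(1, sum(f$good)),
                 ignore_attr = TRUE)
  }
})
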