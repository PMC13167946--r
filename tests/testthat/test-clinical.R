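test_that("the normality gate routes samples as Shapiro-Wilk dictates", {
  set.seed(191)
  g <- normality_gate(rnorm(500))
  expect_true(g$parametric)
  expect_equal(g$branch, "parametric")
  # heavily discrete 0-3 scores: strongly non-normal
  skewed <- rep(c(0, 0, 0, 1, 3), 20)
  g2 <- normality_gate(skewed)
  expect_false(g2$parametric)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_error(normality_gate(rep(2, 10)), "constant")
})

test_that("paired_change reproduces a hand-worked example", {
  # differences {-5, -4, -6, -5}: mean -5, sd = sqrt(2/3),
  # CI = -5 +/- t_{0.975,3} * 0.8165 / 2 = (-6.30, -3.70)
  pre <- c(10, 10, 10, 10)
  post <- pre + c(-5, -4, -6, -5)
  pc <- paired_change(pre, post, method = "parametric")
  expect_equal(pc$estimate, -5)
  expect_equal(pc$conf.low, -5 - stats::qt(0.975, 3) * sqrt(2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(round(c(pc$conf.low, pc$conf.high), 2), c(-6.30, -3.70))
  expect_equal(pc$effect, -5 / sqrt(2 / 3), tolerance = 1e-12)
  # post = pre: zero change, p = 1, CI contains 0
  pc0 <- paired_change(pre, pre)
  expect_equal(pc0$estimate, 0)
  expect_equal(pc0$statistic, 0)
  expect_equal(pc0$p, 1)
  expect_true(pc0$conf.low <= 0 && pc0$conf.high >= 0)
  expect_error(paired_change(1, 2), "n >= 2")
})

test_that("paired_change matches t.test and wilcox.test", {
  set.seed(201)
  pre <- rnorm(25); post <- pre + rnorm(25, 0.3)
  pc <- paired_change(pre, post, method = "parametric")
  tt <- stats::t.test(post, pre, paired = TRUE)
  expect_equal(pc$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(pc$p, tt$p.value, tolerance = 1e-10)
  expect_equal(c(pc$conf.low, pc$conf.high), as.numeric(tt$conf.int),
               tolerance = 1e-10)
  # nonparametric branch: p agrees with the tie-free exact wilcox at small n
  set.seed(202)
  pre2 <- rnorm(8); post2 <- pre2 + rnorm(8, 0.5)
  pn <- paired_change(pre2, post2, method = "nonparametric")
  wt <- stats::wilcox.test(post2, pre2, paired = TRUE, exact = TRUE)
  expect_equal(pn$p, wt$p.value, tolerance = 1e-12)
  expect_equal(pn$effect_type, "r")
  # all-zero differences under the rank test are flagged
  expect_warning(
    pz <- paired_change(pre2, pre2, method = "nonparametric"),
    "all-zero")
  expect_equal(pz$flag, "all differences zero")
  expect_equal(pz$p, 1)
})

test_that("CI inversion recovers the change-score SD of published rows", {
  # intervention PSQI change -4.69 (CI -6.04, -3.33), n = 32
  sd_hat <- sd_from_ci(-6.04, -3.33, 32)
  expect_equal(sd_hat, 3.76, tolerance = 0.02)
  # round trip: CI -> sd -> CI
  set.seed(211)
  x <- rnorm(20)
  pc <- paired_change(rep(0, 20), x, method = "parametric")
  expect_equal(sd_from_ci(pc$conf.low, pc$conf.high, 20), sd(x),
               tolerance = 1e-9)
})

test_that("published effect sizes are reproduced from summary statistics", {
  psqi <- between_group_from_summary(-4.69, -6.04, -3.33, 32,
                                     -2.13, -2.83, -1.42, 32)
  expect_equal(psqi$effect, -0.854, tolerance = 0.003)
  expect_equal(psqi$effect_low, -1.363, tolerance = 0.01)
  expect_equal(psqi$effect_high, -0.338, tolerance = 0.01)
  sds <- between_group_from_summary(-7.78, -10.54, -5.02, 32,
                                    -3.31, -6.22, -0.41, 32)
  expect_equal(sds$effect, -0.569, tolerance = 0.003)
  expect_equal(sds$effect_low, -1.066, tolerance = 0.01)
  expect_equal(sds$effect_high, -0.066, tolerance = 0.01)
})

test_that("between_group_change handles identity, sign and branching", {
  set.seed(221)
  x <- rnorm(20)
  same <- between_group_change(x, x)
  expect_equal(same$effect, 0)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # group 1 improving more (more negative change) gives negative d
  g1 <- rnorm(20, -5); g2 <- rnorm(20, -2)
  bg <- between_group_change(g1, g2, method = "parametric")
  expect_lt(bg$effect, 0)
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(bg$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(bg$p, tt$p.value, tolerance = 1e-10)
  # noncentral-t CI brackets the point estimate
  expect_true(bg$effect_low < bg$effect && bg$effect < bg$effect_high)
  # nonparametric: r = |Z|/sqrt(N), p from the normal approximation
  bn <- between_group_change(g1, g2, method = "nonparametric")
  wt <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
  expect_equal(bn$p, wt$p.value, tolerance = 1e-10)
  expect_equal(bn$effect, abs(bn$statistic) / sqrt(40), tolerance = 1e-12)
  expect_error(between_group_change(rep(1, 5), rep(1, 5) + 0),
               "pooled variance")
})

test_that("the 2x2 chi-square reproduces published trial statistics", {
  blind <- chi_square_2x2(rbind(c(15, 17), c(14, 18)))
  expect_equal(round(blind$statistic, 3), 0.063)
  expect_equal(round(blind$p, 3), 0.802)
  ae <- chi_square_2x2(rbind(c(4, 28), c(3, 29)))
  expect_equal(round(ae$statistic, 3), 0.160)
  expect_equal(round(ae$p, 3), 0.689)
  sex <- chi_square_2x2(rbind(c(11, 21), c(13, 19)))
  expect_equal(round(sex$statistic, 3), 0.267)
  expect_equal(round(sex$p, 3), 0.606)
})

test_that("the chi-square formula equals the expected-counts oracle", {
  set.seed(231)
  for (i in 1:200) {
    tbl <- matrix(sample(1:30, 4, replace = TRUE), 2)
    mine <- chi_square_2x2(tbl)
    # brute force: sum (O - E)^2 / E
    E <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
    expect_equal(mine$statistic, sum((tbl - E)^2 / E), tolerance = 1e-10)
    ref <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(rbind(c(0, 0), c(3, 5))), "marginal")
  expect_error(chi_square_2x2(rbind(c(-1, 2), c(3, 5))), "nonnegative")
})

test_that("the power iteration returns the published sample size", {
  s <- sample_size_two_t(5.19, 2.37, 3.02, alpha = 0.05, power = 0.95)
  expect_equal(s$n_per_group, 31L)
  # bracketing: the returned n is minimal
  expect_gte(power_two_t(31, s$d), 0.95)
  expect_lt(power_two_t(30, s$d), 0.95)
  # oracle: power at the returned n matches power.t.test
  ref <- stats::power.t.test(n = 31, delta = 5.19 - 2.37, sd = 3.02)
  expect_equal(power_two_t(31, s$d), ref$power, tolerance = 1e-6)
  # monotonicity in target power and in effect size
  expect_lt(sample_size_two_t(5.19, 2.37, 3.02, power = 0.80)$n_per_group,
            31)
  expect_lt(sample_size_two_t(5.19, 2.37, 3.02 / 2,
                              power = 0.95)$n_per_group, 31)
  expect_error(sample_size_two_t(3, 3, 1), "differ")
  g <- glance(s)
  expect_equal(g$n_per_group, 31L)
})

test_that("dropout inflation uses the multiplicative ceiling rule", {
  expect_equal(inflate_dropout(31, 0.20), list(n_per_group = 38L,
                                               total = 76L))
  expect_equal(inflate_dropout(31, 0), list(n_per_group = 31L, total = 62L))
  expect_equal(inflate_dropout(10, 0.15), list(n_per_group = 12L,
                                               total = 24L))
  expect_error(inflate_dropout(10, 1), "rate")
})

test_that("scale panel validation enforces instrument ranges", {
  ok <- tibble::tibble(subject = "a", group = "intervention",
                       timepoint = "pre", psqi_total = 12,
                       psqi_quality = 2, sds = 50)
  expect_silent(validate_scale_panel(ok))
  bad <- ok; bad$psqi_total <- 25
  expect_error(validate_scale_panel(bad), "psqi_total")
  bad2 <- ok; bad2$psqi_quality <- 4
  expect_error(validate_scale_panel(bad2), "psqi_quality")
})

test_that("the trial-style scale table has the expected structure", {
  co <- simulate_cohort(sim_config(seed = 241, n_per_group = 25))
  tab <- clinical_table(co$scales)
  expect_equal(nrow(tab), 2 * 10)  # 10 scales x 2 groups
  expect_setequal(unique(tab$group), c("intervention", "control"))
  psqi <- tab[tab$scale == "psqi_total", ]
  # both arms improve; intervention improves more (generator design)
  expect_lt(psqi$change_mean[psqi$group == "intervention"], 0)
  expect_lt(psqi$change_mean[psqi$group == "control"], 0)
  expect_lt(psqi$change_mean[psqi$group == "intervention"],
            psqi$change_mean[psqi$group == "control"])
  # discrete sub-dimensions usually route to the rank test
  subdim <- tab[grepl("psqi_", tab$scale) & tab$scale != "psqi_total", ]
  expect_gt(mean(subdim$within_method == "nonparametric"), 0.5)
  base <- baseline_table(co$scales)
  expect_equal(nrow(base), 10)
  expect_true(all(is.finite(base$p)))
})

test_that("percentages are reported at the printed precision", {
  expect_equal(rate_percent(15, 32), 46.9)
  expect_equal(rate_percent(14, 32), 43.8)
  expect_equal(rate_percent(4, 32), 12.5)
})
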