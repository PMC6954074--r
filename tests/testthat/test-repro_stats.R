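test_that("icc_oneway_single matches the ANOVA oracle and its properties", {
  expect_equal(icc_oneway_single(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5)),
               icc_oracle_aov(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5)),
               tolerance = 1e-12)
  # identical sessions with between-subject spread
  expect_equal(icc_oneway_single(1:10, 1:10), 1)
  # affine invariance under a common transform
  set.seed(11)
  p <- make_icc_pairs(30, 0.5)
  expect_equal(icc_oneway_single(3 * p$s1 - 7, 3 * p$s2 - 7),
               icc_oneway_single(p$s1, p$s2), tolerance = 1e-12)
  # degenerate input
  out <- icc_oneway_single(rep(2, 5), rep(2, 5))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "zero total variance")
  expect_error(icc_oneway_single(1:2, 2:1), "at least 3")
})

test_that("null ICC over independent sessions averages near zero", {
  set.seed(12)
  iccs <- vapply(1:1000, function(i)
    as.numeric(icc_oneway_single(rnorm(75), rnorm(75))), 0)
  # E[ICC(1,1)] under independence is -1/(n-1); band per the stated example
  expect_lt(abs(mean(iccs)), 0.02)
})

test_that("spearman of |difference| vs lowest PSD behaves at the extremes", {
  pe <- data.frame(s1 = (20:1) * 2, s2 = rep(0, 20), lowest_psd = 1:20)
  sr <- abs_diff_min_psd_spearman(pe)  # |delta| strictly decreasing in PSD
  expect_equal(sr$rho, -1)
  expect_equal(sr$n, 20L)
  tie <- data.frame(s1 = rep(3, 12), s2 = rep(1, 12), lowest_psd = 1:12)
  sr <- abs_diff_min_psd_spearman(tie)
  expect_true(is.na(sr$rho))
  expect_match(attr(sr$rho, "reason"), "identical")
  expect_error(abs_diff_min_psd_spearman(pe[1:5, ]), "complete pairs")
})

test_that("spearman null distribution matches the permutation oracle", {
  set.seed(13)
  ad <- abs(rnorm(75))
  psd <- rlnorm(75, 3, 0.8)
  rhos <- vapply(1:1000, function(i) {
    pe <- data.frame(s1 = ad[sample(75)], s2 = 0, lowest_psd = psd)
    abs_diff_min_psd_spearman(pe)$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.015)
  # 95% of null |rho| below the 1.96/sqrt(n-1) ~ 0.23 bound
  expect_equal(unname(quantile(abs(rhos), 0.95)), 0.228, tolerance = 0.2)
  # invariance under strictly monotone transforms of either variable
  pe <- data.frame(s1 = ad, s2 = 0, lowest_psd = psd)
  pe2 <- data.frame(s1 = ad^3, s2 = 0, lowest_psd = exp(psd / 10))
  expect_equal(abs_diff_min_psd_spearman(pe)$rho,
               abs_diff_min_psd_spearman(pe2)$rho, tolerance = 1e-12)
})

test_that("one-sample t test against zero covers degenerate cases", {
  r <- summary_ttest_vs_zero(rep(-0.2, 10))
  expect_equal(r$sd, 0)
  expect_equal(r$p_value, 0)  # below any printable precision
  r <- summary_ttest_vs_zero(c(-0.1, 0.1, -0.1, 0.1))
  expect_equal(r$mean, 0)
  expect_equal(r$p_value, 1)
  set.seed(14)
  hits <- vapply(1:200, function(i)
    summary_ttest_vs_zero(rnorm(24, -0.2, 0.05))$p_value < 0.05, TRUE)
  expect_gt(mean(hits), 0.99)  # power at the stated effect size
})

test_that("boxcox_fit finds normalising lambdas and preserves ICC at lambda 1", {
  set.seed(15)
  # lognormal data should want the log transform; n large enough that the
  # sampling spread of lambda-hat sits well inside the 0.1 band
  y <- rlnorm(3000, 1, 0.6)
  bc <- boxcox_fit(y)
  expect_lt(abs(bc$lambda), 0.1)
  # oracle: profile-likelihood grid from MASS on the same data
  gr <- MASS::boxcox(y ~ 1, lambda = seq(-1, 1, 0.01), plotit = FALSE)
  # agreement to the oracle grid resolution (0.01) plus optimizer tolerance
  expect_lt(abs(bc$lambda - gr$x[which.max(gr$y)]), 0.011)
  x <- rnorm(500, 10, 1)
  bc1 <- boxcox_fit(x)
  # oracle: lambda = 1 lies inside the 95% profile-likelihood interval
  prof <- function(l, z) {
    y <- if (abs(l) < 1e-8) log(z) else (z^l - 1) / l
    -length(z) / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(log(z))
  }
  expect_gt(prof(1, x), prof(bc1$lambda, x) - qchisq(0.95, 1) / 2)
  # lambda = 1 is an affine map, so ICC is unchanged
  p <- make_icc_pairs(40, 0.6, mu = 5)
  tr <- structure(list(lambda = 1, shift = 0), class = "dca_boxcox")
  expect_equal(icc_oneway_single(boxcox_apply(p$s1, tr), boxcox_apply(p$s2, tr)),
               icc_oneway_single(p$s1, p$s2), tolerance = 1e-12)
  # non-positive data are shifted automatically
  bc2 <- boxcox_fit(rnorm(100, 0, 1))
  expect_gt(bc2$shift, 0)
  expect_error(boxcox_fit(rep(1, 50)), "constant")
})

test_that("percentile_cutoffs uses interpolated percentiles", {
  g <- percentile_cutoffs(1:100)
  expect_equal(g$percentile, seq(0, 90, 10))
  expect_equal(g$cutoff[g$percentile == 0], 1)    # minimum removes nothing
  expect_equal(g$cutoff[g$percentile == 20], 20.8)
  expect_true(all(diff(g$cutoff) >= 0))
  g6 <- percentile_cutoffs(1:100, method = "spss")
  expect_equal(g6$cutoff[g6$percentile == 20], quantile(1:100, 0.2, type = 6,
                                                        names = FALSE))
})

test_that("icc_vs_cutoff_curve retains by threshold with a single transform", {
  set.seed(16)
  pe <- make_icc_pairs(75, 0.5, mu = 10)
  pe$lowest_psd <- rlnorm(75, 3, 0.8)
  grid <- percentile_cutoffs(pe$lowest_psd)
  cur <- icc_vs_cutoff_curve(pe, grid)
  expect_equal(cur$n_retained[1], 75L)            # level 0 retains everyone
  expect_true(all(diff(cur$n_retained) <= 0))
  expect_equal(cur$n_retained,
               vapply(grid$cutoff, function(co) sum(pe$lowest_psd >= co), 0L))
  # retained counts track the percentile definition within rounding
  expect_true(all(abs(cur$n_retained - round(75 * (1 - grid$percentile / 100))) <= 1))
  # below min_n the ICC is reported missing
  cur2 <- icc_vs_cutoff_curve(pe, grid, min_n = 70L)
  expect_true(all(is.na(cur2$icc[cur2$n_retained < 70])))
  # a constructed heteroscedastic cohort yields a non-decreasing trend
  g <- gen_estimate_table(table_gen_config(seed = 17, heteroscedasticity = -1))
  pe3 <- paired_estimates(g$est_tbl, g$psd_tbl, "sim.tfa1", "gain_vlf")
  cur3 <- icc_vs_cutoff_curve(pe3, percentile_cutoffs(pe3$lowest_psd))
  ok <- !is.na(cur3$icc)
  expect_gt(mean(cur3$icc[ok][-1]), cur3$icc[1])
})

test_that("icc_curve_table shares retained-case sets across methods", {
  g <- gen_estimate_table(table_gen_config(n_subjects = 40, seed = 18))
  curves <- icc_curve_table(g$est_tbl, g$psd_tbl)
  per_level <- split(curves, interaction(curves$filter_band, curves$percentile))
  for (d in per_level) {
    vlf_only <- d[d$variable %in% c("gain_vlf", "phase_vlf", "ari", "cor") |
                    d$filter_band == "vlf", ]
    expect_length(unique(d$n_retained), 1L)
  }
  # LF variables carry a secondary VLF-filtered curve
  expect_setequal(unique(curves$filter_band[curves$variable == "gain_lf"]),
                  c("lf", "vlf"))
  expect_equal(unique(curves$filter_band[curves$variable == "ari"]), "vlf")
})

test_that("rm_anova_linear_trend detects slopes and honours groups", {
  flat <- matrix(0.5, nrow = 6, ncol = 10)
  r <- rm_anova_linear_trend(flat)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  set.seed(19)
  sloped <- t(replicate(10, 0.3 + 0.02 * (0:9) + rnorm(10, 0, 0.01)))
  r <- rm_anova_linear_trend(sloped)
  expect_gt(r$F, 50)
  expect_lt(r$p, 0.01)
  # grouping reports main effect and interaction
  M <- rbind(sloped, t(replicate(10, 0.6 + rnorm(10, 0, 0.01))))
  grp <- rep(c("a", "b"), each = 10)
  r2 <- rm_anova_linear_trend(M, group = grp)
  expect_lt(r2$interaction_p, 0.01)   # only group "a" trends
  expect_true(is.finite(r2$group_F))
  # rows with missing cells are dropped, top level optionally excluded
  M[1, 3] <- NA
  expect_message(r3 <- rm_anova_linear_trend(M), "dropped 1")
  expect_equal(r3$n_methods, 19L)
  r4 <- rm_anova_linear_trend(sloped, exclude_top_level = TRUE)
  expect_equal(r4$levels_used, 9L)
})

test_that("mc_icc_difference_test is reproducible and detects differences", {
  set.seed(20)
  pa <- make_icc_pairs(75, 0.8)
  # identical inputs: zero observed difference, p ~ 1
  r <- mc_icc_difference_test(pa, pa, 2000, seed = 3)
  expect_equal(r$observed_diff, 0)
  expect_gte(r$p_value, 0.99)
  expect_identical(r$p_value,
                   mc_icc_difference_test(pa, pa, 2000, seed = 3)$p_value)
  # well-separated true ICCs are rejected with high power
  hits <- vapply(1:40, function(i) {
    a <- make_icc_pairs(75, 0.8)
    b <- make_icc_pairs(75, 0.3)
    mc_icc_difference_test(a, b, 1000, seed = i)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.9)
  expect_error(mc_icc_difference_test(pa, pa[1:10, ], 1000, 1), "subject set")
  expect_error(mc_icc_difference_test(pa, pa, 10, 1), "at least 1000")
})

test_that("synthetic cohorts recover their generating ICC", {
  set.seed(21)
  iccs <- vapply(1:500, function(i) {
    cfg <- table_gen_config(true_icc = c(gain_vlf = 0.6),
                            mu = c(gain_vlf = 1), sigma_b = c(gain_vlf = 0.3),
                            heteroscedasticity = 0,
                            n_methods = c(tfa = 1, ari = 0, cor = 0),
                            seed = i)
    g <- gen_estimate_table(cfg)
    pe <- paired_estimates(g$est_tbl, g$psd_tbl, "sim.tfa1", "gain_vlf")
    as.numeric(icc_oneway_single(pe$s1, pe$s2))
  }, 0)
  expect_equal(mean(iccs), 0.6, tolerance = 0.02)
})
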