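test_that("gen_mabp hits its band-power targets within 15%", {
  cfg <- signal_gen_config(seed = 31)
  for (sub in 1:3) {
    x <- gen_mabp(cfg, sub, 1)
    tgt <- attr(x, "psd_target")
    ps <- welch_psd(as.numeric(x), cfg$fs)
    expect_equal(band_power(ps, dca_bands()$vlf), tgt[["vlf"]], tolerance = 0.15)
    expect_equal(band_power(ps, dca_bands()$lf), tgt[["lf"]], tolerance = 0.15)
    expect_equal(mean(x), 90, tolerance = 0.01)
  }
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- signal_gen_config(n_subjects = 2, seed = 32)
  expect_identical(gen_mabp(cfg, 1, 1), gen_mabp(cfg, 1, 1))
  expect_identical(gen_recording(cfg, 1, 2)$cbfv_left,
                   gen_recording(cfg, 1, 2)$cbfv_left)
  expect_false(identical(as.numeric(gen_mabp(cfg, 1, 1)),
                         as.numeric(gen_mabp(cfg, 1, 2))))
  g1 <- gen_estimate_table(table_gen_config(n_subjects = 10, seed = 33))
  g2 <- gen_estimate_table(table_gen_config(n_subjects = 10, seed = 33))
  expect_identical(g1$est_tbl$value, g2$est_tbl$value)
  # and they do not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(gen_mabp(cfg, 1, 1)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("zero band-power targets give near-constant valid series", {
  cfg <- signal_gen_config(psd_median = c(vlf = 0, lf = 0), psd_sdlog = 0,
                           seed = 34)
  x <- gen_mabp(cfg, 1, 1)
  expect_equal(sd(x), 0)
  rec <- gen_recording(cfg, 1, 1)
  expect_true(validate_recording(rec)$passed)
})

test_that("generated recordings pass validation by construction", {
  cfg <- signal_gen_config(n_subjects = 4, seed = 35)
  cohort <- gen_cohort(cfg)
  expect_length(cohort$recordings, 8L)
  expect_true(all(vapply(cohort$recordings,
                         function(r) validate_recording(r)$passed, TRUE)))
  expect_equal(nrow(cohort$truth), 4L)
  expect_true(all(cohort$truth$ari %in% cfg$ari_levels))
})

test_that("gen_cbfv spans the passive limit to full recovery", {
  cfg <- signal_gen_config(seed = 36)
  m <- as.numeric(gen_mabp(cfg, 1, 1))
  # grade 0, no noise: affine in MABP, so TFA phase ~ 0 and Mx ~ 1
  v0 <- gen_cbfv(m, 0, 10, noise_sd = 0)
  expect_equal(cor(m, v0), 1, tolerance = 1e-10)
  expect_equal(unname(tfa_gain_phase(m, v0, 10)$phase), c(0, 0),
               tolerance = 1e-8)
  expect_equal(tiecks_ari(m, gen_cbfv(m, 9, 10, noise_sd = 0), 10,
                          interpolate = FALSE)$ari, 9)
  expect_equal(mean(gen_cbfv(m, 5, 10, noise_sd = 0)), 55, tolerance = 0.01)
  # noisy recovery stays near the generating grade
  hits <- vapply(1:50, function(i) {
    mi <- as.numeric(gen_mabp(cfg, i, 1))
    tiecks_ari(mi, gen_cbfv(mi, 5, 10, noise_sd = 0.1, seed = i), 10)$ari
  }, 0)
  expect_true(median(hits) >= 4 && median(hits) <= 6)
})

test_that("gen_estimate_table reports its implied ICC honestly", {
  g <- gen_estimate_table(table_gen_config(n_subjects = 20, seed = 37))
  expect_s3_class(g$est_tbl, "dca_estimate_table")
  expect_equal(sort(g$truth$variable), sort(names(table_gen_config()$true_icc)))
  # homoscedastic implied ICC equals the configured one exactly
  g0 <- gen_estimate_table(table_gen_config(heteroscedasticity = 0, seed = 38))
  expect_equal(g0$truth$implied_icc,
               unname(table_gen_config()$true_icc[g0$truth$variable]),
               tolerance = 1e-10)
  # sigma_w = 0 (true ICC 1) gives ICC 1 at every cut-off
  g1 <- gen_estimate_table(table_gen_config(
    true_icc = c(gain_vlf = 1), mu = c(gain_vlf = 1),
    sigma_b = c(gain_vlf = 0.3), n_methods = c(tfa = 1, ari = 0, cor = 0),
    seed = 39))
  pe <- paired_estimates(g1$est_tbl, g1$psd_tbl, "sim.tfa1", "gain_vlf")
  cur <- icc_vs_cutoff_curve(pe, percentile_cutoffs(pe$lowest_psd),
                             transform = FALSE)
  expect_true(all(cur$icc[!is.na(cur$icc)] == 1))
})
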