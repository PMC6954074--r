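# Run expr with a private RNG stream; the caller's RNG state is untouched.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic per-(subject, session) sub-seed below 2^31.
sub_seed <- function(seed, subject, session = 0L) {
  (as.numeric(seed) * 48271 + subject * 7919 + session * 104729) %% 2147483629
}

#' Configuration for synthetic paired recordings
#'
#' The generator emulates the measurement protocol: two supine resting
#' sessions of 10 Hz beat-to-beat data per subject, with spontaneous MABP
#' variability concentrated in the VLF and LF bands. Per-subject band-power
#' targets are drawn from lognormal populations whose medians sit at the
#' advisory thresholds (29 mmHg^2/Hz VLF, 10 mmHg^2/Hz LF), so default
#' cohorts straddle them; true autoregulation grades are drawn uniformly
#' from the healthy mid-range 3-7.
#'
#' @param n_subjects cohort size (default 75).
#' @param duration_s session length, seconds (default 600).
#' @param fs sampling rate, Hz (default 10).
#' @param mean_mabp,mean_cbfv channel means (90 mmHg, 55 cm/s).
#' @param psd_median named numeric: population median band PSD targets,
#'   mmHg^2/Hz.
#' @param psd_sdlog lognormal spread of targets across subjects.
#' @param session_jitter_sdlog session-to-session lognormal jitter of a
#'   subject's band-power target.
#' @param ari_levels integer pool the per-subject true grade is drawn from.
#' @param noise_sd CBFV measurement noise, as a fraction of the noise-free
#'   CBFV standard deviation (default 0.1).
#' @param seed master seed; all output is a pure function of (config, seed).
#' @return list of class `dca_signal_gen_config`.
#' @export
signal_gen_config <- function(n_subjects = 75L, duration_s = 600, fs = 10,
                              mean_mabp = 90, mean_cbfv = 55,
                              psd_median = c(vlf = 29, lf = 10),
                              psd_sdlog = 0.8, session_jitter_sdlog = 0.2,
                              ari_levels = 3:7, noise_sd = 0.1, seed = 1L) {
  stopifnot(n_subjects >= 1, duration_s > 0, fs > 0, all(psd_median >= 0),
            psd_sdlog >= 0, session_jitter_sdlog >= 0, noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
                 fs = fs, mean_mabp = mean_mabp, mean_cbfv = mean_cbfv,
                 psd_median = psd_median, psd_sdlog = psd_sdlog,
                 session_jitter_sdlog = session_jitter_sdlog,
                 ari_levels = ari_levels, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "dca_signal_gen_config")
}

# Per-subject ground truth (band targets, true grade), a pure function of
# (cfg$seed, subject).
subject_truth <- function(cfg, subject) {
  with_rng_seed(sub_seed(cfg$seed, subject), {
    tgt <- cfg$psd_median * stats::rlnorm(length(cfg$psd_median), 0, cfg$psd_sdlog)
    ari <- sample(cfg$ari_levels, 1L)
    list(psd_target = tgt, ari = ari)
  })
}

# The analysis grid (100-s Welch segments -> 0.01 Hz bins) puts the shared
# 0.07 Hz bin in both bands, where it is estimated at ~the mean of the two
# synthesis levels. Solve the 2x2 system so the realised band MEANS hit the
# targets; clamped at zero when the targets are too disparate to satisfy.
calibrate_band_levels <- function(bands, tgt, df = 0.01) {
  if (length(bands) != 2L || !isTRUE(all.equal(bands[[1]][2], bands[[2]][1])))
    return(tgt)
  nb <- vapply(bands, function(b) length(seq(b[1], b[2], by = df)), 0L)
  A <- matrix(c(nb[1] - 0.5, 0.5, 0.5, nb[2] - 0.5), 2, byrow = TRUE)
  L <- tryCatch(solve(A, nb * tgt), error = function(e) tgt)
  if (L[1] < 0) { L[1] <- 0; L[2] <- nb[2] * tgt[2] / (nb[2] - 0.5) }
  if (L[2] < 0) { L[2] <- 0; L[1] <- nb[1] * tgt[1] / (nb[1] - 0.5) }
  stats::setNames(pmax(L, 0), names(tgt))
}

# Band-limited Gaussian noise via frequency-domain synthesis with random
# phases: direct control of the one-sided PSD level inside each band.
# Generation bands are widened by ~one analysis-resolution bin so that
# Hann-window leakage does not bias the band-mean PSD low at the edges.
synth_band_noise <- function(n, fs, bands, levels, widen = 0.008) {
  freq <- (seq_len(n %/% 2L)) * fs / n
  S <- numeric(length(freq))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    lo <- if (i == 1L) max(fs / n, b[1] - widen) else b[1]
    hi <- if (i == length(bands)) b[2] + widen else b[2]
    S[freq >= lo & freq < hi] <- levels[i]
  }
  if (all(S == 0)) return(numeric(n))
  amp <- sqrt(S * fs * n / 2)          # |Z_k| giving one-sided PSD S at bin k
  phase <- stats::runif(length(freq), 0, 2 * pi)
  Z <- complex(modulus = amp, argument = phase)
  spec <- complex(real = numeric(n))
  spec[2:(n %/% 2L + 1L)] <- Z
  spec[n:(n - n %/% 2L + 2L)] <- Conj(Z[seq_len(n %/% 2L - 1L)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate one session's MABP series
#'
#' Sum of band-limited Gaussian noise components about a constant mean,
#' scaled so the realised Welch band PSD is within ~15% of the subject's
#' target in each band. Bitwise-reproducible for a fixed
#' (config, subject, session).
#'
#' @param cfg a [signal_gen_config()].
#' @param subject subject index (1-based integer).
#' @param session 1 or 2.
#' @return numeric MABP series, mmHg; attributes `psd_target` (the
#'   session's jittered band targets) and `ari` (the subject's true grade).
#' @export
gen_mabp <- function(cfg, subject, session) {
  truth <- subject_truth(cfg, subject)
  n <- round(cfg$duration_s * cfg$fs)
  bands <- dca_bands()
  with_rng_seed(sub_seed(cfg$seed, subject, session), {
    jit <- stats::rlnorm(length(truth$psd_target), 0, cfg$session_jitter_sdlog)
    tgt <- truth$psd_target * jit
    lev <- calibrate_band_levels(bands, tgt)
    x <- cfg$mean_mabp + synth_band_noise(n, cfg$fs, bands, lev)
    attr(x, "psd_target") <- tgt
    attr(x, "ari") <- truth$ari
    x
  })
}

#' Generate a CBFV series from MABP through the autoregulation model
#'
#' Forward run of the grade's second-order model, rescaled to the requested
#' mean, plus white Gaussian measurement noise.
#'
#' @param mabp MABP series (mmHg).
#' @param ari_level integer grade 0-9.
#' @param fs sampling rate, Hz.
#' @param noise_sd noise fraction of the noise-free CBFV SD.
#' @param seed integer seed for the noise stream.
#' @param params [tiecks_parameters()] table.
#' @param mean_cbfv output mean, cm/s.
#' @return numeric CBFV series, cm/s.
#' @export
gen_cbfv <- function(mabp, ari_level, fs, noise_sd = 0.1, seed = 1L,
                     params = tiecks_parameters(), mean_cbfv = 55) {
  row <- params[params$ari == ari_level, ]
  if (nrow(row) != 1L) stop("ari_level must be an integer grade 0-9")
  v <- if (stats::sd(mabp) == 0) rep(1, length(mabp))
       else tiecks_model(mabp, fs, row$T, row$D, row$K)
  cbfv <- mean_cbfv * v
  if (noise_sd > 0 && stats::sd(cbfv) > 0) {
    cbfv <- cbfv + with_rng_seed(seed,
      stats::rnorm(length(cbfv), 0, noise_sd * stats::sd(cbfv)))
  }
  cbfv
}

#' Generate a full synthetic recording
#'
#' Bilateral CBFV (independent noise per side), EtCO2 as a constant 5 kPa
#' plus small noise. Generated recordings satisfy the mandatory validation
#' rules by construction at default settings.
#'
#' @param cfg a [signal_gen_config()].
#' @param subject,session identity.
#' @return a `dca_recording` with attributes `ari` and `psd_target`.
#' @export
gen_recording <- function(cfg, subject, session) {
  mabp <- gen_mabp(cfg, subject, session)
  ari <- attr(mabp, "ari")
  base <- sub_seed(cfg$seed, subject, session)
  left <- gen_cbfv(as.numeric(mabp), ari, cfg$fs, cfg$noise_sd,
                   seed = (base + 1) %% 2147483629, mean_cbfv = cfg$mean_cbfv)
  right <- gen_cbfv(as.numeric(mabp), ari, cfg$fs, cfg$noise_sd,
                    seed = (base + 2) %% 2147483629, mean_cbfv = cfg$mean_cbfv)
  etco2 <- with_rng_seed((base + 3) %% 2147483629,
                         5 + stats::rnorm(length(mabp), 0, 0.05))
  rec <- recording(subject_id = sprintf("S%03d", subject), session = session,
                   fs = cfg$fs, mabp = as.numeric(mabp), cbfv_left = left,
                   cbfv_right = right, etco2 = etco2)
  attr(rec, "ari") <- ari
  attr(rec, "psd_target") <- attr(mabp, "psd_target")
  rec
}

#' Generate a whole paired cohort
#'
#' @param cfg a [signal_gen_config()].
#' @return list with `recordings` (list of `dca_recording`, two per
#'   subject) and `truth` (data.frame of per-subject grade and band
#'   targets).
#' @export
gen_cohort <- function(cfg) {
  recs <- list()
  truth <- list()
  for (s in seq_len(cfg$n_subjects)) {
    tr <- subject_truth(cfg, s)
    truth[[s]] <- data.frame(subject_id = sprintf("S%03d", s), ari = tr$ari,
                             psd_vlf_target = tr$psd_target[["vlf"]],
                             psd_lf_target = tr$psd_target[["lf"]])
    for (sess in 1:2)
      recs[[length(recs) + 1L]] <- gen_recording(cfg, s, sess)
  }
  list(recordings = recs, truth = do.call(rbind, truth))
}

#' Configuration for synthetic paired-estimate tables
#'
#' Emulates the structure behind a multi-center duplicate-estimate table:
#' per subject a true value ~ Normal(mu, sigma_b^2); session values are
#' truth plus Normal(0, sigma_w(PSD)^2) noise whose SD scales with the
#' subject's lowest-of-pair band power as
#' `sigma_w = sigma_w0 * (psd / median)^heteroscedasticity`. A negative
#' coefficient makes within-subject differences larger at low power — the
#' regime producing negative Spearman correlations and rising ICC curves.
#' The default true ICCs are the study's median reliabilities implied by
#' its duration analysis (gain LF 0.60, phase LF 0.43, gain VLF 0.34,
#' ARI 0.28, phase VLF 0.18; correlation index set to 0.30).
#'
#' @param n_subjects cohort size (default 75).
#' @param true_icc named vector of population ICCs per variable, in \[0, 1).
#' @param mu,sigma_b named vectors of between-subject mean and SD per
#'   variable (units of the variable).
#' @param heteroscedasticity exponent linking within-subject SD to lowest
#'   PSD (default -0.3; 0 = homoscedastic).
#' @param psd_median,psd_sdlog lognormal population of lowest-of-pair band
#'   power, as in [signal_gen_config()].
#' @param n_methods named integer vector: methods per category
#'   (tfa carries gain/phase, ari the index, cor the correlation index).
#' @param seed master seed.
#' @return list of class `dca_table_gen_config`.
#' @export
table_gen_config <- function(n_subjects = 75L,
                             true_icc = c(gain_vlf = 0.34, gain_lf = 0.60,
                                          phase_vlf = 0.18, phase_lf = 0.43,
                                          ari = 0.28, cor = 0.30),
                             mu = c(gain_vlf = 1.0, gain_lf = 1.2,
                                    phase_vlf = 0.9, phase_lf = 0.5,
                                    ari = 5, cor = 0.3),
                             sigma_b = c(gain_vlf = 0.30, gain_lf = 0.35,
                                         phase_vlf = 0.35, phase_lf = 0.25,
                                         ari = 1.5, cor = 0.15),
                             heteroscedasticity = -0.3,
                             psd_median = c(vlf = 29, lf = 10),
                             psd_sdlog = 0.8,
                             n_methods = c(tfa = 4L, ari = 3L, cor = 2L),
                             seed = 1L) {
  stopifnot(all(true_icc >= 0), all(true_icc <= 1), all(sigma_b > 0),
            all(psd_median > 0))
  structure(list(n_subjects = as.integer(n_subjects), true_icc = true_icc,
                 mu = mu, sigma_b = sigma_b,
                 heteroscedasticity = heteroscedasticity,
                 psd_median = psd_median, psd_sdlog = psd_sdlog,
                 n_methods = n_methods, seed = as.integer(seed)),
            class = "dca_table_gen_config")
}

#' Generate a paired-estimate table with known ground truth
#'
#' @param cfg a [table_gen_config()].
#' @return list with `est_tbl` (a `dca_estimate_table`), `psd_tbl`
#'   (lowest-of-pair band power, same layout as [lowest_pair_psd()]), and
#'   `truth` (per-variable implied population ICC
#'   `sigma_b^2 / (sigma_b^2 + mean(sigma_w^2))` given the realised PSD
#'   draw).
#' @export
gen_estimate_table <- function(cfg) {
  with_rng_seed(cfg$seed, {
    n <- cfg$n_subjects
    subjects <- sprintf("S%03d", seq_len(n))
    psd <- data.frame(
      subject_id = rep(subjects, each = 2L),
      band = rep(c("vlf", "lf"), times = n),
      lowest_pair_psd = c(rbind(
        cfg$psd_median[["vlf"]] * stats::rlnorm(n, 0, cfg$psd_sdlog),
        cfg$psd_median[["lf"]] * stats::rlnorm(n, 0, cfg$psd_sdlog))),
      stringsAsFactors = FALSE)

    method_ids <- c(sprintf("sim.tfa%d", seq_len(cfg$n_methods[["tfa"]])),
                    sprintf("sim.ari%d", seq_len(cfg$n_methods[["ari"]])),
                    sprintf("sim.cor%d", seq_len(cfg$n_methods[["cor"]])))
    method_cat <- c(rep(1L, cfg$n_methods[["tfa"]]),
                    rep(2L, cfg$n_methods[["ari"]]),
                    rep(3L, cfg$n_methods[["cor"]]))
    vars_for_cat <- list(`1` = c("gain_vlf", "gain_lf", "phase_vlf", "phase_lf"),
                         `2` = "ari", `3` = "cor")

    rows <- list()
    truth <- list()
    for (v in names(cfg$true_icc)) {
      sb <- cfg$sigma_b[[v]]
      icc <- cfg$true_icc[[v]]
      sw0 <- if (icc == 0) sb * 1e3 else sb * sqrt(1 / icc - 1)
      band <- filter_band_for(v)
      p <- psd$lowest_pair_psd[psd$band == band]
      sw <- sw0 * (p / stats::median(p))^cfg$heteroscedasticity
      # rescale so the mean within-subject variance keeps the target ICC
      if (sw0 > 0) sw <- sw * sw0 / sqrt(mean(sw^2))
      truth[[v]] <- data.frame(variable = v, implied_icc = sb^2 / (sb^2 + mean(sw^2)))
      for (mi in which(vapply(as.character(method_cat),
                              function(k) v %in% vars_for_cat[[k]], TRUE))) {
        tv <- stats::rnorm(n, cfg$mu[[v]], sb)
        rows[[length(rows) + 1L]] <- data.frame(
          method_id = rep(method_ids[mi], 2L * n),
          category = rep(method_cat[mi], 2L * n),
          subject_id = rep(subjects, 2L),
          session = rep(1:2, each = n),
          variable = v,
          value = c(tv + stats::rnorm(n, 0, sw), tv + stats::rnorm(n, 0, sw)),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(est_tbl = estimate_table(do.call(rbind, rows)),
         psd_tbl = psd,
         truth = truth)
  })
}
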