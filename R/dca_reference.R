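#' Parameter table of the second-order autoregulation model
#'
#' The classical grading of dynamic cerebral autoregulation maps each
#' integer index 0-9 to a (time constant T, damping D, gain K) triple of a
#' second-order model predicting CBFV from normalised MABP. Index 0 (K = 0)
#' is the fully pressure-passive limit; index 9 the best autoregulation.
#' These constants come from the model literature the index is defined by;
#' they are not tunable study parameters.
#'
#' @return data.frame with columns `ari`, `T` (s), `D` (dimensionless),
#'   `K` (dimensionless), 10 rows.
#' @export
tiecks_parameters <- function() {
  data.frame(
    ari = 0:9,
    T = c(2.00, 2.00, 2.00, 2.00, 2.00, 1.90, 1.60, 1.20, 0.87, 0.65),
    D = c(0.00, 1.60, 1.50, 1.15, 0.90, 0.75, 0.65, 0.55, 0.52, 0.50),
    K = c(0.00, 0.20, 0.40, 0.60, 0.80, 0.90, 0.94, 0.96, 0.97, 0.98))
}

#' Model-predicted normalised CBFV for one autoregulation grade
#'
#' Runs the second-order state recursion on MABP expressed as fractional
#' change about its mean (dimensionless form; no critical closing pressure
#' offset) and returns the predicted CBFV as a fraction of its baseline.
#'
#' @param mabp MABP series, mmHg.
#' @param fs sampling rate, Hz.
#' @param T,D,K model constants, e.g. one row of [tiecks_parameters()].
#' @return Numeric series of predicted CBFV relative to baseline (~1).
#' @export
tiecks_model <- function(mabp, fs, T, D, K) {
  m <- mean(mabp)
  if (m == 0 || stats::sd(mabp) == 0)
    stop("constant MABP: autoregulation model unidentifiable")
  dP <- (mabp - m) / m
  n <- length(dP)
  x1 <- x2 <- numeric(n)
  fT <- fs * T
  x1p <- x2p <- 0
  for (i in seq_len(n)) {
    x1[i] <- x1p + (dP[i] - x2p) / fT
    x2[i] <- x2p + (x1[i] - 2 * D * x2p) / fT
    x1p <- x1[i]; x2p <- x2[i]
  }
  1 + dP - K * x2
}

#' Autoregulation index by template fitting
#'
#' For each grade 0-9, the model-predicted CBFV response to the observed
#' MABP is compared with the observed CBFV (both as fractional change about
#' their means); the index is the grade minimising the root-mean-square
#' residual, optionally refined by parabolic interpolation between the best
#' grade and its neighbours (clipped to \[0, 9\]).
#'
#' @param mabp,cbfv equal-length series (mmHg, cm/s).
#' @param fs sampling rate, Hz.
#' @param params parameter table, see [tiecks_parameters()].
#' @param interpolate logical; parabolic refinement (default `TRUE`).
#' @return Object of class `dca_ari`: list with `ari` in \[0, 9\],
#'   `fit_error` (residual norm at the reported grade's nearest integer),
#'   `residuals` (per-grade residual norms).
#' @export
tiecks_ari <- function(mabp, cbfv, fs, params = tiecks_parameters(),
                       interpolate = TRUE) {
  if (length(mabp) != length(cbfv)) stop("mabp and cbfv must have equal length")
  vobs <- cbfv / mean(cbfv)
  res <- vapply(seq_len(nrow(params)), function(i) {
    pred <- tiecks_model(mabp, fs, params$T[i], params$D[i], params$K[i])
    sqrt(mean((vobs - pred)^2))
  }, 0)
  k <- which.min(res)
  ari <- params$ari[k]
  if (interpolate && k > 1L && k < nrow(params)) {
    y1 <- res[k - 1L]; y2 <- res[k]; y3 <- res[k + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) ari <- ari + 0.5 * (y1 - y3) / denom
  }
  ari <- min(9, max(0, ari))
  structure(list(ari = ari, fit_error = res[k], residuals = res),
            class = "dca_ari")
}

#' @export
print.dca_ari <- function(x, ...) {
  cat(sprintf("<ARI> %.2f (fit error %.4g)\n", x$ari, x$fit_error))
  invisible(x)
}

#' Transfer function analysis: band-averaged gain, phase, coherence
#'
#' Cross- and auto-spectra are estimated with the same Welch configuration
#' as the MABP power spectra; the frequency response is
#' `H(f) = Sxy(f) / Sxx(f)` with x = MABP and y = CBFV, so positive phase
#' means CBFV leads MABP. By default the complex `H` is averaged over the
#' band bins before taking modulus and angle (robust at low coherence); the
#' alternative averages gain and unwrapped phase separately.
#'
#' @param mabp,cbfv equal-length series.
#' @param fs sampling rate, Hz.
#' @param bands band list from [dca_bands()].
#' @param seg_len_s,overlap_frac,window,detrend Welch settings as in
#'   [welch_psd()].
#' @param band_average `"complex"` (default) or `"polar"`.
#' @param coherence_min optional threshold; band bins with magnitude-squared
#'   coherence below it are excluded from band averaging (default `NULL`,
#'   no exclusion).
#' @return Object of class `dca_tfa`: list with per-band `gain`
#'   (cm/s per mmHg), `phase` (radians, in (-pi, pi]), `coherence`, plus
#'   the per-bin `freq`, `H`, `coherence_spectrum`.
#' @export
tfa_gain_phase <- function(mabp, cbfv, fs, bands = dca_bands(),
                           seg_len_s = 100, overlap_frac = 0.5,
                           window = "hann", detrend = "mean",
                           band_average = c("complex", "polar"),
                           coherence_min = NULL) {
  band_average <- match.arg(band_average)
  if (length(mabp) != length(cbfv)) stop("mabp and cbfv must have equal length")
  if (stats::sd(mabp) == 0) stop("zero MABP variance: transfer function undefined")
  wx <- welch_segments(mabp, fs, seg_len_s, overlap_frac, window, detrend)
  wy <- welch_segments(cbfv, fs, seg_len_s, overlap_frac, window, detrend)
  Sxx <- rowMeans(Re(wx$X * Conj(wx$X)))
  Syy <- rowMeans(Re(wy$X * Conj(wy$X)))
  Sxy <- rowMeans(Conj(wx$X) * wy$X)
  H <- Sxy / Sxx
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  per_band <- lapply(bands, function(b) {
    idx <- band_bins(wx$freq, b)
    if (!length(idx)) stop("no frequency bin inside band [", b[1], ", ", b[2], "] Hz")
    if (!is.null(coherence_min)) {
      keep <- coh[idx] >= coherence_min
      if (any(keep)) idx <- idx[keep]
    }
    if (band_average == "complex") {
      Hb <- mean(H[idx])
      c(gain = Mod(Hb), phase = Arg(Hb), coherence = mean(coh[idx]))
    } else {
      ph <- unwrap_phase(Arg(H[idx]))
      c(gain = mean(Mod(H[idx])), phase = mean(ph), coherence = mean(coh[idx]))
    }
  })
  out <- list(gain = vapply(per_band, `[[`, 0, "gain"),
              phase = vapply(per_band, `[[`, 0, "phase"),
              coherence = vapply(per_band, `[[`, 0, "coherence"),
              freq = wx$freq, H = H, coherence_spectrum = coh,
              n_segments = wx$n_segments)
  class(out) <- "dca_tfa"
  out
}

unwrap_phase <- function(ph) {
  if (length(ph) < 2L) return(ph)
  d <- diff(ph)
  corr <- cumsum(ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0)))
  c(ph[1L], ph[-1L] + corr)
}

#' @export
print.dca_tfa <- function(x, ...) {
  for (b in names(x$gain))
    cat(sprintf("<TFA %s> gain %.3f cm/s/mmHg, phase %.1f deg, coherence %.2f\n",
                b, x$gain[b], x$phase[b] * 180 / pi, x$coherence[b]))
  invisible(x)
}

#' Mx-like correlation index
#'
#' Both series are averaged in non-overlapping blocks (default 10 s); the
#' Pearson correlation of the block means is computed per epoch (default
#' 300 s) and averaged over epochs. Values near +1 indicate
#' pressure-passive flow (poor autoregulation).
#'
#' @param mabp,cbfv equal-length series.
#' @param fs sampling rate, Hz.
#' @param block_s block length, seconds.
#' @param epoch_s epoch length, seconds; must not exceed the recording.
#' @return Object of class `dca_mx`: list with `cor` in \[-1, 1\],
#'   `n_blocks`, `epoch_cors`.
#' @export
mx_index <- function(mabp, cbfv, fs, block_s = 10, epoch_s = 300) {
  if (length(mabp) != length(cbfv)) stop("mabp and cbfv must have equal length")
  if (length(mabp) / fs < epoch_s) stop("recording shorter than one epoch")
  per_block <- round(block_s * fs)
  n_blocks <- floor(length(mabp) / per_block)
  bm <- function(x) vapply(seq_len(n_blocks), function(i)
    mean(x[((i - 1L) * per_block + 1L):(i * per_block)]), 0)
  bp <- bm(mabp); bv <- bm(cbfv)
  blocks_per_epoch <- max(2L, floor(epoch_s / block_s))
  n_epochs <- floor(n_blocks / blocks_per_epoch)
  cors <- numeric(0)
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1L) * blocks_per_epoch + 1L):(e * blocks_per_epoch)
    if (stats::sd(bp[idx]) == 0 || stats::sd(bv[idx]) == 0) {
      message("mx_index: epoch ", e, " skipped (zero variance)")
      next
    }
    cors <- c(cors, stats::cor(bp[idx], bv[idx]))
  }
  if (!length(cors)) stop("no epoch with non-zero variance")
  structure(list(cor = mean(cors), n_blocks = n_blocks, epoch_cors = cors),
            class = "dca_mx")
}

#' @export
print.dca_mx <- function(x, ...) {
  cat(sprintf("<Mx> %.3f over %d blocks (%d epochs)\n", x$cor, x$n_blocks,
              length(x$epoch_cors)))
  invisible(x)
}

#' Run the three reference estimators over a paired cohort
#'
#' One representative estimator per method category: `ref.tfa`
#' (transfer-function gain and phase per band, category 1), `ref.ari`
#' (autoregulation index, category 2), `ref.mx` (correlation index,
#' category 3). Hemispheres are averaged first.
#'
#' @param pairs named list from [pair_sessions()].
#' @param bands band list from [dca_bands()].
#' @param ... Welch settings forwarded to [tfa_gain_phase()].
#' @return A `dca_estimate_table` with duplicate estimates for all subjects.
#' @export
estimate_dca <- function(pairs, bands = dca_bands(), ...) {
  rows <- list()
  for (s in names(pairs)) {
    for (sess in 1:2) {
      rec <- average_hemispheres(pairs[[s]][[sess]])
      tfa <- tfa_gain_phase(rec$mabp, rec$cbfv, rec$fs, bands = bands, ...)
      ari <- tiecks_ari(rec$mabp, rec$cbfv, rec$fs)
      mx <- mx_index(rec$mabp, rec$cbfv, rec$fs)
      rows[[length(rows) + 1L]] <- data.frame(
        method_id = c(rep("ref.tfa", 4L), "ref.ari", "ref.mx"),
        category = c(rep(1L, 4L), 2L, 3L),
        subject_id = s, session = sess,
        variable = c("gain_vlf", "gain_lf", "phase_vlf", "phase_lf", "ari", "cor"),
        value = c(tfa$gain[["vlf"]], tfa$gain[["lf"]],
                  tfa$phase[["vlf"]], tfa$phase[["lf"]],
                  ari$ari, mx$cor),
        stringsAsFactors = FALSE)
    }
  }
  estimate_table(do.call(rbind, rows))
}
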