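#' Frequency bands for DCA analysis
#'
#' Very-low-frequency (VLF) and low-frequency (LF) bands used both for
#' MABP band power and for band-averaging transfer-function estimates.
#' Band edges are inclusive on both ends; the shared 0.07 Hz edge is
#' assigned to both bands consistently (closed-interval reading).
#'
#' @param vlf,lf numeric length-2 vectors `c(f_lo, f_hi)` in Hz.
#' @return Named list of band definitions.
#' @export
dca_bands <- function(vlf = c(0.02, 0.07), lf = c(0.07, 0.2)) {
  for (b in list(vlf, lf))
    if (!(length(b) == 2L && b[1] > 0 && b[1] < b[2]))
      stop("band must satisfy 0 < f_lo < f_hi")
  list(vlf = vlf, lf = lf)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# Segment a series, demean and window each segment, return the one-sided
# rFFT matrix (bins x segments) plus scaling constants shared by auto- and
# cross-spectra.
welch_segments <- function(x, fs, seg_len_s, overlap_frac, window, detrend) {
  n <- length(x)
  L <- round(seg_len_s * fs)
  if (L < 2L) stop("segment shorter than 2 samples")
  if (n < L) stop("signal shorter than one segment (", seg_len_s, " s)")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  step <- max(1L, round(L * (1 - overlap_frac)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- switch(window,
              hann = , hanning = hann_window(L),
              rectangular = , boxcar = rep(1, L),
              stop("unknown window: ", window))
  nf <- L %/% 2L + 1L
  X <- matrix(0 + 0i, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + L - 1L)]
    if (detrend == "mean") seg <- seg - mean(seg)
    else if (detrend == "linear") seg <- stats::residuals(stats::lm.fit(cbind(1, seq_len(L)), seg))
    X[, j] <- stats::fft(w * seg)[seq_len(nf)]
  }
  list(X = X, L = L, n_segments = length(starts),
       freq = (seq_len(nf) - 1L) * fs / L,
       scale = 1 / (fs * sum(w^2)))
}

one_sided <- function(S, L) {
  nf <- nrow(S)
  dbl <- 2L:(nf - if (L %% 2L == 0L) 1L else 0L)
  S[dbl, ] <- 2 * S[dbl, , drop = FALSE]
  S
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed, mean-detrended,
#' overlapping segments; one-sided density scaling, so the integral of the
#' PSD over frequency approximates the signal variance (Parseval). With the
#' study settings (100-s segments, 50% overlap) a 600-s recording at 10 Hz
#' yields 11 segments and a 0.01 Hz frequency resolution.
#'
#' @param x numeric series (e.g. MABP in mmHg).
#' @param fs sampling rate, Hz.
#' @param seg_len_s segment length, seconds (default 100).
#' @param overlap_frac fractional overlap in `[0, 1)` (default 0.5).
#' @param window `"hann"` (default) or `"rectangular"`.
#' @param detrend per-segment detrending: `"mean"` (default), `"linear"`,
#'   or `"none"`.
#' @return Object of class `dca_power_spectrum`: list with `freq` (Hz),
#'   `psd` (input-units^2/Hz), `seg_len_s`, `overlap_frac`, `window_name`,
#'   `n_segments`, `fs`.
#' @examples
#' x <- rnorm(6000)
#' ps <- welch_psd(x, fs = 10)
#' ps$n_segments                       # 11
#' sum(ps$psd) * diff(ps$freq[1:2])   # ~ var(x)
#' @export
welch_psd <- function(x, fs, seg_len_s = 100, overlap_frac = 0.5,
                      window = "hann", detrend = c("mean", "linear", "none")) {
  detrend <- match.arg(detrend)
  ws <- welch_segments(x, fs, seg_len_s, overlap_frac, window, detrend)
  P <- one_sided(Re(ws$X * Conj(ws$X)) * ws$scale, ws$L)
  structure(list(freq = ws$freq, psd = rowMeans(P), seg_len_s = seg_len_s,
                 overlap_frac = overlap_frac, window_name = window,
                 n_segments = ws$n_segments, fs = fs),
            class = "dca_power_spectrum")
}

#' @export
print.dca_power_spectrum <- function(x, ...) {
  cat(sprintf("<power spectrum> %d bins to %.3g Hz, %d segments of %g s (%s, %.0f%% overlap)\n",
              length(x$freq), max(x$freq), x$n_segments, x$seg_len_s,
              x$window_name, 100 * x$overlap_frac))
  invisible(x)
}

band_bins <- function(freq, band, tol = 1e-9) {
  which(freq >= band[1] - tol & freq <= band[2] + tol)
}

#' Band-averaged spectral power
#'
#' Arithmetic mean of PSD values at the grid frequencies falling inside the
#' band (closed interval). This is the "mean PSD-MABP" statistic used to
#' rank and filter subjects by blood-pressure variability.
#'
#' @param ps a `dca_power_spectrum`.
#' @param band length-2 numeric `c(f_lo, f_hi)` in Hz, e.g.
#'   `dca_bands()$vlf`.
#' @return Mean PSD over the band, input-units^2/Hz.
#' @export
band_power <- function(ps, band) {
  idx <- band_bins(ps$freq, band)
  if (!length(idx))
    stop("no frequency grid point inside band [", band[1], ", ", band[2],
         "] Hz: resolution too coarse")
  mean(ps$psd[idx])
}

#' Per-session MABP band-power table
#'
#' Computes the Welch PSD of each recording's MABP channel and its mean
#' band power in each band.
#'
#' @param recs list of `dca_recording`.
#' @param bands band list from [dca_bands()].
#' @param ... Welch settings forwarded to [welch_psd()].
#' @return data.frame with columns `subject_id`, `session`, `band`,
#'   `mean_psd` (mmHg^2/Hz).
#' @export
band_power_table <- function(recs, bands = dca_bands(), ...) {
  rows <- lapply(recs, function(r) {
    ps <- welch_psd(r$mabp, r$fs, ...)
    data.frame(subject_id = r$subject_id, session = r$session,
               band = names(bands),
               mean_psd = vapply(bands, function(b) band_power(ps, b), 0),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Lowest-of-pair band power
#'
#' For each subject and band, the minimum of the two sessions' mean PSD.
#' Filtering on this value guarantees that both sessions exceed any
#' threshold at or below it. Subjects missing a session are excluded with a
#' message.
#'
#' @param tbl data.frame from [band_power_table()].
#' @return data.frame with columns `subject_id`, `band`, `lowest_pair_psd`.
#' @export
lowest_pair_psd <- function(tbl) {
  split_key <- interaction(tbl$subject_id, tbl$band, drop = TRUE)
  rows <- lapply(split(tbl, split_key), function(d) {
    if (!all(c(1L, 2L) %in% d$session)) return(NULL)
    data.frame(subject_id = d$subject_id[1L], band = d$band[1L],
               lowest_pair_psd = min(d$mean_psd[d$session %in% c(1L, 2L)]),
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(rows, is.null, TRUE)
  if (any(dropped))
    message("lowest_pair_psd: excluded ", sum(dropped),
            " subject/band group(s) missing a session")
  out <- do.call(rbind, rows[!dropped])
  rownames(out) <- NULL
  out[order(out$subject_id, out$band), ]
}
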