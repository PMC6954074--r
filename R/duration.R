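#' Spearman-Brown prophecy formula
#'
#' Predicted reliability when the measurement length is multiplied by `n`:
#' `ICC_SB = n ICC / (1 + (n - 1) ICC)`. Strictly increasing in `n` for
#' ICC in (0, 1), with fixed points at ICC = 0 and ICC = 1.
#'
#' @param icc reliability of the base-length measurement, in (-1, 1).
#' @param n duration multiple (>= 0, real).
#' @return Predicted reliability.
#' @examples
#' spearman_brown(0.2, 6)  # 0.6
#' @export
spearman_brown <- function(icc, n) {
  stopifnot(all(is.finite(icc)), all(is.finite(n)), all(n >= 0))
  denom <- 1 + (n - 1) * icc
  if (any(abs(denom) < .Machine$double.eps * 8))
    stop("Spearman-Brown pole: 1 + (n - 1) * ICC = 0")
  n * icc / denom
}

#' Recording duration needed to reach a target reliability
#'
#' Inverts the Spearman-Brown formula: the continuous multiple is
#' `n* = target (1 - icc) / (icc (1 - target))`, rounded up to an integer
#' so durations are multiples of the base length (5-minute blocks in the
#' study design). An ICC already at or above the target needs the base
#' duration; a non-positive ICC cannot be prophesied to any finite
#' duration.
#'
#' @param icc base reliability, in (0, 1) for a finite answer.
#' @param target target reliability (default 0.6, the conventional "good"
#'   threshold).
#' @param base_minutes base recording length in minutes (default 5).
#' @return list with `n_exact` (continuous multiple), `n` (integer
#'   multiple), `required_minutes` (`NA` and `attainable = FALSE` when
#'   icc <= 0).
#' @examples
#' required_duration(0.2, 0.6)$required_minutes  # 30
#' @export
required_duration <- function(icc, target = 0.6, base_minutes = 5) {
  stopifnot(length(icc) == 1L, target > 0, target < 1)
  if (!is.finite(icc) || icc <= 0) {
    return(list(n_exact = Inf, n = NA_integer_, required_minutes = NA_real_,
                attainable = FALSE))
  }
  if (icc >= target) {
    return(list(n_exact = 1, n = 1L, required_minutes = base_minutes,
                attainable = TRUE))
  }
  n_exact <- target * (1 - icc) / (icc * (1 - target))
  n <- ceiling(n_exact - 1e-12)  # guard exact-integer solutions
  list(n_exact = n_exact, n = as.integer(n),
       required_minutes = base_minutes * n, attainable = TRUE)
}

#' Duration predictions for a set of variables
#'
#' For each variable, the median ICC across methods (at cut-off level 0,
#' i.e. no case removal) is extrapolated with the Spearman-Brown formula
#' and inverted for the duration reaching the target.
#'
#' @param curve_tbl data.frame from [icc_curve_table()].
#' @param target target ICC (default 0.6).
#' @param base_minutes base recording length, minutes.
#' @return data.frame with one row per (variable, filter_band): median
#'   base ICC, continuous and integer duration multiples, required minutes.
#' @export
duration_table <- function(curve_tbl, target = 0.6, base_minutes = 5) {
  base <- curve_tbl[curve_tbl$percentile == 0, ]
  out <- do.call(rbind, lapply(
    split(base, interaction(base$variable, base$filter_band, drop = TRUE)),
    function(d) {
      med <- stats::median(d$icc, na.rm = TRUE)
      rd <- required_duration(med, target, base_minutes)
      data.frame(variable = d$variable[1L], filter_band = d$filter_band[1L],
                 median_icc = med, n_exact = rd$n_exact,
                 required_minutes = rd$required_minutes,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Spearman-Brown extrapolation curve
#'
#' Predicted ICC as a function of recording duration, for plotting or
#' tabulating the prophecy alongside the target line.
#'
#' @param icc base reliability.
#' @param minutes vector of durations (default 5 to 60 by 5).
#' @param base_minutes base recording length, minutes.
#' @return data.frame with columns `minutes`, `n`, `icc_sb`.
#' @export
sb_curve <- function(icc, minutes = seq(5, 60, by = 5), base_minutes = 5) {
  n <- minutes / base_minutes
  data.frame(minutes = minutes, n = n,
             icc_sb = vapply(n, function(k) spearman_brown(icc, k), 0))
}
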