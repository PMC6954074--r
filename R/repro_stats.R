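#' One-way random-effects, single-measures intraclass correlation
#'
#' From the one-way ANOVA decomposition over subjects with k replicate
#' sessions, `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`. This is the
#' "one-way" / ICC(1,1) setting, appropriate when session order carries no
#' systematic effect of interest. Invariant under a common affine transform
#' of both sessions.
#'
#' @param s1,s2 numeric vectors of the two sessions' values, one element
#'   per subject; alternatively pass a numeric matrix (subjects x sessions)
#'   as `s1` and leave `s2` `NULL`.
#' @return ICC in \[-1, 1\], or `NA` (with a `reason` attribute) when the
#'   total variance is zero.
#' @examples
#' icc_oneway_single(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5))
#' @export
icc_oneway_single <- function(s1, s2 = NULL) {
  M <- if (is.null(s2)) as.matrix(s1) else cbind(s1, s2)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  n <- nrow(M); k <- ncol(M)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (k < 2L) stop("need at least 2 sessions")
  row_m <- rowMeans(M)
  grand <- mean(M)
  ssb <- k * sum((row_m - grand)^2)
  ssw <- sum((M - row_m)^2)
  if (ssb + ssw == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero total variance"
    return(out)
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Column-wise ICC(1,1) for k = 2, vectorised over replicates.
icc_pairs_cols <- function(S1, S2) {
  n <- nrow(S1)
  m <- (S1 + S2) / 2
  g <- colMeans(m)
  msb <- 2 * colSums((m - rep(g, each = n))^2) / (n - 1)
  msw <- colSums((S1 - S2)^2) / (2 * n)
  (msb - msw) / (msb + msw)
}

#' Spearman correlation of |session difference| with lowest band power
#'
#' The reproducibility mechanism under study: if within-subject differences
#' of a DCA estimate shrink when blood-pressure variability is high, the
#' absolute difference of the duplicate values correlates negatively with
#' the lowest-of-pair PSD-MABP. Mid-rank ties, two-sided asymptotic p.
#'
#' @param pe data.frame with columns `s1`, `s2`, `lowest_psd` (one row per
#'   subject), e.g. from [paired_estimates()].
#' @param min_n minimum number of complete pairs (default 10).
#' @return list with `rho`, `n`, `p_value`; `rho` is `NA` with a `reason`
#'   when all absolute differences are identical.
#' @export
abs_diff_min_psd_spearman <- function(pe, min_n = 10L) {
  pe <- pe[stats::complete.cases(pe[c("s1", "s2", "lowest_psd")]), ]
  if (nrow(pe) < min_n) stop("fewer than ", min_n, " complete pairs")
  ad <- abs(pe$s1 - pe$s2)
  if (length(unique(ad)) == 1L) {
    return(list(rho = structure(NA_real_, reason = "all |differences| identical"),
                n = nrow(pe), p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(ad, pe$lowest_psd, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), n = nrow(pe), p_value = ct$p.value)
}

#' One-sample t test of Spearman coefficients against zero
#'
#' Treats per-method Spearman coefficients as a summary measure and tests
#' their mean against zero (two-sided).
#'
#' @param rhos numeric vector of coefficients (one per method).
#' @return list with `mean`, `sd`, `n`, `p_value`. A degenerate sample
#'   (zero spread, non-zero mean) is reported with `p_value = 0`.
#' @export
summary_ttest_vs_zero <- function(rhos) {
  rhos <- rhos[is.finite(rhos)]
  n <- length(rhos)
  if (n < 2L) stop("need at least 2 coefficients")
  m <- mean(rhos); s <- stats::sd(rhos)
  p <- if (s == 0) {
    if (m == 0) 1 else 0  # degenerate: all equal; report p below any printable precision
  } else stats::t.test(rhos, mu = 0)$p.value
  list(mean = m, sd = s, n = n, p_value = p)
}

#' Box-Cox power transform: fit and apply
#'
#' Profile-likelihood estimate of the power parameter lambda for
#' `y = (x^lambda - 1)/lambda` (lambda = 0: `log x`). Variables that can be
#' non-positive (phase, correlation indices) are shifted by
#' `-min(x) + 1e-6 * range(x)` before fitting; the shift is stored and
#' reapplied by [boxcox_apply()]. One transform is fitted per
#' method/variable on the pooled sessions and reused at every cut-off
#' level, so both sessions always receive the same transformation.
#'
#' @param x numeric values (pooled sessions).
#' @param lambda_range search interval for lambda.
#' @return Object of class `dca_boxcox`: list with `lambda`, `shift`.
#' @export
boxcox_fit <- function(x, lambda_range = c(-5, 5)) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("need at least 10 values")
  if (stats::sd(x) == 0) stop("constant input: Box-Cox transform degenerate")
  shift <- if (min(x) <= 0) -min(x) + 1e-6 * diff(range(x)) else 0
  z <- x + shift
  n <- length(z)
  slog <- sum(log(z))
  prof <- function(l) {
    y <- if (abs(l) < 1e-8) log(z) else (z^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slog
  }
  lambda <- stats::optimize(prof, lambda_range, maximum = TRUE)$maximum
  structure(list(lambda = lambda, shift = shift), class = "dca_boxcox")
}

#' @rdname boxcox_fit
#' @param bc a fitted `dca_boxcox`.
#' @export
boxcox_apply <- function(x, bc) {
  z <- x + bc$shift
  if (any(z[is.finite(z)] <= 0))
    stop("shifted values must be positive under the fitted transform")
  if (abs(bc$lambda) < 1e-8) log(z) else (z^bc$lambda - 1) / bc$lambda
}

#' Percentile cut-off grid for case removal
#'
#' Cut-offs at the 0, 10, ..., 90th percentiles of the lowest-of-pair
#' band-power distribution; the 0th percentile equals the minimum and
#' removes nothing. The default percentile definition is linear
#' interpolation (R type 7); `method = "spss"` uses the weighted-average
#' definition (type 6) matching SPSS EXAMINE.
#'
#' @param values lowest-of-pair PSD values, mmHg^2/Hz.
#' @param percentiles percent points (default `seq(0, 90, 10)`).
#' @param method `"linear"` (default) or `"spss"`.
#' @return data.frame with columns `percentile`, `cutoff` (non-decreasing).
#' @export
percentile_cutoffs <- function(values, percentiles = seq(0, 90, by = 10),
                               method = c("linear", "spss")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 10L) stop("need at least 10 values")
  q <- stats::quantile(values, probs = percentiles / 100,
                       type = if (method == "linear") 7L else 6L, names = FALSE)
  data.frame(percentile = percentiles, cutoff = q)
}

#' Filter band used to remove cases for a DCA variable
#'
#' VLF variables are filtered on PSD-MABP-VLF and LF variables on
#' PSD-MABP-LF; band-free variables (ARI, correlation index) use VLF, the
#' band the advisory power threshold is expressed in. LF variables may
#' additionally be filtered on VLF power as a secondary analysis (the
#' headline gain-LF result in the source study).
#'
#' @param variable one of `gain_vlf`, `gain_lf`, `phase_vlf`, `phase_lf`,
#'   `ari`, `cor`.
#' @return `"vlf"` or `"lf"`.
#' @export
filter_band_for <- function(variable) {
  switch(variable,
         gain_vlf = , phase_vlf = , ari = , cor = "vlf",
         gain_lf = , phase_lf = "lf",
         stop("unknown variable: ", variable))
}

#' Assemble paired estimates for one method and variable
#'
#' Joins the duplicate session values of one method/variable with the
#' lowest-of-pair PSD of the requested filter band. Only complete pairs are
#' kept.
#'
#' @param est_tbl a `dca_estimate_table`.
#' @param psd_tbl lowest-of-pair table from [lowest_pair_psd()].
#' @param method_id,variable selection.
#' @param filter_band `"vlf"` or `"lf"`; default [filter_band_for()] of the
#'   variable.
#' @return data.frame with columns `subject_id`, `s1`, `s2`, `lowest_psd`
#'   and attribute `filter_band`.
#' @export
paired_estimates <- function(est_tbl, psd_tbl, method_id, variable,
                             filter_band = NULL) {
  if (is.null(filter_band)) filter_band <- filter_band_for(variable)
  d <- est_tbl[est_tbl$method_id == method_id & est_tbl$variable == variable, ]
  if (!nrow(d)) stop("no rows for ", method_id, " / ", variable)
  wide <- stats::reshape(d[c("subject_id", "session", "value")],
                         idvar = "subject_id", timevar = "session",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "s", names(wide))
  psd <- psd_tbl[psd_tbl$band == filter_band, c("subject_id", "lowest_pair_psd")]
  out <- merge(wide, psd, by = "subject_id")
  names(out)[names(out) == "lowest_pair_psd"] <- "lowest_psd"
  out <- out[stats::complete.cases(out[c("s1", "s2")]), ]
  attr(out, "filter_band") <- filter_band
  out
}

#' ICC across incremental case removal
#'
#' At each cut-off, subjects whose lowest-of-pair PSD is at or above the
#' cut-off are retained (ties retained), one Box-Cox transform — fitted
#' once on the pooled sessions before any removal — is applied to both
#' sessions, and the one-way single-measures ICC is computed. Levels
#' retaining fewer than `min_n` subjects report `NA`.
#'
#' @param pe data.frame from [paired_estimates()].
#' @param cutoffs data.frame from [percentile_cutoffs()] (computed on the
#'   whole cohort so all methods share retained-case sets).
#' @param transform apply Box-Cox (default `TRUE`); set `FALSE` for raw.
#' @param min_n minimum retained subjects per level (default 10).
#' @param refit_per_level refit the transform within each retained subset
#'   (non-default variant).
#' @return data.frame with columns `percentile`, `cutoff`, `n_retained`,
#'   `icc`; `n_retained` is non-increasing across levels.
#' @export
icc_vs_cutoff_curve <- function(pe, cutoffs, transform = TRUE, min_n = 10L,
                                refit_per_level = FALSE) {
  bc <- if (transform) boxcox_fit(c(pe$s1, pe$s2)) else NULL
  rows <- lapply(seq_len(nrow(cutoffs)), function(i) {
    keep <- pe$lowest_psd >= cutoffs$cutoff[i]
    n <- sum(keep)
    icc <- if (n < min_n) NA_real_ else {
      s1 <- pe$s1[keep]; s2 <- pe$s2[keep]
      if (transform) {
        b <- if (refit_per_level) boxcox_fit(c(s1, s2)) else bc
        s1 <- boxcox_apply(s1, b); s2 <- boxcox_apply(s2, b)
      }
      as.numeric(icc_oneway_single(s1, s2))
    }
    data.frame(percentile = cutoffs$percentile[i], cutoff = cutoffs$cutoff[i],
               n_retained = n, icc = icc)
  })
  do.call(rbind, rows)
}

#' ICC curves for every method and variable in an estimate table
#'
#' Builds, per band, one percentile cut-off grid from the cohort's
#' lowest-of-pair PSD distribution (so retained-case sets are identical
#' across methods at each level), then computes the ICC curve for each
#' (method, variable) under its primary filter band, plus the secondary
#' VLF-filtered curves for LF variables.
#'
#' @param est_tbl a `dca_estimate_table`.
#' @param psd_tbl lowest-of-pair table from [lowest_pair_psd()].
#' @param percentiles percent points for [percentile_cutoffs()].
#' @param secondary_vlf_for_lf also compute LF variables filtered on VLF
#'   power (default `TRUE`).
#' @param ... forwarded to [icc_vs_cutoff_curve()].
#' @return data.frame with columns `method_id`, `variable`, `filter_band`,
#'   `percentile`, `cutoff`, `n_retained`, `icc`.
#' @export
icc_curve_table <- function(est_tbl, psd_tbl, percentiles = seq(0, 90, 10),
                            secondary_vlf_for_lf = TRUE, ...) {
  grids <- lapply(split(psd_tbl, psd_tbl$band), function(d)
    percentile_cutoffs(d$lowest_pair_psd, percentiles))
  combos <- unique(est_tbl[c("method_id", "variable")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    m <- combos$method_id[i]; v <- combos$variable[i]
    bands <- filter_band_for(v)
    if (secondary_vlf_for_lf && bands == "lf") bands <- c(bands, "vlf")
    for (b in bands) {
      pe <- paired_estimates(est_tbl, psd_tbl, m, v, filter_band = b)
      cur <- icc_vs_cutoff_curve(pe, grids[[b]], ...)
      cur <- cbind(method_id = m, variable = v, filter_band = b, cur)
      out[[length(out) + 1L]] <- cur
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeated-measures linear trend test on ICC curves
#'
#' Analysis methods are the repeated-measures "subjects"; the 10 cut-off
#' levels the within-subject factor. The test statistic is the F for the
#' within-subject linear contrast (orthogonal-polynomial weights), i.e.
#' whether the mean linear trend of ICC across levels differs from zero.
#' Because a single contrast is tested, no sphericity correction is needed
#' for this F. When a grouping factor (DCA variable type) is supplied, the
#' between-group main effect (on method mean ICC) and the group x trend
#' interaction (one-way ANOVA on the contrast scores) are also reported.
#'
#' @param icc_matrix numeric matrix, methods x levels; rows with missing
#'   cells are dropped with a message.
#' @param group optional factor of length `nrow(icc_matrix)`.
#' @param exclude_top_level drop the highest cut-off level before testing
#'   (used in the source study for ARI, where the top level behaved
#'   erratically).
#' @return Object of class `dca_trend_test`: list with `F`, `p`, `df`,
#'   `n_methods`, `levels_used`, and (when grouped) `group_F`, `group_p`,
#'   `interaction_F`, `interaction_p`.
#' @export
rm_anova_linear_trend <- function(icc_matrix, group = NULL,
                                  exclude_top_level = FALSE) {
  M <- as.matrix(icc_matrix)
  if (exclude_top_level) M <- M[, -ncol(M), drop = FALSE]
  ok <- stats::complete.cases(M)
  if (!all(ok)) {
    message("rm_anova_linear_trend: dropped ", sum(!ok),
            " method(s) with missing cells")
    M <- M[ok, , drop = FALSE]
    if (!is.null(group)) group <- group[ok]
  }
  n <- nrow(M); L <- ncol(M)
  if (n < 3L) stop("need at least 3 methods with complete curves")
  cpoly <- stats::contr.poly(L)[, 1L]
  scores <- as.numeric(M %*% cpoly)
  # constant curves leave only floating-point residue in the contrast scores
  tol <- 1e-10 * max(1, max(abs(M)))
  if (all(abs(scores) < tol)) scores <- numeric(n)
  if (stats::sd(scores) == 0) {
    Fv <- if (mean(scores) == 0) 0 else Inf
    p <- if (mean(scores) == 0) 1 else 0
  } else {
    tv <- mean(scores) / (stats::sd(scores) / sqrt(n))
    Fv <- tv^2
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
  }
  out <- list(F = Fv, p = p, df = c(1, n - 1), n_methods = n, levels_used = L)
  if (!is.null(group) && length(unique(group)) > 1L) {
    group <- factor(group)
    gfit <- stats::anova(stats::lm(rowMeans(M) ~ group))
    ifit <- stats::anova(stats::lm(scores ~ group))
    out$group_F <- gfit$`F value`[1L]; out$group_p <- gfit$`Pr(>F)`[1L]
    out$interaction_F <- ifit$`F value`[1L]; out$interaction_p <- ifit$`Pr(>F)`[1L]
  }
  class(out) <- "dca_trend_test"
  out
}

#' @export
print.dca_trend_test <- function(x, ...) {
  cat(sprintf("<linear trend> F(%d,%d) = %.2f, p = %.3g (%d methods, %d levels)\n",
              x$df[1], x$df[2], x$F, x$p, x$n_methods, x$levels_used))
  if (!is.null(x$group_F))
    cat(sprintf("  group F = %.2f (p = %.3g); group x trend F = %.2f (p = %.3g)\n",
                x$group_F, x$group_p, x$interaction_F, x$interaction_p))
  invisible(x)
}

#' Monte Carlo test for a difference between two methods' ICCs
#'
#' Null model: both methods share the pooled ICC (mean of the two
#' single-measures estimates). Each replicate draws, twice, n
#' bivariate-normal session pairs whose intraclass correlation equals the
#' pooled estimate, and records the absolute difference of the two
#' replicate ICCs; the p value is the proportion of null differences at
#' least as large as the observed one. Seed-reproducible; the caller's RNG
#' state is left untouched.
#'
#' @param pairs_a,pairs_b data.frames with columns `s1`, `s2` over the same
#'   subject set (column `subject_id` checked when present).
#' @param n_reps number of null replicates (>= 1000).
#' @param seed integer seed.
#' @return Object of class `dca_mc_test`: list with `icc_a`, `icc_b`,
#'   `observed_diff`, `p_value`, `n_reps`, `seed`, `pooled_icc`, `n`.
#' @export
mc_icc_difference_test <- function(pairs_a, pairs_b, n_reps = 2000L, seed = 1L) {
  if (n_reps < 1000L) stop("n_reps must be at least 1000")
  if (nrow(pairs_a) != nrow(pairs_b))
    stop("methods must share the same subject set")
  if (!is.null(pairs_a$subject_id) && !is.null(pairs_b$subject_id) &&
      !setequal(pairs_a$subject_id, pairs_b$subject_id))
    stop("methods must share the same subject set")
  icc_a <- as.numeric(icc_oneway_single(pairs_a$s1, pairs_a$s2))
  icc_b <- as.numeric(icc_oneway_single(pairs_b$s1, pairs_b$s2))
  rho <- (icc_a + icc_b) / 2
  if (!is.finite(rho) || rho <= -1 || rho >= 1)
    stop("pooled ICC outside (-1, 1)")
  n <- nrow(pairs_a)
  obs <- abs(icc_a - icc_b)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  null_icc <- function() {
    Z1 <- matrix(stats::rnorm(n * n_reps), n)
    Z2 <- matrix(stats::rnorm(n * n_reps), n)
    icc_pairs_cols(Z1, rho * Z1 + sqrt(1 - rho^2) * Z2)
  }
  null_diff <- abs(null_icc() - null_icc())
  structure(list(icc_a = icc_a, icc_b = icc_b, observed_diff = obs,
                 p_value = mean(null_diff >= obs), n_reps = n_reps,
                 seed = seed, pooled_icc = rho, n = n),
            class = "dca_mc_test")
}

#' @export
print.dca_mc_test <- function(x, ...) {
  cat(sprintf("<MC ICC test> |%.3f - %.3f| = %.3f, p = %.4f (%d reps, n = %d)\n",
              x$icc_a, x$icc_b, x$observed_diff, x$p_value, x$n_reps, x$n))
  invisible(x)
}

#' Spearman summary table across methods
#'
#' One row per (method, variable): the Spearman correlation of the absolute
#' session difference with the lowest-of-pair PSD of the variable's filter
#' band; plus, per variable, the across-method mean, SD and one-sample
#' t-test p value against zero.
#'
#' @param est_tbl a `dca_estimate_table`.
#' @param psd_tbl lowest-of-pair table from [lowest_pair_psd()].
#' @return list with `rows` (per method/variable) and `summary` (per
#'   variable).
#' @export
spearman_summary_table <- function(est_tbl, psd_tbl) {
  combos <- unique(est_tbl[c("method_id", "variable")])
  rows <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    pe <- paired_estimates(est_tbl, psd_tbl, combos$method_id[i],
                           combos$variable[i])
    sr <- abs_diff_min_psd_spearman(pe)
    data.frame(method_id = combos$method_id[i], variable = combos$variable[i],
               rho = as.numeric(sr$rho), n = sr$n, p_value = sr$p_value,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(rows, rows$variable), function(d) {
    if (sum(is.finite(d$rho)) < 2L)
      return(data.frame(variable = d$variable[1L], mean_rho = mean(d$rho),
                        sd_rho = NA_real_, n_methods = nrow(d),
                        p_value = NA_real_))
    tt <- summary_ttest_vs_zero(d$rho)
    data.frame(variable = d$variable[1L], mean_rho = tt$mean, sd_rho = tt$sd,
               n_methods = tt$n, p_value = tt$p_value)
  }))
  rownames(summ) <- NULL
  list(rows = rows, summary = summ)
}
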