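# Shared fixtures, built in code at test time.

# A short constant-plus-oscillation recording that passes validation.
make_clean_recording <- function(subject = "S001", session = 1L,
                                 duration_s = 600, fs = 10) {
  n <- duration_s * fs
  t <- (0:(n - 1)) / fs
  recording(subject_id = subject, session = session, fs = fs,
            mabp = 90 + 3 * sin(2 * pi * 0.05 * t),
            cbfv_left = 55 + 2 * sin(2 * pi * 0.05 * t),
            cbfv_right = 55 + 2 * sin(2 * pi * 0.05 * t + 0.1),
            etco2 = rep(5, n))
}

# Delimited text file for read_recording tests; returns the path.
write_recording_txt <- function(mat, sep = "\t", header = NULL,
                                path = tempfile(fileext = ".txt")) {
  lines <- apply(mat, 1L, paste, collapse = sep)
  if (!is.null(header)) lines <- c(paste(header, collapse = sep), lines)
  writeLines(lines, path)
  path
}

# Paired bivariate-normal session data with intraclass correlation rho.
make_icc_pairs <- function(n, rho, mu = 0, sd = 1) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             s1 = mu + sd * z1,
             s2 = mu + sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# Brute-force one-way ICC oracle via the stats ANOVA machinery
# (independent of the package's own mean-squares arithmetic).
icc_oracle_aov <- function(s1, s2) {
  d <- data.frame(subject = factor(rep(seq_along(s1), 2L)), value = c(s1, s2))
  tab <- stats::anova(stats::lm(value ~ subject, data = d))
  msb <- tab$`Mean Sq`[1L]
  msw <- tab$`Mean Sq`[2L]
  (msb - msw) / (msb + msw)
}
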