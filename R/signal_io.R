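#' Column map for delimited recording files
#'
#' Declares which column of a delimited text file holds which physiological
#' channel. Columns are 1-based. The deposited-file layout is not
#' standardised, so the map is explicit configuration with a documented
#' default: column 1 time, 2 MABP, 3 CBFV left, 4 CBFV right, 5 EtCO2.
#' Units are declared, never inferred; EtCO2 is accepted in kPa only because
#' the validation bounds are expressed in kPa.
#'
#' @param time,mabp,cbfv_left,cbfv_right,etco2 1-based column indices, or
#'   `NA` for channels absent from the file. `mabp`, `etco2` and at least one
#'   CBFV channel are required.
#' @return An object of class `dca_column_map`.
#' @export
column_map <- function(time = 1L, mabp = 2L, cbfv_left = 3L,
                       cbfv_right = 4L, etco2 = 5L) {
  cm <- list(time = time, mabp = mabp, cbfv_left = cbfv_left,
             cbfv_right = cbfv_right, etco2 = etco2)
  cm <- lapply(cm, function(i) if (is.null(i) || is.na(i)) NA_integer_ else as.integer(i))
  if (is.na(cm$mabp)) stop("column_map: MABP column is required")
  if (is.na(cm$etco2)) stop("column_map: EtCO2 column is required")
  if (is.na(cm$cbfv_left) && is.na(cm$cbfv_right))
    stop("column_map: at least one CBFV column is required")
  idx <- unlist(cm[!is.na(unlist(cm))])
  if (anyDuplicated(idx))
    stop("column_map: each column may be mapped to at most one channel")
  structure(cm, class = "dca_column_map")
}

#' Construct a physiological recording
#'
#' A recording holds one session's multichannel beat-to-beat series for one
#' subject, resampled to a common rate (10 Hz in the study design). MABP is
#' in mmHg, CBFV in cm/s, EtCO2 in kPa.
#'
#' @param subject_id character scalar.
#' @param session integer, 1 or 2.
#' @param fs sampling rate in Hz (> 0).
#' @param mabp numeric vector, mmHg.
#' @param cbfv_left,cbfv_right numeric vectors (cm/s) or `NULL` when the
#'   hemisphere was not measured; at least one must be present.
#' @param etco2 numeric vector, kPa.
#' @param cbfv single averaged CBFV channel (cm/s); usually created by
#'   [average_hemispheres()], rarely supplied directly.
#' @return An object of class `dca_recording`.
#' @seealso [read_recording()], [average_hemispheres()]
#' @export
recording <- function(subject_id, session, fs, mabp, cbfv_left = NULL,
                      cbfv_right = NULL, etco2, cbfv = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  session <- as.integer(session)
  if (!session %in% c(1L, 2L)) stop("session must be 1 or 2")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (is.null(cbfv_left) && is.null(cbfv_right) && is.null(cbfv))
    stop("at least one CBFV channel must be present")
  n <- length(mabp)
  for (ch in list(cbfv_left, cbfv_right, etco2, cbfv)) {
    if (!is.null(ch) && length(ch) != n)
      stop("all present channels must have equal length")
  }
  structure(list(subject_id = subject_id, session = session, fs = fs,
                 t = seq_len(n) / fs - 1 / fs,
                 mabp = as.numeric(mabp),
                 cbfv_left = if (is.null(cbfv_left)) NULL else as.numeric(cbfv_left),
                 cbfv_right = if (is.null(cbfv_right)) NULL else as.numeric(cbfv_right),
                 cbfv = if (is.null(cbfv)) NULL else as.numeric(cbfv),
                 etco2 = as.numeric(etco2)),
            class = "dca_recording")
}

#' @export
print.dca_recording <- function(x, ...) {
  dur <- length(x$mabp) / x$fs
  sides <- c(if (!is.null(x$cbfv_left)) "L", if (!is.null(x$cbfv_right)) "R",
             if (!is.null(x$cbfv)) "avg")
  cat(sprintf("<dca_recording> subject %s session %d: %.0f s @ %g Hz, CBFV [%s]\n",
              x$subject_id, x$session, dur, x$fs, paste(sides, collapse = ",")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `dca_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$mabp) / rec$fs

detect_delimiter <- function(lines) {
  # choose among tab / comma / whitespace by which splits most consistently
  probe <- lines[nzchar(trimws(lines))][seq_len(min(5L, sum(nzchar(trimws(lines)))))]
  for (sep in c("\t", ",")) {
    k <- lengths(strsplit(probe, sep, fixed = TRUE))
    if (all(k == k[1L]) && k[1L] > 1L) return(sep)
  }
  ""  # read.table default: any whitespace
}

#' Read a recording from delimited text
#'
#' Reads a plain-text numeric table (tab-, comma- or whitespace-delimited;
#' the delimiter is auto-detected) and assembles a [recording()] using an
#' explicit [column_map()]. Non-finite samples are flagged via the
#' `n_nonfinite` attribute rather than silently dropped; non-numeric rows
#' raise an error naming the first offending line.
#'
#' @param path file path.
#' @param colmap a [column_map()].
#' @param subject_id,session identity of the recording; defaults derived
#'   from the file name (`<subject>_<session>` stem) when possible.
#' @param fs sampling rate in Hz; the files carry no rate, so this is
#'   configuration (default 10 Hz per the study design).
#' @param header logical; `NA` (default) auto-detects a non-numeric first row.
#' @return A `dca_recording`.
#' @export
read_recording <- function(path, colmap = column_map(), subject_id = NULL,
                           session = NULL, fs = 10, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty recording file: ", path)
  sep <- detect_delimiter(lines)
  first <- strsplit(trimws(lines[1L]), if (sep == "") "[ \t]+" else sep)[[1L]]
  has_header <- if (is.na(header)) any(is.na(suppressWarnings(as.numeric(first)))) else header
  body <- if (has_header) lines[-1L] else lines
  split_re <- if (sep == "") "[ \t]+" else sep
  cells <- strsplit(trimws(body), split_re, fixed = FALSE)
  ncol_needed <- max(unlist(colmap), na.rm = TRUE)
  width <- lengths(cells)
  if (any(width < ncol_needed)) {
    bad <- which(width < ncol_needed)[1L]
    stop(sprintf("row %d of %s has %d columns; column map needs %d",
                 bad + has_header, path, width[bad], ncol_needed))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(lapply(cells, `[`, seq_len(ncol_needed))))),
                nrow = length(cells), byrow = TRUE)
  # distinguish parse failure (non-numeric token) from an in-band NaN/NA marker
  for (i in which(rowSums(is.na(mat)) > 0L)) {
    toks <- cells[[i]][seq_len(ncol_needed)]
    bad <- is.na(suppressWarnings(as.numeric(toks))) & !toks %in% c("nan", "NaN", "NA")
    if (any(bad))
      stop(sprintf("non-numeric value on line %d of %s", i + has_header, path))
  }
  grab <- function(role) if (is.na(colmap[[role]])) NULL else mat[, colmap[[role]]]
  if (is.null(subject_id) || is.null(session)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1L]]
    if (is.null(subject_id))
      subject_id <- if (length(parts) >= 2L) paste(parts[-length(parts)], collapse = "_") else stem
    if (is.null(session)) {
      sess_guess <- suppressWarnings(as.integer(parts[length(parts)]))
      session <- if (length(parts) >= 2L && !is.na(sess_guess)) sess_guess else 1L
    }
  }
  rec <- recording(subject_id = subject_id, session = session, fs = fs,
                   mabp = grab("mabp"), cbfv_left = grab("cbfv_left"),
                   cbfv_right = grab("cbfv_right"), etco2 = grab("etco2"))
  attr(rec, "n_nonfinite") <- sum(!is.finite(mat))
  rec
}

#' Write a recording as canonical CSV
#'
#' UTF-8, '.' decimal separator, one column per present channel. The
#' round-trip `read_recording(write_recording(rec))` reproduces all samples
#' at the stated precision (15 significant digits).
#'
#' @param rec a `dca_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time = rec$t, mabp = rec$mabp)
  for (ch in c("cbfv_left", "cbfv_right", "cbfv"))
    if (!is.null(rec[[ch]])) df[[ch]] <- rec[[ch]]
  df$etco2 <- rec$etco2
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average the two CBFV hemispheres
#'
#' Bilateral recordings get a single CBFV channel equal to the sample-wise
#' mean of the left and right channels; unilateral recordings use the
#' present side singly. Idempotent, and invariant to which side is missing.
#'
#' @param rec a `dca_recording` with at least one CBFV channel.
#' @return The recording with a single `cbfv` channel set.
#' @export
average_hemispheres <- function(rec) {
  if (!is.null(rec$cbfv) && is.null(rec$cbfv_left) && is.null(rec$cbfv_right))
    return(rec)
  sides <- Filter(Negate(is.null), list(rec$cbfv_left, rec$cbfv_right))
  if (!length(sides)) stop("no CBFV channel present")
  rec$cbfv <- if (length(sides) == 2L) (sides[[1L]] + sides[[2L]]) / 2 else sides[[1L]]
  rec$cbfv_left <- NULL
  rec$cbfv_right <- NULL
  rec
}

#' Pair the two sessions of each subject
#'
#' @param recs list of `dca_recording` objects.
#' @return Named list (by subject) of `list(s1 = , s2 = )` pairs; subjects
#'   lacking either session are excluded and listed in the `excluded`
#'   attribute. Duplicate (subject, session) combinations are an error.
#' @export
pair_sessions <- function(recs) {
  if (!length(recs)) {
    out <- list()
    attr(out, "excluded") <- character(0)
    return(out)
  }
  key <- vapply(recs, function(r) paste0(r$subject_id, "#", r$session), "")
  if (anyDuplicated(key))
    stop("duplicate (subject, session): ", key[duplicated(key)][1L])
  subs <- unique(vapply(recs, `[[`, "", "subject_id"))
  pairs <- list()
  excluded <- character(0)
  for (s in subs) {
    mine <- recs[vapply(recs, function(r) r$subject_id == s, TRUE)]
    sess <- vapply(mine, `[[`, 1L, "session")
    if (all(c(1L, 2L) %in% sess)) {
      pairs[[s]] <- list(s1 = mine[[which(sess == 1L)]], s2 = mine[[which(sess == 2L)]])
    } else {
      excluded <- c(excluded, s)
    }
  }
  if (length(excluded))
    message("pair_sessions: excluded subjects missing a session: ",
            paste(excluded, collapse = ", "))
  attr(pairs, "excluded") <- excluded
  pairs
}

estimate_variables <- c("gain_vlf", "gain_lf", "phase_vlf", "phase_lf", "ari", "cor")

#' Validate and normalise an estimate table
#'
#' Long-format table of duplicate DCA estimates: one row per
#' (method, subject, session, variable). Methods belong to one of three
#' broad categories: 1 transfer-function-like (gain/phase), 2 autoregulation
#' index (0-9), 3 correlation-like index.
#'
#' @param df data.frame with columns `method_id`, `category`, `subject_id`,
#'   `session`, `variable`, `value`.
#' @return The validated data.frame, classed `dca_estimate_table`.
#' @export
estimate_table <- function(df) {
  need <- c("method_id", "category", "subject_id", "session", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("estimate table missing columns: ", paste(miss, collapse = ", "))
  df$session <- as.integer(df$session)
  df$category <- as.integer(df$category)
  if (!all(df$category %in% 1:3)) stop("category must be 1, 2 or 3")
  if (!all(df$variable %in% estimate_variables))
    stop("unknown variable(s): ",
         paste(setdiff(unique(df$variable), estimate_variables), collapse = ", "))
  key <- with(df, paste(method_id, subject_id, session, variable, sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (method, subject, session, variable) rows in estimate table")
  cat_per_method <- tapply(df$category, df$method_id, function(x) length(unique(x)))
  if (any(cat_per_method > 1L))
    stop("method with inconsistent category: ",
         names(cat_per_method)[cat_per_method > 1L][1L])
  df <- df[need]
  class(df) <- c("dca_estimate_table", "data.frame")
  df
}

#' Read / write estimate tables as CSV
#' @param path CSV file path.
#' @return [read_estimate_table()] returns a `dca_estimate_table`;
#'   [write_estimate_table()] returns `path` invisibly.
#' @export
read_estimate_table <- function(path) {
  estimate_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_estimate_table
#' @param tbl a `dca_estimate_table`.
#' @export
write_estimate_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
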