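test_that("read_recording parses delimited text under a column map", {
  n <- 6000
  mat <- cbind((0:(n - 1)) / 10, 90 + sin(1:n / 50), 55 + cos(1:n / 50),
               54 + cos(1:n / 40), rep(5, n))
  for (sep in c("\t", ",", " ")) {
    path <- write_recording_txt(mat, sep = sep)
    rec <- read_recording(path, subject_id = "S1", session = 1L)
    expect_s3_class(rec, "dca_recording")
    expect_equal(recording_duration(rec), 600)
    expect_equal(rec$mabp, mat[, 2])
    expect_equal(rec$etco2, mat[, 5])
  }
})

test_that("unilateral column maps give valid one-sided recordings", {
  mat <- cbind(1:3000 / 10, rep(90, 3000), rep(55, 3000), rep(5, 3000))
  path <- write_recording_txt(mat)
  cm <- column_map(time = 1, mabp = 2, cbfv_left = NA, cbfv_right = 3, etco2 = 4)
  rec <- read_recording(path, cm, subject_id = "S1", session = 2L)
  expect_null(rec$cbfv_left)
  expect_equal(rec$cbfv_right, rep(55, 3000))
})

test_that("missing required channels and bad rows are hard errors", {
  expect_error(column_map(mabp = NA), "MABP")
  expect_error(column_map(cbfv_left = NA, cbfv_right = NA), "CBFV")
  expect_error(column_map(mabp = 2, cbfv_left = 2), "at most one")
  mat <- matrix(rnorm(20), 4)
  lines <- apply(format(mat), 1, paste, collapse = "\t")
  lines[3] <- sub("^[^\t]*", "oops", lines[3])
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  expect_error(read_recording(path, subject_id = "x", session = 1L), "line 3")
})

test_that("recording round-trips through canonical CSV", {
  rec <- make_clean_recording()
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  cm <- column_map(time = 1, mabp = 2, cbfv_left = 3, cbfv_right = 4, etco2 = 5)
  back <- read_recording(path, cm, subject_id = rec$subject_id,
                         session = rec$session)
  expect_equal(back$mabp, rec$mabp, tolerance = 1e-12)
  expect_equal(back$cbfv_left, rec$cbfv_left, tolerance = 1e-12)
  expect_equal(back$etco2, rec$etco2, tolerance = 1e-12)
})

test_that("average_hemispheres takes the sample-wise mean and is idempotent", {
  rec <- make_clean_recording()
  rec$cbfv_left <- rep(40, 6000)
  rec$cbfv_right <- rep(60, 6000)
  av <- average_hemispheres(rec)
  expect_equal(av$cbfv, rep(50, 6000))
  expect_null(av$cbfv_left)
  expect_identical(average_hemispheres(av), av)
  # identical sides reproduce the side; single side used singly
  rec2 <- make_clean_recording()
  rec2$cbfv_right <- rec2$cbfv_left
  expect_equal(average_hemispheres(rec2)$cbfv, rec2$cbfv_left)
  rec3 <- make_clean_recording()
  only_right <- rec3$cbfv_right
  rec3$cbfv_left <- NULL
  expect_equal(average_hemispheres(rec3)$cbfv, only_right)
  # commutes with channel order
  swapped <- make_clean_recording()
  tmp <- swapped$cbfv_left
  swapped$cbfv_left <- swapped$cbfv_right
  swapped$cbfv_right <- tmp
  expect_equal(average_hemispheres(swapped)$cbfv,
               average_hemispheres(make_clean_recording())$cbfv)
})

test_that("pair_sessions pairs by subject and excludes incomplete subjects", {
  recs <- list()
  for (s in 1:5) for (k in 1:2)
    recs[[length(recs) + 1L]] <- make_clean_recording(sprintf("S%03d", s), k)
  recs[[length(recs) + 1L]] <- make_clean_recording("S099", 1L)
  expect_message(pairs <- pair_sessions(recs), "S099")
  expect_length(pairs, 5L)
  expect_equal(attr(pairs, "excluded"), "S099")
  expect_equal(pairs[["S003"]]$s1$session, 1L)
  expect_equal(pairs[["S003"]]$s2$session, 2L)
  expect_length(pair_sessions(list()), 0L)
  expect_error(pair_sessions(c(recs[1], recs[1])), "duplicate")
})

test_that("estimate_table enforces uniqueness and category consistency", {
  df <- data.frame(method_id = "m1", category = 1L, subject_id = "S1",
                   session = c(1L, 2L), variable = "gain_vlf", value = c(1, 2))
  tbl <- estimate_table(df)
  expect_s3_class(tbl, "dca_estimate_table")
  expect_error(estimate_table(rbind(df, df[1, ])), "duplicate")
  bad <- rbind(df, data.frame(method_id = "m1", category = 2L,
                              subject_id = "S2", session = 1L,
                              variable = "gain_vlf", value = 3))
  expect_error(estimate_table(bad), "inconsistent category")
  path <- tempfile(fileext = ".csv")
  write_estimate_table(tbl, path)
  expect_equal(read_estimate_table(path)$value, tbl$value)
})
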