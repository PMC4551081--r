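test_that("write/read round-trips values and labels", {
  ts <- wn_ts(3, 50, seed = 2)
  ts$labels <- c("PCC", "MPFC", "RLP")
  rownames(ts$values) <- ts$labels
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_ts(ts, path)
  back <- read_roi_ts(path)
  expect_identical(back$labels, ts$labels)
  expect_lt(max(abs(back$values - ts$values)), 1e-12)
})

test_that("reader handles the canonical 200x3 layout and both orientations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(3)
  m <- matrix(round(rnorm(600), 6), 200, 3)
  writeLines(c(paste(c("ROI1", "ROI2", "ROI3"), collapse = "\t"),
               apply(m, 1, paste, collapse = "\t")), path)
  ts <- read_roi_ts(path)
  expect_equal(dim(ts$values), c(3L, 200L))
  expect_identical(ts$labels, c("ROI1", "ROI2", "ROI3"))

  # the transposed file read as rows-are-roi gives the identical object
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(apply(t(m), 1, paste, collapse = "\t"), path2)
  ts2 <- read_roi_ts(path2, orientation = "roi")
  expect_equal(ts2$values, ts$values, ignore_attr = TRUE)

  # comma-delimited files are auto-detected
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ROI1,ROI2,ROI3", apply(m, 1, paste, collapse = ",")), path3)
  expect_equal(read_roi_ts(path3)$values, ts$values)
})

test_that("malformed files fail fast with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2", "3\tNA", "5\t6"), path)
  expect_error(read_roi_ts(path), "row 2, column 2")
  writeLines(c("1\t2", "3\t4\t9"), path)
  expect_error(read_roi_ts(path), "ragged")
  expect_error(read_roi_ts(tempfile("nope")), "not found")
})

test_that("centering forces zero means, is idempotent, and can standardize", {
  ts <- roi_ts(matrix(c(rep(5, 40), rnorm(40, 3, 2)), 2, 40, byrow = TRUE),
               orientation = "roi")
  ct <- center(ts)
  expect_true(ct$centered)
  expect_equal(ct$values[1, ], rep(0, 40))
  expect_lt(max(abs(rowMeans(ct$values))), 1e-10)
  expect_identical(center(ct)$values, ct$values)
  cs <- center(ts, standardize = TRUE)
  expect_equal(unname(apply(cs$values, 1, sd)[2]), 1)
})

test_that("container invariants are enforced", {
  expect_error(roi_ts(matrix(1:4, 2, 2)), "must exceed")
  expect_error(roi_ts(matrix(c(1, NA, 3, 4, 5, 6), 2, 3),
                      orientation = "roi"), "finite")
  expect_error(roi_ts(matrix(rnorm(20), 2, 10), tr_seconds = -1,
                      orientation = "roi"), "positive")
  expect_error(roi_ts(matrix(rnorm(20), 2, 10), labels = "only-one",
                      orientation = "roi"), "labels")
})
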