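test_that("decision criteria follow the few-vs-pattern rule", {
  mk_wn <- function(mis) {
    mi <- data.frame(matrix = "Phi", q = mis$lag, r = NA, row = mis$row,
                     col = mis$col, lag = mis$lag, mi = mis$mi, epc = 0.1)
    mi$id <- sprintf("Phi%d[%d,%d]", mi$q, mi$row, mi$col)
    class(mi) <- c("mod_index_table", "data.frame")
    structure(list(fit = NULL, mi = mi, passed = FALSE, L = 3, p = 3),
              class = "white_noise_test")
  }
  # two significant MIs: confirmatory revision with the mapped parameters
  wn <- mk_wn(data.frame(lag = c(1, 2, 2), row = c(3, 3, 1),
                         col = c(3, 3, 2), mi = c(31.3, 31.5, 1.0)))
  dec <- decide_option(wn)
  expect_identical(dec$action, "option_a")
  expect_setequal(dec$mapped$id, c("Phi1[3,3]", "Phi2[3,3]"))
  # no significant MI but a failed test: data-driven re-search
  wn0 <- mk_wn(data.frame(lag = 1, row = 1, col = 1, mi = 0.5))
  expect_identical(decide_option(wn0)$action, "option_b")
  # many significant MIs: no clear pattern
  wn10 <- mk_wn(data.frame(lag = rep(1:2, 5), row = rep(1:3, length.out = 10),
                           col = rep(c(1, 2, 3, 1, 2), 2), mi = rep(9, 10)))
  expect_identical(decide_option(wn10)$action, "option_b")
  # mapped parameters already free fall back to the data-driven route
  cur <- quick_spec(3, 2, Phi = list(list(c(3, 3)), list(c(3, 3))))
  wn2 <- mk_wn(data.frame(lag = c(1, 2), row = c(3, 3), col = c(3, 3),
                          mi = c(12, 9)))
  expect_identical(decide_option(wn2, current_spec = cur)$action, "option_b")
  # residual lags beyond order+1 are deferred
  wn3 <- mk_wn(data.frame(lag = 3, row = 1, col = 1, mi = 20))
  expect_identical(decide_option(wn3, current_spec = model_spec(3, 1))$action,
                   "option_b")
  # a passed test is a contract violation
  wn_ok <- mk_wn(data.frame(lag = 1, row = 1, col = 1, mi = 0))
  wn_ok$passed <- TRUE
  expect_error(decide_option(wn_ok), "failed")
})

test_that("correctly specified order-1 data accepts at order 1, usually at once", {
  out <- vapply(1:20, function(r) {
    Phi <- matrix(0, 3, 3); diag(Phi) <- c(0.5, 0.4, 0.45); Phi[2, 1] <- 0.35
    sp <- sim_spec(3, 200, 1, Phi = list(Phi))
    m <- usem(simulate_usem(sp, seed = 1100 + r), order = 1)
    tr <- validate_order(m)
    tr$accepted && tr$final_order == 1 && length(tr$records) == 1
  }, NA)
  expect_gte(mean(out), 0.9)
})

test_that("an order cap below the truth records give_up", {
  # strong lag-2 structure so the order-1 residuals reliably fail
  Phi1 <- diag(0.3, 3); Phi2 <- matrix(0, 3, 3)
  Phi2[1, 1] <- 0.55; Phi2[2, 1] <- 0.4
  sp <- sim_spec(3, 400, 2, Phi = list(Phi1, Phi2))
  m <- usem(simulate_usem(sp, seed = 61), order = 1)
  tr <- validate_order(m, max_order = 1)
  expect_false(tr$accepted)
  expect_identical(tr$records[[length(tr$records)]]$action, "give_up")
  expect_equal(tr$final_order, 1L)
})

test_that("traces keep orders non-decreasing and end in accept or give_up", {
  for (r in 1:5) {
    m <- usem(simulate_usem(scenario_3roi_lag2(), seed = 1200 + r), order = 1)
    tr <- validate_order(m)
    orders <- vapply(tr$records, function(x) x$order, numeric(1))
    expect_true(all(diff(orders) >= 0))
    expect_true(tr$records[[length(tr$records)]]$action %in%
                  c("accept", "give_up"))
    if (tr$accepted) {
      # accepted maps must re-pass the white-noise test post hoc
      wn <- white_noise_test(residuals(tr$final_model))
      expect_true(wn$passed)
    }
  }
})

test_that("trace serialization writes the per-iteration record", {
  m <- usem(simulate_usem(scenario_3roi_lag2(), seed = 62), order = 1)
  tr <- validate_order(m)
  path <- withr::local_tempfile(fileext = ".json")
  trace_to_json(tr, path)
  back <- jsonlite::read_json(path)
  expect_identical(length(back$iterations), length(tr$records))
  expect_identical(back$final_order, tr$final_order)
})

test_that("series subdivision is manual-only", {
  m <- usem(simulate_usem(scenario_3roi_lag2(T = 400), seed = 63), order = 1)
  expect_error(validate_segments(m, 200), "explicitly")
  cfg <- usem_config(allow_subdivision = TRUE)
  segs <- validate_segments(m, 200, config = cfg)
  expect_length(segs, 2)
  expect_s3_class(segs[[1]], "validation_trace")
})
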