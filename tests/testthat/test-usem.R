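test_that("the search recovers a single strong contemporaneous edge", {
  hits <- vapply(1:20, function(r) {
    # autoregressive components make the orientation identifiable
    A <- matrix(0, 2, 2); A[2, 1] <- 0.6
    sp <- sim_spec(2, 1000, 1, A = A, Phi = list(diag(0.4, 2)))
    m <- usem(simulate_usem(sp, seed = 400 + r), order = 1)
    ids <- free_ids(m$spec)
    "A[2,1]" %in% ids
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("the search stays near-empty on independent white noise", {
  k <- vapply(1:20, function(r) {
    m <- usem(wn_ts(3, 200, seed = 500 + r), order = 1)
    nrow(m$params$table)
  }, numeric(1))
  expect_gte(mean(k <= 1), 0.9)
})

test_that("search results commute with ROI relabeling", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 40)
  m <- usem(ts, order = 1)
  perm <- c(2, 3, 1)
  ts_p <- roi_ts(ts$values[perm, ], labels = paste0("ROI", seq_len(3)),
                 orientation = "roi")
  m_p <- usem(ts_p, order = 1)
  remap <- function(ids) {
    # translate ids fitted on permuted data back to original coordinates
    vapply(strsplit(gsub("[][]", ",", ids), ","), function(parts) {
      ij <- as.integer(parts[2:3])
      sprintf("%s[%d,%d]", parts[1], perm[ij[1]], perm[ij[2]])
    }, "")
  }
  expect_setequal(remap(free_ids(m_p$spec)), free_ids(m$spec))
})

test_that("confirmatory mode fits exactly the requested structure", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 41)
  bad <- model_spec(3, 1)
  bad$free_A[1, 1] <- TRUE
  expect_error(usem(ts, order = 1, method = "confirmatory", spec = bad),
               "diagonal")
  expect_error(usem(ts, order = 1, method = "confirmatory"), "requires")
  sp <- quick_spec(3, 2, A = list(c(1, 3)),
                   Phi = list(list(c(1, 1), c(2, 2), c(3, 3), c(2, 1)),
                              list(c(3, 3))))
  m <- usem(ts, order = 2, method = "confirmatory", spec = sp)
  expect_setequal(free_ids(m$spec), free_ids(sp))
  expect_identical(m$fit$df, 15L)
})

test_that("confirmatory null model on white noise has chi2 near its df", {
  ratios <- vapply(1:10, function(r) {
    ts <- wn_ts(3, 300, seed = 600 + r)
    m <- usem(ts, order = 1, method = "confirmatory", spec = model_spec(3, 1))
    m$fit$chi2 / m$fit$df
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.35)
})

test_that("prediction errors reduce to the data under a zero model and to the
           innovations under the truth", {
  ts <- center(wn_ts(2, 100, seed = 42))
  null_fit <- usem(ts, order = 1, method = "confirmatory",
                   spec = model_spec(2, 1))
  z <- residuals(null_fit)
  expect_equal(dim(z$values), c(2L, 99L))    # length T - a
  expect_equal(z$values, ts$values[, 2:100], ignore_attr = TRUE,
               tolerance = 1e-12)
  # with the true generating parameters, residual covariance approaches I
  sp <- scenario_3roi_lag2(T = 5000)
  ts2 <- center(simulate_usem(sp, seed = 43))
  params <- list(A = sp$A, B = cbind(sp$Phi[[2]], sp$Phi[[1]]),
                 psi = rep(1, 3), spec = usemr:::sim_truth_spec(sp))
  z2 <- prediction_errors(ts2, params)
  emp <- tcrossprod(z2$values - rowMeans(z2$values)) / ncol(z2$values)
  expect_lt(max(abs(emp - diag(3))), 0.1)
})

test_that("model methods expose coefficients, simulation and graphs", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 44)
  m <- usem(ts, order = 1)
  expect_named(coef(m), m$params$table$id)
  s1 <- simulate(m, seed = 7)
  s2 <- simulate(m, seed = 7)
  expect_identical(s1$values, s2$values)
  el <- edge_list(m)
  expect_identical(nrow(el), nrow(m$params$table))
  expect_true(all(el$lag[el$type == "roi"] %in% 0:1))
})
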