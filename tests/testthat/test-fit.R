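test_that("degrees-of-freedom bookkeeping matches the moment count", {
  expect_identical(model_df(3, 1, 5), 7L)
  expect_identical(model_df(3, 2, 4), 17L)
  expect_identical(model_df(3, 2, 6), 15L)
  expect_identical(model_df(3, 2, 0), 21L)
  expect_error(model_df(2, 0, 10), "over-parameterized")
  # identity asserted against a direct count of distinct fitted moments:
  # m(m+1)/2 total, minus saturated x-block, minus p variances, minus k
  p <- 3; a <- 2; k <- 4
  m <- p * (a + 1)
  expect_identical(model_df(p, a, k),
                   as.integer(m * (m + 1) / 2 - (m - p) * (m - p + 1) / 2 -
                              p - k))
})

test_that("just-identified single regression equals the closed form", {
  S <- fake_lagged_cov(matrix(c(1, 0.5, 0.5, 1), 2), p = 1, order = 1,
                       n_eff = 101)
  sp <- model_spec(1, 1)
  sp$free_Phi[[1]][1, 1] <- TRUE
  ans <- fit_ml(S, sp)
  expect_equal(unname(ans$params$B[1, 1]), 0.5, tolerance = 1e-8)
  expect_equal(unname(ans$params$psi), 0.75, tolerance = 1e-8)
  expect_lt(ans$fit$chi2, 1e-8)
  expect_identical(ans$fit$df, 0L)
})

test_that("multi-regressor just-identified fits equal covariance regression", {
  ts <- center(var1_ts(matrix(c(0.5, 0.2, 0, 0.4), 2, 2, byrow = TRUE),
                       T = 400, seed = 10))
  S <- block_toeplitz_cov(ts, 1)
  sp <- quick_spec(2, 1, Phi = list(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))))
  ans <- fit_ml(S, sp)
  Sxx <- S$S[1:2, 1:2]; Sxe <- S$S[1:2, 3:4]
  expect_equal(ans$params$B, t(solve(Sxx, Sxe)), tolerance = 1e-7,
               ignore_attr = TRUE)
  # residual variances match the conditional variances
  W <- S$S[3:4, 3:4] - t(Sxe) %*% solve(Sxx, Sxe)
  expect_equal(unname(ans$params$psi), unname(diag(W)), tolerance = 1e-7)
})

test_that("a saturated recursive model reproduces S exactly (chi2 = 0, df = 0)", {
  ts <- center(wn_ts(3, 150, seed = 11))
  S <- block_toeplitz_cov(ts, 1)
  sp <- model_spec(3, 1)
  sp$free_A <- lower.tri(sp$free_A)
  sp$free_Phi[[1]][] <- TRUE
  ans <- fit_ml(S, sp)
  expect_lt(ans$fit$chi2, 1e-6)
  expect_identical(ans$fit$df, 0L)
  Sigma <- implied_sigma(sp, ans$params, S$S[1:3, 1:3])
  expect_lt(max(abs(Sigma - S$S)), 1e-6)
})

test_that("implied covariance reproduces the stationary AR(1) moments", {
  sp <- model_spec(1, 1)
  params <- list(A = matrix(0, 1, 1), B = matrix(0.5, 1, 1), psi = 1)
  Sig <- implied_sigma(sp, params, sigma_xx = matrix(4 / 3, 1, 1))
  expect_equal(Sig[2, 2], 4 / 3)            # 0.25*4/3 + 1
  expect_equal(Sig[1, 2], 0.5 * 4 / 3)
  A <- matrix(c(0, 0.9, 1.2, 0), 2, 2)      # (I-A) singular: det = 1-1.08
  expect_silent(implied_sigma(model_spec(2, 0),
                              list(A = A, B = matrix(0, 2, 0), psi = c(1, 1)),
                              matrix(0, 0, 0)))
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(implied_sigma(model_spec(2, 0),
                             list(A = A2, B = matrix(0, 2, 0), psi = c(1, 1)),
                             matrix(0, 0, 0)),
               "singular")
})

test_that("estimation is invariant to ROI ordering", {
  ts <- center(simulate_usem(scenario_3roi_lag2(), seed = 12))
  perm <- c(3, 1, 2)
  ts2 <- roi_ts(ts$values[perm, ], labels = ts$labels[perm],
                orientation = "roi")
  sp <- quick_spec(3, 1, A = list(c(1, 3)),
                   Phi = list(list(c(1, 1), c(2, 2), c(3, 3), c(2, 1))))
  sp2 <- quick_spec(3, 1, A = list(c(which(perm == 1), which(perm == 3))),
                    Phi = list(lapply(list(c(1, 1), c(2, 2), c(3, 3), c(2, 1)),
                                      function(ij) c(which(perm == ij[1]),
                                                     which(perm == ij[2])))))
  f1 <- fit_ml(block_toeplitz_cov(ts, 1), sp)
  f2 <- fit_ml(block_toeplitz_cov(center(ts2), 1), sp2)
  expect_equal(f1$fit$chi2, f2$fit$chi2, tolerance = 1e-6)
  expect_equal(f1$params$A[1, 3], f2$params$A[which(perm == 1), which(perm == 3)],
               tolerance = 1e-8)
  expect_equal(unname(f1$params$psi), unname(f2$params$psi[order(perm)]),
               tolerance = 1e-8)
})

test_that("freeing a parameter never increases chi2", {
  ts <- center(simulate_usem(scenario_3roi_lag2(), seed = 13))
  S <- block_toeplitz_cov(ts, 2)
  sp <- quick_spec(3, 2, Phi = list(list(c(1, 1), c(2, 2), c(3, 3)), list()))
  f0 <- fit_ml(S, sp)
  for (extra in list(list(m = "A", i = c(1, 3)), list(m = "Phi", i = c(2, 1)),
                     list(m = "Phi2", i = c(3, 3)))) {
    sp1 <- sp
    if (extra$m == "A") sp1$free_A[extra$i[1], extra$i[2]] <- TRUE
    else if (extra$m == "Phi") sp1$free_Phi[[1]][extra$i[1], extra$i[2]] <- TRUE
    else sp1$free_Phi[[2]][extra$i[1], extra$i[2]] <- TRUE
    f1 <- fit_ml(S, sp1)
    expect_lte(f1$fit$chi2, f0$fit$chi2 + 1e-6 * max(f0$fit$chi2, 1))
  }
})

test_that("standard errors carry 95% intervals with the 1.96 convention", {
  ts <- center(var1_ts(matrix(0.5, 1, 1), T = 500, seed = 14))
  S <- block_toeplitz_cov(ts, 1)
  sp <- model_spec(1, 1); sp$free_Phi[[1]][1, 1] <- TRUE
  tab <- fit_ml(S, sp)$params$table
  expect_equal(tab$ci_low, tab$estimate - 1.96 * tab$se)
  expect_equal(tab$ci_high, tab$estimate + 1.96 * tab$se)
  # SE close to the classical sqrt((1-phi^2)/T) for an AR(1)
  expect_equal(tab$se, sqrt((1 - tab$estimate^2) / 500), tolerance = 0.15)
})
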