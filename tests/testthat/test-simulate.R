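test_that("the zero model draws white noise with identity covariance", {
  sp <- sim_spec(3, 10000, 1, Phi = list(matrix(0, 3, 3)))
  ts <- simulate_usem(sp, seed = 80)
  y <- ts$values - rowMeans(ts$values)
  emp <- tcrossprod(y) / ncol(y)
  expect_lt(max(abs(emp - diag(3))), 0.1)
})

test_that("seeds pin the stream and non-stationary specs are refused", {
  sp <- scenario_3roi_lag2()
  expect_identical(simulate_usem(sp, seed = 81)$values,
                   simulate_usem(sp, seed = 81)$values)
  expect_false(identical(simulate_usem(sp, seed = 81)$values,
                         simulate_usem(sp, seed = 82)$values))
  expect_error(sim_spec(2, 100, 1, Phi = list(diag(1.05, 2))),
               "non-stationary")
  expect_error(sim_spec(2, 100, 1, A = matrix(c(0, 1, 1, 0), 2),
                        Phi = list(matrix(0, 2, 2))), "singular")
  expect_error(sim_spec(2, 100, 1, Phi = list(matrix(0, 2, 2)),
                        innovation_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("the 3-ROI demonstration scenario has exactly its six connections", {
  sp <- scenario_3roi_lag2()
  expect_identical(sp$p, 3); expect_identical(sp$T, 200)
  expect_identical(sp$order, 2)
  nz <- sum(sp$A != 0) + sum(sp$Phi[[1]] != 0) + sum(sp$Phi[[2]] != 0)
  expect_identical(nz, 6L)
  expect_lt(sp$spectral_radius, 1)
  expect_identical(sp$innovation_cov, diag(3))
  expect_error(scenario_3roi_lag2(ar1 = 1.2), "non-stationary")
})

test_that("empirical lagged moments match the implied reduced-form moments", {
  sp <- scenario_3roi_lag2(T = 50000)
  ts <- center(simulate_usem(sp, seed = 83))
  S <- block_toeplitz_cov(ts, 1)
  # reduced-form VAR(2): x(t) = P1 x(t-1) + P2 x(t-2) + G e
  G <- solve(diag(3) - sp$A)
  P1 <- G %*% sp$Phi[[1]]; P2 <- G %*% sp$Phi[[2]]
  Se <- G %*% t(G)
  # solve the companion-form Lyapunov equation by fixed-point iteration
  comp <- rbind(cbind(P1, P2), cbind(diag(3), matrix(0, 3, 3)))
  Q <- matrix(0, 6, 6); Q[1:3, 1:3] <- Se
  V <- Q
  for (i in 1:2000) V <- comp %*% V %*% t(comp) + Q
  implied0 <- V[1:3, 1:3]; implied1 <- V[1:3, 4:6]  # lag-0 and lag-1
  scale <- sqrt(outer(diag(implied0), diag(implied0)))
  expect_lt(max(abs(S$S[4:6, 4:6] - implied0) / scale), 0.02)
  expect_lt(max(abs(S$S[1:3, 4:6] - t(implied1)) / scale), 0.02)
})

test_that("series are stationary in distribution across the record", {
  ratios <- vapply(1:10, function(r) {
    ts <- simulate_usem(scenario_3roi_lag2(T = 400), seed = 840 + r)
    q2 <- ts$values[, 101:200]; q4 <- ts$values[, 301:400]
    mean(apply(q4, 1, var) / apply(q2, 1, var))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("euSEM simulation reduces to uSEM when input effects vanish", {
  base <- sim_spec(2, 300, 1, Phi = list(diag(0.4, 2)), seed = 85)
  with_g <- sim_spec(2, 300, 1, Phi = list(diag(0.4, 2)),
                     gamma = list(matrix(0, 2, 1), matrix(0, 2, 1)),
                     seed = 85)
  sim <- simulate_eusem(with_g, protocol = list(onsets = 50, durations = 25))
  expect_equal(sim$ts$values, simulate_usem(base, seed = 85)$values,
               tolerance = 1e-12)
  # a protocol with no blocks gives an all-zero input
  sim0 <- simulate_eusem(with_g, protocol = list(onsets = c(), durations = c()))
  expect_true(all(sim0$input$raw == 0))
  expect_true(all(sim0$input$convolved == 0))
})

test_that("group simulation honors its ledger contract", {
  gsp <- group_sim_spec(seed = 86)   # defaults: 32 subjects, 4 ROIs, T = 160
  sim <- simulate_group(gsp)
  expect_length(sim$ts_list, 32)
  expect_identical(dim(sim$ts_list[[1]]$values), c(4L, 160L))
  # group edges appear in every subject's ledger
  g_edges <- unique(subset(sim$truth, level == "group",
                           c(matrix, lag, row, col)))
  for (i in 1:32) {
    sub <- subset(sim$truth, subject == i & level == "group")
    expect_identical(nrow(unique(sub[, c("matrix", "lag", "row", "col")])),
                     nrow(g_edges))
  }
  expect_equal(sum(tapply(sim$truth$lag == 2, sim$truth$subject, any)), 16)
  # no lag-2 edges when the fraction is zero
  sim0 <- simulate_group(group_sim_spec(n_subjects = 6, fraction_lag2 = 0,
                                        seed = 87))
  expect_false(any(sim0$truth$lag == 2))
})
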