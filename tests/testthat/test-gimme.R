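test_that("grouping criterion counts match the printed 24-of-32 rule", {
  expect_identical(group_threshold_count(32, 0.75), 24L)
  expect_identical(group_threshold_count(4, 0.75), 3L)
  expect_identical(group_threshold_count(10, 0.75), 8L)
  expect_identical(group_threshold_count(1, 0.75), 1L)
})

test_that("a single subject reduces GIMME to the individual search", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 70)
  gm <- gimme(list(ts))
  m <- usem(ts, order = 1)
  expect_setequal(free_ids(gm$fits[[1]]$spec), free_ids(m$spec))
})

test_that("shared structure is recovered at the group level without spurious paths", {
  gs <- simulate_group(group_sim_spec(n_subjects = 10, fraction_lag2 = 0,
                                      n_individual = 0, seed = 71))
  gm <- gimme(gs$ts_list)
  got <- free_ids(gm$group_spec)
  want <- with(unique(subset(gs$truth, level == "group",
                             c(matrix, lag, row, col))),
               ifelse(matrix == "A", sprintf("A[%d,%d]", row, col),
                      sprintf("Phi%d[%d,%d]", lag, row, col)))
  expect_setequal(got, want)
})

test_that("edges present in only half the sample stay individual-level", {
  # 4 of 8 subjects get an extra contemporaneous edge
  gsp <- group_sim_spec(n_subjects = 8, p = 3, T = 200,
                        group_A = matrix(0, 3, 3),
                        group_Phi1 = diag(0.4, 3),
                        n_individual = 0, fraction_lag2 = 0, seed = 72)
  sim <- simulate_group(gsp)
  half <- sample(8, 4)
  for (i in half) {
    A <- matrix(0, 3, 3); A[2, 1] <- 0.5
    sp <- sim_spec(3, 200, 1, A = A,
                   Phi = list(diag(0.4, 3)), seed = 720 + i)
    sim$ts_list[[i]] <- simulate_usem(sp, seed = 720 + i)
  }
  gm <- gimme(sim$ts_list)
  expect_false("A[2,1]" %in% free_ids(gm$group_spec))
})

test_that("group output is invariant to subject ordering and contained in all subjects", {
  gs <- simulate_group(group_sim_spec(n_subjects = 6, fraction_lag2 = 0,
                                      n_individual = 1, seed = 73))
  gm1 <- gimme(gs$ts_list)
  gm2 <- gimme(rev(gs$ts_list))
  expect_setequal(free_ids(gm1$group_spec), free_ids(gm2$group_spec))
  for (f in gm1$fits)
    expect_true(usemr:::spec_contains(f$spec, gm1$group_spec))
})

test_that("mismatched subjects are refused", {
  a <- wn_ts(3, 100, seed = 74)
  b <- wn_ts(4, 100, seed = 75)
  expect_error(gimme(list(a, b)), "share")
})
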