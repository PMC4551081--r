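test_that("edge lists annotate lag, type and level and round-trip the mask", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 90)
  truth <- quick_spec(3, 2, A = list(c(1, 3)),
                      Phi = list(list(c(1, 1), c(2, 2), c(3, 3), c(2, 1)),
                                 list(c(3, 3))))
  m <- usem(ts, order = 2, method = "confirmatory", spec = truth)
  el <- edge_list(m)
  expect_identical(nrow(el), 6L)
  expect_identical(el$lag[el$source == "ROI3" & el$target == "ROI1"], 0L)
  expect_setequal(el$lag, c(0L, 1L, 1L, 1L, 1L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  export_map(m, path, "edgelist")
  back <- read_edge_list(path, labels = m$spec$labels)
  expect_setequal(free_ids(back), free_ids(m$spec))
})

test_that("graph formats carry one edge per freed connection", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 91)
  m <- usem(ts, order = 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_map(m, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(m$params$table))
  dot <- withr::local_tempfile(fileext = ".dot")
  export_map(m, dot, "dot")
  expect_gt(file.size(dot), 0)
  expect_error(export_map(m, gml, "svg"), "unknown format")
})

test_that("model JSON serializes the full parameter table", {
  ts <- simulate_usem(scenario_3roi_lag2(), seed = 92)
  m <- usem(ts, order = 1)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$order, 1L)
  expect_identical(sum(back$parameters$free), nrow(m$params$table))
  expect_identical(back$fit$df, m$fit$df)
})

test_that("GIMME export writes a group model and per-subject edge lists", {
  gs <- simulate_group(group_sim_spec(n_subjects = 4, fraction_lag2 = 0,
                                      n_individual = 0, seed = 93))
  gm <- gimme(gs$ts_list)
  dir <- withr::local_tempdir()
  gimme_to_json(gm, dir)
  expect_true(file.exists(file.path(dir, "group_model.json")))
  expect_length(list.files(dir, pattern = "_edges\\.csv$"), 4L)
  el <- read.table(file.path(dir, "subj01_edges.csv"), sep = ",",
                   header = TRUE)
  expect_true(all(el$level[el$source == el$source] %in%
                    c("group", "individual")))
})
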