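test_that("environment realization follows the exchange/sink rules", {
  toy <- makeToyModel(carbonSources = 2)
  m <- toy$model
  env <- NutrientEnvironment("medium", available = "cs1_e0",
                            uptakeBound = 1000)
  m2 <- applyEnvironment(m, env)
  rx <- stats::setNames(reactions(m2)$lower_bound, reactions(m2)$id)
  # available metabolite with an exchange: lb opened to -1000
  expect_equal(unname(rx["EX_cs1"]), -1000)
  # unlisted exchange closed to uptake but open to secretion
  expect_equal(unname(rx["EX_cs2"]), 0)
  expect_gt(reactions(m2)$upper_bound[reactions(m2)$id == "EX_cs2"], 0)
  # intracellular-only metabolite: supply sink with (-bound, 0)
  env2 <- NutrientEnvironment("sink", available = c("cs1_e0", "m2_c0"))
  m3 <- applyEnvironment(m, env2)
  i <- which(reactions(m3)$id == "SK_m2_c0")
  expect_length(i, 1)
  expect_equal(reactions(m3)$lower_bound[i], -1000)
  expect_equal(reactions(m3)$upper_bound[i], 0)
  expect_identical(reactions(m3)$kind[i], "sink")
  # excluded metabolites never receive an uptake route
  env3 <- NutrientEnvironment("excl", available = "cs1_e0",
                              excluded = "m2_c0")
  m4 <- applyEnvironment(m, env3)
  expect_false("SK_m2_c0" %in% reactions(m4)$id)
  # absent metabolites are skipped with a warning and recorded
  env4 <- NutrientEnvironment("missing", available = c("cs1_e0", "ghost"))
  expect_warning(m5 <- applyEnvironment(m, env4), "ghost")
  expect_identical(attr(m5, "environmentReport")$skipped, "ghost")
})

test_that("fixed uptakes clamp the exchange bound to the measured rate", {
  toy <- makeToyModel(biomassYield = 0.5)
  env <- NutrientEnvironment("glc", available = "cs1_e0",
                             fixedUptakes = c(cs1_e0 = 1.71))
  m2 <- applyEnvironment(toy$model, env)
  expect_equal(reactions(m2)$lower_bound[reactions(m2)$id == "EX_cs1"],
               -1.71)
  expect_equal(as.numeric(predictGrowth(toy$model, env)), 1.71 * 0.5,
               tolerance = 1e-8)
})

test_that("applyEnvironment is idempotent", {
  toy <- makeToyModel(carbonSources = 2)
  env <- NutrientEnvironment("e", available = c("cs1_e0", "m2_c0"))
  m1 <- applyEnvironment(toy$model, env)
  m2 <- applyEnvironment(m1, env)
  expect_identical(reactions(m1), reactions(m2))
  expect_equal(as.matrix(stoichiometricMatrix(m1)),
               as.matrix(stoichiometricMatrix(m2)))
})

test_that("growth is monotone in the available nutrient set", {
  toy <- makeToyModel(carbonSources = 2, uptakeBound = 10)
  sets <- list("cs1_e0", c("cs1_e0", "cs2_e0"),
               c("cs1_e0", "cs2_e0", "m1_c0"))
  g <- vapply(sets, function(av)
    as.numeric(predictGrowth(toy$model,
                             NutrientEnvironment("e", available = av,
                                                 uptakeBound = 10))),
    numeric(1))
  expect_true(all(diff(g) >= -1e-9))
})

test_that("closing all carbon uptake forces zero growth", {
  toy <- makeToyModel(carbonSources = 2)
  env <- NutrientEnvironment("empty", available = character())
  expect_equal(as.numeric(predictGrowth(toy$model, env)), 0,
               tolerance = 1e-9)
})

test_that("carbon-source screens call growth per candidate", {
  toy <- makeToyModel(carbonSources = 2)
  # cripple the second carbon source's transporter: cs2 cannot be used
  m <- setReactionBounds(toy$model, "T_cs2", lower = 0, upper = 0)
  base <- NutrientEnvironment("base", available = character(),
                              uptakeBound = 10)
  sc <- carbonSourceScreen(m, base, c("cs1_e0", "cs2_e0", "notthere"))
  expect_identical(sc$carbon_source, c("cs1_e0", "cs2_e0"))
  expect_identical(sc$grows, c(TRUE, FALSE))
  expect_identical(attr(sc, "absentCandidates"), "notthere")
  # per-source FBA oracle
  for (i in seq_len(nrow(sc))) {
    env <- NutrientEnvironment("one", available = sc$carbon_source[i],
                               uptakeBound = 10)
    expect_equal(sc$predicted_growth[i],
                 as.numeric(predictGrowth(m, env)), tolerance = 1e-9)
  }
  expect_identical(nrow(carbonSourceScreen(m, base, character())), 0L)
})

test_that("environment files round through the TSV format with mapping", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite_id\trole\tfixed_uptake",
               "glucose\tavailable\t1.71",
               "cs2_e0\tavailable\t",
               "m2_c0\texcluded\t"), tf)
  map <- data.frame(external_name = "glucose", model_id = "cs1_e0")
  env <- readEnvironment(tf, mapping = map)
  expect_identical(sort(env@available), c("cs1_e0", "cs2_e0"))
  expect_identical(env@excluded, "m2_c0")
  expect_equal(env@fixedUptakes, c(cs1_e0 = 1.71))
  expect_error(NutrientEnvironment("bad", available = "x", excluded = "x"),
               "overlap")
})
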