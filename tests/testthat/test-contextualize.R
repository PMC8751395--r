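test_that("expression weights normalize and aggregate over GPRs", {
  d <- diamondModel()
  # uniform abundance: every gene-associated weight is 1
  u <- ExpressionProfile(stats::setNames(rep(50, 4),
                                         c("gT", "gD", "gC1", "gC2")))
  w <- expressionToReactionWeights(d, u)
  ga <- nzchar(reactions(d)$gpr)
  expect_equal(unname(w[reactions(d)$id[ga]]), rep(1, sum(ga)))
  # two abundances 10 and 90 normalize to 1/9 and 1
  e <- ExpressionProfile(c(gT = 90, gD = 90, gC1 = 10, gC2 = 90))
  w2 <- expressionToReactionWeights(d, e)
  expect_equal(unname(w2["DECOY1"]), 1 / 9)
  expect_equal(unname(w2["DIRECT"]), 1)
  # OR aggregates with max
  m <- MetabolicModel("or",
    metabolites = data.frame(id = "A_c0"),
    reactions = data.frame(id = c("R1", "R2"), gpr = c("g1 or g2", "g3"),
                           lower_bound = 0),
    stoichiometry = list(c(A_c0 = 1), c(A_c0 = -1)),
    objective = c(R2 = 1))
  w3 <- expressionToReactionWeights(
    m, ExpressionProfile(c(g1 = 5, g2 = 50, g3 = 50)))
  expect_equal(unname(attr(w3, "abundance")["R1"]), 50)
  # AND aggregates with min
  m@reactions$gpr[1] <- "g1 and g2"
  w4 <- expressionToReactionWeights(
    m, ExpressionProfile(c(g1 = 5, g2 = 50, g3 = 50)))
  expect_equal(unname(attr(w4, "abundance")["R1"]), 5)
  # zero overlap errors
  expect_error(
    expressionToReactionWeights(d, ExpressionProfile(c(zz = 1))),
    "overlap")
})

test_that("pruning keeps the expressed route and drops silent decoys", {
  d <- diamondModel()
  w <- expressionToReactionWeights(
    d, ExpressionProfile(c(gT = 90, gD = 90, gC1 = 5, gC2 = 5)))
  pr <- pruneModel(d, w, objectiveFraction = 0.8)
  expect_true(all(c("DECOY1", "DECOY2") %in% pr$removed))
  expect_true(all(c("DIRECT", "EX_A", "T_A", "DM_B") %in%
                  reactions(pr$model)$id))
  expect_gte(objectiveValue(fba(pr$model)), 0.8 * pr$optimum - 1e-6)
})

test_that("task protection overrides expression-based removal", {
  d <- diamondModel()
  w <- expressionToReactionWeights(
    d, ExpressionProfile(c(gT = 90, gD = 90, gC1 = 5, gC2 = 5)))
  pr <- pruneModel(d, w, taskSet(protectedGenes = c("gC1", "gC2")), 0.8)
  expect_true(all(c("DECOY1", "DECOY2") %in% reactions(pr$model)$id))
  # forced reactions gain their minimum flux and are kept
  toy <- makeToyModel()
  w2 <- expressionToReactionWeights(
    toy$model, simulateExpression(toy$model,
      plantedContext(toy$activeReactions, seed = 1)))
  pr2 <- pruneModel(toy$model, w2,
                    taskSet(forcedReactions = c(DM_biomass = 1)), 0.5)
  expect_true("DM_biomass" %in% reactions(pr2$model)$id)
  v <- fluxes(pfba(pr2$model, 1))
  expect_gte(unname(v["DM_biomass"]), 1 - 1e-8)
  expect_error(pruneModel(toy$model, w2,
                          taskSet(forcedReactions = c(DM_biomass = 1e5)),
                          0.9),
               "infeasible")
})

test_that("task protection holds across randomized planted fixtures", {
  for (seed in 1:5) {
    toy <- makeToyModel(nLinearSteps = 3, nDecoyBranches = 2)
    ctx <- plantedContext(toy$activeReactions, toy$decoyReactions,
                          seed = seed)
    w <- expressionToReactionWeights(toy$model,
                                     simulateExpression(toy$model, ctx))
    protectedGene <- sprintf("gD%dc", 1 + seed %% 2)
    pr <- pruneModel(toy$model, w, taskSet(protectedGenes = protectedGene),
                     0.8)
    protectedRxn <- reactions(toy$model)$id[
      vapply(reactions(toy$model)$gpr,
             function(g) protectedGene %in% gprGenes(g), logical(1))]
    expect_true(all(protectedRxn %in% reactions(pr$model)$id),
                info = paste("seed", seed))
  }
})

test_that("pruned models never gain uptake routes (subset property)", {
  toy <- makeToyModel(carbonSources = 2, nDecoyBranches = 1)
  env <- NutrientEnvironment("both", available = c("cs1_e0", "cs2_e0"),
                             uptakeBound = 10)
  m <- applyEnvironment(toy$model, env)
  ctx <- plantedContext(toy$activeReactions, toy$decoyReactions, seed = 2)
  w <- expressionToReactionWeights(m, simulateExpression(m, ctx))
  pr <- pruneModel(m, w, objectiveFraction = 0.8)
  openUptakes <- function(mm) {
    rx <- reactions(mm)
    rx$id[rx$kind %in% c("exchange", "sink") & rx$lower_bound < 0]
  }
  expect_true(all(openUptakes(pr$model) %in% openUptakes(m)))
})

test_that("rank correlation of fluxes and expression follows the definition", {
  smp <- matrix(c(1, 2, 3), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(correlateFluxExpression(
    smp, c(a = 10, b = 20, c = 30))["rho"]), 1)
  expect_equal(unname(correlateFluxExpression(
    smp, c(a = 30, b = 20, c = 10))["rho"]), -1)
  # hand rank computation for (1,2,3) vs (3,1,2): rho = -0.5
  expect_equal(unname(correlateFluxExpression(
    smp, c(a = 3, b = 1, c = 2))["rho"]), -0.5)
  expect_error(correlateFluxExpression(smp[, 1:2, drop = FALSE],
                                       c(a = 1, b = 2)), "at least 3")
})

test_that("a singleton fraction grid returns that fraction", {
  toy <- makeToyModel(nDecoyBranches = 1)
  ctx <- plantedContext(toy$activeReactions, toy$decoyReactions, seed = 4)
  expr <- simulateExpression(toy$model, ctx)
  res <- maxFit(toy$model, expr, fractions = 0.7, nSamples = 60, seed = 9)
  expect_equal(objectiveFraction(res), 0.7)
  expect_true(res@rho >= -1 && res@rho <= 1)
  expect_identical(nrow(sampleMatrix(res)), 60L)
})

test_that("maxFit is reproducible for a fixed seed", {
  tr <- makeTradeoffToy(seed = 5)
  expr <- simulateContextExpression(tr$model, 0.7, seed = 8, nSamples = 80)
  r1 <- maxFit(tr$model, expr, fractions = c(0.6, 0.7, 0.8), nSamples = 80,
               seed = 3, refine = FALSE)
  r2 <- maxFit(tr$model, expr, fractions = c(0.6, 0.7, 0.8), nSamples = 80,
               seed = 3, refine = FALSE)
  expect_identical(r1@rho, r2@rho)
  expect_identical(sampleMatrix(r1), sampleMatrix(r2))
})

test_that("uptake summaries normalize by objective flux and drop secretion", {
  toy <- makeToyModel(biomassYield = 0.5, uptakeBound = 10)
  aug <- rhizoflux:::.constrainObjective(toy$model, 1, toy$optimum)
  fs <- sampleFluxes(aug$model, 40, seed = 6)
  smp <- sampleMatrix(fs)[, reactions(toy$model)$id]
  out <- rhizoflux:::.uptakeSummary(smp, toy$model)
  # uptake 10 per 5 biomass: normalized uptake 2, constant across samples
  expect_equal(out$median[out$metabolite == "cs1_e0"], 2, tolerance = 1e-6)
  expect_equal(out$iqr[out$metabolite == "cs1_e0"], 0, tolerance = 1e-6)
  # hand-built samples: uptakes 1, 2, 4 per unit biomass -> median 2;
  # a secreted metabolite never appears
  m <- makeToyModel(carbonSources = 2)$model
  smp2 <- matrix(0, 3, nrow(reactions(m)),
                 dimnames = list(NULL, reactions(m)$id))
  smp2[, "BIOMASS"] <- 1
  smp2[, "EX_cs1"] <- c(-1, -2, -4)
  smp2[, "EX_cs2"] <- c(2, 3, 4)  # secretion only
  out2 <- rhizoflux:::.uptakeSummary(smp2, m)
  expect_equal(out2$median[out2$metabolite == "cs1_e0"], 2)
  expect_false("cs2_e0" %in% out2$metabolite)
  # zero objective flux in any sample is an error
  smp2[2, "BIOMASS"] <- 0
  expect_error(rhizoflux:::.uptakeSummary(smp2, m), "zero objective")
})
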