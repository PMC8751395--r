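test_that("FBA solves conservation-forced toys and flags infeasibility", {
  m <- chainModel(uptake = 10)
  r <- fba(m)
  expect_identical(solverStatus(r), "optimal")
  expect_equal(objectiveValue(r), 10, tolerance = 1e-9)
  expect_lt(maxStoichResidual(m, fluxes(r)), 1e-6)
  # conflicting bounds: uptake forced open while transport is closed
  m2 <- setReactionBounds(m, "EX_A", lower = -10, upper = -10)
  m2 <- setReactionBounds(m2, "T_A", lower = 0, upper = 0)
  expect_identical(solverStatus(fba(m2)), "infeasible")
  expect_error(fba(MetabolicModel("noobj",
    metabolites = data.frame(id = "A_c0"),
    reactions = data.frame(id = "R1"),
    stoichiometry = list(c(A_c0 = 1)))), "objective")
})

test_that("FBA optimum matches an independent LP solver on branched toys", {
  for (seed in c(3, 14)) {
    toy <- randomToy(seed)
    mine <- objectiveValue(fba(toy$model))
    orc <- oracleFva(toy$model, 1)  # the opt column is the oracle FBA value
    expect_equal(mine, orc$opt[1], tolerance = 1e-7)
  }
})

test_that("pFBA attains the objective and routes flux parsimoniously", {
  # single linear pathway: pfba at fraction 1 equals fba (unique flux vector)
  m <- chainModel()
  expect_equal(fluxes(pfba(m, 1)), fluxes(fba(m)), tolerance = 1e-9)
  # diamond: all flux on the one-step route, none on the two-step decoy
  d <- diamondModel()
  v <- fluxes(pfba(d, 1))
  expect_equal(unname(v["DIRECT"]), 10, tolerance = 1e-8)
  expect_equal(unname(v["DECOY1"]), 0, tolerance = 1e-8)
  # oracle: of the two vertex solutions the direct one has smaller taxicab norm
  vDecoy <- c(10, 10, 0, 10, 10, 10)  # EX,T,DIRECT,DECOY1,DECOY2,DM
  vDirect <- c(10, 10, 10, 0, 0, 10)
  expect_lt(sum(abs(vDirect)), sum(abs(vDecoy)))
  expect_equal(sum(abs(v)), sum(abs(vDirect)), tolerance = 1e-8)
  # internal loop carries zero flux
  toy <- makeToyModel(withLoop = TRUE)
  vl <- fluxes(pfba(toy$model, 1))
  expect_lt(max(abs(vl[c("LOOPF", "LOOPB")])), 1e-8)
})

test_that("pFBA total flux never exceeds the FBA solution's total flux", {
  for (seed in c(5, 21, 33)) {
    toy <- randomToy(seed)
    expect_lte(sum(abs(fluxes(pfba(toy$model, 1)))),
               sum(abs(fluxes(fba(toy$model)))) + 1e-8)
  }
})

test_that("FVA ranges match direct per-reaction LP enumeration", {
  d <- diamondModel()
  mine <- fva(d, 0.95)
  orc <- oracleFva(d, 0.95)
  expect_equal(mine$minimum, orc$minimum, tolerance = 1e-7)
  expect_equal(mine$maximum, orc$maximum, tolerance = 1e-7)
  # unique single pathway: min = max everywhere at fraction 1
  m <- chainModel()
  r <- fva(m, 1)
  expect_equal(r$minimum, r$maximum, tolerance = 1e-8)
})

test_that("loopless FVA collapses internal cycles to zero range", {
  toy <- makeToyModel(withLoop = TRUE)
  plain <- fva(toy$model, 0.95)
  loopless <- fva(toy$model, 0.95, loopless = TRUE)
  loopIdx <- plain$reaction_id %in% c("LOOPF", "LOOPB")
  expect_equal(max(plain$maximum[loopIdx]), 1000)   # unbounded by the loop
  expect_lt(max(abs(loopless$minimum[loopIdx])), 1e-8)
  expect_lt(max(abs(loopless$maximum[loopIdx])), 1e-8)
  # non-loop reactions keep their envelopes
  expect_equal(loopless$maximum[!loopIdx], plain$maximum[!loopIdx],
               tolerance = 1e-6)
  expect_identical(attr(loopless, "method"), "fva+cycle-removal")
})

test_that("MOMA identity, forced-zero and closed-form projection cases", {
  toy <- makeToyModel()
  wt <- pfba(toy$model, 1)
  # empty disabled set: wild type recovered at zero distance
  same <- moma(toy$model, wt, character())
  expect_lt(max(abs(fluxes(same) - fluxes(wt))), 1e-6)
  # disabling the sole biomass-feeding reaction forces zero growth
  dead <- moma(toy$model, wt, "BIOMASS")
  expect_equal(objectiveValue(dead), 0, tolerance = 1e-8)
  # closed form: v1 = v2 + v3, wt = (10, 10, 0), knock out R2.
  # Feasible set is the line (t, 0, t); least-squares projection gives t = 5.
  m <- MetabolicModel("proj",
    metabolites = data.frame(id = "A_c0"),
    reactions = data.frame(id = c("R1", "R2", "R3"),
                           lower_bound = c(0, 0, 0),
                           upper_bound = c(10, 10, 10)),
    stoichiometry = list(c(A_c0 = 1), c(A_c0 = -1), c(A_c0 = -1)),
    objective = c(R2 = 1))
  wt2 <- fba(m)
  expect_equal(unname(fluxes(wt2)), c(10, 10, 0), tolerance = 1e-8)
  proj <- moma(m, wt2, "R2")
  expect_equal(unname(fluxes(proj)), c(5, 0, 5), tolerance = 1e-6)
  # the linear variant also honours the constraint set
  lin <- moma(m, wt2, "R2", method = "linear")
  expect_equal(unname(fluxes(lin)["R2"]), 0, tolerance = 1e-8)
  expect_lt(maxStoichResidual(m, fluxes(lin)), 1e-6)
})

test_that("single-gene deletion classifies isoenzymes, complexes, gatekeepers", {
  toy <- makeToyModel(nLinearSteps = 3, nDecoyBranches = 0)
  del <- singleGeneDeletion(toy$model)
  ess <- stats::setNames(del$essential, del$gene_id)
  # OR isoenzyme pair: neither member essential alone
  expect_false(ess[["gR1"]])
  expect_false(ess[["gR1iso"]])
  # AND complex: each subunit is an essential gatekeeper
  expect_true(ess[["gR2a"]])
  expect_true(ess[["gR2b"]])
  # unique gatekeeper of a chain step
  expect_true(ess[["gR3"]])
  expect_error(singleGeneDeletion(toy$model, geneIds = "not_a_gene"),
               "unknown gene")
  # a gene absent from every failing GPR leaves growth unchanged
  expect_equal(del$growth[del$gene_id == "gR1"], del$wild_type[1],
               tolerance = 1e-9)
})

test_that("MOMA-based deletion reports reduced mutant growth", {
  toy <- makeToyModel(nLinearSteps = 2, nDecoyBranches = 1)
  delF <- singleGeneDeletion(toy$model, method = "fba")
  delM <- singleGeneDeletion(toy$model, method = "moma")
  expect_identical(delF$gene_id, delM$gene_id)
  # MOMA growth never exceeds the FBA (re-optimized) mutant growth
  expect_true(all(delM$growth <= delF$growth + 1e-6))
})

test_that("flux sampling: feasibility, determinism, singleton polytopes", {
  toy <- makeToyModel(nLinearSteps = 2, nDecoyBranches = 1)
  s <- sampleFluxes(toy$model, 60, seed = 11)
  expect_identical(nrow(sampleMatrix(s)), 60L)
  S <- as.matrix(stoichiometricMatrix(toy$model))
  expect_lt(max(abs(S %*% t(sampleMatrix(s)))), 1e-6)
  rx <- reactions(toy$model)
  expect_true(all(t(sampleMatrix(s)) >= rx$lower_bound - 1e-6))
  expect_true(all(t(sampleMatrix(s)) <= rx$upper_bound + 1e-6))
  s2 <- sampleFluxes(toy$model, 60, seed = 11)
  expect_identical(sampleMatrix(s), sampleMatrix(s2))
  expect_false(identical(sampleMatrix(s),
                         sampleMatrix(sampleFluxes(toy$model, 60, seed = 12))))
  # fully fixed bounds: every sample is the forced point
  m <- chainModel()
  m <- setReactionBounds(m, reactions(m)$id, lower = c(-10, 10, 10, 10),
                         upper = c(-10, 10, 10, 10))
  sf <- sampleFluxes(m, 20, seed = 1)
  expect_equal(unname(apply(sampleMatrix(sf), 2, stats::sd)), rep(0, 4))
  # infeasible model errors before sampling
  bad <- setReactionBounds(chainModel(), c("EX_A", "T_A"),
                           lower = c(-10, 0), upper = c(-10, 0))
  expect_error(sampleFluxes(bad, 5, seed = 1), "infeasible")
})

test_that("uniform sampling of a free interval has the expected mean", {
  # one free reaction on [0, 10] (plus its forced companions)
  m <- MetabolicModel("interval",
    metabolites = data.frame(id = "A_c0"),
    reactions = data.frame(id = c("IN", "OUT"),
                           lower_bound = c(0, 0), upper_bound = c(10, 10)),
    stoichiometry = list(c(A_c0 = 1), c(A_c0 = -1)),
    objective = c(OUT = 1))
  s <- sampleFluxes(m, 5000, seed = 42, burnin = 200)
  expect_lt(abs(mean(sampleMatrix(s)[, "OUT"]) - 5), 0.5)
})

test_that("weighted sampling biases flux toward highly weighted reactions", {
  d <- diamondModel()
  wHigh <- c(DIRECT = 1, DECOY1 = 0.05, DECOY2 = 0.05)
  sH <- sampleFluxes(d, 200, seed = 3, weights = wHigh)
  medH <- apply(abs(sampleMatrix(sH)), 2, stats::median)
  expect_gt(medH[["DIRECT"]], medH[["DECOY1"]])
  # flipping the weights flips the preference
  wLow <- c(DIRECT = 0.05, DECOY1 = 1, DECOY2 = 1)
  sL <- sampleFluxes(d, 200, seed = 3, weights = wLow)
  medL <- apply(abs(sampleMatrix(sL)), 2, stats::median)
  expect_gt(medL[["DECOY1"]], medL[["DIRECT"]])
})

test_that("requesting the study-scale 500 samples yields 500 rows", {
  toy <- makeToyModel()
  s <- sampleFluxes(toy$model, 500, seed = 2)
  expect_identical(dim(sampleMatrix(s)),
                   c(500L, nrow(reactions(toy$model))))
})
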