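test_that("single-neighbour metabolite matches an exhaustive permutation", {
  # one metabolite with k = 1 neighbour gene; the corrected z-score and
  # p-value are computable exactly from the empirical background moments,
  # which for k = 1 equal the moments of the full z pool.
  m <- MetabolicModel("tiny",
    metabolites = data.frame(id = c("a_c0", "b_c0")),
    reactions = data.frame(id = c("R1", "R2"),
                           gpr = c("g1", "g2 or g3"), lower_bound = 0),
    stoichiometry = list(c(a_c0 = 1), c(b_c0 = 1)),
    objective = c(R1 = 1))
  scores <- data.frame(gene_id = c("g1", "g2", "g3"),
                       p_value = c(0.01, 0.4, 0.9))
  rt <- reporterMetabolites(m, scores, nBackground = 20000, seed = 1,
                            direction = "both",
                            currencyMetabolites = NULL)
  z <- qnorm(1 - scores$p_value)
  # exhaustive background for k = 1: population moments of the pool itself
  zc <- (z[1] - mean(z)) / sqrt(mean((z - mean(z))^2))
  row <- rt[rt$metabolite_id == "a_c0", ]
  expect_equal(row$k, 1L)
  expect_equal(row$z_raw, z[1], tolerance = 1e-12)
  # Monte-Carlo background estimates the (small-sample corrected) moments
  expect_equal(row$z_corrected, zc, tolerance = 0.05)
  expect_equal(row$p_reporter, pnorm(zc, lower.tail = FALSE),
               tolerance = 0.02)
})

test_that("uninformative scores produce no significant reporters", {
  toy <- makeToyModel(nLinearSteps = 4, nDecoyBranches = 2)
  scores <- data.frame(gene_id = genes(toy$model), p_value = 0.5)
  rt <- reporterMetabolites(toy$model, scores, nBackground = 500, seed = 2,
                            direction = "both")
  expect_true(all(rt$p_reporter > 0.05))
})

test_that("planted perturbations rank the perturbed metabolite first", {
  toy <- makeToyModel(nLinearSteps = 4, nDecoyBranches = 2)
  hits <- 0L
  for (seed in 1:5) {
    sc <- simulateDeScores(toy$model, "m2_c0", effect = 8, seed = seed)
    rt <- reporterMetabolites(toy$model, sc, nBackground = 400,
                              seed = seed)
    hits <- hits + as.integer(rt$metabolite_id[1] == "m2_c0")
  }
  expect_gte(hits, 4L)
})

test_that("neighbourhoods are deduplicated across duplicate reactions", {
  mk <- function(dup) {
    rx <- data.frame(id = c("R1", "R2", if (dup) "R1b"),
                     gpr = c("g1", "g2", if (dup) "g1"),
                     lower_bound = 0)
    MetabolicModel("dup",
      metabolites = data.frame(id = c("a_c0", "b_c0")),
      reactions = rx,
      stoichiometry = c(list(c(a_c0 = 1), c(a_c0 = -1, b_c0 = 1)),
                        if (dup) list(c(a_c0 = 1))),
      objective = c(R2 = 1))
  }
  scores <- data.frame(gene_id = c("g1", "g2"), p_value = c(0.02, 0.3))
  r1 <- reporterMetabolites(mk(FALSE), scores, nBackground = 300, seed = 5,
                            direction = "both", currencyMetabolites = NULL)
  r2 <- reporterMetabolites(mk(TRUE), scores, nBackground = 300, seed = 5,
                            direction = "both", currencyMetabolites = NULL)
  expect_equal(r1$z_raw[r1$metabolite_id == "a_c0"],
               r2$z_raw[r2$metabolite_id == "a_c0"])
  expect_equal(r1$k[r1$metabolite_id == "a_c0"],
               r2$k[r2$metabolite_id == "a_c0"])
})

test_that("reporter tables are deterministic in the seed", {
  toy <- makeToyModel(nLinearSteps = 3)
  sc <- simulateDeScores(toy$model, "m2_c0", effect = 3, seed = 7)
  r1 <- reporterMetabolites(toy$model, sc, nBackground = 300, seed = 9)
  r2 <- reporterMetabolites(toy$model, sc, nBackground = 300, seed = 9)
  expect_identical(r1, r2)
})

test_that("currency metabolites are excluded by default", {
  m <- MetabolicModel("cur",
    metabolites = data.frame(id = c("atp_c0", "a_c0")),
    reactions = data.frame(id = "R1", gpr = "g1", lower_bound = 0),
    stoichiometry = list(c(atp_c0 = -1, a_c0 = 1)),
    objective = c(R1 = 1))
  sc <- data.frame(gene_id = "g1", p_value = 0.01)
  rt <- reporterMetabolites(m, sc, nBackground = 200, seed = 1)
  expect_false("atp_c0" %in% rt$metabolite_id)
  expect_true("a_c0" %in% rt$metabolite_id)
  rt2 <- reporterMetabolites(m, sc, nBackground = 200, seed = 1,
                             currencyMetabolites = NULL)
  expect_true("atp_c0" %in% rt2$metabolite_id)
})

test_that("degenerate inputs are handled explicitly", {
  toy <- makeToyModel()
  sc <- data.frame(gene_id = genes(toy$model), p_value = 0.5)
  expect_warning(reporterMetabolites(toy$model, sc, nBackground = 50,
                                     seed = 1), "nBackground")
  expect_error(reporterMetabolites(
    toy$model, data.frame(gene_id = "nope", p_value = 0.5),
    nBackground = 200, seed = 1), "no scored genes")
  # p = 0 and p = 1 are clamped to finite z-scores
  sc2 <- data.frame(gene_id = genes(toy$model),
                    p_value = rep(c(0, 1), length.out = length(genes(toy$model))))
  rt <- reporterMetabolites(toy$model, sc2, nBackground = 200, seed = 1,
                            direction = "both")
  expect_true(all(is.finite(rt$z_raw)))
  expect_true(all(rt$p_reporter > 0 & rt$p_reporter < 1))
})

test_that("direction filtering analyses the requested gene set", {
  toy <- makeToyModel(nLinearSteps = 3)
  g <- genes(toy$model)
  sc <- data.frame(gene_id = g, p_value = 0.02,
                   direction = rep(c("up", "down"), length.out = length(g)))
  up <- reporterMetabolites(toy$model, sc, nBackground = 200, seed = 3,
                            direction = "up")
  both <- reporterMetabolites(toy$model, sc, nBackground = 200, seed = 3,
                              direction = "both")
  expect_true(all(up$k <= both$k[match(up$metabolite_id,
                                       both$metabolite_id)]))
})

test_that("simulated DE scores have the promised structure", {
  toy <- makeToyModel(nLinearSteps = 4)
  s1 <- simulateDeScores(toy$model, "m2_c0", effect = 5, seed = 3)
  s2 <- simulateDeScores(toy$model, "m2_c0", effect = 5, seed = 3)
  expect_identical(s1, s2)
  nb <- rhizoflux:::.metaboliteNeighbourGenes(toy$model)[["m2_c0"]]
  expect_lt(median(s1$p_value[s1$gene_id %in% nb]),
            median(s1$p_value[!s1$gene_id %in% nb]))
  expect_error(simulateDeScores(toy$model, "biomass_c0", 1, 1),
               "neighbour")
})
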