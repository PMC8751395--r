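test_that("confusion metrics follow the printed formulas", {
  m <- confusionMetrics(tp = 9, tn = 0, fp = 1, fn = 0)
  expect_equal(unname(m), c(0.9, 0.9, 1.0))
  # all-TN: accuracy 1, precision undefined (NA, not 0)
  m2 <- confusionMetrics(tp = 0, tn = 7, fp = 0, fn = 0)
  expect_equal(unname(m2[["accuracy"]]), 1)
  expect_true(is.na(m2[["precision"]]))
  expect_true(is.na(m2[["recall"]]))
  expect_error(confusionMetrics(0, 0, 0, 0), "empty")
})

test_that("confusion metrics equal independent arithmetic on random counts", {
  set.seed(99)
  for (i in 1:200) {
    x <- rpois(4, 10)
    if (sum(x) == 0) next
    m <- confusionMetrics(x[1], x[2], x[3], x[4])
    expect_identical(m[["accuracy"]], (x[1] + x[2]) / sum(x))
    expect_identical(m[["precision"]],
                     if (x[1] + x[3] > 0) x[1] / (x[1] + x[3]) else NA_real_)
    expect_identical(m[["recall"]],
                     if (x[1] + x[4] > 0) x[1] / (x[1] + x[4]) else NA_real_)
  }
})

test_that("confusion matrices are counted over the shared id set", {
  ids <- letters[1:10]
  a <- stats::setNames(rep(c(TRUE, FALSE), 5), ids)
  expect_equal(unname(buildConfusion(a, a)[c("fp", "fn")]), c(0L, 0L))
  expect_equal(sum(buildConfusion(a, a)[c("tp", "tn")]), 10)
  comp <- buildConfusion(a, !a)
  expect_equal(unname(comp[c("tp", "tn")]), c(0L, 0L))
  # planted disagreements on 2 of 10 ids
  b <- a
  b[c("c", "h")] <- !b[c("c", "h")]
  expect_equal(sum(buildConfusion(a, b)[c("fp", "fn")]), 2)
  # only the intersection counts
  expect_equal(attr(buildConfusion(a[1:6], b[4:10]), "n"), 3)
  expect_error(buildConfusion(a, stats::setNames(TRUE, "zz")), "shared")
})

test_that("measured fluxes are flagged against the FVA envelope", {
  toy <- makeToyModel(nLinearSteps = 2, nDecoyBranches = 1)
  pred <- fba(toy$model)
  ranges <- fva(toy$model, 0.95)
  measured <- data.frame(reaction_id = c("R1", "R2", "mfa_R1", "absent"),
                         mean = c(8, 25, -3, 1), sd = c(0.1, 0.2, 0.1, 0))
  mapping <- data.frame(external_name = "mfa_R1", model_reaction_id = "R1")
  cmp <- compareFluxes(pred, ranges, measured, mapping)
  expect_identical(attr(cmp, "unmapped"), "absent")
  # manual interval checks
  for (i in seq_len(nrow(cmp))) {
    expect_identical(cmp$within_range[i],
                     cmp$fva_min[i] <= cmp$measured_mean[i] &&
                     cmp$measured_mean[i] <= cmp$fva_max[i])
  }
  expect_false(cmp$within_range[cmp$measured_mean == 25])   # above envelope
  expect_false(cmp$within_range[cmp$measured_mean == -3])   # below envelope
  expect_equal(attr(cmp, "fractionInRange"), mean(cmp$within_range))
  # exact prediction is always inside its own envelope
  meas2 <- data.frame(reaction_id = "R1",
                      mean = unname(fluxes(pred)["R1"]), sd = 0)
  expect_true(compareFluxes(pred, ranges, meas2)$within_range)
})

test_that("amino-acid enrichment matches direct hypergeometric tail sums", {
  bg <- Biostrings::AAStringSet(c(p1 = "MHHHKLV", p2 = "MKKLVAA",
                                  p3 = "MAAAKLV"))
  sub <- Biostrings::AAStringSet(c(p1 = "MHHHKLV"))
  out <- aaEnrichment(bg, sub)
  expect_identical(out$amino_acid, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  N <- sum(out$count_background)
  n <- sum(out$count_subset)
  # direct tail sum for histidine (planted excess)
  hRow <- out[out$amino_acid == "H", ]
  pdirect <- sum(stats::dhyper(hRow$count_subset:min(hRow$count_background, n),
                               hRow$count_background,
                               N - hRow$count_background, n))
  expect_equal(hRow$p_raw, pdirect, tolerance = 1e-12)
  expect_lt(hRow$p_raw, 0.05)
  # BH adjustment preserves the order of raw p-values
  ord <- order(out$p_raw)
  expect_true(all(diff(out$p_adjusted[ord]) >= -1e-12))
  expect_equal(out$p_adjusted,
               stats::p.adjust(out$p_raw, "BH"))
})

test_that("identical subset and background show no enrichment", {
  bg <- Biostrings::AAStringSet(c(a = "MHKLVWA", b = "MPQRSTV"))
  out <- aaEnrichment(bg, bg)
  expect_true(all(out$p_raw[out$count_subset > 0] == 1))
  # subset not drawn from background errors
  sub <- Biostrings::AAStringSet(c(x = paste(rep("W", 50), collapse = "")))
  expect_error(aaEnrichment(bg, sub), "exceed")
})

test_that("FASTA files are accepted directly", {
  bgf <- withr::local_tempfile(fileext = ".faa")
  subf <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MHHHKLV", ">p2", "MKKLVAA"), bgf)
  writeLines(c(">p1", "MHHHKLV"), subf)
  out <- aaEnrichment(bgf, subf)
  expect_equal(out$count_subset[out$amino_acid == "H"], 3L)
  expect_equal(out$count_background[out$amino_acid == "H"], 3L)
})
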