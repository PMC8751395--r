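# Independent LP oracle: problems are serialized to JSON and solved with
# scipy's HiGHS-based linprog through the system python. The oracle
# formulates each problem directly (inequality rows as A_ub), independent of
# the package's equality-form surplus-variable encoding.

solveLpOracle <- function(problems) {
  inFile <- tempfile(fileext = ".json")
  outFile <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, inFile, auto_unbox = TRUE, digits = NA)
  script <- test_path("solve_lps.py")
  status <- system2("python", c(script, inFile, outFile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("LP oracle (python/scipy) failed")
  jsonlite::read_json(outFile, simplifyVector = FALSE)
}

# Oracle FVA: per-reaction min/max with the objective-fraction constraint
# expressed as an inequality row. Returns a data.frame like fva().
oracleFva <- function(model, fraction) {
  A <- as.matrix(stoichiometricMatrix(model))
  rx <- reactions(model)
  cvec <- numeric(nrow(rx))
  obj <- rhizoflux::objectiveCoefficients(model)
  cvec[match(names(obj), rx$id)] <- obj
  probs <- list(list(sense = "max", c = as.list(cvec),
                     A_eq = as.list(as.vector(t(A))),
                     m = nrow(A), n = ncol(A),
                     b_eq = as.list(numeric(nrow(A))),
                     lb = as.list(rx$lower_bound),
                     ub = as.list(rx$upper_bound)))
  opt <- solveLpOracle(probs)[[1]]$obj
  mk <- function(j, sense) {
    e <- numeric(nrow(rx)); e[j] <- 1
    list(sense = sense, c = as.list(e),
         A_eq = as.list(as.vector(t(A))), m = nrow(A), n = ncol(A),
         b_eq = as.list(numeric(nrow(A))),
         A_ub = as.list(-cvec), b_ub = -fraction * opt,
         lb = as.list(rx$lower_bound), ub = as.list(rx$upper_bound))
  }
  probs <- c(lapply(seq_len(nrow(rx)), mk, sense = "min"),
             lapply(seq_len(nrow(rx)), mk, sense = "max"))
  res <- solveLpOracle(probs)
  n <- nrow(rx)
  data.frame(reaction_id = rx$id,
             minimum = vapply(res[seq_len(n)], function(r) r$obj, 0),
             maximum = vapply(res[n + seq_len(n)], function(r) r$obj, 0),
             opt = opt)
}
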