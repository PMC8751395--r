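# Shared fixture builders and oracles for the test suite.

# Minimal hand-built model: EX_A (uptake <= 10) -> T_A -> R1 -> biomass.
chainModel <- function(uptake = 10) {
  MetabolicModel("chain",
    metabolites = data.frame(id = c("A_e0", "A_c0", "B_c0")),
    reactions = data.frame(id = c("EX_A", "T_A", "R1", "DM_B"),
                           lower_bound = c(-uptake, 0, 0, 0),
                           gpr = c("", "gT", "gR1", "")),
    stoichiometry = list(c(A_e0 = -1), c(A_e0 = -1, A_c0 = 1),
                         c(A_c0 = -1, B_c0 = 1), c(B_c0 = -1)),
    objective = c(R1 = 1))
}

# Diamond: direct route A -> B, decoy route A -> C -> B.
diamondModel <- function(uptake = 10) {
  MetabolicModel("diamond",
    metabolites = data.frame(id = c("A_e0", "A_c0", "C_c0", "B_c0")),
    reactions = data.frame(
      id = c("EX_A", "T_A", "DIRECT", "DECOY1", "DECOY2", "DM_B"),
      lower_bound = c(-uptake, 0, 0, 0, 0, 0),
      gpr = c("", "gT", "gD", "gC1", "gC2", "")),
    stoichiometry = list(
      c(A_e0 = -1), c(A_e0 = -1, A_c0 = 1), c(A_c0 = -1, B_c0 = 1),
      c(A_c0 = -1, C_c0 = 1), c(C_c0 = -1, B_c0 = 1), c(B_c0 = -1)),
    objective = c(DM_B = 1))
}

# Random toy drawn from the generator's parameter space.
randomToy <- function(seed) {
  set.seed(seed)
  makeToyModel(nLinearSteps = sample(1:5, 1),
               nDecoyBranches = sample(0:3, 1),
               withLoop = sample(c(TRUE, FALSE), 1),
               carbonSources = sample(1:2, 1),
               biomassYield = round(runif(1, 0.2, 1), 2),
               uptakeBound = sample(c(5, 10, 20), 1),
               seed = seed)
}

# Exhaustive truth-table evaluation of a GPR rule via R's own parser:
# substitute & and |, evaluate with logical bindings.
gprTruthOracle <- function(rule, deleted) {
  if (!nzchar(trimws(rule))) return(TRUE)
  expr <- gsub("\\band\\b", "&", rule, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  genes <- gprGenes(rule)
  env <- as.list(stats::setNames(!(genes %in% deleted), genes))
  eval(parse(text = expr), envir = env)
}

maxStoichResidual <- function(model, v) {
  max(abs(as.matrix(stoichiometricMatrix(model)) %*% v))
}
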