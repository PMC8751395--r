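# Generators for synthetic fixtures: mass-balanced toy models with known
# optima, expression profiles with planted active subnetworks, brute-force
# essentiality labels, and differential-expression score sets. These are
# first-class, tested generators: every property test and the acceptance
# suite run on them, so their defaults define the study conditions.

#' Generate a mass-balanced toy metabolic model with a known optimum
#'
#' Builds a small model with extracellular carbon sources (exchange +
#' transport), a linear catabolic chain, optional decoy branches that bypass
#' the first chain step through two-reaction detours, an optional internal
#' two-cycle (futile loop), a sink-supplied intracellular cofactor, a
#' biomass reaction and a biomass demand. GPR rules include plain genes, an
#' OR isoenzyme pair and an AND complex. The FBA optimum is analytic:
#' \code{carbonSources * uptakeBound * biomassYield}.
#'
#' @param nLinearSteps chain length (>= 1).
#' @param nDecoyBranches number of two-reaction decoy detours around the
#'   first chain step.
#' @param withLoop append an internal futile cycle.
#' @param carbonSources number of independent carbon inlets.
#' @param biomassYield biomass produced per unit carbon (> 0).
#' @param uptakeBound per-source uptake bound (flux units, default 10).
#' @param seed unused by the deterministic construction; kept so specs can
#'   carry one.
#' @return list with elements \code{model} (a
#'   \linkS4class{MetabolicModel}) and \code{optimum} (the analytic FBA
#'   optimum), plus \code{activeReactions} (the direct chain) and
#'   \code{decoyReactions}.
#' @examples
#' toy <- makeToyModel(nLinearSteps = 3, nDecoyBranches = 1)
#' toy$optimum
#' objectiveValue(fba(toy$model))
#' @export
makeToyModel <- function(nLinearSteps = 3, nDecoyBranches = 1,
                         withLoop = FALSE, carbonSources = 1,
                         biomassYield = 0.5, uptakeBound = 10, seed = 1) {
  stopifnot(nLinearSteps >= 1, nDecoyBranches >= 0, carbonSources >= 1,
            biomassYield > 0, uptakeBound > 0)
  mets <- list()
  rxns <- list()
  sto <- list()
  addMet <- function(id) mets[[length(mets) + 1L]] <<- id
  addRxn <- function(id, st, lb = 0, ub = 1000, gpr = "", kind = NA) {
    rxns[[length(rxns) + 1L]] <<- list(id = id, lb = lb, ub = ub, gpr = gpr,
                                       kind = kind)
    sto[[length(sto) + 1L]] <<- st
  }

  chain <- paste0("m", seq_len(nLinearSteps + 1L), "_c0")
  for (m in chain) addMet(m)
  addMet("cofact_c0")
  addMet("biomass_c0")

  for (s in seq_len(carbonSources)) {
    cs <- sprintf("cs%d_e0", s)
    addMet(cs)
    addRxn(sprintf("EX_cs%d", s), stats::setNames(-1, cs),
           lb = -uptakeBound, ub = 1000, kind = "exchange")
    addRxn(sprintf("T_cs%d", s), stats::setNames(c(-1, 1), c(cs, chain[1])),
           gpr = sprintf("gT%d", s), kind = "transport")
  }

  for (k in seq_len(nLinearSteps)) {
    gpr <- if (k == 1L) "gR1 or gR1iso"
           else if (k == 2L) "(gR2a and gR2b)"
           else sprintf("gR%d", k)
    addRxn(sprintf("R%d", k),
           stats::setNames(c(-1, 1), c(chain[k], chain[k + 1])),
           gpr = gpr, kind = "metabolic")
  }

  active <- c(sprintf("R%d", seq_len(nLinearSteps)),
              sprintf("T_cs%d", seq_len(carbonSources)))

  decoys <- character()
  if (nDecoyBranches > 0 && nLinearSteps >= 1) {
    for (d in seq_len(nDecoyBranches)) {
      dm <- sprintf("dmet%d_c0", d)
      addMet(dm)
      addRxn(sprintf("D%da", d), stats::setNames(c(-1, 1), c(chain[1], dm)),
             gpr = sprintf("gD%da or gD%db", d, d), kind = "metabolic")
      addRxn(sprintf("D%db", d), stats::setNames(c(-1, 1), c(dm, chain[2])),
             gpr = sprintf("gD%dc", d), kind = "metabolic")
      decoys <- c(decoys, sprintf("D%da", d), sprintf("D%db", d))
    }
  }

  if (withLoop) {
    addMet("lmet_c0")
    addRxn("LOOPF", stats::setNames(c(-1, 1), c(chain[2], "lmet_c0")),
           gpr = "gloopf", kind = "metabolic")
    addRxn("LOOPB", stats::setNames(c(-1, 1), c("lmet_c0", chain[2])),
           gpr = "gloopb", kind = "metabolic")
  }

  addRxn("SK_cofact", stats::setNames(-1, "cofact_c0"), lb = -1000, ub = 0,
         kind = "sink")
  last <- chain[nLinearSteps + 1L]
  addRxn("BIOMASS",
         stats::setNames(c(-1 / biomassYield, -0.01, 1),
                         c(last, "cofact_c0", "biomass_c0")),
         gpr = "", kind = "objective")
  addRxn("DM_biomass", stats::setNames(-1, "biomass_c0"), lb = 0, ub = 1000,
         kind = "demand")

  model <- MetabolicModel(
    id = sprintf("toy_L%d_D%d_C%d", nLinearSteps, nDecoyBranches,
                 carbonSources),
    metabolites = data.frame(id = unlist(mets), stringsAsFactors = FALSE),
    reactions = data.frame(
      id = vapply(rxns, `[[`, "", "id"),
      lower_bound = vapply(rxns, `[[`, 0, "lb"),
      upper_bound = vapply(rxns, `[[`, 0, "ub"),
      gpr = vapply(rxns, `[[`, "", "gpr"),
      kind = vapply(rxns, function(r)
        if (is.na(r$kind[1])) NA_character_ else r$kind, "",
        USE.NAMES = FALSE),
      stringsAsFactors = FALSE),
    stoichiometry = sto,
    objective = c(BIOMASS = 1))

  list(model = model, optimum = carbonSources * uptakeBound * biomassYield,
       activeReactions = active, decoyReactions = decoys)
}

#' Generate a toy model whose flux ranks track the objective fraction
#'
#' The model has one free degree of freedom: carbon uptake feeds a biomass
#' pathway whose steps carry a log-ladder of stoichiometric gains, so every
#' pathway flux scales with the biomass flux, which the objective-fraction
#' constraint confines to [fraction x optimum, optimum]. Alongside, a set
#' of forced constant-flux modules (sink -> conversion -> fixed demand)
#' carries flux levels that tile the range the biomass-pathway medians
#' sweep as the fraction varies. The rank order between pathway and
#' constant-module fluxes therefore changes monotonically with the
#' fraction, making the fraction identifiable from rank correlations with
#' an expression profile generated at one fraction. Used for
#' objective-fraction recovery fixtures.
#'
#' @param nSteps biomass-pathway reactions (>= 2).
#' @param nConstant forced constant-flux modules (>= 2).
#' @param uptake carbon uptake bound (flux units).
#' @param seed seed for the gain/level jitter.
#' @return list(model, optimum) as for \code{\link{makeToyModel}}.
#' @export
makeTradeoffToy <- function(nSteps = 6, nConstant = 16, uptake = 10,
                            seed = 1) {
  stopifnot(nSteps >= 2, nConstant >= 2)
  .withSeed(seed, function() {
    mets <- c("A_e0", "A_c0")
    rxns <- list(); sto <- list()
    addRxn <- function(id, st, lb = 0, ub = 1000, gpr = "", kind = NA) {
      rxns[[length(rxns) + 1L]] <<- list(id = id, lb = lb, ub = ub,
                                         gpr = gpr, kind = kind)
      sto[[length(sto) + 1L]] <<- st
    }
    addRxn("EX_A", c(A_e0 = -1), lb = -uptake, ub = 0, kind = "exchange")
    addRxn("T_A", c(A_e0 = -1, A_c0 = 1), gpr = "gT", kind = "transport")
    # biomass pathway: cumulative gains form a log-ladder over [-2, 2]
    cumlog <- seq(-2, 2, length.out = nSteps) +
      stats::runif(nSteps, -0.05, 0.05)
    prev <- "A_c0"; prevlog <- 0
    for (k in seq_len(nSteps)) {
      mid <- sprintf("B%d_c0", k)
      mets <- c(mets, mid)
      addRxn(sprintf("B%d", k),
             stats::setNames(c(-1, exp(cumlog[k] - prevlog)), c(prev, mid)),
             gpr = sprintf("gB%d", k), kind = "metabolic")
      prev <- mid; prevlog <- cumlog[k]
    }
    mets <- c(mets, "biomass_c0")
    addRxn("BIOMASS", stats::setNames(c(-1, 1), c(prev, "biomass_c0")),
           kind = "objective")
    addRxn("DM_biomass", c(biomass_c0 = -1), lb = 0, kind = "demand")
    # constant-flux modules: levels tile the window the pathway-head median
    # sweeps (roughly 0.6 x uptake .. uptake), combined with the pathway
    # gain ladder so rank crossings occur throughout the fraction range
    window <- log(c(0.875, 0.9875) * uptake)
    thr <- window[1] + (seq_len(nConstant) - 0.5) / nConstant *
      diff(window) + stats::runif(nConstant, -0.01, 0.01)
    lvl <- exp(thr + cumlog[(seq_len(nConstant) - 1L) %% nSteps + 1L])
    for (j in seq_len(nConstant)) {
      fm <- sprintf("f%d_c0", j); wm <- sprintf("w%d_c0", j)
      mets <- c(mets, fm, wm)
      addRxn(sprintf("SK_f%d", j), stats::setNames(-1, fm), lb = -1000,
             ub = 0, kind = "sink")
      addRxn(sprintf("C%d", j), stats::setNames(c(-1, 1), c(fm, wm)),
             gpr = sprintf("gC%d", j), kind = "metabolic")
      addRxn(sprintf("DM_w%d", j), stats::setNames(-1, wm), lb = lvl[j],
             ub = lvl[j], kind = "demand")
    }
    model <- MetabolicModel(
      id = sprintf("tradeoff_%d", seed),
      metabolites = data.frame(id = mets, stringsAsFactors = FALSE),
      reactions = data.frame(
        id = vapply(rxns, `[[`, "", "id"),
        lower_bound = vapply(rxns, `[[`, 0, "lb"),
        upper_bound = vapply(rxns, `[[`, 0, "ub"),
        gpr = vapply(rxns, `[[`, "", "gpr"),
        stringsAsFactors = FALSE),
      stoichiometry = sto,
      objective = c(BIOMASS = 1))
    opt <- objectiveValue(fba(model))
    list(model = model, optimum = opt)
  })
}

#' Describe a planted expression context
#'
#' @param activeReactions reactions whose genes are highly expressed.
#' @param decoyReactions reactions whose genes are lowly expressed.
#' @param trueFraction the objective fraction the context was generated at,
#'   in (0, 1].
#' @param noiseSd lognormal noise scale (sdlog); 0 gives exact means.
#' @param seed integer seed.
#' @return a list of class "plantedContext".
#' @export
plantedContext <- function(activeReactions, decoyReactions = character(),
                           trueFraction = 0.8, noiseSd = 0.2, seed = 1) {
  stopifnot(trueFraction > 0, trueFraction <= 1, noiseSd >= 0,
            !length(intersect(activeReactions, decoyReactions)))
  structure(list(activeReactions = activeReactions,
                 decoyReactions = decoyReactions,
                 trueFraction = trueFraction, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "plantedContext")
}

#' Simulate an expression profile with a planted active subnetwork
#'
#' Genes of active reactions are drawn lognormally around a high mean,
#' genes of decoy reactions around a low mean (10x separation), all other
#' genes around the geometric midpoint. RPKM-like abundances are heavy-
#' tailed and right-skewed, which the lognormal emulates; with
#' \code{noiseSd = 0} the medians are hit exactly.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param context a \code{\link{plantedContext}}.
#' @param highMean,lowMean median abundance for active and decoy genes.
#' @return an \linkS4class{ExpressionProfile}.
#' @export
simulateExpression <- function(model, context, highMean = 100,
                               lowMean = 10) {
  stopifnot(inherits(context, "plantedContext"))
  sets <- .reactionGeneSets(model)
  names(sets) <- model@reactions$id
  noGpr <- intersect(context$activeReactions,
                     model@reactions$id[!.geneAssociated(model)])
  if (length(noGpr))
    warning("active reactions without GPR: ", paste(noGpr, collapse = ", "))
  activeGenes <- unique(unlist(sets[context$activeReactions]))
  decoyGenes <- setdiff(unique(unlist(sets[context$decoyReactions])),
                        activeGenes)
  .withSeed(context$seed, function() {
    g <- model@genes
    mid <- sqrt(highMean * lowMean)
    mu <- ifelse(g %in% activeGenes, highMean,
                 ifelse(g %in% decoyGenes, lowMean, mid))
    ab <- mu * exp(context$noiseSd * stats::rnorm(length(g)))
    methods::new("ExpressionProfile", abundance = stats::setNames(ab, g),
                 condition = sprintf("planted_f%.3g", context$trueFraction))
  })
}

#' Simulate expression consistent with fluxes at a given objective fraction
#'
#' Samples the model's flux space under the constraint that the objective
#' carries at least \code{fraction} of its optimum, takes per-reaction
#' median absolute fluxes, and assigns each gene an abundance proportional
#' to the largest median flux among its reactions (floored so unused genes
#' keep a small positive abundance), with lognormal noise. An
#' objective-fraction sweep over such a profile should recover
#' \code{fraction}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param fraction objective fraction the profile encodes, in (0, 1].
#' @param seed integer seed.
#' @param noiseSd lognormal noise scale.
#' @param nSamples flux samples used for the reference medians.
#' @param scale abundance per unit flux.
#' @return an \linkS4class{ExpressionProfile}.
#' @export
simulateContextExpression <- function(model, fraction, seed, noiseSd = 0.003,
                                      nSamples = 300, scale = 10) {
  stopifnot(fraction > 0, fraction <= 1)
  opt <- objectiveValue(fba(model))
  aug <- .constrainObjective(model, fraction, opt)
  sets <- .reactionGeneSets(model)
  medToAbundance <- function(med, noise) {
    vapply(seq_along(model@genes), function(gi) {
      g <- model@genes[gi]
      r <- vapply(sets, function(s) g %in% s, logical(1))
      v <- if (any(r)) max(med[r]) else 0
      max(scale * v, 0.5) * noise[gi]
    }, numeric(1))
  }
  # Two passes: a first unweighted pass yields provisional abundances from
  # which sampling weights are derived, and the emitted profile comes from a
  # weighted pass with those weights. This keeps the generator consistent
  # with the weighted sampling that a fraction sweep applies when it
  # evaluates candidate fractions.
  fs0 <- sampleFluxes(aug$model, nSamples, seed = seed)
  med0 <- apply(abs(sampleMatrix(fs0)[, model@reactions$id, drop = FALSE]),
                2, stats::median)
  ab0 <- medToAbundance(med0, rep(1, length(model@genes)))
  prof0 <- methods::new("ExpressionProfile",
                        abundance = stats::setNames(ab0, model@genes),
                        condition = "provisional")
  w0 <- expressionToReactionWeights(model, prof0)
  wSub <- w0[intersect(names(w0), aug$model@reactions$id)]
  wSub[aug$surplusId] <- 1
  fs1 <- sampleFluxes(aug$model, nSamples, seed = seed, weights = wSub)
  med1 <- apply(abs(sampleMatrix(fs1)[, model@reactions$id, drop = FALSE]),
                2, stats::median)
  .withSeed(seed + 1L, function() {
    noise <- exp(noiseSd * stats::rnorm(length(model@genes)))
    ab <- medToAbundance(med1, noise)
    methods::new("ExpressionProfile",
                 abundance = stats::setNames(ab, model@genes),
                 condition = sprintf("context_f%.3g", fraction))
  })
}

#' Brute-force gene essentiality labels
#'
#' Independent oracle for \code{\link{singleGeneDeletion}}: for each gene,
#' finds the reactions whose GPR fails under the deletion, zeroes their
#' bounds, and re-solves the FBA LP built directly from the stoichiometric
#' matrix. Essential when mutant growth < threshold x wild type.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param threshold growth-ratio threshold (default 0.5).
#' @return data.frame with columns gene_id, growth, essential.
#' @export
bruteForceEssentiality <- function(model, threshold = 0.5) {
  lp <- .modelLP(model)
  wt <- .solveLP(lp$c, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (wt$status != "optimal") stop("model is not FBA-feasible")
  growth <- vapply(model@genes, function(g) {
    lb <- lp$lb; ub <- lp$ub
    off <- !vapply(model@reactions$gpr, evaluateGpr, logical(1),
                   deletedGenes = g)
    lb[off] <- ub[off] <- 0
    res <- .solveLP(lp$c, lp$A, lp$b, lb, ub, maximize = TRUE)
    if (res$status == "optimal") res$objval else 0
  }, numeric(1))
  data.frame(gene_id = model@genes, growth = unname(growth),
             essential = unname(growth) < threshold * wt$objval,
             stringsAsFactors = FALSE)
}

#' Simulate differential-expression scores around a perturbed metabolite
#'
#' Genes neighbouring the metabolite (via the GPRs of its reactions) receive
#' p-values from a shifted null \eqn{p = u^{1+effect}}; all other genes are
#' uniform. With \code{effect = 0} everything is uniform.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param perturbedMetabolite metabolite id.
#' @param effect non-negative effect size.
#' @param seed integer seed.
#' @return data.frame with columns gene_id, p_value, direction.
#' @export
simulateDeScores <- function(model, perturbedMetabolite, effect, seed) {
  stopifnot(effect >= 0)
  nb <- .metaboliteNeighbourGenes(model)
  if (!perturbedMetabolite %in% names(nb) ||
      !length(nb[[perturbedMetabolite]]))
    stop("metabolite ", sQuote(perturbedMetabolite),
         " has no neighbour genes")
  hot <- nb[[perturbedMetabolite]]
  .withSeed(seed, function() {
    u <- stats::runif(length(model@genes))
    p <- ifelse(model@genes %in% hot, u^(1 + effect), u)
    data.frame(gene_id = model@genes, p_value = p, direction = "up",
               stringsAsFactors = FALSE)
  })
}
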