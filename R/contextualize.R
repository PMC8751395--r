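#' Construct an ExpressionProfile
#'
#' @param abundance named non-negative numeric vector, gene id -> abundance
#'   (RPKM or similar).
#' @param condition condition label.
#' @return an \linkS4class{ExpressionProfile}.
#' @export
ExpressionProfile <- function(abundance, condition = "unspecified") {
  methods::new("ExpressionProfile", abundance = abundance,
               condition = condition)
}

#' Read an expression profile from TSV (columns gene_id, rpkm)
#'
#' @param path TSV file path.
#' @param condition condition label (default: file base name).
#' @return an \linkS4class{ExpressionProfile}.
#' @export
readExpression <- function(path, condition = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm") %in% names(df)))
    stop("expression file needs columns gene_id and rpkm")
  ExpressionProfile(stats::setNames(df$rpkm, df$gene_id),
                    condition = if (is.null(condition))
                      sub("\\.[^.]*$", "", basename(path)) else condition)
}

#' Define the protected tasks for model contextualization
#'
#' Tasks prevent the pruning step from discarding functions known to be
#' required in a condition: reactions of protected genes (e.g. genes
#' essential in that environment) are never removed, and forced reactions
#' (e.g. demand reactions for exopolysaccharide, lipopolysaccharide or Nod
#' factor synthesis) receive a positive minimum flux.
#'
#' @param protectedGenes character vector of gene ids.
#' @param forcedReactions named numeric vector, reaction id -> minimum flux
#'   (non-negative).
#' @return a list of class "taskSet".
#' @export
taskSet <- function(protectedGenes = character(),
                    forcedReactions = numeric()) {
  if (length(forcedReactions) &&
      (is.null(names(forcedReactions)) || any(forcedReactions < 0)))
    stop("forcedReactions must be a named vector of non-negative minima")
  structure(list(protectedGenes = as.character(protectedGenes),
                 forcedReactions = forcedReactions), class = "taskSet")
}

#' Read a task gene list (one gene id per line)
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
readTaskGenes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read forced-reaction minima from TSV (columns reaction_id, min_flux)
#' @param path TSV file path.
#' @return named numeric vector.
#' @export
readForcedReactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "min_flux") %in% names(df)))
    stop("forced-reaction file needs columns reaction_id and min_flux")
  stats::setNames(df$min_flux, df$reaction_id)
}

# Aggregated transcript abundance per reaction: OR = max (isoenzymes add
# capacity), AND = min (a complex is limited by its scarcest subunit).
# Genes missing from the profile contribute the median observed abundance.
.reactionAbundance <- function(model, expr) {
  ab <- expr@abundance
  overlap <- intersect(names(ab), model@genes)
  if (!length(overlap))
    stop("no overlap between expression profile genes and model genes")
  med <- stats::median(ab[overlap])
  vapply(model@reactions$gpr, .gprAggregate, numeric(1), values = ab,
         missing = med, USE.NAMES = FALSE)
}

#' Map transcript abundances to reaction weights
#'
#' Aggregates gene abundance over each reaction's GPR (OR = max, AND = min),
#' then normalizes by the maximum over gene-associated reactions so weights
#' lie in [0, 1]. Reactions without gene association receive the median
#' gene-associated weight.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param expr an \linkS4class{ExpressionProfile} overlapping the model's
#'   genes.
#' @return named numeric vector of weights (reaction id -> [0, 1]), with
#'   attribute \code{"abundance"} holding the aggregated per-reaction
#'   abundances.
#' @export
expressionToReactionWeights <- function(model, expr) {
  a <- .reactionAbundance(model, expr)
  ga <- .geneAssociated(model)
  if (!any(ga)) stop("model has no gene-associated reactions")
  w <- rep(NA_real_, length(a))
  mx <- max(a[ga])
  w[ga] <- if (mx > 0) a[ga] / mx else 1
  w[!ga] <- stats::median(w[ga])
  names(w) <- model@reactions$id
  attr(w, "abundance") <- stats::setNames(a, model@reactions$id)
  w
}

# Augment a model with the constraint c'v >= fraction * opt, encoded as a
# pseudo-metabolite balanced by a surplus pseudo-reaction with lower bound
# fraction * opt. Sampling / FBA machinery then applies unchanged.
.constrainObjective <- function(model, fraction, opt) {
  pseudoMet <- ".objcon_x0"
  surplus <- ".OBJCON"
  met <- rbind(model@metabolites,
               data.frame(id = pseudoMet, name = "objective constraint",
                          compartment = "x0", formula = NA_character_,
                          charge = NA_integer_, stringsAsFactors = FALSE))
  cvec <- numeric(nrow(model@reactions))
  cvec[match(names(model@objective), model@reactions$id)] <- model@objective
  S <- rbind(model@stoichiometry, Matrix::Matrix(cvec, 1,
                                                 sparse = TRUE))
  rownames(S) <- met$id
  scol <- Matrix::sparseMatrix(i = nrow(met), j = 1L, x = -1,
                               dims = c(nrow(met), 1L),
                               dimnames = list(met$id, surplus))
  S <- cbind(S, scol)
  rxn <- rbind(model@reactions,
               data.frame(id = surplus, name = "objective surplus",
                          lower_bound = fraction * opt, upper_bound = 1e6,
                          gpr = "", kind = "demand",
                          stringsAsFactors = FALSE))
  rownames(rxn) <- NULL
  aug <- methods::new("MetabolicModel", metabolites = met, reactions = rxn,
                      stoichiometry = .asDgC(S), genes = model@genes,
                      objective = model@objective, id = model@id)
  list(model = aug, surplusId = surplus)
}

#' Extract a context-specific model by expression-weighted pruning
#'
#' Solves the weighted parsimony LP \eqn{\min \sum_r (1 - w_r) |v_r|}
#' subject to the steady state, bounds, the objective carrying at least
#' \code{objectiveFraction} of its FBA optimum, and any forced task minima.
#' A reaction is removed only when its flux is below the zero threshold in
#' that solution \emph{and} it cannot carry flux in any solution within the
#' same constraints plus the weighted-parsimony budget (an FVA check), so
#' alternates that sampling would use are preserved. Reactions of protected
#' genes, forced reactions and objective reactions are never removed.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param weights named weight vector from
#'   \code{\link{expressionToReactionWeights}}.
#' @param tasks optional \code{\link{taskSet}}.
#' @param objectiveFraction fraction of the optimum in (0, 1].
#' @param zeroTol flux magnitude below which a reaction counts as inactive
#'   (default 1e-6).
#' @return list with elements \code{model} (pruned), \code{removed},
#'   \code{optimum} (FBA optimum of the input under tasks) and
#'   \code{weightedOptimum} (the parsimony budget).
#' @export
pruneModel <- function(model, weights, tasks = NULL, objectiveFraction,
                       zeroTol = 1e-6) {
  stopifnot(objectiveFraction > 0, objectiveFraction <= 1)
  forced <- character()
  protectedGenes <- character()
  if (!is.null(tasks)) {
    stopifnot(inherits(tasks, "taskSet"))
    protectedGenes <- tasks$protectedGenes
    missing <- setdiff(protectedGenes, model@genes)
    if (length(missing))
      warning("protected genes absent from model: ",
              paste(missing, collapse = ", "))
    if (length(tasks$forcedReactions)) {
      forced <- names(tasks$forcedReactions)
      model <- setReactionBounds(model, forced,
        lower = pmax(tasks$forcedReactions,
                     model@reactions$lower_bound[
                       match(forced, model@reactions$id)]))
    }
  }
  base <- fba(model)
  if (base@status != "optimal")
    stop("model infeasible under task constraints (status: ", base@status,
         "); conflicting constraints: forced minima {",
         paste(forced, collapse = ", "), "} + objective fraction ",
         objectiveFraction)
  opt <- base@objectiveValue

  wvec <- weights[model@reactions$id]
  wvec[is.na(wvec)] <- stats::median(weights, na.rm = TRUE)
  wvec <- pmin(pmax(as.numeric(wvec), 0), 1)
  cost <- 1 - wvec

  lp <- .addFractionRow(.modelLP(model), objectiveFraction, opt)
  sp <- .splitLP(lp, extraCols = 1L)
  costSplit <- c(cost, cost, numeric(sp$extraCols))
  res <- .solveLP(costSplit, sp$A, sp$b, sp$lb, sp$ub, maximize = FALSE)
  if (res$status != "optimal")
    stop("weighted parsimony LP not optimal (", res$status, ")")
  v <- .unsplit(res$x, sp$n)
  wOpt <- sum(cost * abs(v))

  geneSets <- .reactionGeneSets(model)
  protectedRxn <- vapply(geneSets, function(s)
    any(s %in% protectedGenes), logical(1))
  keepAlways <- protectedRxn | model@reactions$id %in% forced |
    model@reactions$id %in% names(model@objective) |
    model@reactions$kind == "objective"

  candidates <- which(abs(v) < zeroTol & !keepAlways)

  removed <- character()
  if (length(candidates)) {
    # FVA on the net flux under the same constraints plus an (essentially
    # tight) parsimony budget: a reaction survives only if some solution
    # within the weighted-flux budget can route flux through it.
    nb <- ncol(sp$A)
    budgetRow <- c(cost, cost, numeric(sp$extraCols), 1)
    A2 <- rbind(cbind(sp$A, 0), budgetRow)
    b2 <- c(sp$b, wOpt + 1e-9 * (1 + abs(wOpt)))
    lb2 <- c(sp$lb, 0)
    ub2 <- c(sp$ub, .LP_BIG)
    for (k in candidates) {
      obj <- numeric(nb + 1)
      obj[k] <- 1
      obj[sp$n + k] <- -1
      mx <- .solveLP(obj, A2, b2, lb2, ub2, maximize = TRUE)
      mn <- .solveLP(obj, A2, b2, lb2, ub2, maximize = FALSE)
      env <- max(abs(c(if (mx$status == "optimal") mx$objval else Inf,
                       if (mn$status == "optimal") mn$objval else Inf)))
      if (env < zeroTol) removed <- c(removed, model@reactions$id[k])
    }
  }
  pruned <- removeReactions(model, removed)
  check <- fba(pruned)
  if (check@status != "optimal" ||
      check@objectiveValue < objectiveFraction * opt - 1e-6)
    stop("internal error: pruned model lost feasibility")
  list(model = pruned, removed = removed, optimum = opt,
       weightedOptimum = wOpt)
}

#' Spearman correlation between sampled fluxes and transcript abundance
#'
#' Correlates per-reaction median absolute flux (across samples) with the
#' aggregated transcript abundance of the same reactions, using a
#' tie-corrected Spearman rank test.
#'
#' @param samples a \linkS4class{FluxSampleSet} or a samples matrix with
#'   reaction-id column names.
#' @param abundance named numeric vector, reaction id -> aggregated
#'   abundance; only reactions present in both are used (>= 3 required).
#' @return named numeric vector c(rho, p).
#' @export
correlateFluxExpression <- function(samples, abundance) {
  m <- if (is(samples, "FluxSampleSet")) samples@samples else samples
  common <- intersect(colnames(m), names(abundance))
  if (length(common) < 3)
    stop("need at least 3 reactions in common to correlate")
  med <- apply(abs(m[, common, drop = FALSE]), 2, stats::median)
  ct <- suppressWarnings(stats::cor.test(med, abundance[common],
                                         method = "spearman",
                                         exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Objective-fraction sweep ("max fit") contextualization
#'
#' For each candidate objective fraction: prunes the model with
#' \code{\link{pruneModel}}, draws expression-weighted flux samples under
#' the same objective-fraction constraint, and computes the Spearman
#' correlation between per-reaction median absolute flux and transcript
#' abundance. After the coarse grid, one refinement pass evaluates the two
#' midpoints flanking the best fraction (half the grid step), which is how
#' a best fraction off the coarse grid (e.g. 77.5\% from a 5\% grid) can
#' arise. The result with maximal correlation is returned.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param expr an \linkS4class{ExpressionProfile}.
#' @param tasks optional \code{\link{taskSet}}.
#' @param fractions candidate fractions in (0, 1] (default 0.5 to 0.95 by
#'   0.05).
#' @param nSamples flux samples per fraction (default 500).
#' @param seed integer seed; per-fraction sampler seeds are derived from it.
#' @param correlateOn "gene" restricts the correlation to gene-associated
#'   reactions (default), "all" uses every reaction.
#' @param refine run the bisection refinement pass (default TRUE).
#' @return a \linkS4class{ContextualizationResult}.
#' @export
maxFit <- function(model, expr, tasks = NULL,
                   fractions = seq(0.5, 0.95, by = 0.05), nSamples = 500,
                   seed = 1, correlateOn = c("gene", "all"), refine = TRUE) {
  stopifnot(length(fractions) >= 1, all(fractions > 0), all(fractions <= 1))
  correlateOn <- match.arg(correlateOn)
  weights <- expressionToReactionWeights(model, expr)
  abundance <- attr(weights, "abundance")
  ga <- stats::setNames(.geneAssociated(model), model@reactions$id)

  evalFraction <- function(f) {
    pr <- tryCatch(pruneModel(model, weights, tasks, f),
                   error = function(e) NULL)
    if (is.null(pr)) return(NULL)
    pm <- pr$model
    aug <- .constrainObjective(pm, f, pr$optimum)
    wSub <- weights[intersect(names(weights), pm@reactions$id)]
    wSub[aug$surplusId] <- 1  # bookkeeping variable: never penalized
    fs <- tryCatch(
      sampleFluxes(aug$model, nSamples, seed = seed + round(1000 * f),
                   weights = wSub),
      error = function(e) NULL)
    if (is.null(fs)) return(NULL)
    keepCols <- setdiff(colnames(fs@samples), aug$surplusId)
    smp <- fs@samples[, keepCols, drop = FALSE]
    rids <- if (correlateOn == "gene")
      keepCols[ga[keepCols]] else keepCols
    cr <- tryCatch(correlateFluxExpression(smp, abundance[rids]),
                   error = function(e) c(rho = NA_real_, p = NA_real_))
    list(fraction = f, prune = pr,
         samples = methods::new("FluxSampleSet", samples = smp,
                                seed = fs@seed, sampler = fs@sampler),
         rho = cr[["rho"]], p = cr[["p"]])
  }

  evaluated <- list()
  for (f in sort(unique(fractions)))
    evaluated[[sprintf("%.6g", f)]] <- evalFraction(f)
  ok <- !vapply(evaluated, is.null, logical(1))
  if (!any(ok)) stop("all objective fractions were infeasible")
  rhos <- vapply(evaluated[ok], function(e)
    ifelse(is.na(e$rho), -Inf, e$rho), numeric(1))
  best <- evaluated[ok][[which.max(rhos)]]

  if (refine && length(fractions) > 1) {
    step <- min(diff(sort(unique(fractions))))
    for (f in c(best$fraction - step / 2, best$fraction + step / 2)) {
      if (f <= 0 || f > 1) next
      key <- sprintf("%.6g", f)
      if (!is.null(evaluated[[key]])) next
      e <- evalFraction(f)
      evaluated[[key]] <- e
      if (!is.null(e) && !is.na(e$rho) && e$rho > best$rho) best <- e
    }
  }

  upt <- tryCatch(
    .uptakeSummary(best$samples@samples, best$prune$model),
    error = function(e) data.frame(metabolite = character(),
                                   median = numeric(), iqr = numeric()))
  rhoGrid <- vapply(evaluated, function(e)
    if (is.null(e)) NA_real_ else e$rho, numeric(1))
  methods::new("ContextualizationResult",
    prunedModel = best$prune$model, samples = best$samples,
    objectiveFraction = best$fraction, rho = best$rho, rhoP = best$p,
    removedReactions = best$prune$removed, uptakeSummary = upt,
    metadata = list(fractions = names(rhoGrid), rho = unname(rhoGrid),
                    seed = seed, nSamples = nSamples,
                    correlateOn = correlateOn,
                    gprAggregation = "OR=max, AND=min"))
}

# Core of summarizeUptake, operating on a samples matrix + model.
.uptakeSummary <- function(m, model, objectiveReaction = NULL) {
  if (is.null(objectiveReaction))
    objectiveReaction <- names(model@objective)[1]
  if (!objectiveReaction %in% colnames(m))
    stop("objective reaction ", sQuote(objectiveReaction),
         " absent from samples")
  objFlux <- m[, objectiveReaction]
  if (any(objFlux <= 1e-9))
    stop("zero objective flux in at least one sample; ",
         "normalized uptake undefined")
  exIdx <- which(model@reactions$kind == "exchange" &
                 model@reactions$id %in% colnames(m))
  rows <- lapply(exIdx, function(k) {
    rid <- model@reactions$id[k]
    met <- rownames(model@stoichiometry)[
      which(model@stoichiometry[, k] != 0)[1]]
    u <- pmax(-m[, rid], 0) / objFlux
    data.frame(metabolite = met, median = stats::median(u),
               iqr = stats::IQR(u), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    return(data.frame(metabolite = character(), median = numeric(),
                      iqr = numeric()))
  out[out$median > 0, , drop = FALSE]
}

#' Biomass-normalized nutrient uptake summary
#'
#' For every exchange reaction of the contextualized model, divides the
#' uptake flux (negative exchange flux, zero when secreting) by the
#' objective flux in each sample and reports the median and interquartile
#' range; metabolites with zero median uptake are dropped, and metabolites
#' secreted in all samples therefore never appear.
#'
#' @param result a \linkS4class{ContextualizationResult}.
#' @param objectiveReaction reaction id to normalize by (default: the first
#'   objective reaction of the pruned model).
#' @return data.frame with columns metabolite, median, iqr.
#' @export
summarizeUptake <- function(result, objectiveReaction = NULL) {
  stopifnot(is(result, "ContextualizationResult"))
  .uptakeSummary(result@samples@samples, result@prunedModel,
                 objectiveReaction)
}
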