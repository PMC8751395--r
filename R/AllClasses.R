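#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Matrix dgCMatrix
#' @useDynLib rhizoflux, .registration = TRUE
NULL

# canonical sparse storage for stoichiometric matrices
.asDgC <- function(S) {
  methods::as(methods::as(methods::as(S, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

#' MetabolicModel: a constraint-based metabolic network
#'
#' Container for a genome-scale (or toy) metabolic model: the stoichiometric
#' matrix \eqn{S} (metabolites x reactions), flux bounds, the linear objective
#' \eqn{c}, gene-protein-reaction (GPR) rules and per-reaction classification.
#' Steady-state flux vectors \eqn{v} satisfy \eqn{S v = 0} and
#' \eqn{lb \le v \le ub}.
#'
#' Reaction kinds follow the usual constraint-based conventions:
#' \describe{
#'   \item{metabolic}{enzymatic conversion within a compartment}
#'   \item{transport}{moves metabolites between compartments}
#'   \item{exchange}{boundary reaction for an extracellular metabolite;
#'     negative flux is uptake, positive flux is secretion}
#'   \item{sink}{boundary reaction supplying an intracellular metabolite
#'     (lb < 0, ub <= 0 when used as pure supply)}
#'   \item{demand}{boundary reaction consuming an intracellular metabolite
#'     (lb >= 0)}
#'   \item{objective}{objective-support pseudo-reactions such as biomass}
#' }
#'
#' @slot metabolites data.frame with columns id, name, compartment, formula,
#'   charge (one row per metabolite).
#' @slot reactions data.frame with columns id, name, lower_bound, upper_bound,
#'   gpr, kind (one row per reaction).
#' @slot stoichiometry sparse \code{Matrix::dgCMatrix}, metabolites x
#'   reactions, dimnames set to the respective ids.
#' @slot genes character vector of gene identifiers.
#' @slot objective named numeric vector of objective weights over reaction
#'   ids (the vector c).
#' @slot id character scalar, model identifier.
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "dgCMatrix",
    genes = "character",
    objective = "numeric",
    id = "character"
  )
)

.reactionKinds <- c("metabolic", "transport", "exchange", "sink", "demand",
                    "objective")

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment", "formula", "charge")
  need_rxn <- c("id", "name", "lower_bound", "upper_bound", "gpr", "kind")
  if (!all(need_met %in% names(met)))
    msg <- c(msg, "metabolites must have columns id, name, compartment, formula, charge")
  if (!all(need_rxn %in% names(rxn)))
    msg <- c(msg, "reactions must have columns id, name, lower_bound, upper_bound, gpr, kind")
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (nrow(met) && any(!nzchar(met$compartment)))
    msg <- c(msg, "metabolite compartments must be non-empty")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msg <- c(msg, "stoichiometry dimensions do not match metabolite/reaction tables")
  if (nrow(met) && !identical(rownames(S), met$id))
    msg <- c(msg, "stoichiometry rownames must equal metabolite ids")
  if (nrow(rxn) && !identical(colnames(S), rxn$id))
    msg <- c(msg, "stoichiometry colnames must equal reaction ids")
  if (any(rxn$lower_bound > rxn$upper_bound + 1e-12))
    msg <- c(msg, "lower_bound > upper_bound for some reactions")
  if (!all(rxn$kind %in% .reactionKinds))
    msg <- c(msg, paste("reaction kind must be one of:",
                        paste(.reactionKinds, collapse = ", ")))
  if (nrow(rxn)) {
    nnz <- Matrix::colSums(S != 0)
    if (any(nnz == 0)) {
      msg <- c(msg, paste("reactions with empty stoichiometry:",
                          paste(rxn$id[nnz == 0], collapse = ", ")))
    }
    boundary <- rxn$kind %in% c("exchange", "sink", "demand")
    if (any(boundary & nnz != 1))
      msg <- c(msg, "exchange/sink/demand reactions must touch exactly one metabolite")
  }
  gg <- unique(unlist(lapply(rxn$gpr, gprGenes), use.names = FALSE))
  if (length(setdiff(gg, object@genes)))
    msg <- c(msg, paste("GPR genes missing from gene list:",
                        paste(setdiff(gg, object@genes), collapse = ", ")))
  if (length(object@objective)) {
    if (is.null(names(object@objective)) ||
        length(setdiff(names(object@objective), rxn$id)))
      msg <- c(msg, "objective must be named with existing reaction ids")
  }
  if (length(msg)) msg else TRUE
})

#' FluxResult: solution of a flux optimization
#'
#' @slot objectiveValue numeric scalar, value of the linear objective
#'   (NA unless status is "optimal").
#' @slot fluxes named numeric vector v over reaction ids.
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @slot method character, the procedure that produced the result.
#' @export
setClass("FluxResult",
  representation(objectiveValue = "numeric", fluxes = "numeric",
                 status = "character", method = "character"))

setValidity("FluxResult", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' FluxSampleSet: feasible flux vectors drawn from the solution space
#'
#' @slot samples numeric matrix, n_samples x reactions, columns named by
#'   reaction id; every row satisfies S v = 0 and the bounds.
#' @slot seed integer seed used for the sampler.
#' @slot sampler character description of the sampling scheme.
#' @export
setClass("FluxSampleSet",
  representation(samples = "matrix", seed = "integer", sampler = "character"))

#' NutrientEnvironment: an in-silico nutrient environment
#'
#' Describes which metabolites an environment (growth medium, root exudate,
#' nodule interior) makes available. Applying it to a model opens the
#' corresponding exchange reactions to uptake (lower bound -uptakeBound),
#' adds supply sinks for metabolites present only intracellularly, and closes
#' all other exchanges to uptake while leaving secretion open.
#'
#' @slot name character scalar.
#' @slot available character vector of metabolite ids available for uptake.
#' @slot excluded character vector of metabolite ids that must never receive
#'   an uptake route (e.g. central intermediates such as glyceraldehyde
#'   3-phosphate).
#' @slot uptakeBound positive numeric, magnitude of the uptake bound
#'   (default 1000 flux units).
#' @slot fixedUptakes named numeric vector of fixed uptake rates
#'   (mmol h-1 gDW-1), clamping the exchange lower bound to -rate.
#' @export
setClass("NutrientEnvironment",
  representation(name = "character", available = "character",
                 excluded = "character", uptakeBound = "numeric",
                 fixedUptakes = "numeric"))

setValidity("NutrientEnvironment", function(object) {
  msg <- character()
  if (length(intersect(object@available, object@excluded)))
    msg <- c(msg, "available and excluded metabolite sets overlap")
  if (length(object@uptakeBound) != 1 || object@uptakeBound <= 0)
    msg <- c(msg, "uptakeBound must be a single positive number")
  if (length(object@fixedUptakes)) {
    if (is.null(names(object@fixedUptakes)) || any(object@fixedUptakes < 0))
      msg <- c(msg, "fixedUptakes must be a named vector of non-negative rates")
  }
  if (length(msg)) msg else TRUE
})

#' ExpressionProfile: gene-level transcript abundances
#'
#' @slot abundance named non-negative numeric vector (gene id -> abundance,
#'   typically RPKM).
#' @slot condition character label for the condition.
#' @export
setClass("ExpressionProfile",
  representation(abundance = "numeric", condition = "character"))

setValidity("ExpressionProfile", function(object) {
  a <- object@abundance
  if (length(a) && (is.null(names(a)) || any(!is.finite(a)) || any(a < 0)))
    return("abundance must be a named vector of finite non-negative values")
  TRUE
})

#' ContextualizationResult: a context-specific model and its diagnostics
#'
#' @slot prunedModel the context-specific MetabolicModel.
#' @slot samples FluxSampleSet drawn from the pruned model under the
#'   objective-fraction constraint.
#' @slot objectiveFraction numeric, the fraction of the optimum the
#'   objective was constrained to.
#' @slot rho Spearman correlation between per-reaction median absolute flux
#'   and transcript abundance.
#' @slot rhoP p-value of the correlation.
#' @slot removedReactions character vector of pruned reaction ids.
#' @slot uptakeSummary data.frame (metabolite, median, iqr) of
#'   biomass-normalized uptake.
#' @slot metadata list of run parameters (fraction grid, seed, weights mode).
#' @export
setClass("ContextualizationResult",
  representation(prunedModel = "MetabolicModel", samples = "FluxSampleSet",
                 objectiveFraction = "numeric", rho = "numeric",
                 rhoP = "numeric", removedReactions = "character",
                 uptakeSummary = "data.frame", metadata = "list"))
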