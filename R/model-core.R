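#' Construct a MetabolicModel
#'
#' Assembles a \linkS4class{MetabolicModel} from metabolite and reaction
#' tables. Stoichiometry is supplied per reaction as a named numeric vector
#' (metabolite id -> coefficient, negative = consumed). Missing bounds
#' default to -1000/1000 flux units (0 lower bound for irreversible
#' reactions must be set explicitly by the caller or the input file).
#'
#' @param id model identifier.
#' @param metabolites data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{compartment}, \code{formula}, \code{charge}. The
#'   compartment defaults to the suffix of the id after the last underscore
#'   (e.g. \code{"glc_c0"} -> \code{"c0"}).
#' @param reactions data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{lower_bound}, \code{upper_bound}, \code{gpr},
#'   \code{kind}. An unspecified kind is inferred (see
#'   \code{\link{inferReactionKind}}).
#' @param stoichiometry list (parallel to reactions) of named numeric
#'   vectors, or a metabolites x reactions matrix.
#' @param genes character vector of gene ids; defaults to the union of all
#'   genes referenced by GPR rules.
#' @param objective named numeric vector of objective weights over reaction
#'   ids.
#' @return a validated \linkS4class{MetabolicModel}.
#' @examples
#' m <- MetabolicModel("toy",
#'   metabolites = data.frame(id = c("A_e0", "A_c0", "B_c0")),
#'   reactions = data.frame(id = c("EX_A", "T_A", "R1"),
#'                          lower_bound = c(-10, 0, 0)),
#'   stoichiometry = list(c(A_e0 = -1), c(A_e0 = -1, A_c0 = 1),
#'                        c(A_c0 = -1, B_c0 = 1)),
#'   objective = c(R1 = 1))
#' m
#' @export
MetabolicModel <- function(id = "model", metabolites, reactions,
                           stoichiometry, genes = NULL,
                           objective = numeric()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "))
  nm <- nrow(metabolites)
  nr <- nrow(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- sub("^.*_", "", metabolites$id)
  if (is.null(metabolites$formula))
    metabolites$formula <- rep(NA_character_, nm)
  if (is.null(metabolites$charge)) metabolites$charge <- rep(NA_integer_, nm)
  metabolites <- metabolites[, c("id", "name", "compartment", "formula",
                                 "charge")]

  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- rep(-1000, nr)
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- rep(1000, nr)
  reactions$lower_bound[is.na(reactions$lower_bound)] <- -1000
  reactions$upper_bound[is.na(reactions$upper_bound)] <- 1000
  if (is.null(reactions$gpr)) reactions$gpr <- rep("", nr)
  reactions$gpr[is.na(reactions$gpr)] <- ""

  if (is.matrix(stoichiometry) || inherits(stoichiometry, "Matrix")) {
    S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (is.null(rownames(S))) rownames(S) <- metabolites$id
    if (is.null(colnames(S))) colnames(S) <- reactions$id
    S <- S[metabolites$id, reactions$id, drop = FALSE]
  } else {
    stopifnot(length(stoichiometry) == nrow(reactions))
    i <- integer(); j <- integer(); x <- numeric()
    midx <- stats::setNames(seq_len(nrow(metabolites)), metabolites$id)
    for (k in seq_along(stoichiometry)) {
      st <- stoichiometry[[k]]
      st <- st[st != 0]
      if (anyNA(midx[names(st)]))
        stop("reaction ", reactions$id[k], " references unknown metabolites: ",
             paste(setdiff(names(st), metabolites$id), collapse = ", "))
      i <- c(i, unname(midx[names(st)]))
      j <- c(j, rep.int(k, length(st)))
      x <- c(x, unname(st))
    }
    S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(nrow(metabolites), nrow(reactions)),
                              dimnames = list(metabolites$id, reactions$id))
  }

  if (is.null(reactions$kind)) reactions$kind <- rep(NA_character_, nr)
  fill <- is.na(reactions$kind)
  if (any(fill))
    reactions$kind[fill] <- inferReactionKind(S, metabolites, reactions,
                                              objective)[fill]
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound",
                             "gpr", "kind")]

  if (is.null(genes))
    genes <- unique(unlist(lapply(reactions$gpr, gprGenes), use.names = FALSE))
  objective <- objective[objective != 0]

  methods::validObject(m <- methods::new("MetabolicModel",
    metabolites = metabolites, reactions = reactions, stoichiometry = .asDgC(S),
    genes = as.character(genes), objective = objective, id = id))
  m
}

#' Infer reaction kinds from network structure
#'
#' Boundary reactions (touching exactly one metabolite) are classified as
#' exchange when the metabolite is extracellular (compartment starting with
#' "e"), otherwise as sink when their lower bound allows supply (lb < 0) and
#' as demand otherwise. Internal reactions carrying objective weight are
#' "objective" (objective-support), reactions spanning more than one
#' compartment are "transport", everything else is "metabolic".
#'
#' @param S stoichiometric matrix (metabolites x reactions).
#' @param metabolites,reactions the model tables.
#' @param objective named objective vector.
#' @return character vector of kinds, parallel to reactions.
#' @export
inferReactionKind <- function(S, metabolites, reactions,
                              objective = numeric()) {
  kinds <- character(nrow(reactions))
  comp <- stats::setNames(metabolites$compartment, metabolites$id)
  for (k in seq_len(nrow(reactions))) {
    nz <- which(S[, k] != 0)
    mets <- rownames(S)[nz]
    if (length(nz) == 1L) {
      if (startsWith(comp[mets], "e")) {
        kinds[k] <- "exchange"
      } else if (reactions$lower_bound[k] < 0) {
        kinds[k] <- "sink"
      } else {
        kinds[k] <- "demand"
      }
    } else if (reactions$id[k] %in% names(objective) &&
               objective[reactions$id[k]] != 0) {
      kinds[k] <- "objective"
    } else if (length(unique(comp[mets])) > 1L) {
      kinds[k] <- "transport"
    } else {
      kinds[k] <- "metabolic"
    }
  }
  kinds
}

#' @rdname accessors
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel", function(object) {
  object@stoichiometry
})

# Named stoichiometry of one reaction.
.reactionStoichiometry <- function(model, rid) {
  col <- model@stoichiometry[, rid]
  col[col != 0]
}

# Per-reaction gene sets (list parallel to reactions), cached computation.
.reactionGeneSets <- function(model) {
  lapply(model@reactions$gpr, gprGenes)
}

# Logical: which reactions have a gene association.
.geneAssociated <- function(model) {
  nzchar(trimws(model@reactions$gpr))
}

#' Set reaction bounds
#'
#' @param model a MetabolicModel.
#' @param reactionIds reaction ids to modify.
#' @param lower,upper new bounds (recycled); NA leaves a bound unchanged.
#' @return the modified model.
#' @export
setReactionBounds <- function(model, reactionIds, lower = NA, upper = NA) {
  idx <- match(reactionIds, model@reactions$id)
  if (anyNA(idx))
    stop("unknown reaction ids: ",
         paste(reactionIds[is.na(idx)], collapse = ", "))
  lower <- rep_len(lower, length(idx))
  upper <- rep_len(upper, length(idx))
  sel <- !is.na(lower)
  model@reactions$lower_bound[idx[sel]] <- lower[sel]
  sel <- !is.na(upper)
  model@reactions$upper_bound[idx[sel]] <- upper[sel]
  model
}

#' Remove reactions (and orphaned metabolites and genes) from a model
#'
#' @param model a MetabolicModel.
#' @param reactionIds reactions to drop.
#' @param dropOrphans drop metabolites no longer used and genes no longer
#'   referenced by any GPR (default TRUE).
#' @return the reduced model.
#' @export
removeReactions <- function(model, reactionIds, dropOrphans = TRUE) {
  keep <- !(model@reactions$id %in% reactionIds)
  rxn <- model@reactions[keep, , drop = FALSE]
  S <- model@stoichiometry[, keep, drop = FALSE]
  met <- model@metabolites
  if (dropOrphans && nrow(met)) {
    used <- Matrix::rowSums(S != 0) > 0
    met <- met[used, , drop = FALSE]
    S <- S[used, , drop = FALSE]
  }
  rownames(rxn) <- NULL
  rownames(met) <- NULL
  genes <- unique(unlist(lapply(rxn$gpr, gprGenes), use.names = FALSE))
  if (!dropOrphans) genes <- model@genes
  obj <- model@objective[names(model@objective) %in% rxn$id]
  methods::new("MetabolicModel", metabolites = met, reactions = rxn,
               stoichiometry = .asDgC(S), genes = genes, objective = obj,
               id = model@id)
}

# Append one reaction column (used by applyEnvironment to add sinks).
.addReaction <- function(model, id, name = id, stoich, lower = -1000,
                         upper = 1000, gpr = "", kind = NA_character_) {
  if (id %in% model@reactions$id)
    stop("reaction ", sQuote(id), " already exists")
  midx <- match(names(stoich), model@metabolites$id)
  if (anyNA(midx))
    stop("unknown metabolites in new reaction: ",
         paste(names(stoich)[is.na(midx)], collapse = ", "))
  newcol <- Matrix::sparseMatrix(i = midx, j = rep(1L, length(stoich)),
                                 x = unname(stoich),
                                 dims = c(nrow(model@metabolites), 1L),
                                 dimnames = list(model@metabolites$id, id))
  S <- cbind(model@stoichiometry, newcol)
  rxn <- rbind(model@reactions,
               data.frame(id = id, name = name, lower_bound = lower,
                          upper_bound = upper, gpr = gpr,
                          kind = if (is.na(kind)) "sink" else kind,
                          stringsAsFactors = FALSE))
  rownames(rxn) <- NULL
  methods::new("MetabolicModel", metabolites = model@metabolites,
               reactions = rxn, stoichiometry = .asDgC(S), genes = model@genes,
               objective = model@objective, id = model@id)
}

# Strip the compartment suffix from a metabolite id ("atp_c0" -> "atp").
.metaboliteBaseName <- function(model) {
  mapply(function(id, comp) sub(paste0("_", comp, "$"), "", id),
         model@metabolites$id, model@metabolites$compartment,
         USE.NAMES = FALSE)
}
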