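#' Construct a NutrientEnvironment
#'
#' @param name environment label (e.g. "UMS+glucose", "rhizosphere").
#' @param available metabolite ids available for uptake.
#' @param excluded metabolite ids that must not receive an uptake route
#'   (central intermediates whose uptake would blur pathway predictions).
#' @param uptakeBound uptake bound magnitude (default 1000 flux units).
#' @param fixedUptakes named numeric vector of fixed uptake rates; the
#'   exchange lower bound is clamped to -rate.
#' @return a \linkS4class{NutrientEnvironment}.
#' @export
NutrientEnvironment <- function(name, available, excluded = character(),
                                uptakeBound = 1000,
                                fixedUptakes = numeric()) {
  methods::new("NutrientEnvironment", name = name,
               available = as.character(available),
               excluded = as.character(excluded),
               uptakeBound = as.numeric(uptakeBound),
               fixedUptakes = fixedUptakes)
}

#' Apply a nutrient environment to a model
#'
#' Realizes the environment as exchange/sink bounds: every available
#' metabolite with an existing extracellular exchange has that exchange
#' opened to uptake (lower bound \code{-uptakeBound}); available metabolites
#' present only intracellularly get a supply sink (lower bound
#' \code{-uptakeBound}, upper bound 0), so nutrients without an annotated
#' transporter are not erroneously unavailable. Exchanges of metabolites not
#' listed as available are closed to uptake (lower bound 0) but left open to
#' secretion. Fixed uptakes clamp the corresponding exchange lower bound to
#' -rate. Excluded metabolites never receive an uptake route. Available
#' metabolites absent from the model are skipped with a warning and recorded
#' in the \code{"environmentReport"} attribute of the result. The operation
#' is idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param env a \linkS4class{NutrientEnvironment}.
#' @return the adjusted model, with attribute \code{"environmentReport"}
#'   (list with elements \code{skipped}, \code{sinksAdded},
#'   \code{exchangesOpened}).
#' @export
applyEnvironment <- function(model, env) {
  stopifnot(is(env, "NutrientEnvironment"))
  rxn <- model@reactions
  S <- model@stoichiometry
  exIdx <- which(rxn$kind == "exchange")
  # metabolite each exchange touches
  exMet <- vapply(exIdx, function(k) rownames(S)[which(S[, k] != 0)[1]], "")

  avail <- setdiff(env@available, env@excluded)
  skipped <- character(); sinksAdded <- character(); opened <- character()

  # close all exchanges to uptake first (idempotent baseline), keep secretion
  rxn$lower_bound[exIdx] <- pmax(rxn$lower_bound[exIdx], 0)
  model@reactions <- rxn

  for (met in avail) {
    hit <- exIdx[exMet == met]
    if (length(hit)) {
      bound <- if (met %in% names(env@fixedUptakes))
        env@fixedUptakes[[met]] else env@uptakeBound
      model@reactions$lower_bound[hit[1]] <- -bound
      opened <- c(opened, model@reactions$id[hit[1]])
    } else if (met %in% model@metabolites$id) {
      sid <- paste0("SK_", met)
      if (sid %in% model@reactions$id) {
        model <- setReactionBounds(model, sid, lower = -env@uptakeBound,
                                   upper = 0)
      } else {
        model <- .addReaction(model, sid, name = paste("sink for", met),
                              stoich = stats::setNames(-1, met),
                              lower = -env@uptakeBound, upper = 0,
                              kind = "sink")
      }
      sinksAdded <- c(sinksAdded, sid)
    } else {
      skipped <- c(skipped, met)
    }
  }
  if (length(skipped))
    warning("environment metabolites absent from the model (skipped): ",
            paste(skipped, collapse = ", "))
  attr(model, "environmentReport") <- list(skipped = skipped,
                                           sinksAdded = sinksAdded,
                                           exchangesOpened = opened)
  model
}

#' Predict growth in a nutrient environment
#'
#' Applies the environment and returns the FBA optimum of the model
#' objective (growth rate in h-1 when bounds are in mmol h-1 gDW-1 and the
#' objective is biomass). An infeasible model reports growth 0.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param env a \linkS4class{NutrientEnvironment}.
#' @return numeric growth rate, with attribute \code{"status"}.
#' @export
predictGrowth <- function(model, env) {
  m <- suppressWarnings(applyEnvironment(model, env))
  res <- fba(m)
  g <- if (res@status == "optimal") res@objectiveValue else 0
  attr(g, "status") <- res@status
  g
}

#' Screen candidate carbon sources for growth support
#'
#' For each candidate metabolite present in the model, adds it to the base
#' environment (salts and nitrogen source, no carbon) and evaluates flux
#' through the objective. A candidate supports growth when the predicted
#' growth exceeds the tolerance (default 1e-6, strictly positive to absorb
#' solver noise). Candidates absent from the model are reported in the
#' \code{"absentCandidates"} attribute, mirroring screens restricted to
#' compounds present as model metabolites.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param baseEnv a \linkS4class{NutrientEnvironment} without carbon source.
#' @param candidates metabolite ids to screen.
#' @param tolerance growth-call tolerance (default 1e-6).
#' @return data.frame with columns carbon_source, predicted_growth, grows;
#'   attribute \code{"absentCandidates"} lists unmatched candidates.
#' @export
carbonSourceScreen <- function(model, baseEnv, candidates,
                               tolerance = 1e-6) {
  present <- candidates[candidates %in% model@metabolites$id]
  absent <- setdiff(candidates, present)
  growth <- vapply(present, function(met) {
    env <- baseEnv
    env@available <- unique(c(env@available, met))
    as.numeric(predictGrowth(model, env))
  }, numeric(1))
  out <- data.frame(carbon_source = present,
                    predicted_growth = unname(growth),
                    grows = unname(growth) > tolerance,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "absentCandidates") <- absent
  out
}

#' Read a nutrient environment from a TSV file
#'
#' Expected columns: \code{metabolite_id}, \code{role} ("available" or
#' "excluded"), optional \code{fixed_uptake}. Metabolite name matching to
#' model ids is deliberately exact; cross-naming is handled by an explicit
#' mapping table (columns \code{external_name}, \code{model_id}) rather
#' than fuzzy matching.
#'
#' @param path TSV file path.
#' @param name environment name (default: file base name).
#' @param uptakeBound default uptake bound.
#' @param mapping optional data.frame (external_name, model_id) applied to
#'   metabolite_id before construction.
#' @return a \linkS4class{NutrientEnvironment}.
#' @export
readEnvironment <- function(path, name = NULL, uptakeBound = 1000,
                            mapping = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "role") %in% names(df)))
    stop("environment file needs columns metabolite_id and role")
  if (!is.null(mapping)) {
    idx <- match(df$metabolite_id, mapping$external_name)
    df$metabolite_id[!is.na(idx)] <- mapping$model_id[idx[!is.na(idx)]]
  }
  fixed <- numeric()
  if ("fixed_uptake" %in% names(df)) {
    sel <- !is.na(df$fixed_uptake) & df$role == "available"
    fixed <- stats::setNames(df$fixed_uptake[sel], df$metabolite_id[sel])
  }
  NutrientEnvironment(
    name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
    available = df$metabolite_id[df$role == "available"],
    excluded = df$metabolite_id[df$role == "excluded"],
    uptakeBound = uptakeBound, fixedUptakes = fixed)
}
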