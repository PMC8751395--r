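#' @name accessors
#' @title Accessors for rhizoflux classes
#' @description Slot accessors for \linkS4class{MetabolicModel},
#'   \linkS4class{FluxResult}, \linkS4class{FluxSampleSet} and
#'   \linkS4class{ContextualizationResult}.
#' @param object an object of the documented class
#' @return the corresponding slot value
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("objectiveCoefficients",
           function(object) standardGeneric("objectiveCoefficients"))
#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix",
           function(object) standardGeneric("stoichiometricMatrix"))
#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))
#' @rdname accessors
#' @export
setGeneric("sampleMatrix", function(object) standardGeneric("sampleMatrix"))
#' @rdname accessors
#' @export
setGeneric("prunedModel", function(object) standardGeneric("prunedModel"))
#' @rdname accessors
#' @export
setGeneric("objectiveFraction",
           function(object) standardGeneric("objectiveFraction"))

setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)
setMethod("reactions", "MetabolicModel", function(object) object@reactions)
setMethod("genes", "MetabolicModel", function(object) object@genes)
setMethod("objectiveCoefficients", "MetabolicModel",
          function(object) object@objective)
setMethod("fluxes", "FluxResult", function(object) object@fluxes)
setMethod("objectiveValue", "FluxResult", function(object) object@objectiveValue)
setMethod("solverStatus", "FluxResult", function(object) object@status)
setMethod("sampleMatrix", "FluxSampleSet", function(object) object@samples)
setMethod("prunedModel", "ContextualizationResult",
          function(object) object@prunedModel)
setMethod("objectiveFraction", "ContextualizationResult",
          function(object) object@objectiveFraction)
setMethod("sampleMatrix", "ContextualizationResult",
          function(object) object@samples@samples)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel", sQuote(object@id), "\n")
  cat("  metabolites:", nrow(object@metabolites), "\n")
  cat("  reactions:  ", nrow(object@reactions), "\n")
  cat("  genes:      ", length(object@genes), "\n")
  if (length(object@objective)) {
    cat("  objective:  ",
        paste(sprintf("%s (%g)", names(object@objective), object@objective),
              collapse = ", "), "\n")
  } else {
    cat("  objective:   <none>\n")
  }
  kinds <- table(object@reactions$kind)
  if (length(kinds))
    cat("  kinds:      ",
        paste(sprintf("%s=%d", names(kinds), as.integer(kinds)),
              collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "FluxResult", function(object) {
  cat("FluxResult:", object@status)
  if (object@status == "optimal")
    cat(sprintf(", objective = %.6g", object@objectiveValue))
  cat(sprintf(" [%s, %d reactions]\n", object@method, length(object@fluxes)))
  invisible(object)
})

setMethod("show", "FluxSampleSet", function(object) {
  cat(sprintf("FluxSampleSet: %d samples x %d reactions (%s, seed %d)\n",
              nrow(object@samples), ncol(object@samples), object@sampler,
              object@seed))
  invisible(object)
})

setMethod("show", "NutrientEnvironment", function(object) {
  cat("NutrientEnvironment", sQuote(object@name), "\n")
  cat("  available:", length(object@available),
      " excluded:", length(object@excluded),
      " fixed uptakes:", length(object@fixedUptakes), "\n")
  cat("  uptake bound:", object@uptakeBound, "\n")
  invisible(object)
})

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile (%s): %d genes, median abundance %.3g\n",
              object@condition, length(object@abundance),
              stats::median(object@abundance)))
  invisible(object)
})

setMethod("show", "ContextualizationResult", function(object) {
  cat("ContextualizationResult\n")
  cat(sprintf("  pruned model: %d reactions, %d metabolites\n",
              nrow(object@prunedModel@reactions),
              nrow(object@prunedModel@metabolites)))
  cat(sprintf("  objective fraction: %.4g\n", object@objectiveFraction))
  cat(sprintf("  Spearman rho: %.4g (p = %.3g)\n", object@rho, object@rhoP))
  cat(sprintf("  removed reactions: %d\n", length(object@removedReactions)))
  invisible(object)
})
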