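# JSON model dialect: mirrors the SBML/FBC content one-to-one so fixtures
# round-trip without XML overhead. Schema:
# {
#   "id": "<model id>",
#   "metabolites": [{"id","name","compartment","formula","charge"}, ...],
#   "reactions":   [{"id","name","metabolites":{"<met id>": coeff, ...},
#                    "lower_bound","upper_bound","gene_reaction_rule",
#                    "objective_coefficient","kind"}, ...],
#   "genes":       ["<gene id>", ...]
# }
# Coefficients are negative for consumed metabolites; bounds default to
# +/-1000 when absent.

.readModelJson <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON model file ", sQuote(path), ": ",
                         conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("malformed model file ", sQuote(path),
         ": missing 'metabolites' or 'reactions' element")
  toChr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  toNum <- function(x, default) if (is.null(x)) default else as.numeric(x)
  met <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in ", sQuote(path))
    data.frame(id = m$id, name = toChr(m$name),
               compartment = toChr(m$compartment), formula = toChr(m$formula),
               charge = if (is.null(m$charge)) NA_integer_
                        else as.integer(m$charge),
               stringsAsFactors = FALSE)
  }))
  rxn <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in ", sQuote(path))
    data.frame(id = r$id, name = toChr(r$name),
               lower_bound = toNum(r$lower_bound, -1000),
               upper_bound = toNum(r$upper_bound, 1000),
               gpr = if (is.null(r$gene_reaction_rule)) ""
                     else r$gene_reaction_rule,
               kind = toChr(r$kind), stringsAsFactors = FALSE)
  }))
  sto <- lapply(doc$reactions, function(r)
    stats::setNames(as.numeric(unlist(r$metabolites)),
                    names(r$metabolites)))
  obj <- numeric()
  for (r in doc$reactions)
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      obj[r$id] <- as.numeric(r$objective_coefficient)
  genes <- if (is.null(doc$genes)) NULL else
    vapply(doc$genes, function(g) if (is.list(g)) g$id else g, "")
  if (is.null(met)) met <- data.frame(id = character())
  if (is.null(rxn)) rxn <- data.frame(id = character())
  MetabolicModel(id = if (is.null(doc$id)) "model" else doc$id,
                 metabolites = met, reactions = rxn, stoichiometry = sto,
                 genes = genes, objective = obj)
}

.writeModelJson <- function(model, path) {
  met <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  obj <- model@objective
  rxn <- lapply(seq_len(nrow(model@reactions)), function(i) {
    r <- model@reactions[i, ]
    st <- .reactionStoichiometry(model, r$id)
    list(id = r$id, name = r$name, metabolites = as.list(st),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr,
         objective_coefficient = if (r$id %in% names(obj))
           unname(obj[r$id]) else 0,
         kind = r$kind)
  })
  jsonlite::write_json(
    list(id = model@id, metabolites = met, reactions = rxn,
         genes = as.list(model@genes)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
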