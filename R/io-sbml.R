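# SBML reader/writer. Writing targets Level 3 Version 1 with the FBC
# version 2 package (flux bounds as parameters, objectives, gene-product
# associations). Reading accepts Level 3 FBC as well as legacy Level 2
# files (bounds and GENE_ASSOCIATION notes inside kineticLaw); the level
# actually parsed is recorded in the "sbmlLevel" attribute of the returned
# model. Identifiers are written with the conventional M_/R_/G_ prefixes.

.sbmlSanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.writeModelSbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">",
            esc(.sbmlSanitize(model@id))))

  comps <- unique(model@metabolites$compartment)
  if (length(comps)) {
    out <- c(out, "    <listOfCompartments>",
             sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
                     esc(comps)),
             "    </listOfCompartments>")
  }

  if (nrow(model@metabolites)) {
    sp <- vapply(seq_len(nrow(model@metabolites)), function(i) {
      m <- model@metabolites[i, ]
      extra <- ""
      if (!is.na(m$formula))
        extra <- paste0(extra, sprintf(" fbc:chemicalFormula=\"%s\"",
                                       esc(m$formula)))
      if (!is.na(m$charge))
        extra <- paste0(extra, sprintf(" fbc:charge=\"%d\"",
                                       as.integer(m$charge)))
      sprintf(paste0("      <species id=\"M_%s\" name=\"%s\" ",
                     "compartment=\"%s\" hasOnlySubstanceUnits=\"false\" ",
                     "boundaryCondition=\"false\" constant=\"false\"%s/>"),
              .sbmlSanitize(m$id), esc(m$name), esc(m$compartment), extra)
    }, "")
    out <- c(out, "    <listOfSpecies>", sp, "    </listOfSpecies>")
  }

  # flux bounds as shared constant parameters
  vals <- sort(unique(c(model@reactions$lower_bound,
                        model@reactions$upper_bound)))
  pid <- stats::setNames(sprintf("FB_%d", seq_along(vals)), num(vals))
  if (length(vals)) {
    out <- c(out, "    <listOfParameters>",
             sprintf(paste0("      <parameter id=\"%s\" value=\"%s\"",
                            " constant=\"true\"/>"),
                     pid, names(pid)),
             "    </listOfParameters>")
  }

  gprXml <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (is.character(ast))
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                     pad, .sbmlSanitize(ast)))
    tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(ast$args, gprXml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }

  if (nrow(model@reactions)) {
    rx <- unlist(lapply(seq_len(nrow(model@reactions)), function(i) {
      r <- model@reactions[i, ]
      st <- .reactionStoichiometry(model, r$id)
      lines <- sprintf(paste0("      <reaction id=\"R_%s\" name=\"%s\" ",
                              "reversible=\"%s\" fast=\"false\" ",
                              "fbc:lowerFluxBound=\"%s\" ",
                              "fbc:upperFluxBound=\"%s\">"),
                       .sbmlSanitize(r$id), esc(r$name),
                       if (r$lower_bound < 0) "true" else "false",
                       pid[num(r$lower_bound)], pid[num(r$upper_bound)])
      sref <- function(ids, coefs)
        sprintf(paste0("          <speciesReference species=\"M_%s\" ",
                       "stoichiometry=\"%s\" constant=\"true\"/>"),
                .sbmlSanitize(ids), num(coefs))
      rea <- st[st < 0]
      if (length(rea))
        lines <- c(lines, "        <listOfReactants>",
                   sref(names(rea), -rea), "        </listOfReactants>")
      pro <- st[st > 0]
      if (length(pro))
        lines <- c(lines, "        <listOfProducts>",
                   sref(names(pro), pro), "        </listOfProducts>")
      ast <- .gprParse(r$gpr)
      if (!is.null(ast))
        lines <- c(lines, "        <fbc:geneProductAssociation>",
                   gprXml(ast, 10), "        </fbc:geneProductAssociation>")
      c(lines, "      </reaction>")
    }))
    out <- c(out, "    <listOfReactions>", rx, "    </listOfReactions>")
  }

  if (length(model@objective)) {
    out <- c(out,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>",
      sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"R_%s\" ",
                     "fbc:coefficient=\"%s\"/>"),
              .sbmlSanitize(names(model@objective)), num(model@objective)),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }

  if (length(model@genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf(paste0("      <fbc:geneProduct fbc:id=\"G_%s\" ",
                            "fbc:label=\"%s\"/>"),
                     .sbmlSanitize(model@genes), esc(model@genes)),
             "    </fbc:listOfGeneProducts>")
  }

  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

# namespace-agnostic helpers
.xfind <- function(node, name)
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
.xattr <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- c(name, paste0("fbc:", name))
  hit <- hit[hit %in% names(a)]
  if (length(hit)) unname(a[[hit[1]]]) else NA_character_
}

.readModelSbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed SBML file ", sQuote(path), ": ",
                         conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "sbml")
    stop("malformed SBML file ", sQuote(path), ": root element is <",
         root, ">, expected <sbml>")
  level <- xml2::xml_attr(doc, "level")
  mnode <- .xfind(doc, "model")
  if (!length(mnode)) stop("malformed SBML file: no <model> element")
  mnode <- mnode[[1]]
  mid <- xml2::xml_attr(mnode, "id")
  if (is.na(mid)) mid <- "model"

  stripPrefix <- function(x, prefix) {
    ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
  }

  spn <- .xfind(mnode, "species")
  met <- data.frame(
    id = stripPrefix(xml2::xml_attr(spn, "id"), "M_"),
    name = xml2::xml_attr(spn, "name"),
    compartment = xml2::xml_attr(spn, "compartment"),
    formula = vapply(spn, .xattr, "", name = "chemicalFormula"),
    charge = suppressWarnings(
      as.integer(vapply(spn, .xattr, "", name = "charge"))),
    stringsAsFactors = FALSE)
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]
  if (anyDuplicated(met$id))
    stop("duplicate species ids in ", sQuote(path), ": ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))

  # flux-bound parameters (L3) live under the model; kineticLaw parameters
  # (L2) are handled per reaction below
  pars <- .xfind(mnode, "parameter")
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gp <- .xfind(mnode, "geneProduct")
  gpLabel <- stats::setNames(
    vapply(gp, .xattr, "", name = "label"),
    vapply(gp, .xattr, "", name = "id"))
  resolveGene <- function(ref) {
    if (ref %in% names(gpLabel) && !is.na(gpLabel[[ref]]) &&
        nzchar(gpLabel[[ref]])) gpLabel[[ref]] else stripPrefix(ref, "G_")
  }

  gprFromNode <- function(node) {
    nm <- xml2::xml_name(node)
    kids <- xml2::xml_children(node)
    if (nm == "geneProductRef") return(resolveGene(.xattr(node, "geneProduct")))
    parts <- vapply(kids, gprFromNode, "")
    parts <- parts[nzchar(parts)]
    if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
    if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
    if (length(parts) == 1) parts else ""
  }

  rxnNodes <- .xfind(mnode, "reaction")
  rids <- stripPrefix(xml2::xml_attr(rxnNodes, "id"), "R_")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids in ", sQuote(path), ": ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  sto <- vector("list", length(rxnNodes))
  lbv <- ubv <- numeric(length(rxnNodes))
  gpr <- character(length(rxnNodes))
  objL2 <- numeric()
  for (i in seq_along(rxnNodes)) {
    r <- rxnNodes[[i]]
    st <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      box <- xml2::xml_find_first(
        r, sprintf("./*[local-name()='%s']", side))
      if (inherits(box, "xml_missing")) next
      refs <- .xfind(box, "speciesReference")
      for (s in refs) {
        sid <- stripPrefix(xml2::xml_attr(s, "species"), "M_")
        coef <- as.numeric(xml2::xml_attr(s, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        st[sid] <- (if (sid %in% names(st)) st[[sid]] else 0) + sgn * coef
      }
    }
    sto[[i]] <- st

    lbRef <- .xattr(r, "lowerFluxBound")
    ubRef <- .xattr(r, "upperFluxBound")
    if (!is.na(lbRef) || !is.na(ubRef)) {
      lbv[i] <- if (!is.na(lbRef)) parVal[[lbRef]] else -1000
      ubv[i] <- if (!is.na(ubRef)) parVal[[ubRef]] else 1000
    } else {
      # Level 2 style: kineticLaw parameters
      kl <- .xfind(r, "parameter")
      klv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                             xml2::xml_attr(kl, "id"))
      rev <- xml2::xml_attr(r, "reversible")
      defLb <- if (identical(rev, "false")) 0 else -1000
      lbv[i] <- if ("LOWER_BOUND" %in% names(klv)) klv[["LOWER_BOUND"]]
                else defLb
      ubv[i] <- if ("UPPER_BOUND" %in% names(klv)) klv[["UPPER_BOUND"]]
                else 1000
      if ("OBJECTIVE_COEFFICIENT" %in% names(klv) &&
          klv[["OBJECTIVE_COEFFICIENT"]] != 0)
        objL2[rids[i]] <- klv[["OBJECTIVE_COEFFICIENT"]]
    }

    gpa <- xml2::xml_find_first(
      r, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      gpr[i] <- if (length(kids)) gprFromNode(kids[[1]]) else ""
    } else {
      notes <- xml2::xml_find_first(r, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("GENE_ASSOCIATION:\\s*([^\n<]*)", txt))[[1]]
        if (length(m) == 2) gpr[i] <- trimws(m[2])
      }
    }
  }

  obj <- objL2
  fo <- .xfind(mnode, "fluxObjective")
  if (length(fo)) {
    obj <- stats::setNames(
      as.numeric(vapply(fo, .xattr, "", name = "coefficient")),
      stripPrefix(vapply(fo, .xattr, "", name = "reaction"), "R_"))
  }

  rxn <- data.frame(id = rids,
                    name = xml2::xml_attr(rxnNodes, "name"),
                    lower_bound = lbv, upper_bound = ubv, gpr = gpr,
                    stringsAsFactors = FALSE)
  rxn$name[is.na(rxn$name)] <- rxn$id[is.na(rxn$name)]
  genes <- if (length(gpLabel)) unname(
    ifelse(nzchar(gpLabel) & !is.na(gpLabel), gpLabel,
           stripPrefix(names(gpLabel), "G_"))) else NULL

  model <- MetabolicModel(id = mid, metabolites = met, reactions = rxn,
                          stoichiometry = sto, genes = genes,
                          objective = obj)
  attr(model, "sbmlLevel") <- if (is.na(level)) "unknown" else level
  model
}

#' Read a metabolic model from SBML or the JSON dialect
#'
#' SBML Level 3 with the FBC package is supported in full (bounds,
#' objectives, gene-product associations); legacy Level 2 files are read
#' via kineticLaw bound parameters and GENE_ASSOCIATION notes, and the
#' parsed level is recorded in the \code{"sbmlLevel"} attribute. Bounds
#' default to -1000/1000 flux units when absent.
#'
#' @param path file path.
#' @param format "sbml", "json", or "auto" (by file extension; default).
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
readModel <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  if (format == "json") .readModelJson(path) else .readModelSbml(path)
}

#' Write a metabolic model to SBML (Level 3 FBC) or the JSON dialect
#'
#' The emitted file re-reads to an equivalent model (up to field ordering;
#' reaction kinds are stored explicitly in JSON and re-inferred from
#' structure for SBML).
#'
#' @param model a valid \linkS4class{MetabolicModel}.
#' @param path output file path.
#' @param format "sbml", "json", or "auto" (by extension; default).
#' @return the path, invisibly.
#' @export
writeModel <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  methods::validObject(model)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  if (format == "json") .writeModelJson(model, path)
  else .writeModelSbml(model, path)
}
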