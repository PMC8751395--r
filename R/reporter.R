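# Reporter-metabolite analysis: aggregate gene-level differential-expression
# significance over the metabolite neighbourhoods defined by the model
# topology, so that compounds around which coordinated transcriptional
# change occurs rank highly.

# Default currency metabolites (base names, compartment-independent): they
# neighbour most genes and would swamp the ranking.
.defaultCurrency <- c("h", "h2o", "atp", "adp", "amp", "pi", "ppi", "nad",
                      "nadh", "nadp", "nadph", "co2", "o2", "nh4", "coa")

# metabolite id -> distinct neighbour genes (genes in the GPRs of the
# reactions that contain the metabolite); duplicates deduplicated so
# duplicate reactions cannot inflate a neighbourhood.
.metaboliteNeighbourGenes <- function(model) {
  S <- model@stoichiometry
  sets <- .reactionGeneSets(model)
  out <- lapply(seq_len(nrow(S)), function(i) {
    rxns <- which(S[i, ] != 0)
    unique(unlist(sets[rxns], use.names = FALSE))
  })
  stats::setNames(out, rownames(S))
}

#' Read gene-level differential-expression scores from TSV
#'
#' Expected columns: \code{gene_id}, \code{p_value}, optional
#' \code{direction} ("up", "down" or "both").
#'
#' @param path TSV file path.
#' @return data.frame of gene scores.
#' @export
readGeneScores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "p_value") %in% names(df)))
    stop("gene score file needs columns gene_id and p_value")
  if (is.null(df$direction)) df$direction <- "both"
  df
}

#' Reporter-metabolite analysis
#'
#' Converts gene p-values to z-scores (\eqn{z_g = \Phi^{-1}(1 - p)}),
#' aggregates them over each metabolite's neighbour genes
#' (\eqn{z_{raw} = \sum z_g / \sqrt{k}}), corrects against a background of
#' random same-size gene sets drawn from the scored gene pool
#' (\eqn{z_{corr} = (z_{raw} - \mu_k) / \sigma_k}) and reports
#' \eqn{p = 1 - \Phi(z_{corr})}. P-values are clamped to
#' \eqn{[10^{-16}, 1 - 10^{-16}]} before transformation so z-scores stay
#' finite. Metabolites with no scored neighbour genes are omitted; currency
#' metabolites (protons, water, ATP/ADP, NAD(P)(H), phosphate, CO2, ...)
#' are excluded by default since they neighbour most genes.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param scores data.frame with columns gene_id, p_value and optionally
#'   direction ("up"/"down"/"both").
#' @param nBackground number of random gene sets per neighbourhood size
#'   (default 1000; < 100 triggers a warning).
#' @param seed integer seed for the background sampling.
#' @param direction which gene set to analyse: "up" (default, genes
#'   upregulated in the condition), "down", or "both" (all scored genes).
#' @param currencyMetabolites base names (compartment suffix stripped) to
#'   exclude; NULL disables the exclusion.
#' @param pFloor clamp for p-values at 0/1 (default 1e-16).
#' @return data.frame with columns metabolite_id, k, z_raw, z_corrected,
#'   p_reporter, neg_log10_p, ordered by p_reporter.
#' @export
reporterMetabolites <- function(model, scores, nBackground = 1000, seed = 1,
                                direction = c("up", "down", "both"),
                                currencyMetabolites = .defaultCurrency,
                                pFloor = 1e-16) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "p_value") %in% names(scores)))
  if (nBackground < 100)
    warning("nBackground < 100: background moments will be noisy")
  if (direction != "both" && !is.null(scores$direction))
    scores <- scores[scores$direction %in% c(direction, "both"), ,
                     drop = FALSE]
  scores <- scores[scores$gene_id %in% model@genes, , drop = FALSE]
  if (!nrow(scores))
    stop("no scored genes map into the model via GPR rules")
  p <- pmin(pmax(scores$p_value, pFloor), 1 - pFloor)
  z <- stats::setNames(stats::qnorm(1 - p), scores$gene_id)

  nb <- .metaboliteNeighbourGenes(model)
  nb <- lapply(nb, intersect, y = names(z))
  keep <- lengths(nb) >= 1
  if (!is.null(currencyMetabolites)) {
    base <- .metaboliteBaseName(model)
    keep <- keep & !(base %in% currencyMetabolites)
  }
  nb <- nb[keep]
  if (!length(nb))
    return(data.frame(metabolite_id = character(), k = integer(),
                      z_raw = numeric(), z_corrected = numeric(),
                      p_reporter = numeric(), neg_log10_p = numeric()))

  k <- lengths(nb)
  zraw <- vapply(nb, function(g) sum(z[g]) / sqrt(length(g)), numeric(1))

  .withSeed(seed, function() {
    mu <- sd <- stats::setNames(numeric(length(unique(k))),
                                as.character(unique(k)))
    pool <- unname(z)
    for (kk in unique(k)) {
      draws <- vapply(seq_len(nBackground), function(i)
        sum(sample(pool, kk, replace = FALSE)) / sqrt(kk), numeric(1))
      mu[as.character(kk)] <- mean(draws)
      sd[as.character(kk)] <- stats::sd(draws)
    }
    zc <- (zraw - mu[as.character(k)]) / pmax(sd[as.character(k)], 1e-12)
    pr <- stats::pnorm(zc, lower.tail = FALSE)
    pr <- pmin(pmax(pr, pFloor), 1 - pFloor)
    out <- data.frame(metabolite_id = names(nb), k = as.integer(k),
                      z_raw = unname(zraw), z_corrected = unname(zc),
                      p_reporter = unname(pr),
                      neg_log10_p = -log10(unname(pr)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$p_reporter), , drop = FALSE]
  })
}
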