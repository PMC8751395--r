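# Validation statistics: confusion metrics for growth/essentiality
# predictions, measured-flux versus FVA-envelope comparison, and amino-acid
# composition enrichment testing.

#' Confusion-matrix metrics
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN); precision = TP / (TP + FP);
#' recall = TP / (TP + FN). Metrics with a zero denominator are reported as
#' NA (undefined), never as 0. Note: the standard recall denominator TP + FN
#' is used throughout (a published variant printing FP + FN in the recall
#' denominator is inconsistent with the accompanying reported values and is
#' treated as a typographical error).
#'
#' @param tp,tn,fp,fn non-negative integer counts, or pass a list/vector
#'   with those names as \code{tp}.
#' @return named numeric vector c(accuracy, precision, recall).
#' @examples
#' confusionMetrics(tp = 9, tn = 0, fp = 1, fn = 0)
#' @export
confusionMetrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4)) {
    x <- unlist(tp)
    tn <- x[["tn"]]; fp <- x[["fp"]]; fn <- x[["fn"]]; tp <- x[["tp"]]
  }
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total < 1) stop("confusion matrix is empty")
  c(accuracy = (tp + tn) / total,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Build a confusion matrix from predicted and observed calls
#'
#' Counts are taken over the intersection of the two id sets (analyses are
#' typically limited to compounds/genes present in both the model and the
#' experiment).
#'
#' @param predicted,observed named logical vectors (TRUE = positive call:
#'   growth, essential, ...).
#' @return named integer vector c(tp, tn, fp, fn) with attribute
#'   \code{"n"}.
#' @export
buildConfusion <- function(predicted, observed) {
  ids <- intersect(names(predicted), names(observed))
  if (!length(ids)) stop("no shared ids between predicted and observed")
  p <- predicted[ids]; o <- observed[ids]
  out <- c(tp = sum(p & o), tn = sum(!p & !o), fp = sum(p & !o),
           fn = sum(!p & o))
  attr(out, "n") <- length(ids)
  out
}

#' Compare measured fluxes with FVA envelopes
#'
#' Flags, for each measured reaction, whether the measured mean flux lies
#' within the FVA range computed at the same objective fraction, alongside
#' the point prediction. Measured reaction names can be translated to model
#' ids with an explicit mapping table; unmapped reactions are excluded from
#' the summary and listed in the \code{"unmapped"} attribute.
#'
#' @param predicted a \linkS4class{FluxResult} (the point predictions).
#' @param ranges data.frame from \code{\link{fva}}.
#' @param measured data.frame with columns reaction_id, mean, sd.
#' @param mapping optional data.frame (external_name, model_reaction_id).
#' @return data.frame with columns reaction_id, measured_mean, measured_sd,
#'   predicted, fva_min, fva_max, within_range; attributes
#'   \code{"fractionInRange"} and \code{"unmapped"}.
#' @export
compareFluxes <- function(predicted, ranges, measured, mapping = NULL) {
  stopifnot(is(predicted, "FluxResult"),
            all(c("reaction_id", "mean") %in% names(measured)))
  if (is.null(measured$sd)) measured$sd <- NA_real_
  rid <- measured$reaction_id
  if (!is.null(mapping)) {
    idx <- match(rid, mapping$external_name)
    rid[!is.na(idx)] <- mapping$model_reaction_id[idx[!is.na(idx)]]
  }
  known <- rid %in% ranges$reaction_id & rid %in% names(predicted@fluxes)
  unmapped <- measured$reaction_id[!known]
  m <- measured[known, , drop = FALSE]
  rid <- rid[known]
  ri <- match(rid, ranges$reaction_id)
  out <- data.frame(
    reaction_id = rid,
    measured_mean = m$mean,
    measured_sd = m$sd,
    predicted = unname(predicted@fluxes[rid]),
    fva_min = ranges$minimum[ri],
    fva_max = ranges$maximum[ri],
    stringsAsFactors = FALSE)
  out$within_range <- out$fva_min <= out$measured_mean &
    out$measured_mean <= out$fva_max
  attr(out, "fractionInRange") <- mean(out$within_range)
  attr(out, "unmapped") <- unmapped
  out
}

#' Amino-acid enrichment of a protein subset
#'
#' Compares the amino-acid composition of a protein subset (e.g. the
#' highly expressed Nif/Fix proteins of nitrogen-fixing bacteroids) with a
#' background proteome: per standard amino acid, an upper-tail
#' hypergeometric test for over-representation among the subset residues
#' (draws = total subset residues, successes = background residues of that
#' amino acid), followed by Benjamini-Hochberg correction across the 20
#' tests. Non-standard letters are counted but excluded from testing.
#'
#' @param background,subset FASTA file paths or
#'   \code{Biostrings::AAStringSet} objects; the subset must be part of the
#'   background (residue counts must not exceed the background's).
#' @return data.frame with columns amino_acid, count_subset,
#'   count_background, p_raw, p_adjusted; attribute
#'   \code{"nonStandard"} reports letters outside the 20-letter alphabet.
#' @export
aaEnrichment <- function(background, subset) {
  asSet <- function(x) {
    if (is(x, "AAStringSet")) x else Biostrings::readAAStringSet(x)
  }
  bg <- asSet(background)
  sb <- asSet(subset)
  if (!length(bg) || !length(sb))
    stop("background and subset must be non-empty")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  countAll <- function(s) {
    f <- colSums(Biostrings::letterFrequency(s, Biostrings::AA_ALPHABET))
    f
  }
  fb <- countAll(bg)
  fs <- countAll(sb)
  nonStandard <- fs[setdiff(names(fs), aa)]
  nonStandard <- nonStandard[nonStandard > 0]
  cb <- fb[aa]; cs <- fs[aa]
  if (any(cs > cb))
    stop("subset residue counts exceed background counts for: ",
         paste(aa[cs > cb], collapse = ", "),
         "; the subset must be drawn from the background")
  N <- sum(cb)
  n <- sum(cs)
  # P(X >= k) for X ~ Hypergeom(successes = K, failures = N - K, draws = n)
  praw <- stats::phyper(cs - 1, cb, N - cb, n, lower.tail = FALSE)
  out <- data.frame(amino_acid = aa,
                    count_subset = as.integer(cs),
                    count_background = as.integer(cb),
                    p_raw = unname(praw),
                    p_adjusted = unname(stats::p.adjust(praw, "BH")),
                    stringsAsFactors = FALSE)
  attr(out, "nonStandard") <- nonStandard
  out
}
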