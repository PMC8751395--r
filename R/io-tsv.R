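#' Write a result table as TSV with fixed numeric formatting
#'
#' Numeric columns are formatted at a fixed number of significant digits so
#' repeated runs with the same inputs and seed produce byte-identical
#' files.
#'
#' @param x data.frame (or FluxResult, written as reaction_id/flux).
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6);
#'   \code{NA} writes full precision.
#' @return the path, invisibly.
#' @export
writeResultTable <- function(x, path, digits = 6) {
  if (is(x, "FluxResult"))
    x <- data.frame(reaction_id = names(x@fluxes), flux = unname(x@fluxes),
                    stringsAsFactors = FALSE)
  x <- as.data.frame(x)
  if (!is.na(digits)) {
    for (j in seq_along(x))
      if (is.numeric(x[[j]]) && !is.integer(x[[j]]))
        x[[j]] <- sprintf(paste0("%.", digits, "g"), x[[j]])
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
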