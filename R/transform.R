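#' Transform an enumerated alignment into factor-score variables
#'
#' Each residue is replaced by one of the five Atchley factor scores (or, for
#' \code{factorSet = "all"}, by all five), yielding a numeric dataset with one
#' row per sequence. Single-factor sets have one variable per fixed site (43
#' under the default map); \code{"all"} has five per site (215), ordered
#' site-major with factors in the order pah, pss, ms, cc, ec within each
#' site. A cell is missing (\code{NA}) exactly when the residue at that site
#' is a gap.
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param factorSet One of \code{"pah"}, \code{"pss"}, \code{"ms"},
#'   \code{"cc"}, \code{"ec"}, \code{"all"}.
#' @param table Factor-score lookup table; defaults to [factorScoreTable()].
#' @return A \code{NumericDataset}; row order matches the alignment.
#' @export
#' @examples
#' aln <- EnumeratedAlignment(c(a = paste(rep("K", 43), collapse = "")))
#' nd <- factorTransform(aln, "ms")
#' values(nd)[1, 1] == factorScoreTable()["K", "ms"]
factorTransform <- function(alignment, factorSet = c("pah", "pss", "ms",
                                                     "cc", "ec", "all"),
                            table = factorScoreTable()) {
  if (length(factorSet) == 1L && !factorSet %in% c(.FACTORS, "all"))
    stop("unknown factor set '", factorSet, "'; expected one of ",
         paste(c(.FACTORS, "all"), collapse = ", "))
  factorSet <- match.arg(factorSet)
  res <- residueMatrix(alignment)
  fx <- fixedSites(coordinateMap(alignment))
  facs <- if (factorSet == "all") .FACTORS else factorSet
  # site-major layout: all factors for site 1, then site 2, ...
  vars <- data.frame(site = rep(fx, each = length(facs)),
                     factor = rep(facs, length(fx)),
                     stringsAsFactors = FALSE)
  idx <- match(res, rownames(table))   # NA for gaps
  out <- matrix(NA_real_, nrow(res), nrow(vars),
                dimnames = list(rownames(res),
                                paste0(vars$factor, "_s", vars$site)))
  for (k in seq_along(facs)) {
    scores <- table[, facs[k]][idx]
    dim(scores) <- dim(res)
    out[, seq(k, ncol(out), by = length(facs))] <- scores
  }
  new("NumericDataset", values = out, variables = vars,
      labels = kingdoms(alignment), factorSet = factorSet)
}

#' Numeric factor-score datasets
#'
#' A \code{NumericDataset} is an n x p numeric matrix produced by
#' [factorTransform()] plus its variable descriptors (one (site, factor)
#' pair per column) and optional per-row Kingdom labels.
#'
#' @param x A \code{NumericDataset}.
#' @return \code{values}: the numeric matrix (NA = gap); \code{variableInfo}:
#'   data.frame with \code{site} and \code{factor}; \code{classLabels}: the
#'   Kingdom label per row (NA if unlabelled).
#' @aliases NumericDataset-class values variableInfo classLabels
#' @name NumericDataset
NULL

#' @rdname NumericDataset
#' @export
setMethod("values", "NumericDataset", function(x) x@values)

#' @rdname NumericDataset
#' @export
setMethod("variableInfo", "NumericDataset", function(x) x@variables)

#' @rdname NumericDataset
#' @export
setMethod("classLabels", "NumericDataset", function(x) x@labels)

#' @rdname NumericDataset
#' @export
setMethod("dim", "NumericDataset", function(x) dim(x@values))

setMethod("show", "NumericDataset", function(object) {
  cat("NumericDataset: ", nrow(object@values), " sequence(s) x ",
      ncol(object@values), " variable(s) [factor set: ", object@factorSet,
      "]\n", sep = "")
  cat(sprintf("  missing cells: %.3f\n", mean(is.na(object@values))))
})

#' Restrict a numeric dataset to a subset of variables
#'
#' @param dataset A \code{NumericDataset}.
#' @param columns Column indices or descriptor names (\code{<factor>_s<site>}).
#' @return A \code{NumericDataset} over the selected variables.
#' @export
selectVariables <- function(dataset, columns) {
  if (is.character(columns))
    columns <- match(columns, colnames(dataset@values))
  if (anyNA(columns)) stop("unknown variable descriptor(s)")
  new("NumericDataset",
      values = dataset@values[, columns, drop = FALSE],
      variables = dataset@variables[columns, , drop = FALSE],
      labels = dataset@labels,
      factorSet = dataset@factorSet)
}
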