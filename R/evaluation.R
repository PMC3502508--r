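#' Confusion matrix with an Unclassified column
#'
#' Rows are the true Kingdoms; columns the predicted Kingdoms plus
#' \code{Unclassified}. Row sums equal the class sizes.
#'
#' @param truth True Kingdom per sequence (must be Plant/Animal/Fungal).
#' @param predicted Predicted Kingdom or \code{"Unclassified"} per sequence.
#' @return 3 x 4 integer matrix.
#' @export
#' @examples
#' confusionKingdom(c("Plant", "Plant", "Fungal"),
#'                  c("Plant", "Unclassified", "Animal"))
confusionKingdom <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must be paired vectors of equal length")
  bad <- setdiff(unique(truth), .KINGDOMS)
  if (length(bad))
    stop("truth labels outside the three Kingdoms: ",
         paste(bad, collapse = ", "))
  badp <- setdiff(unique(predicted), c(.KINGDOMS, .UNCLASSIFIED))
  if (length(badp))
    stop("predictions must be a Kingdom or 'Unclassified'; got: ",
         paste(badp, collapse = ", "))
  cols <- c(.KINGDOMS, .UNCLASSIFIED)
  tab <- table(factor(truth, levels = .KINGDOMS),
               factor(predicted, levels = cols))
  m <- matrix(as.integer(tab), nrow = 3, dimnames = list(.KINGDOMS, cols))
  m
}

#' One-versus-all classification metrics
#'
#' Per-Kingdom sensitivity and specificity computed one-versus-all, with
#' \code{Unclassified} counted as a negative prediction for every Kingdom.
#' Two accuracy conventions are reported because an unclassified call can be
#' counted as an error or excluded: \code{overallAccuracy} counts
#' unclassified sequences as incorrect; \code{accuracyAmongClassified}
#' restricts to classified sequences (likewise for the per-class recalls).
#' Zero-denominator rates are \code{NA}, never 0.
#'
#' @param cm A confusion matrix from [confusionKingdom()].
#' @return List with \code{perClass} (data.frame: class, sensitivity,
#'   specificity, recall, recallAmongClassified), \code{overallAccuracy},
#'   \code{accuracyAmongClassified}, \code{nUnclassified}, \code{n}.
#' @export
classificationMetrics <- function(cm) {
  if (!all(dim(cm) == c(3L, 4L)))
    stop("expected a 3 x 4 Kingdom confusion matrix")
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  per <- lapply(.KINGDOMS, function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    classifiedK <- sum(cm[k, .KINGDOMS])
    data.frame(class = k,
               sensitivity = rate(tp, tp + fn),
               specificity = rate(tn, tn + fp),
               recall = rate(tp, sum(cm[k, ])),
               recallAmongClassified = rate(tp, classifiedK),
               stringsAsFactors = FALSE)
  })
  diagSum <- sum(diag(cm[, .KINGDOMS]))
  nUncl <- sum(cm[, .UNCLASSIFIED])
  list(perClass = do.call(rbind, per),
       overallAccuracy = diagSum / n,
       accuracyAmongClassified = rate(diagSum, n - nUncl),
       nUnclassified = as.integer(nUncl),
       n = as.integer(n))
}

#' Write a metrics report as JSON
#'
#' Lossless round-trip with [readMetricsReport()].
#'
#' @param report Output of [classificationMetrics()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname writeMetricsReport
#' @return \code{readMetricsReport}: the report list.
#' @export
readMetricsReport <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$perClass <- as.data.frame(rep$perClass, stringsAsFactors = FALSE)
  rep$nUnclassified <- as.integer(rep$nUnclassified)
  rep$n <- as.integer(rep$n)
  rep
}
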