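#' Classify sequences with a fitted CVA model
#'
#' For each sequence the squared Mahalanobis distance to every group mean is
#' computed with the pooled within-group covariance, and posterior
#' probabilities are proportional to \code{prior * exp(-d^2 / 2)}. A sequence
#' missing any model variable (a gap at a model site) is returned
#' \code{Unclassified}: distances and posteriors are \code{NA}.
#'
#' @param model A \code{CVAModel}.
#' @param x A \code{NumericDataset} or numeric matrix aligned to the model's
#'   variables.
#' @return data.frame with \code{sequence_id}, \code{predicted} (group name
#'   or \code{"Unclassified"}), one \code{dist_<group>} column (Mahalanobis
#'   distance, the square root of \eqn{d^2}) and one \code{post_<group>}
#'   column per group (posteriors sum to 1 when classified).
#' @export
#' @seealso [fitCVA()], [swdaClassifier()]
classifySequences <- function(model, x) {
  xm <- .alignToModel(model, x)
  ids <- rownames(xm)
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(xm)))
  G <- length(model@groups)
  R <- chol(model@Sw)
  d2 <- matrix(NA_real_, nrow(xm), G, dimnames = list(ids, model@groups))
  ok <- stats::complete.cases(xm)
  if (any(ok)) {
    for (g in model@groups) {
      cg <- sweep(xm[ok, , drop = FALSE], 2L, model@groupMeans[, g])
      z <- backsolve(R, t(cg), transpose = TRUE)
      d2[ok, g] <- colSums(z^2)
    }
  }
  logpost <- sweep(-d2 / 2, 2L, log(model@priors), `+`)
  m <- apply(logpost, 1L, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  pred <- rep(.UNCLASSIFIED, nrow(xm))
  pred[ok] <- model@groups[max.col(post[ok, , drop = FALSE],
                                   ties.method = "first")]
  out <- data.frame(sequence_id = ids, predicted = pred,
                    stringsAsFactors = FALSE)
  for (g in model@groups) out[[paste0("dist_", g)]] <- sqrt(d2[, g])
  for (g in model@groups) out[[paste0("post_", g)]] <- post[, g]
  rownames(out) <- NULL
  out
}

#' Write a classification report as TSV
#'
#' @param report Output of [classifySequences()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeClassification <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
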