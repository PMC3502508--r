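# Step-up (entry-only) stepwise discriminant analysis.
#
# At each step the candidate variable minimizing Wilks' lambda of the
# enlarged set is entered; the improvement is tracked as the partial
# r-squared 1 - lambda(M+v)/lambda(M), tested with the F-to-enter statistic.
# Stepping stops at the ASCC target, the step limit, or when no candidate
# passes the significance-to-enter threshold. Fitting is complete-case over
# all candidate variables, so every candidate subset sees the same rows and
# lambda is guaranteed to decrease monotonically along the entry path.

#' Stepwise discriminant analysis (step-up variable entry)
#'
#' @param x A \code{NumericDataset} or numeric matrix.
#' @param labels Group labels; taken from the dataset when omitted.
#' @param targetASCC Stop once the average squared canonical correlation of
#'   the entered set reaches this value. Default: 0.80 for the \code{"all"}
#'   factor set, 0.70 otherwise.
#' @param maxSteps Maximum number of variables to enter (default 20).
#' @param entryAlpha Significance-to-enter for the F-to-enter test
#'   (default 0.15).
#' @return A \code{SWDAResult}; see [stepTable()].
#' @export
#' @seealso [swdaClassifier()], [discerningSites()]
fitSWDA <- function(x, labels = NULL, targetASCC = NULL, maxSteps = 20,
                    entryAlpha = 0.15) {
  if (maxSteps < 1) stop("maxSteps must be at least 1")
  factorSet <- if (is(x, "NumericDataset")) x@factorSet else "custom"
  if (is.null(targetASCC))
    targetASCC <- if (identical(factorSet, "all")) 0.80 else 0.70
  d <- .resolveXy(x, labels)
  s <- .sscp(d$x, d$y)
  G <- s$G
  n <- s$n
  p <- ncol(d$x)
  sel <- integer()
  lambdaCur <- 1
  steps <- NULL
  reason <- "max steps reached"
  singTol <- 1e-8   # pivot tolerance: candidate must keep >1e-8 of its
                    # total variance after projecting out the entered set
  for (step in seq_len(maxSteps)) {
    best <- NULL
    for (v in setdiff(seq_len(p), sel)) {   # column order = site-major tie-break
      S <- c(sel, v)
      RT <- tryCatch(chol(s$T[S, S, drop = FALSE]), error = function(e) NULL)
      if (is.null(RT) ||
          utils::tail(diag(RT), 1)^2 < singTol * s$T[v, v])
        next                                 # collinear with entered set
      RW <- tryCatch(chol(s$W[S, S, drop = FALSE]), error = function(e) NULL)
      if (is.null(RW) ||
          utils::tail(diag(RW), 1)^2 < singTol * s$W[v, v])
        next
      lam <- exp(2 * sum(log(diag(RW))) - 2 * sum(log(diag(RT))))
      if (is.null(best) || lam < best$lambda - 1e-12)
        best <- list(v = v, lambda = lam)
    }
    if (is.null(best) || best$lambda >= lambdaCur) {
      reason <- if (length(sel)) "no candidate improves Wilks' lambda"
                else "no admissible candidate at step 1"
      break
    }
    r2 <- 1 - best$lambda / lambdaCur
    m <- length(sel)
    df2 <- n - G - m
    Fstat <- if (df2 > 0) (r2 / (1 - r2)) * df2 / (G - 1) else NA_real_
    pval <- if (is.na(Fstat)) NA_real_
            else stats::pf(Fstat, G - 1, df2, lower.tail = FALSE)
    if (!is.na(pval) && pval > entryAlpha) {
      reason <- "entry threshold"
      break
    }
    sel <- c(sel, best$v)
    lambdaCur <- best$lambda
    S <- sel
    ev <- .cvaEigen(s$W[S, S, drop = FALSE], s$B[S, S, drop = FALSE],
                    length(S))
    asccCur <- sum(ev$lambda / (1 + ev$lambda)) / (G - 1)
    steps <- rbind(steps, data.frame(
      step = step,
      site = d$vars$site[best$v],
      factor = d$vars$factor[best$v],
      wilks = lambdaCur,
      partialR2 = r2,
      F = Fstat,
      p = pval,
      ascc = asccCur,
      stringsAsFactors = FALSE))
    if (asccCur >= targetASCC) {
      reason <- "ASCC target reached"
      break
    }
  }
  if (is.null(steps))
    steps <- data.frame(step = integer(), site = integer(),
                        factor = character(), wilks = numeric(),
                        partialR2 = numeric(), F = numeric(), p = numeric(),
                        ascc = numeric(), stringsAsFactors = FALSE)
  new("SWDAResult", steps = steps, reason = reason,
      factorSet = factorSet, targetASCC = targetASCC,
      groups = s$groups, nComplete = as.integer(n))
}

#' Accessors for stepwise discriminant results
#'
#' @param object A \code{SWDAResult}.
#' @aliases SWDAResult-class SWDAResult stepTable stoppingReason
#' @name SWDAResult-accessors
NULL

#' @describeIn SWDAResult-accessors The ordered entry steps: variable (site,
#'   factor), Wilks' lambda after entry, partial r-squared, F-to-enter,
#'   p-value, cumulative ASCC.
#' @export
setMethod("stepTable", "SWDAResult", function(object) object@steps)

#' @describeIn SWDAResult-accessors Why stepping stopped.
#' @export
setMethod("stoppingReason", "SWDAResult", function(object) object@reason)

setMethod("show", "SWDAResult", function(object) {
  cat("SWDAResult [factor set: ", object@factorSet, "]: ",
      nrow(object@steps), " step(s), stopped: ", object@reason, "\n",
      sep = "")
  if (nrow(object@steps)) {
    last <- object@steps[nrow(object@steps), ]
    cat(sprintf("  final Wilks' lambda %.4f, ASCC %.3f (target %.2f)\n",
                last$wilks, last$ascc, object@targetASCC))
    cat("  entered sites:", paste(object@steps$site, collapse = ", "), "\n")
  }
})

#' Write a stepwise entry table as TSV
#'
#' @param swda A \code{SWDAResult}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeStepTable <- function(swda, path) {
  utils::write.table(stepTable(swda), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a CVA classifier on the variables a stepwise analysis selected
#'
#' Refits [fitCVA()] restricted to the entered variables. Classification
#' then requires residues only at the selected sites, so sequences with gaps
#' elsewhere remain classifiable -- the practical advantage of the stepwise
#' model over the full CVA.
#'
#' @param x The \code{NumericDataset} (or matrix) the stepwise analysis was
#'   fitted on.
#' @param swda A \code{SWDAResult} with at least one step.
#' @param labels,priors,ridge Passed to [fitCVA()].
#' @return A \code{CVAModel} over the selected variables.
#' @export
swdaClassifier <- function(x, swda, labels = NULL, priors = "equal",
                           ridge = 0) {
  st <- stepTable(swda)
  if (!nrow(st)) stop("stepwise result has no entered variables")
  if (is(x, "NumericDataset")) {
    cols <- paste0(st$factor, "_s", st$site)
    x <- selectVariables(x, cols)
  } else {
    x <- as.matrix(x)[, st$site, drop = FALSE]
  }
  fitCVA(x, labels = labels, priors = priors, ridge = ridge)
}

#' Highly diagnostic sites from a stepwise analysis
#'
#' Sites whose entry partial r-squared exceeds a threshold (default 20%),
#' deduplicated across factor scores.
#'
#' @param swda A \code{SWDAResult}.
#' @param threshold Partial r-squared cutoff (strict inequality).
#' @return Sorted integer vector of sites.
#' @export
discerningSites <- function(swda, threshold = 0.20) {
  st <- stepTable(swda)
  sort(unique(st$site[st$partialR2 > threshold]))
}
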