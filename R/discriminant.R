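# Canonical variate analysis and Wilks' lambda on factor-score datasets.
#
# Conventions: W = within-group SSCP about group means, T = total SSCP about
# the grand mean, B = T - W. The CVA eigenproblem is B a = lambda W a, solved
# symmetrically through the Cholesky factor of W; canonical coefficients are
# scaled so each variate has unit pooled within-group variance
# (a' Sw a = 1, Sw = W / (n - G)).

.resolveXy <- function(x, labels = NULL) {
  if (is(x, "NumericDataset")) {
    if (is.null(labels)) labels <- classLabels(x)
    vars <- variableInfo(x)
    x <- values(x)
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
    vars <- data.frame(site = seq_len(ncol(x)),
                       factor = rep(NA_character_, ncol(x)),
                       stringsAsFactors = FALSE)
  }
  if (is.null(labels) || all(is.na(labels)))
    stop("group labels are required")
  keep <- stats::complete.cases(x) & !is.na(labels)
  list(x = x[keep, , drop = FALSE], y = as.character(labels)[keep],
       vars = vars, nDropped = sum(!keep))
}

.sscp <- function(x, y) {
  groups <- sort(unique(y))
  grand <- colMeans(x)
  tc <- sweep(x, 2L, grand)
  Tm <- crossprod(tc)
  W <- matrix(0, ncol(x), ncol(x))
  means <- matrix(NA_real_, ncol(x), length(groups),
                  dimnames = list(colnames(x), groups))
  for (g in groups) {
    xg <- x[y == g, , drop = FALSE]
    mg <- colMeans(xg)
    means[, g] <- mg
    W <- W + crossprod(sweep(xg, 2L, mg))
  }
  dimnames(W) <- dimnames(Tm) <- list(colnames(x), colnames(x))
  list(W = W, T = Tm, B = Tm - W, groups = groups, groupMeans = means,
       grandMean = grand, n = nrow(x), G = length(groups),
       counts = table(y)[groups])
}

.cholOrNULL <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  # Cholesky pivots of a numerically singular (collinear) matrix come out as
  # floating-point noise; a relative cut on the diagonal catches them
  if (!is.null(r) &&
      any(diag(r) < 1e-7 * max(diag(r), .Machine$double.eps)))
    return(NULL)
  r
}

# eigenvalues/vectors of solve(W) %*% B via the symmetric Cholesky route
.cvaEigen <- function(W, B, nKeep) {
  R <- .cholOrNULL(W)
  if (is.null(R))
    stop("within-group SSCP is singular (collinear or constant variables); ",
         "drop variables or use ridge > 0")
  Y <- backsolve(R, B, transpose = TRUE)          # R^-T B
  K <- backsolve(R, t(Y), transpose = TRUE)       # R^-T B' R^-1
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  keep <- seq_len(min(nKeep, length(lambda)))
  vec <- backsolve(R, eig$vectors[, keep, drop = FALSE])  # a: a'Wa = 1
  list(lambda = lambda, vectors = vec, keep = keep)
}

#' Wilks' lambda
#'
#' The likelihood-ratio statistic for equality of group means,
#' \eqn{\Lambda = \det(W) / \det(T)}: 1 means no separation, values near 0
#' strong separation. Rows with any missing value are dropped (complete-case).
#'
#' @param x A \code{NumericDataset} or numeric matrix.
#' @param labels Group labels; taken from the dataset when omitted.
#' @return \eqn{\Lambda} in \code{(0, 1]}.
#' @export
wilksLambda <- function(x, labels = NULL) {
  d <- .resolveXy(x, labels)
  s <- .sscp(d$x, d$y)
  Rt <- .cholOrNULL(s$T)
  if (is.null(Rt)) {
    rk <- qr(s$T)$rank
    stop("total SSCP is singular (rank ", rk, " < ", ncol(s$T),
         "); collinear variables, e.g. among: ",
         paste(utils::head(colnames(s$T), 5), collapse = ", "))
  }
  Rw <- .cholOrNULL(s$W)
  if (is.null(Rw))
    stop("within-group SSCP is singular; drop collinear variables")
  exp(2 * sum(log(diag(Rw))) - 2 * sum(log(diag(Rt))))
}

#' Average squared canonical correlation (ASCC)
#'
#' Pillai's trace of the group-separation eigenproblem divided by
#' \eqn{G - 1}: the mean squared canonical correlation across the canonical
#' variates. 1 would mean complete discrimination of the groups, 0 none.
#'
#' @inheritParams wilksLambda
#' @return A value in \code{[0, 1]}.
#' @export
ascc <- function(x, labels = NULL) {
  d <- .resolveXy(x, labels)
  s <- .sscp(d$x, d$y)
  ev <- .cvaEigen(s$W, s$B, ncol(s$W))
  rho2 <- ev$lambda / (1 + ev$lambda)
  sum(rho2) / (s$G - 1)
}

#' Fit a canonical variate analysis model
#'
#' Solves the generalized eigenproblem \eqn{B a = \lambda W a} on the
#' complete-case rows, keeping \eqn{\min(p, G - 1)} canonical variates scaled
#' to unit pooled within-group variance. The returned model carries
#' everything needed for classification: raw coefficients, group centroids in
#' canonical space, group means and the pooled within-group covariance in
#' variable space, and the group priors.
#'
#' @inheritParams wilksLambda
#' @param priors \code{"equal"} (default), \code{"proportional"}, or a named
#'   numeric vector over the groups.
#' @param ridge Optional non-negative ridge: \code{ridge * diag(diag(W)) / n}
#'   is added to \eqn{W}. Default 0 -- a singular \eqn{W} fails loudly rather
#'   than being silently regularized.
#' @return A \code{CVAModel}.
#' @export
fitCVA <- function(x, labels = NULL, priors = "equal", ridge = 0) {
  d <- .resolveXy(x, labels)
  p <- ncol(d$x)
  s <- .sscp(d$x, d$y)
  if (s$G < 2) stop("at least two groups are required")
  if (s$n < s$G + p)
    stop("need more complete-case rows (", s$n, ") than groups + variables (",
         s$G + p, ")")
  W <- s$W
  if (ridge > 0) W <- W + ridge * diag(diag(W), p) / s$n
  ncv <- min(p, s$G - 1)
  ev <- .cvaEigen(W, s$B, ncv)
  lambda <- ev$lambda[ev$keep]
  coef <- ev$vectors * sqrt(s$n - s$G)      # unit pooled within-group variance
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(ncol(coef))) {
    j <- which.max(abs(coef[, k]))
    if (coef[j, k] < 0) coef[, k] <- -coef[, k]
  }
  dimnames(coef) <- list(colnames(d$x), paste0("CV", seq_len(ncv)))
  pri <- .resolvePriors(priors, s$groups, s$counts)
  centroids <- t(crossprod(coef, s$groupMeans - s$grandMean))
  dimnames(centroids) <- list(s$groups, colnames(coef))
  new("CVAModel",
      variables = d$vars,
      coefficients = coef,
      eigenvalues = lambda,
      canCor2 = lambda / (1 + lambda),
      proportions = if (sum(lambda) > 0) lambda / sum(lambda)
                    else rep(0, length(lambda)),
      centroids = centroids,
      groupMeans = s$groupMeans,
      grandMean = s$grandMean,
      Sw = W / (s$n - s$G),
      priors = pri,
      groups = s$groups,
      nComplete = as.integer(s$n))
}

.resolvePriors <- function(priors, groups, counts) {
  if (identical(priors, "equal"))
    return(stats::setNames(rep(1 / length(groups), length(groups)), groups))
  if (identical(priors, "proportional"))
    return(stats::setNames(as.numeric(counts) / sum(counts), groups))
  if (is.numeric(priors) && !is.null(names(priors))) {
    pri <- priors[groups]
    if (anyNA(pri)) stop("priors must name every group")
    return(pri / sum(pri))
  }
  stop("priors must be 'equal', 'proportional', or a named numeric vector")
}

#' @describeIn CVAModel-accessors Raw canonical coefficients
#'   (p x number of canonical variates).
#' @export
setMethod("canonicalCoefficients", "CVAModel",
          function(object) object@coefficients)

#' @describeIn CVAModel-accessors Eigenvalues of the within-inverse times
#'   between problem, non-increasing.
#' @export
setMethod("eigenvalues", "CVAModel", function(object) object@eigenvalues)

#' @describeIn CVAModel-accessors Proportion of among-group variation
#'   explained per canonical variate.
#' @export
setMethod("varianceProportions", "CVAModel",
          function(object) object@proportions)

#' @describeIn CVAModel-accessors Group centroids in canonical space
#'   (G x number of canonical variates).
#' @export
setMethod("groupCentroids", "CVAModel", function(object) object@centroids)

#' @describeIn CVAModel-accessors (site, factor) descriptor per model
#'   variable.
#' @export
setMethod("modelVariables", "CVAModel", function(object) object@variables)

#' Accessors for fitted CVA models
#'
#' @param object A \code{CVAModel}.
#' @aliases CVAModel-class CVAModel canonicalCoefficients eigenvalues
#'   varianceProportions groupCentroids modelVariables
#' @name CVAModel-accessors
NULL

setMethod("show", "CVAModel", function(object) {
  cat("CVAModel: ", length(object@groups), " groups (",
      paste(object@groups, collapse = ", "), "), ",
      nrow(object@coefficients), " variable(s), ",
      ncol(object@coefficients), " canonical variate(s)\n", sep = "")
  cat("  fitted on", object@nComplete, "complete-case sequence(s)\n")
  cat(sprintf("  variance proportions: %s\n",
              paste(sprintf("%.1f%%", 100 * object@proportions),
                    collapse = ", ")))
})

#' Project sequences onto the canonical variates
#'
#' @param model A \code{CVAModel}.
#' @param x A \code{NumericDataset} or numeric matrix aligned to the model's
#'   variables (matched by descriptor name when available).
#' @return n x ncv matrix of canonical scores (NA rows where any model
#'   variable is missing).
#' @export
canonicalScores <- function(model, x) {
  xm <- .alignToModel(model, x)
  sweep(xm, 2L, model@grandMean) %*% model@coefficients
}

.alignToModel <- function(model, x) {
  want <- paste0(model@variables$factor, "_s", model@variables$site)
  if (is(x, "NumericDataset")) x <- values(x)
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !anyNA(model@variables$factor)) {
    if (!all(want %in% colnames(x)))
      stop("input lacks model variable(s): ",
           paste(utils::head(setdiff(want, colnames(x)), 5), collapse = ", "))
    x <- x[, want, drop = FALSE]
  } else if (ncol(x) != nrow(model@coefficients)) {
    stop("input has ", ncol(x), " variables; model expects ",
         nrow(model@coefficients))
  }
  x
}

#' Mahalanobis distance between two group centroids
#'
#' \eqn{\sqrt{(m_g - m_h)' S_W^{-1} (m_g - m_h)}} on the model's variables,
#' using the pooled within-group covariance -- a relative measure of the
#' divergence between groups.
#'
#' @param model A \code{CVAModel}.
#' @param g,h Group names.
#' @return Non-negative distance (0 when \code{g == h}).
#' @export
mahalanobisBetween <- function(model, g, h) {
  if (!all(c(g, h) %in% model@groups)) stop("unknown group name")
  dm <- model@groupMeans[, g] - model@groupMeans[, h]
  R <- chol(model@Sw)
  sqrt(sum(backsolve(R, dm, transpose = TRUE)^2))
}

#' Highly weighted sites per canonical variate
#'
#' Sites whose raw canonical coefficient exceeds a magnitude threshold in a
#' given variate; the conventional screen for discerning sites in a fitted
#' CVA. Thresholding is on raw coefficients, so it is sensitive to variable
#' scale; factor scores share a common standardized scale.
#'
#' @param model A \code{CVAModel}.
#' @param threshold Magnitude cutoff (default 1).
#' @return Named list, one sorted integer vector of sites per canonical
#'   variate.
#' @export
cvTopSites <- function(model, threshold = 1) {
  out <- lapply(seq_len(ncol(model@coefficients)), function(k) {
    hit <- abs(model@coefficients[, k]) > threshold
    sort(unique(model@variables$site[hit]))
  })
  stats::setNames(out, colnames(model@coefficients))
}
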