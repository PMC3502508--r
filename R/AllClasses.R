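#' @import methods
NULL

#' The twenty canonical amino acids
#'
#' Single-letter codes, alphabetical, used as the residue alphabet throughout
#' the package. Gaps are written \code{"-"}.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.GAP <- "-"
.UNCLASSIFIED <- "Unclassified"
.KINGDOMS <- c("Plant", "Animal", "Fungal")

#' Label used for sequences a model declines to classify
#'
#' @return The string \code{"Unclassified"}.
#' @export
unclassifiedLabel <- function() .UNCLASSIFIED

#' The three Kingdom labels
#'
#' @return \code{c("Plant", "Animal", "Fungal")}.
#' @export
kingdomLabels <- function() .KINGDOMS

# ---------------------------------------------------------------------------
# BhlhCoordinateMap
# ---------------------------------------------------------------------------

#' @rdname BhlhCoordinateMap
#' @export
setClass("BhlhCoordinateMap",
  representation(
    basic = "integer",
    helix1 = "integer",
    loop = "integer",
    helix2 = "integer"
  )
)

setValidity("BhlhCoordinateMap", function(object) {
  msg <- character()
  fx <- c(object@basic, object@helix1, object@helix2)
  if (anyDuplicated(c(fx, object@loop)))
    msg <- c(msg, "subdomain site ranges must be disjoint")
  if (is.unsorted(fx, strictly = TRUE) ||
      is.unsorted(object@loop, strictly = TRUE))
    msg <- c(msg, "site indices must be strictly increasing within subdomains")
  if (length(object@loop) &&
      (max(object@helix1) > min(object@loop) ||
       max(object@loop) > min(object@helix2)))
    msg <- c(msg, "loop must lie between helix 1 and helix 2")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EnumeratedAlignment
# ---------------------------------------------------------------------------

#' @rdname EnumeratedAlignment
#' @export
setClass("EnumeratedAlignment",
  representation(
    residues = "matrix",      # character, n x n_fixed_sites
    loopSeqs = "character",   # one (possibly empty) string per record
    kingdom = "character",    # Plant/Animal/Fungal or NA
    map = "BhlhCoordinateMap"
  )
)

setValidity("EnumeratedAlignment", function(object) {
  msg <- character()
  fx <- fixedSites(object@map)
  if (!is.character(object@residues))
    msg <- c(msg, "residues must be a character matrix")
  if (ncol(object@residues) != length(fx))
    msg <- c(msg, sprintf("residues must have %d columns (one per fixed site)",
                          length(fx)))
  if (!identical(colnames(object@residues), paste0("s", fx)))
    msg <- c(msg, "residue columns must be named s<site> in fixed-site order")
  if (is.null(rownames(object@residues)) ||
      anyDuplicated(rownames(object@residues)))
    msg <- c(msg, "sequence ids (rownames) must be present and unique")
  bad <- setdiff(unique(as.vector(object@residues)), c(aminoAcids(), .GAP))
  if (length(bad))
    msg <- c(msg, paste0("residues outside the amino-acid alphabet: ",
                         paste(bad, collapse = ", ")))
  n <- nrow(object@residues)
  if (length(object@loopSeqs) != n || length(object@kingdom) != n)
    msg <- c(msg, "loopSeqs and kingdom must have one entry per record")
  kk <- object@kingdom[!is.na(object@kingdom)]
  if (length(setdiff(kk, .KINGDOMS)))
    msg <- c(msg, "kingdom labels must be Plant, Animal or Fungal (or NA)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# NumericDataset
# ---------------------------------------------------------------------------

#' @rdname NumericDataset
#' @export
setClass("NumericDataset",
  representation(
    values = "matrix",       # numeric, n x p, NA where residue was a gap
    variables = "data.frame", # columns: site (int), factor (chr)
    labels = "character",    # kingdom per row or NA
    factorSet = "character"  # pah/pss/ms/cc/ec/all
  )
)

setValidity("NumericDataset", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (nrow(object@variables) != ncol(object@values))
    msg <- c(msg, "one variable descriptor per column required")
  if (!all(c("site", "factor") %in% names(object@variables)))
    msg <- c(msg, "variables must have 'site' and 'factor' columns")
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, "one label (possibly NA) per row required")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CVAModel
# ---------------------------------------------------------------------------

#' @rdname CVAModel
#' @export
setClass("CVAModel",
  representation(
    variables = "data.frame",   # (site, factor) per model variable
    coefficients = "matrix",    # p x ncv raw canonical coefficients
    eigenvalues = "numeric",    # of solve(W) %*% B, non-increasing
    canCor2 = "numeric",        # squared canonical correlations
    proportions = "numeric",    # eigenvalue / sum(eigenvalues)
    centroids = "matrix",       # G x ncv group means in canonical space
    groupMeans = "matrix",      # p x G group means in variable space
    grandMean = "numeric",      # length p
    Sw = "matrix",              # pooled within-group covariance, p x p
    priors = "numeric",         # named, sums to 1
    groups = "character",
    nComplete = "integer"
  )
)

setValidity("CVAModel", function(object) {
  msg <- character()
  p <- nrow(object@coefficients)
  G <- length(object@groups)
  if (nrow(object@variables) != p)
    msg <- c(msg, "one variable descriptor per coefficient row required")
  if (length(object@eigenvalues) != ncol(object@coefficients))
    msg <- c(msg, "one eigenvalue per canonical variate required")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@canCor2 < 0 | object@canCor2 >= 1))
    msg <- c(msg, "squared canonical correlations must lie in [0, 1)")
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  if (!identical(dim(object@Sw), c(p, p)))
    msg <- c(msg, "Sw must be p x p")
  if (nrow(object@centroids) != G || ncol(object@groupMeans) != G)
    msg <- c(msg, "centroids/groupMeans must have one entry per group")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SWDAResult
# ---------------------------------------------------------------------------

#' @rdname SWDAResult
#' @export
setClass("SWDAResult",
  representation(
    steps = "data.frame",   # step, site, factor, wilks, partialR2, F, p, ascc
    reason = "character",   # why stepping stopped
    factorSet = "character",
    targetASCC = "numeric",
    groups = "character",
    nComplete = "integer"
  )
)

setValidity("SWDAResult", function(object) {
  msg <- character()
  need <- c("step", "site", "factor", "wilks", "partialR2", "F", "p", "ascc")
  if (!all(need %in% names(object@steps)))
    msg <- c(msg, paste("steps must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@steps) > 1) {
    if (any(diff(object@steps$wilks) >= 0))
      msg <- c(msg, "Wilks' lambda must strictly decrease across steps")
    if (any(diff(object@steps$ascc) < -1e-10))
      msg <- c(msg, "ASCC must be non-decreasing across steps")
  }
  if (nrow(object@steps) &&
      any(object@steps$partialR2 < 0 | object@steps$partialR2 > 1))
    msg <- c(msg, "partial r-squared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ProfileHMM
# ---------------------------------------------------------------------------

#' @rdname ProfileHMM
#' @export
setClass("ProfileHMM",
  representation(
    matchEmissions = "matrix",  # L x 20, rows sum to 1
    background = "numeric",     # length 20, sums to 1; also insert emission
    deleteEntry = "numeric",    # length L, P(enter delete at column j)
    matchInsert = "numeric",    # P(M -> I)
    insertInsert = "numeric",   # P(I -> I)
    deleteDelete = "numeric",   # P(D -> D)
    helix = "character",
    kingdom = "character"
  )
)

setValidity("ProfileHMM", function(object) {
  msg <- character()
  L <- nrow(object@matchEmissions)
  if (ncol(object@matchEmissions) != 20L)
    msg <- c(msg, "matchEmissions must have 20 columns")
  if (any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    msg <- c(msg, "each match emission distribution must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background distribution must sum to 1")
  if (length(object@deleteEntry) != L)
    msg <- c(msg, "one delete-entry probability per column required")
  pr <- c(object@deleteEntry, object@matchInsert, object@insertInsert,
          object@deleteDelete)
  if (any(pr < 0 | pr >= 1))
    msg <- c(msg, "transition probabilities must lie in [0, 1)")
  if (any(object@matchInsert + object@deleteEntry >= 1))
    msg <- c(msg, "matchInsert + deleteEntry must leave mass for M->M")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# BhlhDecisionTree
# ---------------------------------------------------------------------------

#' @rdname BhlhDecisionTree
#' @export
setClass("BhlhDecisionTree",
  representation(
    root = "list",
    config = "list",
    groups = "character"
  )
)
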