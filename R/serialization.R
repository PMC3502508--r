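# JSON serialization of fitted models (plain text, round-trips exactly
# at full double precision).

.mat2list <- function(m) {
  list(values = as.numeric(m), nrow = nrow(m), ncol = ncol(m),
       rownames = rownames(m), colnames = colnames(m))
}

.list2mat <- function(l) {
  m <- matrix(as.numeric(l$values), l$nrow[[1]], l$ncol[[1]])
  if (!is.null(l$rownames) && length(l$rownames))
    rownames(m) <- as.character(l$rownames)
  if (!is.null(l$colnames) && length(l$colnames))
    colnames(m) <- as.character(l$colnames)
  m
}

#' Export or import a fitted CVA model as JSON
#'
#' @param model A \code{CVAModel}.
#' @param path JSON file.
#' @return \code{exportCVAModel}: \code{path} invisibly;
#'   \code{importCVAModel}: the reconstructed \code{CVAModel}.
#' @export
exportCVAModel <- function(model, path) {
  obj <- list(
    type = "CVAModel",
    variables = model@variables,
    coefficients = .mat2list(model@coefficients),
    eigenvalues = model@eigenvalues,
    canCor2 = model@canCor2,
    proportions = model@proportions,
    centroids = .mat2list(model@centroids),
    groupMeans = .mat2list(model@groupMeans),
    grandMean = model@grandMean,
    Sw = .mat2list(model@Sw),
    priors = as.list(model@priors),
    groups = model@groups,
    nComplete = model@nComplete)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname exportCVAModel
#' @export
importCVAModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$type, "CVAModel")) stop("not a serialized CVAModel")
  new("CVAModel",
      variables = data.frame(site = as.integer(o$variables$site),
                             factor = as.character(o$variables$factor),
                             stringsAsFactors = FALSE),
      coefficients = .list2mat(o$coefficients),
      eigenvalues = as.numeric(o$eigenvalues),
      canCor2 = as.numeric(o$canCor2),
      proportions = as.numeric(o$proportions),
      centroids = .list2mat(o$centroids),
      groupMeans = .list2mat(o$groupMeans),
      grandMean = as.numeric(o$grandMean),
      Sw = .list2mat(o$Sw),
      priors = unlist(o$priors),
      groups = as.character(o$groups),
      nComplete = as.integer(o$nComplete))
}

#' Export or import a decision tree as JSON
#'
#' Nested-node layout mirroring the fitted tree.
#'
#' @param tree A \code{BhlhDecisionTree}.
#' @param path JSON file.
#' @return \code{exportDecisionTree}: \code{path} invisibly;
#'   \code{importDecisionTree}: the reconstructed tree.
#' @export
exportDecisionTree <- function(tree, path) {
  prep <- function(node) {
    node$counts <- as.list(node$counts)   # keep group names in JSON
    if (!isTRUE(node$leaf)) {
      node$children$left <- prep(node$children$left)
      node$children$right <- prep(node$children$right)
    }
    node
  }
  obj <- list(type = "BhlhDecisionTree", root = prep(tree@root),
              config = tree@config, groups = tree@groups)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname exportDecisionTree
#' @export
importDecisionTree <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$type, "BhlhDecisionTree"))
    stop("not a serialized decision tree")
  fix <- function(node) {
    node$counts <- vapply(node$counts, as.integer, integer(1))
    node$n <- as.integer(node$n)
    node$depth <- as.integer(node$depth)
    if (!isTRUE(node$leaf)) {
      node$site <- as.integer(node$site)
      node$children$left <- fix(node$children$left)
      node$children$right <- fix(node$children$right)
    }
    node
  }
  new("BhlhDecisionTree", root = fix(o$root),
      config = lapply(o$config, as.numeric),
      groups = as.character(o$groups))
}

#' Export or import a profile HMM as JSON
#'
#' @param hmm A \code{ProfileHMM}.
#' @param path JSON file.
#' @return \code{exportProfileHMM}: \code{path} invisibly;
#'   \code{importProfileHMM}: the reconstructed \code{ProfileHMM}.
#' @export
exportProfileHMM <- function(hmm, path) {
  obj <- list(type = "ProfileHMM",
              matchEmissions = .mat2list(hmm@matchEmissions),
              background = as.list(hmm@background),
              deleteEntry = hmm@deleteEntry,
              matchInsert = hmm@matchInsert,
              insertInsert = hmm@insertInsert,
              deleteDelete = hmm@deleteDelete,
              helix = hmm@helix, kingdom = hmm@kingdom)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname exportProfileHMM
#' @export
importProfileHMM <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$type, "ProfileHMM")) stop("not a serialized ProfileHMM")
  new("ProfileHMM",
      matchEmissions = .list2mat(o$matchEmissions),
      background = unlist(o$background),
      deleteEntry = as.numeric(o$deleteEntry),
      matchInsert = as.numeric(o$matchInsert),
      insertInsert = as.numeric(o$insertInsert),
      deleteDelete = as.numeric(o$deleteDelete),
      helix = as.character(o$helix),
      kingdom = as.character(o$kingdom))
}
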