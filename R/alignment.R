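#' Enumerated bHLH domain alignments
#'
#' An \code{EnumeratedAlignment} holds domain sequences mapped onto the fixed
#' bHLH site numbering (sites 1-28 and 50-64 under the default coordinate
#' map), one row per sequence, with optional Kingdom labels and optional loop
#' residues. Gaps are \code{"-"}. Ambiguity codes (B, J, Z, X, U, O) carry no
#' factor scores and are converted to gaps with a warning.
#'
#' @param residues Character matrix (n records x 43 fixed sites) of
#'   single-letter residues, or a character vector of 43-character strings.
#'   Row names (or names) give sequence ids; unnamed input gets
#'   \code{seq_1, ...}.
#' @param kingdom Character vector of Kingdom labels (\code{"Plant"},
#'   \code{"Animal"}, \code{"Fungal"}) or \code{NA}; recycled if length 1.
#' @param loopSeqs Character vector of loop residues (one string per record,
#'   \code{""} if absent); recycled if length 1.
#' @param map A \code{BhlhCoordinateMap}.
#' @param x An \code{EnumeratedAlignment} (accessors).
#'
#' @return \code{EnumeratedAlignment} constructs the object. \code{seqIds},
#'   \code{kingdoms}, \code{loopSeqs} return per-record vectors;
#'   \code{residueMatrix} the n x 43 residue matrix (columns \code{s<site>});
#'   \code{coordinateMap} the coordinate map.
#' @aliases EnumeratedAlignment-class seqIds kingdoms residueMatrix loopSeqs
#'   coordinateMap
#' @name EnumeratedAlignment
#' @export
#' @examples
#' aa <- paste(rep("A", 43), collapse = "")
#' aln <- EnumeratedAlignment(c(x1 = aa, x2 = aa), kingdom = "Plant")
#' seqIds(aln)
#' residueMatrix(aln)[, "s27"]
EnumeratedAlignment <- function(residues, kingdom = NA_character_,
                                loopSeqs = "", map = BhlhCoordinates()) {
  fx <- fixedSites(map)
  if (is.character(residues) && !is.matrix(residues)) {
    if (any(nchar(residues) != length(fx)))
      stop("each sequence string must have exactly ", length(fx),
           " characters (one per fixed site)")
    nm <- names(residues)
    residues <- do.call(rbind, strsplit(residues, "", fixed = TRUE))
    rownames(residues) <- nm
  }
  if (is.null(rownames(residues)))
    rownames(residues) <- paste0("seq_", seq_len(nrow(residues)))
  residues <- toupper(residues)
  residues <- .maskAmbiguity(residues)
  colnames(residues) <- paste0("s", fx)
  n <- nrow(residues)
  new("EnumeratedAlignment",
      residues = residues,
      loopSeqs = rep_len(as.character(loopSeqs), n),
      kingdom = rep_len(as.character(kingdom), n),
      map = map)
}

.AMBIGUOUS <- c("B", "J", "Z", "X", "U", "O", ".")

.maskAmbiguity <- function(residues) {
  hit <- residues %in% .AMBIGUOUS
  if (any(hit)) {
    warning(sum(hit), " ambiguity-code residue(s) (",
            paste(sort(unique(residues[hit])), collapse = ", "),
            ") converted to gaps: factor scores exist only for the 20 ",
            "canonical amino acids")
    residues[hit] <- .GAP
  }
  residues
}

#' @rdname EnumeratedAlignment
#' @export
setMethod("seqIds", "EnumeratedAlignment", function(x) rownames(x@residues))

#' @rdname EnumeratedAlignment
#' @export
setMethod("kingdoms", "EnumeratedAlignment", function(x) x@kingdom)

#' @rdname EnumeratedAlignment
#' @export
setMethod("residueMatrix", "EnumeratedAlignment", function(x) x@residues)

#' @rdname EnumeratedAlignment
#' @export
setMethod("loopSeqs", "EnumeratedAlignment", function(x) x@loopSeqs)

#' @rdname EnumeratedAlignment
#' @export
setMethod("coordinateMap", "EnumeratedAlignment", function(x) x@map)

#' @rdname EnumeratedAlignment
#' @export
setMethod("length", "EnumeratedAlignment", function(x) nrow(x@residues))

#' @param i Record indices (integer, logical or sequence ids).
#' @param j,drop,... Ignored.
#' @rdname EnumeratedAlignment
#' @export
setMethod("[", "EnumeratedAlignment", function(x, i, j, ..., drop = FALSE) {
  new("EnumeratedAlignment",
      residues = x@residues[i, , drop = FALSE],
      loopSeqs = x@loopSeqs[i],
      kingdom = x@kingdom[i],
      map = x@map)
})

#' Residues of one site across an alignment
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param site A fixed site index.
#' @return Named character vector of residues (gaps included).
#' @export
siteResidues <- function(alignment, site) {
  col <- paste0("s", site)
  if (!col %in% colnames(alignment@residues))
    stop("site ", site, " is not a fixed site of the coordinate map")
  stats::setNames(alignment@residues[, col], seqIds(alignment))
}

setMethod("show", "EnumeratedAlignment", function(object) {
  n <- length(object)
  cat("EnumeratedAlignment with ", n, " record(s) over ",
      ncol(object@residues), " fixed sites\n", sep = "")
  kk <- table(factor(object@kingdom, levels = .KINGDOMS), useNA = "ifany")
  cat("  kingdoms: ",
      paste(sprintf("%s=%d", names(kk), kk), collapse = ", "), "\n", sep = "")
  gp <- mean(object@residues == .GAP)
  cat(sprintf("  gap fraction: %.3f\n", gp))
})
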