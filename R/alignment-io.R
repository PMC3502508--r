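#' Read an enumerated bHLH alignment
#'
#' Two plain-text layouts are supported. An aligned FASTA whose sequences all
#' have exactly as many columns as the coordinate map has fixed sites (43 by
#' default): column k maps to the k-th fixed site; Kingdom labels can be
#' supplied separately. Or a TSV with columns \code{sequence_id},
#' \code{kingdom}, \code{site_1 ... site_28}, \code{site_50 ... site_64} and
#' an optional \code{loop} column.
#'
#' @param path File to read.
#' @param format \code{"auto"} (by extension), \code{"fasta"} or \code{"tsv"}.
#' @param labels Optional TSV with columns \code{sequence_id} and
#'   \code{kingdom}, used to label FASTA input.
#' @param map A \code{BhlhCoordinateMap}.
#' @return An \code{EnumeratedAlignment}; input order is preserved.
#' @seealso [writeEnumeratedAlignment()]
#' @export
readEnumeratedAlignment <- function(path, format = c("auto", "fasta", "tsv"),
                                    labels = NULL, map = BhlhCoordinates()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa|afa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  aln <- if (format == "fasta") .readAlignedFasta(path, map)
         else .readAlignedTsv(path, map)
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, stringsAsFactors = FALSE)
    if (!all(c("sequence_id", "kingdom") %in% names(lab)))
      stop("labels file needs columns 'sequence_id' and 'kingdom'")
    king <- lab$kingdom[match(seqIds(aln), lab$sequence_id)]
    aln <- EnumeratedAlignment(residueMatrix(aln), kingdom = king,
                               loopSeqs = loopSeqs(aln), map = map)
  }
  aln
}

.readAlignedFasta <- function(path, map) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated sequence_id in ", path, ": ",
         ids[duplicated(ids)][1])
  nf <- length(fixedSites(map))
  wid <- Biostrings::width(seqs)
  if (any(wid != nf))
    stop("record '", ids[which(wid != nf)[1]], "' has ", wid[wid != nf][1],
         " columns; aligned FASTA input must have exactly ", nf,
         " columns (one per fixed site); use the TSV layout otherwise")
  chars <- as.character(seqs)
  names(chars) <- ids
  EnumeratedAlignment(chars, map = map)
}

.readAlignedTsv <- function(path, map) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (!"sequence_id" %in% names(tab))
    stop("TSV alignment needs a 'sequence_id' column")
  if (anyDuplicated(tab$sequence_id))
    stop("duplicated sequence_id: ",
         tab$sequence_id[duplicated(tab$sequence_id)][1])
  fx <- fixedSites(map)
  need <- paste0("site_", fx)
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("TSV alignment is missing site columns: ",
         paste(utils::head(missing, 5), collapse = ", "))
  res <- as.matrix(tab[, need, drop = FALSE])
  res[is.na(res) | res == ""] <- .GAP
  bad <- which(nchar(res) != 1L, arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed record '", tab$sequence_id[bad[1, 1]],
         "': cell ", need[bad[1, 2]], " is not a single residue")
  rownames(res) <- tab$sequence_id
  king <- if ("kingdom" %in% names(tab)) {
    k <- tab$kingdom
    k[k == ""] <- NA_character_
    k
  } else NA_character_
  loop <- if ("loop" %in% names(tab)) {
    l <- tab$loop
    l[is.na(l)] <- ""
    l
  } else ""
  EnumeratedAlignment(res, kingdom = king, loopSeqs = loop, map = map)
}

#' Write an enumerated alignment
#'
#' The TSV layout keeps Kingdom labels and loop residues and round-trips
#' exactly through [readEnumeratedAlignment()]. The FASTA layout writes the
#' 43 fixed-site columns only.
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param path Output file.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @return \code{path}, invisibly.
#' @export
writeEnumeratedAlignment <- function(alignment, path,
                                     format = c("tsv", "fasta")) {
  format <- match.arg(format)
  res <- residueMatrix(alignment)
  if (format == "fasta") {
    lines <- character(2L * nrow(res))
    lines[c(TRUE, FALSE)] <- paste0(">", seqIds(alignment))
    lines[c(FALSE, TRUE)] <- apply(res, 1L, paste, collapse = "")
    writeLines(lines, path)
  } else {
    fx <- fixedSites(coordinateMap(alignment))
    tab <- data.frame(sequence_id = seqIds(alignment),
                      kingdom = kingdoms(alignment),
                      res, loop = loopSeqs(alignment),
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(tab)[2L + seq_along(fx)] <- paste0("site_", fx)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write a numeric factor-score dataset as TSV
#'
#' Header row carries \code{<factor>_s<site>} variable descriptors; missing
#' cells (gaps) are written as \code{NA}.
#'
#' @param dataset A \code{NumericDataset}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeNumericDataset <- function(dataset, path) {
  tab <- data.frame(sequence_id = rownames(values(dataset)),
                    kingdom = classLabels(dataset),
                    values(dataset),
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
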