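#' Physicochemical amino-acid grouping
#'
#' The eight-group partition used for grouped conservation entropy: acidic
#' (DE), basic (HKR), aromatic (FWY), aliphatic (AGILMV), aminic (NQ),
#' hydroxylated (ST), and the singletons C and P.
#'
#' @return Named list of eight character vectors partitioning the 20 amino
#'   acids.
#' @export
aminoAcidGroups <- function() {
  list(acidic = c("D", "E"),
       basic = c("H", "K", "R"),
       aromatic = c("F", "W", "Y"),
       aliphatic = c("A", "G", "I", "L", "M", "V"),
       aminic = c("N", "Q"),
       hydroxylated = c("S", "T"),
       C = "C",
       P = "P")
}

.groupOf <- function() {
  g <- aminoAcidGroups()
  stats::setNames(rep(names(g), lengths(g)), unlist(g))
}

#' Residue frequencies at one site
#'
#' Counts and relative frequencies of the residues observed at a fixed site.
#' Gaps are excluded from the denominator: frequencies are residue
#' concentrations among the sequences that have a residue at the site.
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param site A fixed site index.
#' @return List with \code{site}, named \code{counts}, named \code{freqs}
#'   (sum to 1 when anything is observed), \code{nObserved} and \code{nGaps}.
#' @export
#' @examples
#' aln <- EnumeratedAlignment(c(paste(rep("L", 43), collapse = ""),
#'                              paste(rep("V", 43), collapse = "")))
#' siteFrequencies(aln, 27)$freqs
siteFrequencies <- function(alignment, site) {
  res <- siteResidues(alignment, site)
  obs <- res[res != .GAP]
  counts <- table(factor(obs, levels = aminoAcids()))
  counts <- counts[counts > 0]
  counts <- stats::setNames(as.integer(counts), names(counts))
  freqs <- if (length(obs)) counts / length(obs) else stats::setNames(numeric(), character())
  list(site = site, counts = counts, freqs = freqs,
       nObserved = length(obs), nGaps = length(res) - length(obs))
}

#' Normalized group entropy of a site
#'
#' Shannon entropy of the residue distribution collapsed onto the eight
#' physicochemical groups, normalized by its maximum (log of the number of
#' groups) so that 0 means all observed residues fall in one group and 1
#' means the eight groups are equally occupied. The value is independent of
#' the logarithm base (natural log internally, normalized by \code{log(8)}).
#'
#' @param freqs Output of [siteFrequencies()], or a named numeric frequency
#'   vector over residues.
#' @param grouping Partition of the amino acids; defaults to
#'   [aminoAcidGroups()].
#' @return A value in \code{[0, 1]}, or \code{NA} when nothing is observed at
#'   the site (all gaps) -- never 0.
#' @export
normalizedGroupEntropy <- function(freqs, grouping = aminoAcidGroups()) {
  f <- if (is.list(freqs) && !is.null(freqs$freqs)) freqs$freqs else freqs
  if (!length(f) || sum(f) == 0) return(NA_real_)
  gmap <- stats::setNames(rep(names(grouping), lengths(grouping)),
                          unlist(grouping))
  pg <- tapply(as.numeric(f), gmap[names(f)], sum)
  pg <- pg[pg > 0]
  -sum(pg * log(pg)) / log(length(grouping))
}

#' Sequence-logo bit scores of a site
#'
#' Information content \eqn{R = \log_2 20 - H_{20}} where \eqn{H_{20}} is the
#' Shannon entropy (bits) of the 20-residue frequency distribution; each
#' residue's logo height is its frequency times \eqn{R}. An optional
#' small-sample correction subtracts the standard \eqn{e_n = 19 / (2 n \ln 2)}
#' term from \eqn{R} (floored at 0), for comparability with logo tools.
#'
#' @param freqs Output of [siteFrequencies()].
#' @param correction Apply the small-sample correction (default off).
#' @return List with \code{information} (bits) and named \code{heights}
#'   (non-negative, summing to \code{information}); \code{NA}s when the site
#'   is all gaps.
#' @export
logoBits <- function(freqs, correction = FALSE) {
  f <- freqs$freqs
  if (!length(f))
    return(list(information = NA_real_, heights = stats::setNames(numeric(), character())))
  h20 <- -sum(f * log2(f))
  r <- log2(20) - h20
  if (correction && freqs$nObserved > 0)
    r <- max(0, r - 19 / (2 * freqs$nObserved * log(2)))
  list(information = r, heights = f * r)
}

#' 50-10 consensus motif of an alignment
#'
#' A site contributes to the consensus when its most frequent residue has a
#' concentration strictly above 50%; at such a site every residue with
#' concentration strictly above 10% is listed, primary residue first, the
#' rest by decreasing frequency. All other sites are unconstrained.
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param primary,secondary Concentration thresholds (strict inequalities).
#' @return Named list over fixed sites: a character vector of residues, or
#'   \code{NULL} for unconstrained sites. The printable one-line motif is in
#'   attribute \code{"motif"} (unconstrained sites shown as \code{"x"}).
#' @export
consensusMotif <- function(alignment, primary = 0.5, secondary = 0.1) {
  fx <- fixedSites(coordinateMap(alignment))
  out <- vector("list", length(fx))
  names(out) <- paste0("s", fx)
  for (k in seq_along(fx)) {
    f <- siteFrequencies(alignment, fx[k])$freqs
    if (!length(f)) next
    f <- sort(f, decreasing = TRUE)
    if (f[1] > primary)
      out[[k]] <- names(f)[f > secondary]
  }
  motif <- vapply(out, function(r) {
    if (is.null(r)) "x"
    else if (length(r) == 1L) r
    else paste0("[", paste(r, collapse = ""), "]")
  }, character(1))
  attr(out, "motif") <- paste(motif, collapse = "")
  out
}

#' Per-site conservation profile
#'
#' Normalized group entropy, logo information content and the 50-10 consensus
#' for every fixed site of an alignment (optionally restricted to one
#' Kingdom).
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param kingdom Optional single Kingdom label to subset to.
#' @param correction Passed to [logoBits()].
#' @return data.frame with one row per fixed site: \code{site},
#'   \code{n_observed}, \code{group_entropy}, \code{information_bits},
#'   \code{consensus} (\code{"x"} when unconstrained).
#' @export
conservationProfile <- function(alignment, kingdom = NULL,
                                correction = FALSE) {
  if (!is.null(kingdom))
    alignment <- alignment[which(kingdoms(alignment) == kingdom)]
  fx <- fixedSites(coordinateMap(alignment))
  cons <- consensusMotif(alignment)
  rows <- lapply(seq_along(fx), function(k) {
    fr <- siteFrequencies(alignment, fx[k])
    lb <- logoBits(fr, correction = correction)
    r <- cons[[k]]
    data.frame(site = fx[k],
               n_observed = fr$nObserved,
               group_entropy = normalizedGroupEntropy(fr),
               information_bits = lb$information,
               consensus = if (is.null(r)) "x" else paste(r, collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export per-residue logo heights as TSV
#'
#' Long-format table (site, residue, frequency, bits) consumable by standard
#' logo plotters.
#'
#' @param alignment An \code{EnumeratedAlignment}.
#' @param path Output file.
#' @param correction Passed to [logoBits()].
#' @return \code{path}, invisibly.
#' @export
writeLogoHeights <- function(alignment, path, correction = FALSE) {
  fx <- fixedSites(coordinateMap(alignment))
  rows <- lapply(fx, function(s) {
    fr <- siteFrequencies(alignment, s)
    lb <- logoBits(fr, correction = correction)
    if (!length(lb$heights)) return(NULL)
    data.frame(site = s, residue = names(lb$heights),
               frequency = as.numeric(fr$freqs),
               bits = as.numeric(lb$heights), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
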