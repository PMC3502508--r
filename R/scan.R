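# Two-helix bHLH identification and proteome scanning.

#' Build the two-helix HMM pair of one Kingdom
#'
#' Subsets a labelled alignment to one Kingdom and builds a Helix 1 and a
#' Helix 2 profile HMM from it.
#'
#' @param alignment A labelled \code{EnumeratedAlignment}.
#' @param kingdom Kingdom to model.
#' @param ... Passed to [buildProfileHMM()].
#' @return List with elements \code{helix1}, \code{helix2} (each a
#'   \code{ProfileHMM}) and \code{kingdom}.
#' @export
buildKingdomHMMs <- function(alignment, kingdom, ...) {
  idx <- which(kingdoms(alignment) == kingdom)
  if (!length(idx)) stop("no sequences labelled ", kingdom)
  sub <- alignment[idx]
  list(helix1 = buildProfileHMM(sub, "helix1", kingdom = kingdom, ...),
       helix2 = buildProfileHMM(sub, "helix2", kingdom = kingdom, ...),
       kingdom = kingdom)
}

#' Identify a bHLH domain in one protein
#'
#' A sequence is identified as bHLH if and only if the best Helix 1 hit
#' completely precedes the best Helix 2 hit, both helices score strictly
#' above the threshold, and the residues between the two hits fit a bHLH
#' loop. The loop of the domain is variable in length but short -- the fixed
#' site numbering reserves positions 29-49 for it -- so two high-scoring
#' windows at opposite ends of a protein are not a domain; \code{maxLoop}
#' bounds the separation (set it to \code{Inf} to disable).
#'
#' @param query Protein sequence (string or character vector).
#' @param hmms A Kingdom HMM pair from [buildKingdomHMMs()] (or any list with
#'   \code{helix1}/\code{helix2} \code{ProfileHMM}s).
#' @param threshold Per-helix bit-score cutoff, strict (default 0.1).
#' @param maxLoop Maximum number of residues between the Helix 1 and Helix 2
#'   hits (default 30: the 21 enumerable loop sites plus slack).
#' @param id Optional query id carried through.
#' @return List with \code{id}, \code{helix1}/\code{helix2} hits (or
#'   \code{NULL}), \code{identified} flag and \code{kingdom}.
#' @export
identifyBhlh <- function(query, hmms, threshold = 0.1, maxLoop = 30,
                         id = NA_character_) {
  h1 <- viterbiHit(hmms$helix1, query)
  h2 <- viterbiHit(hmms$helix2, query)
  identified <- !is.null(h1) && !is.null(h2) &&
    h1$qend < h2$qstart &&
    (h2$qstart - h1$qend - 1L) <= maxLoop &&
    h1$score > threshold && h2$score > threshold
  list(id = id, helix1 = h1, helix2 = h2, identified = identified,
       kingdom = if (!is.null(hmms$kingdom)) hmms$kingdom else NA_character_)
}

#' Scan a proteome with Kingdom-specific HMM pairs
#'
#' Runs [identifyBhlh()] for every sequence against every Kingdom pair and
#' summarises which sequences each Kingdom model identified, the Venn-style
#' overlap of the identified sets, and the sequences identified by exactly
#' one Kingdom.
#'
#' @param sequences FASTA path, \code{Biostrings::AAStringSet}, or named
#'   character vector of protein sequences.
#' @param hmmPairs Named list of Kingdom HMM pairs ([buildKingdomHMMs()]).
#' @param threshold Per-helix bit-score cutoff.
#' @param maxLoop Maximum separation of the two helix hits; see
#'   [identifyBhlh()].
#' @return List with \code{calls} (per Kingdom, per sequence), \code{identified}
#'   (per Kingdom character vectors of ids), \code{overlap} (table of counts
#'   by membership pattern), and \code{unique} (ids identified by exactly one
#'   Kingdom, per Kingdom).
#' @export
scanProteome <- function(sequences, hmmPairs, threshold = 0.1,
                         maxLoop = 30) {
  seqs <- .asProteinVector(sequences)
  if (is.null(names(hmmPairs)))
    names(hmmPairs) <- vapply(hmmPairs, function(p)
      as.character(p$kingdom), character(1))
  calls <- lapply(hmmPairs, function(pair) {
    out <- lapply(names(seqs), function(id)
      identifyBhlh(seqs[[id]], pair, threshold = threshold,
                   maxLoop = maxLoop, id = id))
    names(out) <- names(seqs)
    out
  })
  identified <- lapply(calls, function(cl)
    names(cl)[vapply(cl, `[[`, logical(1), "identified")])
  allIds <- unique(unlist(identified))
  pattern <- vapply(allIds, function(id)
    paste(names(identified)[vapply(identified, function(v) id %in% v,
                                   logical(1))], collapse = "+"),
    character(1))
  uniq <- lapply(names(identified), function(k)
    allIds[pattern == k])
  names(uniq) <- names(identified)
  list(calls = calls, identified = identified,
       overlap = if (length(allIds)) table(pattern) else table(character()),
       unique = uniq)
}

.asProteinVector <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)
  if (methods::is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences),
                                 sub("\\s.*$", "", names(sequences)))
  if (!is.character(sequences))
    stop("sequences must be a FASTA path, an AAStringSet, or a named ",
         "character vector")
  if (length(sequences) && is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  sequences
}

#' Map an identified bHLH call back onto the fixed site numbering
#'
#' Helix 1 match states map to sites 14-28 and Helix 2 match states to sites
#' 50-64 (via each hit's state path, so partial or gapped hits leave gaps at
#' the unmatched sites). The 13 residues immediately preceding the Helix 1
#' hit map to sites 1-13, gap-padded on the left when the hit starts near the
#' N-terminus; residues between the two hits are stored as the loop,
#' truncated to the loop capacity of the coordinate map.
#'
#' @param call An identified call from [identifyBhlh()].
#' @param query The protein sequence the call was made on.
#' @param map A \code{BhlhCoordinateMap}.
#' @return A one-record \code{EnumeratedAlignment}.
#' @export
extractDomain <- function(call, query, map = BhlhCoordinates()) {
  if (!isTRUE(call$identified))
    stop("extractDomain requires an identified call")
  if (length(query) == 1L) query <- strsplit(query, "", fixed = TRUE)[[1]]
  fx <- fixedSites(map)
  res <- stats::setNames(rep(.GAP, length(fx)), paste0("s", fx))
  h1sites <- subdomainSites(map, "helix1")
  h2sites <- subdomainSites(map, "helix2")
  m1 <- call$helix1$matches
  res[paste0("s", h1sites[m1$state])] <- query[m1$qpos]
  m2 <- call$helix2$matches
  res[paste0("s", h2sites[m2$state])] <- query[m2$qpos]
  basicSites <- subdomainSites(map, "basic")
  nb <- length(basicSites)
  from <- max(1L, call$helix1$qstart - nb)
  basicRes <- query[seq(from, call$helix1$qstart - 1L)]
  if (call$helix1$qstart == 1L) basicRes <- character()
  if (length(basicRes))
    res[paste0("s", utils::tail(basicSites, length(basicRes)))] <- basicRes
  loopCap <- length(subdomainSites(map, "loop"))
  loop <- if (call$helix2$qstart - call$helix1$qend > 1L)
    paste(utils::head(query[(call$helix1$qend + 1L):(call$helix2$qstart - 1L)],
                      loopCap), collapse = "")
  else ""
  id <- if (is.na(call$id)) "query" else call$id
  m <- matrix(res, nrow = 1L, dimnames = list(id, names(res)))
  EnumeratedAlignment(m, kingdom = call$kingdom, loopSeqs = loop, map = map)
}

#' Extract all identified domains of a scan into one alignment
#'
#' @param calls One Kingdom's call list from [scanProteome()] (an element of
#'   \code{$calls}), or a list of [identifyBhlh()] calls.
#' @param sequences The scanned sequences (same forms as [scanProteome()]).
#' @param map A \code{BhlhCoordinateMap}.
#' @return An \code{EnumeratedAlignment} of the identified records (possibly
#'   empty).
#' @export
extractDomains <- function(calls, sequences, map = BhlhCoordinates()) {
  seqs <- .asProteinVector(sequences)
  hits <- Filter(function(cl) isTRUE(cl$identified), calls)
  if (!length(hits)) {
    fx <- fixedSites(map)
    return(EnumeratedAlignment(
      matrix(character(), 0L, length(fx),
             dimnames = list(NULL, paste0("s", fx))), map = map))
  }
  parts <- lapply(hits, function(cl) extractDomain(cl, seqs[[cl$id]], map))
  EnumeratedAlignment(
    do.call(rbind, lapply(parts, residueMatrix)),
    kingdom = unlist(lapply(parts, kingdoms)),
    loopSeqs = unlist(lapply(parts, loopSeqs)),
    map = map)
}

#' Write HMM hits as TSV
#'
#' One row per helix hit of each identified or attempted call.
#'
#' @param scan Output of [scanProteome()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(scan, path) {
  rows <- list()
  for (k in names(scan$calls)) for (cl in scan$calls[[k]]) {
    for (hx in c("helix1", "helix2")) {
      h <- cl[[hx]]
      if (is.null(h)) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = cl$id, kingdom = k, helix = hx, start = h$qstart,
        end = h$qend, bits = h$score, identified = cl$identified,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(id = character(), kingdom = character(),
                         helix = character(), start = integer(),
                         end = integer(), bits = numeric(),
                         identified = logical())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
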