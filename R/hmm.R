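# Self-contained profile HMM for helix scanning.
#
# Architecture: L match states with position-specific emissions, insert
# states emitting the background (log-odds zero), and delete states. The
# alignment is local in the query (a hit may begin and end anywhere in the
# protein, at no positional charge) and global in the model: a path enters
# at match state 1, or pays the delete-chain probability to enter at a later
# state, and symmetrically pays to exit before the last state. Scores are
# log2 odds (bits) of the path against the background model of the aligned
# residues, so all transition probabilities act as penalties; in particular
# a short spurious partial match cannot outscore the delete chain it would
# need to skip the rest of the model. This is deliberately simpler than the
# full Plan7 architecture (no null2 correction, E-values, or multi-hit
# mode); the per-helix bit-score threshold is a configurable default.

#' Build a profile HMM from a gapped helix alignment
#'
#' Match emissions at column j are pseudocount-smoothed residue frequencies,
#' \code{(count_a + pseudocount * background_a) / (n_j + pseudocount)} with
#' \code{n_j} the non-gap count; the probability of entering a delete state
#' at column j comes from the column's gap fraction smoothed toward
#' \code{deletePrior}; insert states emit the background.
#'
#' @param x Character matrix of aligned helix residues (one column per helix
#'   site, gaps \code{"-"}), or an \code{EnumeratedAlignment} together with
#'   \code{helix}.
#' @param helix When \code{x} is an alignment: \code{"helix1"} or
#'   \code{"helix2"}.
#' @param pseudocount Emission/transition smoothing weight (default 1).
#' @param background \code{"pooled"} (Laplace-smoothed residue frequencies of
#'   the training columns, the default), \code{"uniform"}, or a named numeric
#'   vector over the 20 amino acids.
#' @param deletePrior,matchInsert,insertInsert,deleteDelete Transition
#'   parameters; the defaults (0.025, 0.025, 0.3, 0.3) suit short, nearly
#'   gap-free helices.
#' @param kingdom Optional Kingdom tag carried on the model.
#' @return A \code{ProfileHMM}.
#' @aliases ProfileHMM-class ProfileHMM
#' @export
buildProfileHMM <- function(x, helix = c("helix1", "helix2"),
                            pseudocount = 1, background = "pooled",
                            deletePrior = 0.025, matchInsert = 0.025,
                            insertInsert = 0.3, deleteDelete = 0.3,
                            kingdom = NA_character_) {
  if (is(x, "EnumeratedAlignment")) {
    helix <- match.arg(helix)
    sites <- subdomainSites(coordinateMap(x), helix)
    x <- residueMatrix(x)[, paste0("s", sites), drop = FALSE]
  } else {
    helix <- if (length(helix) == 1L) helix else NA_character_
  }
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty alignment")
  aa <- aminoAcids()
  L <- ncol(x)
  counts <- apply(x, 2L, function(col)
    table(factor(col[col != .GAP], levels = aa)))
  counts <- matrix(as.numeric(counts), nrow = 20L,
                   dimnames = list(aa, NULL))
  bg <- if (identical(background, "pooled")) {
    tot <- rowSums(counts)
    (tot + 1) / (sum(tot) + 20)
  } else if (identical(background, "uniform")) {
    stats::setNames(rep(1 / 20, 20), aa)
  } else {
    if (is.null(names(background)) || !all(aa %in% names(background)))
      stop("custom background must be named over the 20 amino acids")
    background <- background[aa]
    background / sum(background)
  }
  nObs <- colSums(counts)
  if (any(nObs + pseudocount <= 0))
    stop("column with no observations and no pseudocount")
  emis <- t((counts + pseudocount * bg) /
              rep(nObs + pseudocount, each = 20L))
  gaps <- nrow(x) - nObs
  delEntry <- (gaps + pseudocount * deletePrior) / (nrow(x) + pseudocount)
  delEntry <- pmin(delEntry, 1 - matchInsert - 1e-6)
  dimnames(emis) <- list(colnames(x), aa)
  new("ProfileHMM", matchEmissions = emis,
      background = stats::setNames(as.numeric(bg), aa),
      deleteEntry = as.numeric(delEntry),
      matchInsert = matchInsert, insertInsert = insertInsert,
      deleteDelete = deleteDelete,
      helix = as.character(helix), kingdom = kingdom)
}

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM: ", nrow(object@matchEmissions), " match states",
      if (!is.na(object@helix)) paste0(" [", object@helix, "]"),
      if (!is.na(object@kingdom)) paste0(" (", object@kingdom, ")"),
      "\n", sep = "")
  cons <- colnames(object@matchEmissions)[
    apply(object@matchEmissions, 1L, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
})

#' Consensus sequence of a profile HMM
#'
#' @param hmm A \code{ProfileHMM}.
#' @return Character vector of per-column argmax residues.
#' @export
hmmConsensus <- function(hmm) {
  aminoAcids()[apply(hmm@matchEmissions, 1L, which.max)]
}

#' Best hit of a profile HMM in a query sequence
#'
#' Viterbi over the query-local, model-global architecture: the hit may start
#' and end anywhere in the query, and unvisited leading or trailing model
#' states are paid for as delete chains. The score is the log2 odds (bits) of
#' the best path against the background model; residues outside the 20-letter
#' alphabet are scored as background. Returns \code{NULL} when no path scores
#' above zero.
#'
#' @param hmm A \code{ProfileHMM}.
#' @param query Protein sequence: single string or character vector.
#' @return \code{NULL}, or a list with \code{qstart}, \code{qend} (1-based,
#'   inclusive), \code{score} (bits) and \code{matches}, a data.frame mapping
#'   matched query positions to model states.
#' @export
viterbiHit <- function(hmm, query) {
  if (length(query) == 1L && is.character(query))
    query <- strsplit(query, "", fixed = TRUE)[[1]]
  n <- length(query)
  L <- nrow(hmm@matchEmissions)
  if (n == 0L) return(NULL)
  lom <- log2(hmm@matchEmissions / rep(hmm@background, each = L))  # L x 20
  qidx <- match(toupper(query), aminoAcids())
  LO <- matrix(0, n, L)
  kn <- !is.na(qidx)
  LO[kn, ] <- t(lom[, qidx[kn], drop = FALSE])
  ltMM <- log2(1 - hmm@matchInsert - hmm@deleteEntry)  # into state j
  ltIM <- log2(1 - hmm@insertInsert)
  ltDM <- log2(1 - hmm@deleteDelete)
  ltMD <- log2(hmm@deleteEntry)                        # into D_j from M_{j-1}
  ltDD <- log2(hmm@deleteDelete)
  ltMI <- log2(hmm@matchInsert)
  ltII <- log2(hmm@insertInsert)
  # closed-form cost of entering at match j through the leading delete chain
  # (begin -> D_1 -> ... -> D_{j-1} -> M_j) and of exiting from match j
  # through the trailing one (M_j -> D_{j+1} -> ... -> D_L -> end)
  entry <- c(log2(1 - hmm@deleteEntry[1]),
             if (L > 1L) log2(hmm@deleteEntry[1]) +
               (seq_len(L - 1L) - 1L) * ltDD + ltDM)
  exitc <- c(if (L > 1L) log2(hmm@deleteEntry[2:L]) +
               (L - (1:(L - 1L)) - 1L) * ltDD, 0)
  M <- I <- D <- matrix(-Inf, n, L)
  PM <- PI <- PD <- matrix(0L, n, L)   # 0 = model entry, 1 = M, 2 = I, 3 = D
  shift <- function(v) c(-Inf, v[-L])
  for (i in seq_len(n)) {
    pM <- if (i > 1L) M[i - 1L, ] else rep(-Inf, L)
    pI <- if (i > 1L) I[i - 1L, ] else rep(-Inf, L)
    pD <- if (i > 1L) D[i - 1L, ] else rep(-Inf, L)
    cand <- cbind(shift(pM) + ltMM, shift(pI) + ltIM, shift(pD) + ltDM,
                  entry)                         # fresh start in the query
    pick <- max.col(cand, ties.method = "first")
    M[i, ] <- LO[i, ] + cand[cbind(seq_len(L), pick)]
    PM[i, ] <- c(1L, 2L, 3L, 0L)[pick]
    iC <- cbind(pM + ltMI, pI + ltII)
    ip <- max.col(iC, ties.method = "first")
    I[i, ] <- iC[cbind(seq_len(L), ip)]
    PI[i, ] <- c(1L, 2L)[ip]
    for (j in 2:L) {
      a <- M[i, j - 1L] + ltMD[j]
      b <- D[i, j - 1L] + ltDD
      if (a >= b) { D[i, j] <- a; PD[i, j] <- 1L }
      else { D[i, j] <- b; PD[i, j] <- 3L }
    }
  }
  total <- sweep(M, 2L, exitc, `+`)
  best <- which(total == max(total), arr.ind = TRUE)[1, ]
  score <- total[best[1], best[2]]
  if (!is.finite(score) || score <= 0) return(NULL)
  # traceback
  i <- unname(best[1]); j <- unname(best[2]); state <- 1L
  qpos <- integer(); mstate <- integer()
  repeat {
    if (state == 1L) {
      qpos <- c(i, qpos); mstate <- c(j, mstate)
      ptr <- PM[i, j]
      if (ptr == 0L) break
      i <- i - 1L; j <- j - 1L; state <- ptr
    } else if (state == 2L) {
      ptr <- PI[i, j]
      i <- i - 1L; state <- ptr
    } else {
      ptr <- PD[i, j]
      j <- j - 1L; state <- ptr
    }
  }
  list(qstart = qpos[1], qend = qpos[length(qpos)], score = as.numeric(score),
       matches = data.frame(qpos = qpos, state = mstate))
}
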