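# Fixture builders and independent oracles used across the suite.

# alignment whose 43 fixed-site columns are all `fill` except the named sites
siteAlignment <- function(patterns, fill = "A", kingdom = NA_character_,
                          n = NULL) {
  if (is.null(n)) n <- length(patterns[[1]])
  fx <- fixedSites(BhlhCoordinates())
  m <- matrix(fill, n, length(fx),
              dimnames = list(paste0("q", seq_len(n)), paste0("s", fx)))
  for (s in names(patterns)) m[, paste0("s", s)] <- patterns[[s]]
  EnumeratedAlignment(m, kingdom = kingdom)
}

# within- and total-SSCP computed the long way (independent of .sscp)
directSSCP <- function(x, y) {
  x <- as.matrix(x)
  grand <- colMeans(x)
  Tm <- matrix(0, ncol(x), ncol(x))
  for (i in seq_len(nrow(x)))
    Tm <- Tm + tcrossprod(x[i, ] - grand)
  W <- matrix(0, ncol(x), ncol(x))
  for (g in unique(y)) {
    xg <- x[y == g, , drop = FALSE]
    mg <- colMeans(xg)
    for (i in seq_len(nrow(xg)))
      W <- W + tcrossprod(xg[i, ] - mg)
  }
  list(W = W, T = Tm, B = Tm - W)
}

# exhaustive enumeration of every glocal path; independent of the DP
oracleViterbi <- function(hmm, query) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  n <- length(q)
  L <- nrow(hmm@matchEmissions)
  lom <- log2(hmm@matchEmissions / rep(hmm@background, each = L))
  qi <- match(q, aminoAcids())
  lo <- function(i, j) if (is.na(qi[i])) 0 else lom[j, qi[i]]
  del <- hmm@deleteEntry
  lmi <- log2(hmm@matchInsert); lii <- log2(hmm@insertInsert)
  ldd <- log2(hmm@deleteDelete)
  lmm <- log2(1 - hmm@matchInsert - del)   # into state j
  lim <- log2(1 - hmm@insertInsert)
  ldm <- log2(1 - hmm@deleteDelete)
  lmd <- log2(del)                          # into D_j from M_{j-1}
  best <- -Inf
  recM <- function(i, j, sc) {
    if (j == L) best <<- max(best, sc)      # end after the last match state
    if (i < n && j < L) recM(i + 1L, j + 1L, sc + lmm[j + 1L] + lo(i + 1L, j + 1L))
    if (i < n) recI(i + 1L, j, sc + lmi)
    if (j < L) recD(i, j + 1L, sc + lmd[j + 1L], TRUE)
  }
  recI <- function(i, j, sc) {
    if (i < n) recI(i + 1L, j, sc + lii)
    if (i < n && j < L) recM(i + 1L, j + 1L, sc + lim + lo(i + 1L, j + 1L))
  }
  recD <- function(i, j, sc, hasMatch) {
    if (j == L && hasMatch) best <<- max(best, sc)   # trailing delete chain
    if (j < L) recD(i, j + 1L, sc + ldd, hasMatch)
    if (i < n && j < L) recM(i + 1L, j + 1L, sc + ldm + lo(i + 1L, j + 1L))
  }
  for (i0 in seq_len(n)) {
    recM(i0, 1L, log2(1 - del[1]) + lo(i0, 1L))        # enter at match 1
    if (L > 1L) recD(i0 - 1L, 1L, log2(del[1]), FALSE) # enter through deletes
  }
  if (is.finite(best) && best > 0) best else NULL
}

# tiny HMM built from explicit column strings, e.g. c("KK", "RA") = 2 columns
tinyHMM <- function(columns, pseudocount = 1, background = "uniform", ...) {
  m <- do.call(cbind, strsplit(columns, "", fixed = TRUE))
  buildProfileHMM(m, pseudocount = pseudocount, background = background, ...)
}
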