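# Kingdom-structured synthetic bHLH alignments.
#
# The preset emulates the qualitative conservation architecture of real bHLH
# alignments: a handful of sites conserved in all Kingdoms (site 27 almost
# always L; site 28 P-dominant; buried helix sites with shared hydrophobic
# mixtures), a set of Kingdom-discerning sites with distinct dominant
# residues, site 50 strongly conserved (K) in Animals and Fungi but spread
# in Plants, and moderate-entropy filler elsewhere. Sites are sampled
# independently: phylogenetic correlation and within-helix indels are
# deliberately absent.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

.spread <- function(dominant, weight, aa = aminoAcids()) {
  p <- stats::setNames(rep((1 - sum(weight)) / (20 - length(dominant)), 20), aa)
  p[dominant] <- weight
  p / sum(p)
}

#' Default Kingdom profile preset
#'
#' Per-site, per-Kingdom categorical residue distributions with known ground
#' truth: shared conserved sites, the planted Kingdom-discerning sites
#' \{2, 5, 8, 12, 13, 56\} (a distinct dominant residue per Kingdom at each),
#' site 50 discerning through conservation contrast (K-conserved in
#' Animals/Fungi versus spread in Plants), and moderate-entropy filler.
#' Deterministic given its arguments.
#'
#' @param discerningDominance Frequency of the dominant residue at planted
#'   discerning sites (default 0.85; lower it for harder regimes).
#' @param loopLengthRange Loop lengths sampled uniformly in this range.
#' @param map A \code{BhlhCoordinateMap}.
#' @return A \code{KingdomProfileSpec}: list with \code{probs} (per Kingdom, a
#'   43 x 20 matrix of site distributions), \code{roles} (per-site
#'   designation), \code{discerningSites}, \code{conservationContrastSite},
#'   \code{loopLengthRange}, \code{map}.
#' @export
defaultKingdomSpec <- function(discerningDominance = 0.85,
                               loopLengthRange = c(8L, 20L),
                               map = BhlhCoordinates()) {
  aa <- aminoAcids()
  fx <- fixedSites(map)
  base <- function() {
    m <- matrix(NA_real_, length(fx), 20,
                dimnames = list(paste0("s", fx), aa))
    m
  }
  probs <- list(Plant = base(), Animal = base(), Fungal = base())
  roles <- stats::setNames(rep("variable", length(fx)), paste0("s", fx))
  # moderate-entropy filler: dominant residue cycles with site index
  for (k in seq_along(fx)) {
    dom <- aa[(fx[k] %% 20) + 1]
    p <- .spread(dom, 0.35)
    for (g in names(probs)) probs[[g]][k, ] <- p
  }
  setSite <- function(site, plant, animal, fungal, role) {
    key <- paste0("s", site)
    probs$Plant[key, ] <<- plant
    probs$Animal[key, ] <<- animal
    probs$Fungal[key, ] <<- fungal
    roles[key] <<- role
  }
  same <- function(p) list(p, p, p)
  # shared conserved sites
  sh <- list(
    s27 = .spread("L", 0.96),
    s16 = .spread(c("L", "I", "V", "M"), c(0.40, 0.25, 0.20, 0.14)),
    s23 = .spread(c("L", "I", "V", "M"), c(0.40, 0.25, 0.20, 0.14)),
    s20 = .spread(c("F", "I", "L", "M"), c(0.30, 0.25, 0.25, 0.19)),
    s53 = .spread("A", 0.60), s54 = .spread("I", 0.60),
    s57 = .spread("E", 0.60), s60 = .spread("L", 0.60),
    s61 = .spread("R", 0.60), s64 = .spread("L", 0.60))
  for (key in names(sh)) {
    site <- as.integer(sub("s", "", key))
    do.call(setSite, c(list(site), same(sh[[key]]), list("shared-conserved")))
  }
  # site 28: P-dominant everywhere, at Kingdom-specific frequencies
  setSite(28, .spread("P", 0.88), .spread("P", 0.73), .spread("P", 0.92),
          "shared-conserved")
  d <- discerningDominance
  # planted Kingdom-discerning sites: distinct dominant residues
  setSite(2, .spread("S", d), .spread("R", d), .spread("K", d), "discerning")
  setSite(5, .spread("A", d), .spread("R", d), .spread("E", d), "discerning")
  setSite(8, .spread("N", d), .spread("E", d), .spread("D", d), "discerning")
  setSite(12, .spread("T", d), .spread("R", d), .spread("K", d), "discerning")
  setSite(13, .spread("R", d), .spread("E", d), .spread("K", d), "discerning")
  setSite(56, .spread("D", d), .spread("K", d), .spread("R", d), "discerning")
  # site 50: K-conserved in Animal/Fungal, spread in Plant
  setSite(50, stats::setNames(rep(1 / 20, 20), aa),
          .spread("K", 0.90), .spread("K", 0.90), "discerning")
  structure(list(probs = probs, roles = roles,
                 discerningSites = c(2L, 5L, 8L, 12L, 13L, 56L),
                 conservationContrastSite = 50L,
                 loopLengthRange = as.integer(loopLengthRange), map = map),
            class = "KingdomProfileSpec")
}

#' Site distribution of a preset
#'
#' @param spec A \code{KingdomProfileSpec}.
#' @param kingdom Kingdom name.
#' @param site Fixed site index.
#' @return Named probability vector over the 20 amino acids.
#' @export
specSiteDistribution <- function(spec, kingdom, site) {
  spec$probs[[kingdom]][paste0("s", site), ]
}

#' Sample a Kingdom-labelled synthetic alignment
#'
#' Residues are drawn i.i.d. per site from the preset's per-Kingdom
#' distributions; gaps are injected independently per cell at \code{gapRate}.
#' Reproducible under \code{seed}; the caller's RNG state is restored.
#'
#' @param spec A \code{KingdomProfileSpec}.
#' @param n Sequences per Kingdom (scalar, or named vector over Kingdoms).
#' @param seed Integer seed (required for reproducibility; \code{NULL} uses
#'   the current RNG state).
#' @param gapRate Per-cell gap probability (default 0).
#' @return An \code{EnumeratedAlignment} with Kingdom labels and sampled
#'   loop residues.
#' @export
sampleAlignment <- function(spec, n = 100, seed = NULL, gapRate = 0) {
  .withSeed(seed, {
    aa <- aminoAcids()
    fx <- fixedSites(spec$map)
    kings <- names(spec$probs)
    if (is.null(names(n))) {
      n <- stats::setNames(rep_len(n, length(kings)), kings)
    } else {
      full <- stats::setNames(rep(0L, length(kings)), kings)
      full[names(n)] <- n
      n <- full
    }
    blocks <- lapply(kings, function(g) {
      ng <- n[[g]]
      if (ng == 0L)
        return(matrix(character(), 0L, length(fx)))
      m <- matrix(.GAP, ng, length(fx))
      for (k in seq_along(fx))
        m[, k] <- sample(aa, ng, replace = TRUE, prob = spec$probs[[g]][k, ])
      rownames(m) <- sprintf("%s_%d", g, seq_len(ng))
      m
    })
    res <- do.call(rbind, blocks)
    if (gapRate > 0) {
      mask <- matrix(stats::runif(length(res)) < gapRate, nrow(res))
      res[mask] <- .GAP
    }
    king <- rep(kings, n[kings])
    loops <- vapply(seq_len(nrow(res)), function(i) {
      len <- sample(seq(spec$loopLengthRange[1], spec$loopLengthRange[2]), 1)
      paste(sample(aa, len, replace = TRUE), collapse = "")
    }, character(1))
    colnames(res) <- paste0("s", fx)
    EnumeratedAlignment(res, kingdom = king, loopSeqs = loops, map = spec$map)
  })
}

#' Monte-Carlo Bayes rate of a preset
#'
#' Accuracy of the optimal (true-model) classifier on sequences sampled from
#' the preset with equal Kingdom priors: each sampled sequence is assigned to
#' the Kingdom maximizing its exact log-likelihood under the generating
#' distributions. An upper bound on what any classifier can achieve on this
#' generator.
#'
#' @param spec A \code{KingdomProfileSpec}.
#' @param n Total Monte-Carlo draws (default 5000, balanced over Kingdoms).
#' @param seed Integer seed.
#' @return Estimated Bayes accuracy in \code{[0, 1]}.
#' @export
bayesRate <- function(spec, n = 5000, seed = NULL) {
  .withSeed(seed, {
    kings <- names(spec$probs)
    per <- ceiling(n / length(kings))
    aln <- sampleAlignment(spec, n = per, seed = NULL)
    res <- residueMatrix(aln)
    aa <- aminoAcids()
    fx <- fixedSites(spec$map)
    ll <- sapply(kings, function(g) {
      lp <- log(spec$probs[[g]])
      rowSums(matrix(lp[cbind(rep(seq_along(fx), each = nrow(res)),
                              match(res, aa))],
                     nrow(res)))
    })
    pred <- kings[max.col(ll, ties.method = "first")]
    mean(pred == kingdoms(aln))
  })
}

#' Embed synthetic domains in full-length proteins
#'
#' Each gap-free record becomes basic + Helix 1 + loop + Helix 2 flanked by
#' background-sampled residues, emulating full-length proteins for scanner
#' testing. Records with gaps are skipped with a warning. Loop residues come
#' from the record (sampled at generation); flanks are uniform over the 20
#' amino acids.
#'
#' @param alignment An \code{EnumeratedAlignment} (e.g. from
#'   [sampleAlignment()]).
#' @param flankRange Integer range of N- and C-terminal flank lengths.
#' @param seed Integer seed.
#' @return List with \code{sequences} (named character vector) and
#'   \code{truth}: data.frame of Kingdom labels and 1-based domain
#'   coordinates (\code{basic_start}, \code{h1_start}, \code{h1_end},
#'   \code{h2_start}, \code{h2_end}).
#' @export
embedInProteins <- function(alignment, flankRange = c(20L, 80L),
                            seed = NULL) {
  .withSeed(seed, {
    aa <- aminoAcids()
    res <- residueMatrix(alignment)
    ok <- rowSums(res == .GAP) == 0L
    if (!all(ok))
      warning(sum(!ok), " gapped record(s) skipped")
    map <- coordinateMap(alignment)
    nb <- length(subdomainSites(map, "basic"))
    nh1 <- length(subdomainSites(map, "helix1"))
    idx <- which(ok)
    seqs <- character(length(idx))
    truth <- vector("list", length(idx))
    for (q in seq_along(idx)) {
      i <- idx[q]
      loop <- loopSeqs(alignment)[i]
      fl <- sample(seq(flankRange[1], flankRange[2]), 2, replace = TRUE)
      nFlank <- paste(sample(aa, fl[1], replace = TRUE), collapse = "")
      cFlank <- paste(sample(aa, fl[2], replace = TRUE), collapse = "")
      domain <- paste(res[i, ], collapse = "")
      core <- paste0(substr(domain, 1, nb + nh1), loop,
                     substr(domain, nb + nh1 + 1, ncol(res)))
      seqs[q] <- paste0(nFlank, core, cFlank)
      bs <- fl[1] + 1L
      truth[[q]] <- data.frame(
        id = seqIds(alignment)[i],
        kingdom = kingdoms(alignment)[i],
        basic_start = bs,
        h1_start = bs + nb,
        h1_end = bs + nb + nh1 - 1L,
        h2_start = bs + nb + nh1 + nchar(loop),
        h2_end = bs + nb + nh1 + nchar(loop) +
          length(subdomainSites(map, "helix2")) - 1L,
        length = nchar(seqs[q]),
        stringsAsFactors = FALSE)
    }
    names(seqs) <- seqIds(alignment)[idx]
    list(sequences = seqs, truth = do.call(rbind, truth))
  })
}
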