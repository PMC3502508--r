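test_that("built models are proper probability models", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 40, seed = 51)
  hmm <- buildProfileHMM(aln, "helix1")
  expect_identical(nrow(hmm@matchEmissions), 15L)
  expect_true(all(abs(rowSums(hmm@matchEmissions) - 1) < 1e-12))
  expect_equal(sum(hmm@background), 1, tolerance = 1e-12)
  expect_true(all(hmm@deleteEntry >= 0 & hmm@deleteEntry < 1))
})

test_that("emission smoothing follows its closed forms", {
  # single sequence, no pseudocount: indicator emissions
  h0 <- tinyHMM(c("K", "R", "L"), pseudocount = 0)
  expect_equal(unname(h0@matchEmissions[1, "K"]), 1)
  expect_equal(sum(h0@matchEmissions[1, ] > 0), 1)
  # huge pseudocount: emissions converge to the background
  hInf <- tinyHMM(c("KKKK", "RRRR"), pseudocount = 1e9)
  expect_equal(unname(hInf@matchEmissions[1, ]), unname(hInf@background),
               tolerance = 1e-6)
  # 50/50 column of n = 10 with pseudocount 1 and uniform background:
  # (5 + 0.05) / (10 + 1) for each of the two residues
  h <- tinyHMM(c("KKKKKRRRRR"), pseudocount = 1)
  expect_equal(unname(h@matchEmissions[1, "K"]), (5 + 0.05) / 11)
  expect_equal(unname(h@matchEmissions[1, "R"]), (5 + 0.05) / 11)
  expect_equal(unname(h@matchEmissions[1, "A"]), 0.05 / 11)
  expect_error(buildProfileHMM(matrix(character(), 0, 3)), "empty")
})

test_that("the consensus query scores its closed form with pseudocount 0", {
  cols <- c("KKK", "LLL", "EEE", "RRR", "WWW")
  hmm <- tinyHMM(cols, pseudocount = 0, background = "uniform")
  cons <- paste(hmmConsensus(hmm), collapse = "")
  hit <- viterbiHit(hmm, cons)
  expect_identical(hit$qstart, 1L)
  expect_identical(hit$qend, 5L)
  # all-match path: 5 emissions of log2(1 / 0.05) plus 4 match-match moves
  expected <- 5 * log2(20) + 4 * log2(1 - hmm@matchInsert)
  expect_equal(hit$score, expected, tolerance = 1e-10)
  expect_identical(hit$matches$state, 1:5)
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  set.seed(52)
  aa <- aminoAcids()
  for (rep in 1:6) {
    L <- sample(3:5, 1)
    cols <- vapply(seq_len(L), function(j)
      paste(sample(aa, 4, replace = TRUE), collapse = ""), character(1))
    hmm <- tinyHMM(cols, pseudocount = 0.7, background = "pooled")
    for (qlen in c(4, 7, 9)) {
      q <- paste(sample(aa, qlen, replace = TRUE), collapse = "")
      hit <- viterbiHit(hmm, q)
      oracle <- oracleViterbi(hmm, q)
      if (is.null(oracle)) {
        expect_null(hit)
      } else {
        expect_equal(hit$score, oracle, tolerance = 1e-9,
                     info = paste("L", L, "qlen", qlen, "rep", rep))
      }
    }
    # the planted consensus always agrees with the oracle
    cons <- paste(hmmConsensus(hmm), collapse = "")
    expect_equal(viterbiHit(hmm, cons)$score, oracleViterbi(hmm, cons),
                 tolerance = 1e-9)
  }
})

test_that("hopeless and empty queries return no hit", {
  hmm <- tinyHMM(c("AAAA", "AAAA", "AAAA", "AAAA"), pseudocount = 0)
  expect_null(viterbiHit(hmm, "WYW"))
  expect_null(viterbiHit(hmm, ""))
})

test_that("random background queries never beat the planted consensus", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 60, seed = 53)
  hmm <- buildProfileHMM(aln, "helix1")
  cons <- paste(hmmConsensus(hmm), collapse = "")
  consScore <- viterbiHit(hmm, cons)$score
  set.seed(54)
  rand <- vapply(1:200, function(i) {
    q <- paste(sample(aminoAcids(), 15, replace = TRUE,
                      prob = hmm@background), collapse = "")
    h <- viterbiHit(hmm, q)
    if (is.null(h)) 0 else h$score
  }, numeric(1))
  expect_lt(mean(rand), consScore)
  expect_true(all(rand < consScore))
})

test_that("the two-helix rule enforces ordering and strict thresholds", {
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 80, seed = 55)
  prot <- embedInProteins(aln[1:3], seed = 56)
  hmms <- buildKingdomHMMs(aln, "Plant")
  q <- prot$sequences[[1]]
  call <- identifyBhlh(q, hmms, id = names(prot$sequences)[1])
  expect_true(call$identified)
  expect_lt(call$helix1$qend, call$helix2$qstart)
  # swapped helices: helix 2 now precedes helix 1
  tr <- prot$truth[1, ]
  chars <- strsplit(q, "")[[1]]
  h1 <- chars[tr$h1_start:tr$h1_end]
  h2 <- chars[tr$h2_start:tr$h2_end]
  swapped <- chars
  swapped[tr$h1_start:tr$h1_end] <- h2
  swapped[tr$h2_start:tr$h2_end] <- h1
  expect_false(identifyBhlh(paste(swapped, collapse = ""), hmms)$identified)
  # a threshold exactly at the weaker score excludes the call (strict >)
  weaker <- min(call$helix1$score, call$helix2$score)
  expect_false(identifyBhlh(q, hmms, threshold = weaker)$identified)
  expect_true(identifyBhlh(q, hmms, threshold = weaker - 1e-9)$identified)
  # two hits further apart than a plausible loop are not one domain
  gap <- call$helix2$qstart - call$helix1$qend - 1L
  expect_false(identifyBhlh(q, hmms, maxLoop = gap - 1L)$identified)
  expect_true(identifyBhlh(q, hmms, maxLoop = gap)$identified)
  # a long-insertion protein is recovered by disabling the cap
  set.seed(561)
  chars2 <- strsplit(q, "")[[1]]
  stretched <- paste(c(chars2[1:tr$h1_end],
                       sample(aminoAcids(), 60, replace = TRUE),
                       chars2[(tr$h1_end + 1L):length(chars2)]),
                     collapse = "")
  expect_false(identifyBhlh(stretched, hmms)$identified)
  expect_true(identifyBhlh(stretched, hmms, maxLoop = Inf)$identified)
})

test_that("identification is monotone in the threshold", {
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 50, seed = 57)
  prot <- embedInProteins(aln[1:20], seed = 58)
  hmms <- buildKingdomHMMs(aln, "Fungal")
  thresholds <- c(0.1, 1, 5, 20, 60)
  idSets <- lapply(thresholds, function(t)
    names(Filter(isTRUE, lapply(prot$sequences, function(s)
      identifyBhlh(s, hmms, threshold = t)$identified))))
  for (k in seq_len(length(thresholds) - 1))
    expect_true(all(idSets[[k + 1]] %in% idSets[[k]]))
})

test_that("scan overlap accounting is a set identity", {
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 30, seed = 59)
  prot <- embedInProteins(aln[c(1:5, 31:35, 61:65)], seed = 60)
  hmms <- lapply(kingdomLabels(), function(k) buildKingdomHMMs(aln, k))
  names(hmms) <- kingdomLabels()
  scan <- scanProteome(prot$sequences, hmms)
  allIds <- unique(unlist(scan$identified))
  expect_identical(sum(scan$overlap), length(allIds))
  expect_true(all(unlist(scan$unique) %in% allIds))
  # empty proteome: empty sets
  empty <- scanProteome(character(0), hmms)
  expect_identical(unique(unlist(empty$identified)), NULL)
})

test_that("extraction maps hits back to the fixed sites and pads the basic region", {
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 60, seed = 61)
  hmms <- buildKingdomHMMs(aln, "Animal")
  sub <- aln[which(kingdoms(aln) == "Animal")[1:10]]
  prot <- embedInProteins(sub, seed = 62)
  calls <- lapply(names(prot$sequences), function(id)
    identifyBhlh(prot$sequences[[id]], hmms, id = id))
  dom <- extractDomains(calls, prot$sequences)
  truth <- residueMatrix(sub)[seqIds(dom), , drop = FALSE]
  expect_gt(mean(residueMatrix(dom) == truth), 0.95)
  # helix 1 starting near the N-terminus: leading basic sites are gap-padded
  short <- embedInProteins(sub[1], flankRange = c(0, 0), seed = 63)
  q <- substring(short$sequences[[1]], 9)   # truncate most of the basic
  call <- identifyBhlh(q, hmms, id = "trunc")
  expect_true(call$identified)
  rec <- extractDomain(call, q)
  res <- residueMatrix(rec)[1, ]
  expect_identical(unname(res[paste0("s", 1:8)]), rep("-", 8))
  expect_false(any(res[paste0("s", 9:13)] == "-"))
  # only identified calls can be extracted
  bad <- call; bad$identified <- FALSE
  expect_error(extractDomain(bad, q), "identified")
})

test_that("profile HMMs serialize to JSON losslessly", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 25, seed = 64)
  hmm <- buildProfileHMM(aln, "helix2", kingdom = "Plant")
  f <- withr::local_tempfile(fileext = ".json")
  exportProfileHMM(hmm, f)
  back <- importProfileHMM(f)
  expect_equal(back@matchEmissions, hmm@matchEmissions)
  expect_equal(back@background, hmm@background)
  q <- paste(hmmConsensus(hmm), collapse = "")
  expect_equal(viterbiHit(back, q)$score, viterbiHit(hmm, q)$score)
})
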