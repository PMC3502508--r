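plantedDataset <- function(n = 100, noiseVars = 20, seed = 31) {
  set.seed(seed)
  y <- rep(c("a", "b", "c"), each = n)
  info <- rnorm(3 * n, rep(c(-2, 0, 2), each = n))
  noise <- matrix(rnorm(3 * n * noiseVars), 3 * n)
  x <- cbind(info, noise)
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  rownames(x) <- paste0("r", seq_len(nrow(x)))
  list(x = x, y = y)
}

test_that("the single informative variable enters at step 1", {
  d <- plantedDataset()
  sw <- fitSWDA(d$x, d$y, targetASCC = 0.99, maxSteps = 5)
  st <- stepTable(sw)
  expect_identical(st$site[1], 1L)           # columns are indexed as sites here
  expect_gt(st$partialR2[1], 0.5)
})

test_that("lambda strictly decreases and ASCC never decreases along the path", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 150, seed = 32)
  sw <- fitSWDA(factorTransform(aln, "pah"), targetASCC = 0.95, maxSteps = 12)
  st <- stepTable(sw)
  expect_gt(nrow(st), 3)
  expect_true(all(diff(st$wilks) < 0))
  expect_true(all(diff(st$ascc) >= -1e-12))
  # internal consistency: reported ASCC equals ascc() on the selected subset
  nd <- factorTransform(aln, "pah")
  cols <- paste0(st$factor, "_s", st$site)
  expect_equal(st$ascc[nrow(st)], ascc(selectVariables(nd, cols)),
               tolerance = 1e-10)
  # and the final lambda equals wilksLambda() on the same subset
  expect_equal(st$wilks[nrow(st)], wilksLambda(selectVariables(nd, cols)),
               tolerance = 1e-10)
})

test_that("an exact duplicate of an entered variable is never entered", {
  d <- plantedDataset(noiseVars = 5)
  x <- cbind(d$x, dup = d$x[, 1])
  sw <- fitSWDA(x, d$y, targetASCC = 0.999, maxSteps = 7)
  st <- stepTable(sw)
  expect_identical(st$site[1], 1L)
  expect_false((ncol(d$x) + 1L) %in% st$site)  # the duplicate column
})

test_that("permuted labels stop on the entry threshold with tiny ASCC", {
  d <- plantedDataset(seed = 33)
  set.seed(34)
  yperm <- sample(d$y)
  sw <- fitSWDA(d$x, yperm, targetASCC = 0.7, maxSteps = 20,
                entryAlpha = 0.05)
  expect_identical(stoppingReason(sw), "entry threshold")
  st <- stepTable(sw)
  if (nrow(st)) expect_lt(st$ascc[nrow(st)], 0.1)
})

test_that("default ASCC targets follow the factor set", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 120, seed = 35)
  swSingle <- fitSWDA(factorTransform(aln, "ec"))
  expect_equal(swSingle@targetASCC, 0.70)
  swAll <- fitSWDA(factorTransform(aln, "all"))
  expect_equal(swAll@targetASCC, 0.80)
  expect_identical(stoppingReason(swAll), "ASCC target reached")
  expect_gte(stepTable(swAll)$ascc[nrow(stepTable(swAll))], 0.80)
})

test_that("the stepwise classifier tolerates gaps at non-selected sites only", {
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 150, seed = 36)
  nd <- factorTransform(aln, "ec")
  sw <- fitSWDA(nd)
  model <- swdaClassifier(nd, sw)
  selected <- sort(unique(stepTable(sw)$site))
  other <- setdiff(fixedSites(BhlhCoordinates()), selected)
  # gap a non-selected site everywhere: still classified
  res <- residueMatrix(aln)
  res[, paste0("s", other[1])] <- "-"
  cl <- classifySequences(model, factorTransform(EnumeratedAlignment(res), "ec"))
  expect_false(any(cl$predicted == unclassifiedLabel()))
  # gap a selected site in the first record: that record is Unclassified
  res2 <- residueMatrix(aln)
  res2[1, paste0("s", selected[1])] <- "-"
  cl2 <- classifySequences(model, factorTransform(EnumeratedAlignment(res2), "ec"))
  expect_identical(cl2$predicted[1], unclassifiedLabel())
  # and its training accuracy is near the generator's Bayes ceiling
  clAll <- classifySequences(model, nd)
  expect_gt(mean(clAll$predicted == kingdoms(aln)), 0.9)
})

test_that("restricting the full CVA to stepwise variables cannot lower lambda", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 150, seed = 37)
  nd <- factorTransform(aln, "pah")
  sw <- fitSWDA(nd, targetASCC = 0.9, maxSteps = 10)
  cols <- paste0(stepTable(sw)$factor, "_s", stepTable(sw)$site)
  expect_gte(wilksLambda(selectVariables(nd, cols)), wilksLambda(nd))
})

test_that("discerning-site extraction honours its threshold", {
  d <- plantedDataset(seed = 38)
  sw <- fitSWDA(d$x, d$y, targetASCC = 0.99, maxSteps = 6)
  st <- stepTable(sw)
  expect_identical(discerningSites(sw, threshold = 0),
                   sort(unique(st$site)))
  expect_identical(discerningSites(sw, threshold = 1), integer(0))
  expect_identical(discerningSites(sw), sort(unique(st$site[st$partialR2 > 0.2])))
})

test_that("zero admissible candidates yield an empty result with a reason", {
  x <- matrix(1, 20, 2)   # constant columns: no candidate is admissible
  colnames(x) <- c("v1", "v2")
  y <- rep(c("a", "b"), 10)
  sw <- fitSWDA(x, y, maxSteps = 3)
  expect_identical(nrow(stepTable(sw)), 0L)
  expect_match(stoppingReason(sw), "no admissible")
})
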