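test_that("the chi-square split statistic matches a direct contingency oracle", {
  tab <- matrix(c(30, 5, 2, 4, 25, 14), nrow = 2, byrow = TRUE)
  ours <- chisqStatistic(tab)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_identical(ours$df, 2L)
  # hand-computed 2x2: O = (10, 0 / 0, 10), all E = 5 -> chi2 = 20
  expect_equal(chisqStatistic(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  # degenerate tables cannot split
  expect_equal(chisqStatistic(matrix(c(5, 7, 0, 0), 2))$statistic, 0)
})

test_that("a perfectly separating residue is found and used", {
  # site 8: E is exclusively Animal, all others are Plant
  aln <- siteAlignment(list(`8` = c(rep("E", 20), rep(c("K", "R"), 10))),
                       kingdom = c(rep("Animal", 20), rep("Plant", 20)))
  sp <- bestSplit(residueMatrix(aln), kingdoms(aln),
                  fixedSites(BhlhCoordinates()))
  expect_identical(sp$site, 8L)
  expect_true(setequal(sp$left, "E") || setequal(sp$right, "E"))
  expect_lt(sp$p, 1e-8)
  tree <- fitDecisionTree(aln)
  expect_identical(treeDepth(tree), 1L)
  expect_identical(unname(predictTree(tree, aln)), kingdoms(aln))
})

test_that("minimum split size and pure nodes yield leaves", {
  aln9 <- siteAlignment(list(`8` = c(rep("E", 5), rep("K", 4))),
                        kingdom = c(rep("Animal", 5), rep("Plant", 4)))
  expect_null(bestSplit(residueMatrix(aln9), kingdoms(aln9),
                        fixedSites(BhlhCoordinates())))
  expect_identical(treeDepth(fitDecisionTree(aln9)), 0L)
  pure <- siteAlignment(list(`8` = rep(c("E", "K"), 10)),
                        kingdom = rep("Fungal", 20))
  tree <- fitDecisionTree(pure)
  expect_true(tree@root$leaf)
  expect_identical(unique(unname(predictTree(tree, pure))), "Fungal")
})

test_that("child class counts sum to parent counts and depth is capped", {
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 150, seed = 41)
  tree <- fitDecisionTree(aln)
  expect_lte(treeDepth(tree), treeConfig()$maxDepth)
  check <- function(node) {
    if (node$leaf) return(invisible())
    kids <- node$children
    expect_identical(kids$left$counts + kids$right$counts, node$counts)
    expect_gte(kids$left$n, treeConfig()$minLeaf)
    expect_gte(kids$right$n, treeConfig()$minLeaf)
    check(kids$left); check(kids$right)
  }
  check(tree@root)
})

test_that("training records are routed to their leaf's majority label", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 150, seed = 42)
  tree <- fitDecisionTree(aln)
  pred <- predictTree(tree, aln)
  # follow each record down by hand and compare
  manual <- vapply(seq_len(length(aln)), function(i) {
    node <- tree@root
    row <- residueMatrix(aln)[i, ]
    while (!node$leaf) {
      r <- row[paste0("s", node$site)]
      if (r %in% node$left) node <- node$children$left
      else if (r %in% node$right) node <- node$children$right
      else return(unclassifiedLabel())
    }
    node$label
  }, character(1))
  expect_identical(unname(pred), manual)
  expect_gt(mean(pred == kingdoms(aln)), 0.9)
})

test_that("gaps and unseen residues predict Unclassified", {
  aln <- siteAlignment(list(`8` = c(rep("E", 10), rep("K", 10))),
                       kingdom = c(rep("Animal", 10), rep("Plant", 10)))
  tree <- fitDecisionTree(aln)
  gapped <- siteAlignment(list(`8` = c("-", "W", "E")))
  pred <- predictTree(tree, gapped)
  expect_identical(unname(pred[1]), unclassifiedLabel())  # gap at split site
  expect_identical(unname(pred[2]), unclassifiedLabel())  # unseen residue
  expect_identical(unname(pred[3]), "Animal")
})

test_that("the discriminating splits on the default preset are planted sites", {
  # the top levels carry the Kingdom separation and must come from planted
  # signal; deeper nodes refine nearly-pure subsets and (like any decision
  # tree) admit many equivalent solutions, so they are not constrained here
  spec <- defaultKingdomSpec()
  aln <- sampleAlignment(spec, n = 334, seed = 43)   # ~1000 records
  tree <- fitDecisionTree(aln)
  sites <- integer()
  walk <- function(node) {
    if (node$leaf || node$depth >= 2) return(invisible())
    sites <<- c(sites, node$site)
    walk(node$children$left); walk(node$children$right)
  }
  walk(tree@root)
  informative <- c(spec$discerningSites, spec$conservationContrastSite)
  expect_gt(length(sites), 1)
  expect_true(all(sites %in% informative))
  expect_gt(mean(predictTree(tree, aln) == kingdoms(aln)), 0.9)
})

test_that("decision trees serialize to JSON losslessly", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 60, seed = 44)
  tree <- fitDecisionTree(aln)
  f <- withr::local_tempfile(fileext = ".json")
  exportDecisionTree(tree, f)
  back <- importDecisionTree(f)
  expect_identical(predictTree(back, aln), predictTree(tree, aln))
  expect_identical(treeKey(back), treeKey(tree))
})
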