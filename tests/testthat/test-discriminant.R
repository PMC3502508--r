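makeGaussian <- function(n, means, sd = 1, p = 1, seed = 1) {
  # means: named list group -> mean vector of length p
  set.seed(seed)
  x <- do.call(rbind, lapply(names(means), function(g)
    matrix(rnorm(n * p, rep(means[[g]], each = n), sd), n, p)))
  rownames(x) <- paste0("r", seq_len(nrow(x)))
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, y = rep(names(means), each = n))
}

test_that("Wilks' lambda matches the one-way ANOVA sums-of-squares identity", {
  d <- makeGaussian(30, list(a = 0, b = 1.5), seed = 4)
  ssw <- sum(tapply(d$x[, 1], d$y, function(v) sum((v - mean(v))^2)))
  sst <- sum((d$x[, 1] - mean(d$x[, 1]))^2)
  expect_equal(wilksLambda(d$x, d$y), ssw / sst, tolerance = 1e-12)
})

test_that("Wilks' lambda is near 1 without separation and tiny with strong separation", {
  same <- makeGaussian(200, list(a = c(0, 0, 0), b = c(0, 0, 0),
                                 c = c(0, 0, 0)), p = 3, seed = 5)
  expect_gt(wilksLambda(same$x, same$y), 0.9)
  # two groups 20 within-sd apart: lambda ~ 1 / (1 + 100) at large n
  far <- makeGaussian(2000, list(a = -10, b = 10), seed = 6)
  expect_lt(wilksLambda(far$x, far$y), 0.01)
})

test_that("singular totals raise a collinearity diagnostic", {
  d <- makeGaussian(30, list(a = 0, b = 1), seed = 7)
  x2 <- cbind(d$x, v2 = 2 * d$x[, 1])
  expect_error(wilksLambda(x2, d$y), "singular")
})

test_that("CVA eigenvalues match a brute-force dense solve of solve(W) B", {
  d <- makeGaussian(60, list(a = c(0, 0, 1, 0, 0), b = c(1, 0, 0, 0.5, 0),
                             c = c(0, 1, 0, 0, 0.5)), p = 5, seed = 11)
  fit <- fitCVA(d$x, d$y)
  ss <- directSSCP(d$x, d$y)
  brute <- sort(Re(eigen(solve(ss$W) %*% ss$B)$values),
                decreasing = TRUE)[1:2]
  expect_equal(eigenvalues(fit), brute, tolerance = 1e-8)
  # coefficients solve the generalized eigenproblem: B a = lambda W a
  for (k in 1:2) {
    a <- canonicalCoefficients(fit)[, k]
    expect_equal(as.numeric(ss$B %*% a),
                 eigenvalues(fit)[k] * as.numeric(ss$W %*% a),
                 tolerance = 1e-6)
  }
})

test_that("canonical scores have unit pooled within-group variance and zero within-group correlation", {
  d <- makeGaussian(80, list(a = c(0, 1, 0), b = c(1, 0, 0), c = c(0, 0, 1)),
                    p = 3, seed = 12)
  fit <- fitCVA(d$x, d$y)
  sc <- canonicalScores(fit, d$x)
  centered <- do.call(rbind, lapply(unique(d$y), function(g)
    scale(sc[d$y == g, ], scale = FALSE)))
  pooled <- crossprod(centered) / (nrow(sc) - 3)
  expect_equal(diag(pooled), c(CV1 = 1, CV2 = 1), tolerance = 1e-8)
  expect_lt(abs(pooled[1, 2]), 1e-8)
})

test_that("separation along one axis puts all discrimination on CV1", {
  d <- makeGaussian(150, list(a = c(-3, 0), b = c(0, 0), c = c(3, 0)),
                    p = 2, seed = 13)
  fit <- fitCVA(d$x, d$y)
  co <- canonicalCoefficients(fit)
  expect_lt(abs(co[2, 1] / co[1, 1]), 0.1)           # CV1 ~ axis 1
  expect_lt(varianceProportions(fit)[2], 0.02)       # CV2 explains ~nothing
})

test_that("CVA agrees with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  d <- makeGaussian(70, list(a = c(0, 1, 0, 0), b = c(1, 0, 1, 0),
                             c = c(0, 0, 0, 1)), p = 4, seed = 14)
  fit <- fitCVA(d$x, d$y)
  ld <- MASS::lda(d$x, grouping = d$y)
  ours <- canonicalScores(fit, d$x)
  theirs <- predict(ld)$x
  for (k in 1:2)
    expect_gt(abs(cor(ours[, k], theirs[, k])), 1 - 1e-8)
})

test_that("ASCC identities hold", {
  # G = 2, p = 1: the single squared canonical correlation is 1 - lambda
  d2 <- makeGaussian(50, list(a = 0, b = 2), seed = 15)
  expect_equal(ascc(d2$x, d2$y), 1 - wilksLambda(d2$x, d2$y),
               tolerance = 1e-10)
  # no separation: ASCC near 0
  null3 <- makeGaussian(300, list(a = 0, b = 0, c = 0), seed = 16)
  expect_lt(ascc(null3$x, null3$y), 0.02)
  # equals the mean of the squared canonical correlations of the fitted CVA
  d3 <- makeGaussian(60, list(a = c(0, 1), b = c(1, 0), c = c(1, 1)),
                     p = 2, seed = 17)
  fit <- fitCVA(d3$x, d3$y)
  expect_equal(ascc(d3$x, d3$y), mean(fit@canCor2), tolerance = 1e-10)
})

test_that("between-centroid Mahalanobis distance is a metric and equals the canonical-space distance", {
  d <- makeGaussian(80, list(a = c(0, 0, 0), b = c(2, 0, 1), c = c(0, 2, 0)),
                    p = 3, seed = 18)
  fit <- fitCVA(d$x, d$y)
  expect_equal(mahalanobisBetween(fit, "a", "a"), 0)
  dab <- mahalanobisBetween(fit, "a", "b")
  expect_equal(dab, mahalanobisBetween(fit, "b", "a"))
  expect_gt(dab, 0)
  # triangle inequality
  expect_lte(dab, mahalanobisBetween(fit, "a", "c") +
                  mahalanobisBetween(fit, "c", "b") + 1e-12)
  # mean differences lie in the canonical span, so the centroid distance in
  # full canonical space reproduces the Mahalanobis distance
  cen <- groupCentroids(fit)
  expect_equal(dab, sqrt(sum((cen["a", ] - cen["b", ])^2)),
               tolerance = 1e-8)
})

test_that("classification contracts: centroids, gaps, symmetry", {
  d <- makeGaussian(100, list(a = c(-2, 0), b = c(2, 0), c = c(0, 3)),
                    p = 2, seed = 19)
  fit <- fitCVA(d$x, d$y)
  cen <- t(fit@groupMeans)
  cl <- classifySequences(fit, cen)
  expect_identical(cl$predicted, c("a", "b", "c"))
  expect_equal(cl$dist_a[1], 0, tolerance = 1e-10)
  # a missing model variable makes the row Unclassified, distances NA
  xg <- rbind(c(NA, 1), c(0, 0))
  clg <- classifySequences(fit, xg)
  expect_identical(clg$predicted[1], unclassifiedLabel())
  expect_true(is.na(clg$dist_a[1]))
  expect_false(clg$predicted[2] == unclassifiedLabel())
  # posteriors sum to 1 when classified
  expect_equal(clg$post_a[2] + clg$post_b[2] + clg$post_c[2], 1)
})

test_that("equidistant sequences get equal posteriors under equal priors", {
  # three groups at the vertices of an equilateral triangle, each built from
  # the same spherical offsets: centroids are exact and Sw is spherical, so
  # the origin is exactly equidistant from all three in Mahalanobis terms
  ang <- c(90, 210, 330) * pi / 180
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  x <- do.call(rbind, lapply(ang, function(t)
    sweep(offs, 2L, 10 * c(cos(t), sin(t)), `+`)))
  colnames(x) <- c("v1", "v2")
  y <- rep(c("a", "b", "c"), each = 4)
  fit <- fitCVA(x, y)
  cl <- classifySequences(fit, matrix(c(0, 0), 1, 2))
  post <- as.numeric(cl[1, c("post_a", "post_b", "post_c")])
  expect_equal(post, rep(1 / 3, 3), tolerance = 1e-10)
  d <- as.numeric(cl[1, c("dist_a", "dist_b", "dist_c")])
  expect_equal(d, rep(d[1], 3), tolerance = 1e-10)
})

test_that("CVA models serialize to JSON losslessly", {
  aln <- sampleAlignment(defaultKingdomSpec(), n = 40, seed = 21)
  fit <- fitCVA(factorTransform(aln, "pah"))
  f <- withr::local_tempfile(fileext = ".json")
  exportCVAModel(fit, f)
  back <- importCVAModel(f)
  expect_equal(canonicalCoefficients(back), canonicalCoefficients(fit))
  expect_equal(back@Sw, fit@Sw)
  expect_identical(back@groups, fit@groups)
  aln2 <- sampleAlignment(defaultKingdomSpec(), n = 10, seed = 22)
  nd2 <- factorTransform(aln2, "pah")
  expect_equal(classifySequences(back, nd2), classifySequences(fit, nd2),
               tolerance = 1e-12)
})
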