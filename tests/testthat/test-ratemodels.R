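test_that("zero-intercept linear fit matches its closed form", {
  f <- fitLinearOrigin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unname(f@coefficients["b"]), 2)
  expect_equal(f@rss, 0)
  f2 <- fitLinearOrigin(c(1, 2), c(1, 3))
  expect_equal(unname(f2@coefficients["b"]), 7 / 5)
  expect_error(fitLinearOrigin(c(0, 0), c(1, 2)), "all zero")
  expect_error(fitLinearOrigin(1, 1), "at least")
})

test_that("scale equivariance: multiplying x by c divides the slope by c", {
  set.seed(101)
  x <- runif(30, 0, 1)
  y <- 3 * x + rnorm(30, 0, 0.2)
  b1 <- fitLinearOrigin(x, y)@coefficients[["b"]]
  b2 <- fitLinearOrigin(5 * x, y)@coefficients[["b"]]
  expect_equal(b1, 5 * b2, tolerance = 1e-12)
})

test_that("quadratic origin fit is exact on quadratic data and nests the linear fit", {
  x <- seq(0.1, 1, by = 0.1)
  fq <- fitQuadraticOrigin(x, x^2)
  expect_equal(unname(fq@coefficients), c(0, 1), tolerance = 1e-9)
  expect_equal(fq@rss, 0, tolerance = 1e-12)
  # linear data: b2 ~ 0 and rss equal to the linear fit
  set.seed(102)
  y <- 2 * x
  fl <- fitLinearOrigin(x, y)
  fq2 <- fitQuadraticOrigin(x, y)
  expect_equal(unname(fq2@coefficients["b2"]), 0, tolerance = 1e-9)
  expect_lt(abs(fq2@rss - fl@rss), 1e-12)
  # nested models: quadratic rss never exceeds linear rss
  for (i in 1:20) {
    yy <- 2 * x + rnorm(10, 0, 0.3)
    expect_lte(fitQuadraticOrigin(x, yy)@rss,
               fitLinearOrigin(x, yy)@rss + 1e-12)
  }
  expect_error(fitQuadraticOrigin(c(1, 1, 1), c(1, 2, 3)), "rank-deficient")
})

test_that("fixed-scale logarithmic fit is exact and linear in the small-x regime", {
  x <- seq(0, 1, by = 0.05)
  y <- 3 * log1p(x / 0.1)
  fl <- fitLogarithmic(x, y)
  expect_equal(unname(fl@coefficients["a"]), 3, tolerance = 1e-12)
  expect_equal(fl@rss, 0, tolerance = 1e-12)
  # ln(1 + u) ~ u regime (x/scale <= 0.1): log and linear fits agree within 5%
  xs <- seq(0.0005, 0.01, by = 0.0005)
  ys <- 5 * xs
  flog <- fitLogarithmic(xs, ys, scale = 0.1)
  flin <- fitLinearOrigin(xs, ys)
  predLog <- flog@coefficients[["a"]] * log1p(xs / 0.1)
  predLin <- flin@coefficients[["b"]] * xs
  expect_lt(max(abs(predLog - predLin) / predLin), 0.05)
  expect_error(fitLogarithmic(c(-1, 1), c(1, 2)), ">= 0")
})

test_that("model selection controls type I error on linear-truth data", {
  set.seed(103)
  x <- runif(50, 0.02, 0.6)
  sel <- logical(200)
  for (r in seq_len(200)) {
    y <- 4 * x + rnorm(50, 0, 0.4)
    ch <- selectModel(fitLinearOrigin(x, y), fitQuadraticOrigin(x, y))
    sel[r] <- ch@model == "quadratic_origin"
  }
  rate <- mean(sel)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("model selection finds curvature and handles degenerate fits", {
  set.seed(104)
  x <- runif(60, 0.05, 0.8)
  y <- 5 * x - 4 * x^2 + rnorm(60, 0, 0.05)
  ch <- selectModel(fitLinearOrigin(x, y), fitQuadraticOrigin(x, y))
  expect_equal(ch@model, "quadratic_origin")
  expect_lt(ch@coefficients[["b2"]], 0)
  expect_lt(ch@pValue, 0.05)
  # perfectly interpolating quadratic beats an imperfect linear fit
  x3 <- c(1, 2, 3); y3 <- x3^2
  ch2 <- selectModel(fitLinearOrigin(x3, y3), fitQuadraticOrigin(x3, y3))
  expect_equal(ch2@model, "quadratic_origin")
  # both interpolate: keep the parsimonious linear model
  y4 <- 2 * x3
  ch3 <- selectModel(fitLinearOrigin(x3, y4), fitQuadraticOrigin(x3, y4))
  expect_equal(ch3@model, "linear_origin")
  expect_error(selectModel(fitLinearOrigin(x, y),
                           fitQuadraticOrigin(x[1:10], y[1:10])),
               "same data")
})

test_that("slope ratio recovers planted ratios with a finite standard error", {
  set.seed(105)
  x <- runif(40, 0.05, 0.5)
  fa <- fitLinearOrigin(x, 10 * x + rnorm(40, 0, 0.1))
  fb <- fitLinearOrigin(x, 1 * x + rnorm(40, 0, 0.1))
  sr <- slopeRatio(fa, fb)
  expect_lt(abs(sr$ratio - 10), 2)
  expect_true(is.finite(sr$se) && sr$se > 0)
  expect_equal(slopeRatio(fa, fa)$ratio, 1)
  fz <- fitLinearOrigin(c(1, 2), c(0, 0))
  expect_error(slopeRatio(fa, fz), "zero")
})

test_that("fitted slope recovers the planted rRNA rate factor on clock simulations", {
  # with markers at rate 1 and rRNA at rate r16, percent 16S divergence per
  # unit tree distance is ~100 * r16 at small divergence (JC curvature is
  # second-order here)
  r16 <- 0.1
  tr <- simulateTree(30, treeDepth = 0.15, seed = 111)
  p <- simParams(nSpecies = 30, nGenes = 0L, rrnaLen = 1200L,
                 rrnaCopyNumber = 2L, rrnaRateFactor = r16)
  sim <- simulateGenus(tr, p, seed = 112)
  dm <- ape::cophenetic.phylo(tr)
  gs <- simGenomes(sim)
  ids <- sort(names(gs))
  x <- c(); y <- c()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq.int(i + 1, length(ids))) {
      rep_i <- selectRepresentative(rrnaCopies(gs[[ids[i]]]))
      rep_j <- selectRepresentative(rrnaCopies(gs[[ids[j]]]))
      idy <- if (rep_i == rep_j) 100
             else percentIdentity(globalAlign(rep_i, rep_j, band = 30L))
      x <- c(x, dm[ids[i], ids[j]]); y <- c(y, 100 - idy)
    }
  }
  b <- fitLinearOrigin(x, y)@coefficients[["b"]]
  expect_lt(abs(b - 100 * r16) / (100 * r16), 0.15)
})

test_that("copy number leaves the fitted 16S rate unchanged under strong conversion", {
  # the negative result: slopes across copy numbers show no monotone trend
  set.seed(113)
  copyNumbers <- c(1L, 4L, 7L, 10L)
  batchP <- numeric(4)
  for (batch in seq_len(4)) {
    slopes <- numeric(length(copyNumbers))
    for (k in seq_along(copyNumbers)) {
      C <- copyNumbers[k]
      tr <- simulateTree(10, treeDepth = 0.25)
      p <- simParams(nSpecies = 10, nGenes = 0L, rrnaLen = 600L,
                     rrnaCopyNumber = C, rrnaRateFactor = 0.3,
                     conversionRate = if (C > 1) 2 * 0.3 * 600 else 0)
      sim <- simulateGenus(tr, p)
      dm <- ape::cophenetic.phylo(tr)
      gs <- simGenomes(sim)
      ids <- sort(names(gs))
      x <- c(); y <- c()
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in seq.int(i + 1, length(ids))) {
          ri <- selectRepresentative(rrnaCopies(gs[[ids[i]]]))
          rj <- selectRepresentative(rrnaCopies(gs[[ids[j]]]))
          idy <- if (ri == rj) 100
                 else percentIdentity(globalAlign(ri, rj, band = 30L))
          x <- c(x, dm[ids[i], ids[j]]); y <- c(y, 100 - idy)
        }
      }
      slopes[k] <- fitLinearOrigin(x, y)@coefficients[["b"]]
    }
    batchP[batch] <- suppressWarnings(
      cor.test(copyNumbers, slopes, method = "spearman")$p.value)
  }
  # no detectable monotone trend in at least 3 of 4 batches
  expect_gte(sum(batchP > 0.05), 3)
})
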