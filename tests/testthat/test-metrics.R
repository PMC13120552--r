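# Diagnostic metrics: normalization, residual maps, SCI, global metrics,
# intensity histograms, jackknife.

test_that("mean normalization has unit mean, preserves shape, ignores scale", {
  set.seed(1)
  X <- matrix(runif(100, 1, 3), 10)
  Xn <- normalizeMean(X)
  expect_equal(mean(Xn), 1)
  expect_equal(sum(Xn), length(X))
  expect_equal(normalizeMean(2 * X), Xn)
  expect_equal(normalizeMean(matrix(7, 5, 5)), matrix(1, 5, 5))
  expect_error(normalizeMean(matrix(0, 3, 3)), "positive mean")
})

test_that("residual and chi-square maps follow their definitions", {
  expect_equal(residualMaps(12, 10, 4)$chi2Reduced, 1.0)
  set.seed(2)
  X <- matrix(rnorm(64, 10), 8); Y <- matrix(rnorm(64, 10), 8)
  v <- matrix(runif(64, 0.5, 2), 8)
  rm <- residualMaps(X, Y, v)
  expect_equal(rm$signed, X - Y)
  expect_equal(rm$absolute, abs(X - Y))
  expect_equal(rm$chi2Reduced, mean(rm$chi2Map))
  expect_equal(sum(rm$signed), sum(X) - sum(Y))
  z <- residualMaps(X, X, v)
  expect_equal(z$chi2Reduced, 0)
  # invalid-variance pixels are excluded and flagged
  v2 <- v; v2[1, 1] <- 0
  rm2 <- residualMaps(X, Y, v2)
  expect_false(rm2$validMask[1, 1])
  expect_equal(rm2$chi2Reduced, mean(rm2$chi2Map[rm2$validMask]))
  expect_error(residualMaps(X, Y, v * 0), "valid variance")
})

test_that("the SCI is the product of its contrast and structure components", {
  set.seed(3)
  for (rep in 1:10) {
    X <- matrix(runif(256, 0.5, 2), 16)
    Y <- matrix(runif(256, 0.5, 2), 16)
    s <- sci(X, Y)
    expect_equal(s$sci, s$contrast * s$structure)
  }
})

test_that("mean-normalized residuals have zero luminance and zero SCI at X = Y", {
  set.seed(4)
  X <- matrix(runif(400, 1, 4), 20)
  Y <- matrix(runif(400, 1, 4), 20)
  s <- sci(X, Y)
  expect_equal(round(s$luminance, 3), 0)
  z <- sci(Y, Y)
  expect_equal(z$sci, 0)
  expect_equal(z$contrast, 0)
  expect_error(sci(X, matrix(1, 20, 20)), "constant reference")
})

test_that("the windowed SCI variant also reports a near-zero luminance", {
  set.seed(12)
  X <- matrix(runif(1024, 1, 4), 32)
  Y <- matrix(runif(1024, 1, 4), 32)
  s <- sci(X, Y, windowed = TRUE)
  expect_equal(round(s$luminance, 3), 0)
  expect_equal(s$sci, s$contrast * s$structure)
})

test_that("global metrics behave on identical, shifted and toy inputs", {
  set.seed(5)
  Y <- matrix(runif(400, 1, 5), 20)
  m <- globalMetrics(Y, Y)
  expect_equal(m$nmse, 0)
  expect_equal(m$cc, 1)
  expect_equal(m$ssim, 1)
  expect_true(is.infinite(m$psnr))

  m2 <- globalMetrics(Y + 2, Y)
  expect_equal(m2$cc, 1)
  expect_gt(m2$nmse, 0)
  expect_true(is.finite(m2$psnr))

  expect_error(globalMetrics(matrix(1, 20, 20), Y), "constant")

  # chi-square wiring
  m3 <- globalMetrics(Y + 1, Y, variance = matrix(4, 20, 20))
  expect_equal(m3$chi2Reduced, 0.25)
})

test_that("CNR follows its defining arithmetic", {
  X <- matrix(5, 10, 10)
  X[1:3, 1:3] <- 10
  bg <- matrix(FALSE, 10, 10); bg[8:10, 1:10] <- TRUE
  sig <- matrix(FALSE, 10, 10); sig[1:3, 1:3] <- TRUE
  # inject a background with known sd 2 around mean 5
  X[bg] <- 5 + 2 * scale(stats::rnorm(sum(bg)))[, 1]
  expect_equal(cnr(X, sig, bg), (10 - 5) / 2, tolerance = 1e-10)
  expect_error(cnr(matrix(1, 4, 4),
                   matrix(c(TRUE, rep(FALSE, 15)), 4),
                   matrix(c(rep(FALSE, 15), TRUE), 4)), "background sd")
})

test_that("SSIM decreases under blur and is symmetric-range stable", {
  img <- values(rasterize(discSpec(value = 2, radiusMm = 30, gridN = 64)))
  k <- matrix(1 / 25, 5, 5)
  blur <- img
  # crude box blur via embedding
  n <- 64
  pad <- matrix(0, n + 4, n + 4); pad[3:(n + 2), 3:(n + 2)] <- img
  for (i in 1:n) for (j in 1:n)
    blur[i, j] <- sum(pad[i:(i + 4), j:(j + 4)] * k)
  expect_lt(ssim(blur, img), 1)
  expect_gt(ssim(blur, img), 0)
})

test_that("intensity histograms count every pixel and respect shared edges", {
  X <- matrix(1, 16, 16)
  h <- intensityHistogram(X, nb = 10)
  expect_equal(sum(h$counts), 256)
  expect_equal(sum(h$counts > 0), 1) # constant image fills one bin

  set.seed(6)
  A <- matrix(runif(256, 0, 2), 16)
  B <- matrix(runif(256, 1, 3), 16)
  e <- sharedEdges(A, B, nb = 32)
  hA <- intensityHistogram(A, 32, e)
  hB <- intensityHistogram(B, 32, e)
  expect_equal(sum(hA$counts), 256)
  expect_equal(sum(hB$counts), 256)
  expect_identical(intensityHistogram(A, 32, e)$counts, hA$counts)
  expect_error(intensityHistogram(A, nb = 1), "at least 2")
})

test_that("histogram reduced chi-square follows its unweighted definition", {
  mk <- function(counts) structure(
    list(edges = seq(0, 1, length.out = length(counts) + 1), counts = counts,
         nb = length(counts)), class = "IntensityHistogram")
  expect_equal(histogramChi2Red(mk(c(4, 0)), mk(c(0, 4))), 16)
  expect_equal(histogramChi2Red(mk(c(3, 2, 1)), mk(c(3, 2, 1))), 0)
  # permuting bins changes the value: no invariance is claimed
  expect_false(histogramChi2Red(mk(c(5, 1, 0)), mk(c(1, 5, 0))) ==
               histogramChi2Red(mk(c(5, 1, 0)), mk(c(0, 1, 5))))
  expect_error(histogramChi2Red(mk(c(1, 2)), mk(c(1, 2, 3))), "edges")
})

test_that("jackknife of the mean equals the closed form s/sqrt(n)", {
  j <- jackknife(c(1, 2, 3), mean)
  expect_equal(j$value, 2)
  expect_equal(j$se, 1 / sqrt(3))
  expect_equal(jackknife(rep(5, 8), mean)$se, 0)
  # linear statistics scale linearly
  a <- 3; b <- 7
  set.seed(7)
  x <- runif(20)
  expect_equal(jackknife(x, function(v) a * mean(v) + b)$se,
               a * jackknife(x, mean)$se)
  expect_error(jackknife(c(1, 2), mean), "at least 3")
})

test_that("metric jackknife resamples angles or row blocks", {
  set.seed(8)
  X <- matrix(runif(32 * 20), 32)
  Y <- matrix(runif(32 * 20), 32)
  jA <- jackknifeMetric(X, Y, function(a, b) mean(a - b), unit = "angles")
  jB <- jackknifeMetric(X, Y, function(a, b) mean(a - b), unit = "rowBlocks",
                        blockRows = 8)
  expect_equal(jA$value, mean(X - Y))
  expect_equal(jB$value, mean(X - Y))
  expect_gt(jA$se, 0)
  expect_gt(jB$se, 0)
  expect_error(jackknifeMetric(X[1:2, ], Y[1:2, ], function(a, b) mean(a - b),
                               unit = "angles"), "at least 3")
})
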