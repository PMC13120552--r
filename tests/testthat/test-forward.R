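# Analytic forward model: projector geometry, attenuation, counting noise,
# detector image, standardized set.

test_that("projection angles are equally spaced (128 over 360 gives 2.8125)", {
  cfg <- acquisitionConfig(nProjections = 128)
  a <- projectionAngles(cfg)
  expect_equal(length(a), 128L)
  expect_equal(unique(diff(a)), 2.8125)
  expect_equal(a[1], 0)
})

test_that("every angle conserves the projected mass", {
  img <- rasterize(discSpec(value = 2, radiusMm = 35))
  cfg <- tinyConfig(nProjections = 8)
  s <- values(parallelProject(img, cfg))
  mass <- sum(values(img)) * img@pixelMm^2
  for (a in seq_len(nrow(s)))
    expect_lt(abs(sum(s[a, ]) * cfg@binMm - mass) / mass, 5e-3)
})

test_that("uniform disc projects to the closed-form chord profile", {
  r <- 40
  img <- rasterize(discSpec(value = 1, radiusMm = r, gridN = 128))
  cfg <- tinyConfig(gridN = 128, nProjections = 4)
  s <- values(parallelProject(img, cfg))
  off <- (seq_len(cfg@nBins) - (cfg@nBins + 1) / 2) * cfg@binMm
  chord <- ifelse(abs(off) < r, 2 * sqrt(pmax(r^2 - off^2, 0)), 0)
  for (a in seq_len(nrow(s))) {
    # compare away from the tangent bins where the chord slope diverges
    inner <- abs(off) < 0.85 * r
    expect_lt(max(abs(s[a, inner] - chord[inner])) / max(chord), 0.02)
  }
})

test_that("projection is linear in the image", {
  cfg <- tinyConfig(nProjections = 6)
  set.seed(7)
  X <- matrix(runif(64 * 64), 64); Y <- matrix(runif(64 * 64), 64)
  pr <- function(m) values(parallelProject(activityImage(m, 2), cfg))
  expect_equal(pr(2 * X + 3 * Y), 2 * pr(X) + 3 * pr(Y), tolerance = 1e-12)
})

test_that("attenuated projection reduces to the unattenuated one at mu = 0", {
  spec <- discSpec(); img <- rasterize(spec)
  cfg <- tinyConfig(nProjections = 6)
  mu0 <- buildAttenuationMap(spec, 0)
  expect_equal(values(attenuatedProject(img, mu0, cfg)),
               values(parallelProject(img, cfg)))
})

test_that("attenuation only ever removes signal, bin-wise", {
  spec <- discSpec(value = 3, radiusMm = 45)
  img <- rasterize(spec)
  mu <- buildAttenuationMap(spec, 0.02)
  cfg <- tinyConfig(nProjections = 10)
  expect_true(all(values(attenuatedProject(img, mu, cfg)) <=
                  values(parallelProject(img, cfg)) + 1e-9))
})

test_that("a central point source in a uniform disc is attenuated by exp(-mu r)", {
  n <- 129 # odd grid: a pixel center sits exactly at the origin
  fov <- 129
  spec <- discSpec(value = 1, radiusMm = 50, gridN = n, fovMm = fov)
  muw <- 0.0146
  mu <- buildAttenuationMap(spec, muw)
  pt <- matrix(0, n, n); pt[(n + 1) / 2, (n + 1) / 2] <- 7
  img <- activityImage(pt, fov / n)
  cfg <- acquisitionConfig(nProjections = 12, nBins = n, binMm = fov / n)
  un <- rowSums(values(parallelProject(img, cfg)))
  at <- rowSums(values(attenuatedProject(img, mu, cfg)))
  expect_equal(at / un, rep(exp(-muw * 50), 12), tolerance = 0.01)
})

test_that("counting noise is reproducible, scales, and is Poisson-consistent", {
  img <- rasterize(discSpec())
  cfg <- tinyConfig(nProjections = 4)
  s0 <- parallelProject(img, cfg)
  a <- addCountingNoise(s0, 1e5, seed = 11)
  b <- addCountingNoise(s0, 1e5, seed = 11)
  expect_identical(values(a), values(b))
  expect_false(identical(values(a), values(addCountingNoise(s0, 1e5, 12))))
  # expected total halves when the count budget halves
  expect_equal(sum(sinogramVariance(addCountingNoise(s0, 5e4, 1))[
    sinogramVariance(addCountingNoise(s0, 5e4, 1)) > 1]) /
    sum(sinogramVariance(a)[sinogramVariance(a) > 1]), 0.5, tolerance = 1e-6)
  expect_error(addCountingNoise(sinogram(matrix(0, 4, 4), 1:4), 100), "zero-sum")

  # replicate means match expectations within 5 sigma of Monte Carlo error
  lam <- values(s0) * (2e4 / sum(values(s0)))
  reps <- vapply(1:200, function(i)
    values(addCountingNoise(s0, 2e4, seed = 1000 + i)), lam)
  mc <- apply(reps, c(1, 2), mean)
  tol <- 5 * sqrt(lam / 200)
  keep <- lam > 0.5
  expect_true(all(abs(mc - lam)[keep] <= tol[keep]))
  # sample variance tracks the mean (Poisson)
  vv <- apply(reps, c(1, 2), stats::var)
  big <- lam > 20
  expect_lt(median(abs(vv[big] / lam[big] - 1)), 0.2)
})

test_that("detector image equals source when mu = 0 and never exceeds it otherwise", {
  spec <- discSpec(value = 2, radiusMm = 45)
  img <- rasterize(spec)
  cfg <- tinyConfig(nProjections = 8)
  expect_equal(values(makeDetectorImage(img, buildAttenuationMap(spec, 0), cfg)),
               values(img))
  mu <- buildAttenuationMap(spec, 0.0146)
  det <- makeDetectorImage(img, mu, cfg)
  expect_true(all(values(det) <= values(img) + 1e-12))
  inside <- values(img) > 0
  expect_true(all(values(det)[inside] < values(img)[inside]))
  p <- detectionProbability(mu, cfg)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("central pixel detection probability matches exp(-mu r)", {
  n <- 129; fov <- 129
  spec <- discSpec(value = 1, radiusMm = 50, gridN = n, fovMm = fov)
  muw <- 0.01
  mu <- buildAttenuationMap(spec, muw)
  cfg <- acquisitionConfig(nProjections = 16, nBins = n, binMm = 1)
  p <- detectionProbability(mu, cfg)
  expect_equal(p[(n + 1) / 2, (n + 1) / 2], exp(-muw * 50), tolerance = 0.01)
})

test_that("the standardized set is internally consistent", {
  spec <- discSpec(value = 2, radiusMm = 40, gridN = 64)
  cfg <- tinyConfig(nProjections = 24, totalCounts = 2e5, seed = 5)
  st <- reconSettings(maxIterations = 60)

  # mu = 0: the ideal reconstruction must recover the source closely
  set0 <- makeStandardizedSet(spec, cfg, settings = st, muWater = 0)
  nmse0 <- sum((values(set0@idealImage) - values(set0@source))^2) /
    sum(values(set0@source)^2)
  expect_lt(nmse0, 0.01)

  # mu > 0: residual against the source is nonzero and concentrated inside
  set1 <- makeStandardizedSet(spec, cfg, settings = st, muWater = 0.0146)
  d <- values(set1@source) - values(set1@idealImage)
  inside <- values(set1@source) > 0
  expect_gt(mean(abs(d[inside])), 10 * mean(abs(d[!inside])))
  expect_gt(sum(abs(d)), 0)

  # realistic sinogram carries Poisson counts at the configured level
  expect_equal(sum(values(set1@realisticSinogram)), cfg@totalCounts,
               tolerance = 0.01)

  # detector blur breaks equality with the ideal reconstruction
  cfgB <- tinyConfig(nProjections = 24, totalCounts = 2e5, seed = 5,
                     detectorBlurSigmaMm = 4)
  setB <- makeStandardizedSet(spec, cfgB, settings = st, muWater = 0.0146)
  expect_lt(ssim(values(setB@realisticImage), values(setB@idealImage)), 1)
  expect_false(identical(values(setB@realisticSinogram),
                         values(set1@realisticSinogram)))
})

test_that("sinogram blur preserves per-projection counts", {
  img <- rasterize(discSpec())
  cfg <- tinyConfig(nProjections = 4)
  s <- parallelProject(img, cfg)
  b <- blurSinogram(s, sigmaMm = 3)
  expect_equal(rowSums(values(b)), rowSums(values(s)), tolerance = 1e-10)
  expect_identical(blurSinogram(s, 0), s)
})
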