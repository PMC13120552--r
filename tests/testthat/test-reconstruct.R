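# System matrix, ART and MLEM reconstructors, chi-square stationarity.

test_that("matrix-free operator matches its dense materialization and is adjoint-consistent", {
  cfg <- acquisitionConfig(nProjections = 4, nBins = 8, binMm = 8)
  P <- buildSystemMatrix(8, cfg, NULL, pixelMm = 8)
  D <- as.matrix(P) # dense oracle built from delta images

  # forward on a delta image is the corresponding column of the dense matrix
  d <- matrix(0, 8, 8); d[3, 5] <- 1
  j <- (5 - 1) * 8 + 3 # column-major pixel index
  expect_equal(as.vector(t(values(forwardProject(P, d)))), D[, j])

  # adjoint identity <P f, g> = <f, P' g> against the dense matrix
  set.seed(42)
  for (rep in 1:5) {
    f <- matrix(runif(64), 8); g <- matrix(runif(32), 4)
    lhs <- sum(values(forwardProject(P, f)) * g)
    rhs <- sum(f * backProject(P, g))
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_equal(as.vector(values(forwardProject(P, f))),
                 as.vector(matrix(D %*% as.vector(f), 4, 8, byrow = TRUE)),
                 tolerance = 1e-12)
  }
  expect_true(all(D >= 0))
})

test_that("omitting mu equals a zero attenuation map", {
  spec <- discSpec(gridN = 32, fovMm = 64)
  cfg <- acquisitionConfig(nProjections = 6, nBins = 32, binMm = 2)
  Pn <- buildSystemMatrix(32, cfg, NULL, pixelMm = 2)
  P0 <- buildSystemMatrix(32, cfg, buildAttenuationMap(spec, 0), pixelMm = 2)
  f <- values(rasterize(spec))
  expect_equal(values(forwardProject(Pn, f)), values(forwardProject(P0, f)))
})

test_that("system matrix forward agrees with the simulator projector", {
  spec <- discSpec(gridN = 64)
  img <- rasterize(spec)
  mu <- buildAttenuationMap(spec, 0.0146)
  cfg <- tinyConfig(nProjections = 12)
  P <- buildSystemMatrix(64, cfg, mu, pixelMm = img@pixelMm)
  expect_equal(values(forwardProject(P, img)),
               values(attenuatedProject(img, mu, cfg)))
})

test_that("one unrelaxed ART row action annihilates that ray's residual", {
  set.seed(3)
  P <- matrix(runif(12), 3, 4) # 3 rays, 4 pixels
  S <- c(5, 2, 7)
  f <- runif(4)
  i <- 2
  fNew <- f + (S[i] - sum(P[i, ] * f)) / sum(P[i, ]^2) * P[i, ]
  expect_equal(sum(P[i, ] * fNew), S[i], tolerance = 1e-12)
  # and the packaged ART with relaxation 1, a single sweep over one ray
  r <- art(matrix(S[i], 1, 1), matrix(P[i, ], 1, 4),
           reconSettings("art", maxIterations = 1, relaxation = 1))
  expect_equal(sum(P[i, ] * values(reconImage(r))), S[i], tolerance = 1e-12)
})

test_that("ART solves exactly determined and consistent systems", {
  # identity system: converges to the data immediately
  r <- art(c(3, 5), diag(2), reconSettings("art", maxIterations = 5,
                                           relaxation = 1))
  expect_equal(as.vector(values(reconImage(r))), c(3, 5))

  # consistent 16-pixel system vs the direct-solve oracle
  set.seed(8)
  A <- matrix(runif(24 * 16), 24, 16)
  fTrue <- runif(16)
  g <- as.vector(A %*% fTrue)
  r <- art(g, A, reconSettings("art", maxIterations = 5000, relaxation = 1,
                               chi2Tol = 1e-12))
  fHat <- as.vector(values(reconImage(r)))
  oracle <- qr.solve(A, g)
  expect_equal(fHat, oracle, tolerance = 1e-4)
  expect_equal(fHat, fTrue, tolerance = 1e-4)
})

test_that("ART with zero data and zero start stays at zero with chi2 = 0", {
  r <- art(c(0, 0, 0), rbind(c(1, 0), c(0, 1), c(1, 1)),
           reconSettings("art", maxIterations = 2))
  expect_true(all(values(reconImage(r)) == 0))
  expect_true(all(chi2History(r) == 0))
})

test_that("ART warns about and skips all-zero rays", {
  P <- rbind(c(1, 1), c(0, 0))
  expect_warning(art(c(2, 0), P, reconSettings("art", maxIterations = 1)),
                 "zero weights")
})

test_that("MLEM closed forms: one-step update and fixed point", {
  # 1 pixel / 1 ray: P = 2, g = 6, f0 = 1 -> f1 = f0 * (P g / (P f0)) / P = 3
  # (the packaged initializer already lands on the fixed point 3, so apply
  # the update formula directly for the one-step value)
  P <- matrix(2, 1, 1); g <- 6; f0 <- 1
  f1 <- f0 / sum(P) * sum(P * (g / (P %*% f0)))
  expect_equal(f1, 3)
  # a consistent state is a fixed point of the packaged update
  r <- mlem(g, P, reconSettings(maxIterations = 3))
  expect_equal(as.vector(values(reconImage(r))), 3, tolerance = 1e-12)

  set.seed(5)
  A <- matrix(runif(8 * 4), 8, 4)
  fStar <- runif(4) + 0.5
  gC <- as.vector(A %*% fStar)
  # run from the consistent forward data: iterates stay consistent
  r2 <- mlem(gC, A, reconSettings(maxIterations = 800, chi2Tol = 1e-10))
  expect_equal(as.vector(A %*% as.vector(values(reconImage(r2)))), gC,
               tolerance = 1e-4)
})

test_that("MLEM preserves non-negativity and increases the Poisson likelihood", {
  spec <- discSpec(value = 2, radiusMm = 12, gridN = 32, fovMm = 64)
  img <- rasterize(spec)
  cfg <- acquisitionConfig(nProjections = 12, nBins = 32, binMm = 2,
                           totalCounts = 5e4, seed = 2)
  P <- buildSystemMatrix(32, cfg, NULL, pixelMm = 2)
  g <- addCountingNoise(parallelProject(img, cfg), cfg@totalCounts, cfg@seed)
  r <- mlem(g, P, reconSettings(maxIterations = 25),
            checkpoints = 1:25)
  expect_true(all(values(reconImage(r)) >= 0))
  ll <- vapply(reconCheckpoints(r), function(im)
    poissonLogLik(values(g), values(forwardProject(P, values(im)))),
    numeric(1))
  ll <- ll[order(as.integer(names(ll)))]
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("MLEM matches total counts at convergence", {
  spec <- discSpec(value = 1, radiusMm = 20, gridN = 32, fovMm = 64)
  img <- rasterize(spec)
  cfg <- acquisitionConfig(nProjections = 16, nBins = 32, binMm = 2,
                           totalCounts = 1e5, seed = 9)
  P <- buildSystemMatrix(32, cfg, NULL, pixelMm = 2)
  g <- addCountingNoise(parallelProject(img, cfg), cfg@totalCounts, cfg@seed)
  r <- mlem(g, P, reconSettings(maxIterations = 150))
  reproj <- values(forwardProject(P, values(reconImage(r))))
  expect_equal(sum(reproj), sum(values(g)), tolerance = 1e-3)
})

test_that("chi-square stationarity rule follows its definition", {
  expect_true(chi2Stationary(rep(4, 10), tol = 1e-6, window = 3))
  expect_false(chi2Stationary(10 * 0.5^(0:20), tol = 1e-6, window = 3))
  expect_true(chi2Stationary(c(10, 5, 4.999, 4.9989), tol = 1e-3, window = 2))
  expect_false(chi2Stationary(c(10, 5), tol = 1e-3, window = 3)) # too short
})

test_that("the chi-square trace decreases toward stationarity on noisy data", {
  spec <- discSpec(value = 2, radiusMm = 20, gridN = 32, fovMm = 64)
  img <- rasterize(spec)
  cfg <- acquisitionConfig(nProjections = 16, nBins = 32, binMm = 2,
                           totalCounts = 2e5, seed = 4)
  P <- buildSystemMatrix(32, cfg, NULL, pixelMm = 2)
  g <- addCountingNoise(parallelProject(img, cfg), cfg@totalCounts, cfg@seed)
  r <- mlem(g, P, reconSettings(maxIterations = 60))
  h <- chi2History(r)
  expect_gt(h[3], h[9])
  expect_gt(h[9], tail(h, 1))
})
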