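# System matrix and the ART / MLEM iterative reconstructors with
# chi-square stationarity stopping.

#' Build the projection operator (system matrix)
#'
#' Constructs the matrix-free projection operator used by the reconstructors.
#' Its forward map uses the same discretization as [attenuatedProject()] (ray
#' sampling at `stepFrac` of the pixel pitch, bilinear interpolation,
#' per-sample attenuation weighting), so `forwardProject(P, image)` agrees
#' with the simulator to floating-point tolerance; its adjoint is the exact
#' transpose of the forward discretization.
#'
#' @param gridN image pixels per side.
#' @param config an [AcquisitionConfig-class].
#' @param mu an [AttenuationMap-class], or `NULL` for the unattenuated
#'   operator.
#' @param pixelMm image pixel pitch (default: `mu`'s pitch, else 1).
#' @param stepFrac ray sampling step fraction (default 0.5).
#' @return a [SystemMatrix-class].
#' @export
buildSystemMatrix <- function(gridN, config, mu = NULL,
                              pixelMm = if (is.null(mu)) 1 else mu@pixelMm,
                              stepFrac = 0.5) {
  gridN <- as.integer(gridN)
  muMat <- if (is.null(mu)) NULL else mu@mu
  if (!is.null(muMat) && !all(dim(muMat) == gridN))
    stop("attenuation map shape does not match gridN")
  new("SystemMatrix", gridN = gridN, pixelMm = as.numeric(pixelMm),
      anglesDeg = projectionAngles(config), nBins = config@nBins,
      binMm = config@binMm, mu = muMat, stepFrac = as.numeric(stepFrac))
}

asImageMatrix <- function(image, n) {
  m <- if (is(image, "ActivityImage")) image@values else as.matrix(image)
  if (!all(dim(m) == n)) stop("image grid does not match the system matrix")
  m
}

#' @describeIn forwardProject Apply the forward map of a matrix-free system
#'   matrix to an image.
#' @param ... unused.
#' @export
setMethod("forwardProject", "SystemMatrix", function(object, image, ...) {
  m <- asImageMatrix(image, object@gridN)
  v <- forward_project_cpp(m, object@mu, object@pixelMm,
                           object@anglesDeg * pi / 180, object@nBins,
                           object@binMm, object@stepFrac)
  sinogram(v, anglesDeg = object@anglesDeg, binMm = object@binMm,
           variance = pmax(v, 1))
})

#' @describeIn backProject Apply the adjoint map of a matrix-free system
#'   matrix to a sinogram.
#' @param ... unused.
#' @export
setMethod("backProject", "SystemMatrix", function(object, sinogram, ...) {
  s <- if (is(sinogram, "Sinogram")) sinogram@values else as.matrix(sinogram)
  if (ncol(s) != object@nBins || nrow(s) != length(object@anglesDeg))
    stop("sinogram shape does not match the system matrix")
  back_project_cpp(s, object@mu, object@gridN, object@pixelMm,
                   object@anglesDeg * pi / 180, object@binMm, object@stepFrac)
})

#' Materialize a system matrix densely
#'
#' Builds the explicit `nRays x nPixels` matrix by forward-projecting pixel
#' delta images (column-major pixel order). Intended for small grids in tests
#' and didactics only.
#'
#' @param x a [SystemMatrix-class].
#' @param ... unused.
#' @return a dense numeric matrix.
#' @export
as.matrix.SystemMatrix <- function(x, ...) {
  n <- x@gridN
  nray <- length(x@anglesDeg) * x@nBins
  out <- matrix(0, nray, n * n)
  for (j in seq_len(n * n)) {
    d <- matrix(0, n, n); d[j] <- 1
    out[, j] <- as.vector(t(forwardProject(x, d)@values))
  }
  out
}
setMethod("as.matrix", "SystemMatrix", as.matrix.SystemMatrix)

# Internal forward/adjoint dispatch so the reconstructors also accept a plain
# base-R matrix P (rays x pixels) for small closed-form systems.
opForward <- function(P, f) {
  if (is(P, "SystemMatrix")) forwardProject(P, f)@values
  else as.numeric(P %*% as.vector(f))
}
opAdjoint <- function(P, g) {
  if (is(P, "SystemMatrix")) backProject(P, g)
  else as.numeric(crossprod(P, as.vector(g)))
}
opImageDim <- function(P) {
  if (is(P, "SystemMatrix")) c(P@gridN, P@gridN) else c(ncol(P), 1L)
}

sinoValues <- function(g) if (is(g, "Sinogram")) g@values else as.matrix(g)
sinoVar <- function(g) {
  if (is(g, "Sinogram")) g@variance else pmax(as.matrix(g), 1)
}

#' Reduced chi-square between two arrays with counting variance
#'
#' @param x,y numeric arrays of equal shape.
#' @param variance per-element variance (floored internally at a tiny
#'   positive value).
#' @return mean over elements of `(x - y)^2 / variance`.
#' @export
reducedChi2 <- function(x, y, variance) {
  mean((x - y)^2 / pmax(variance, .Machine$double.eps))
}

#' Chi-square stationarity test
#'
#' TRUE when the maximum relative change of the chi-square trace over the
#' trailing `window` transitions falls below `tol` — the standardized
#' convergence criterion shared by ART and MLEM.
#'
#' @param history numeric vector of per-iteration reduced chi-square values.
#' @param tol relative-change threshold.
#' @param window number of trailing transitions assessed.
#' @return logical.
#' @export
chi2Stationary <- function(history, tol = 1e-3, window = 3L) {
  n <- length(history)
  if (n < window + 1L) return(FALSE)
  tail <- history[(n - window):n]
  rel <- abs(diff(tail)) / pmax(abs(tail[-length(tail)]), .Machine$double.eps)
  max(rel) < tol
}

runIterative <- function(g, P, settings, stepFun, f0, checkpoints) {
  gv <- sinoValues(g)
  var <- sinoVar(g)
  f <- f0
  hist <- numeric(0)
  saved <- list()
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(settings@maxIterations)) {
    f <- stepFun(f, k)
    iters <- k
    proj <- opForward(P, f)
    hist <- c(hist, reducedChi2(proj, gv, var))
    if (k %in% checkpoints)
      saved[[as.character(k)]] <- f
    if (chi2Stationary(hist, settings@chi2Tol, settings@chi2Window)) {
      converged <- TRUE
      break
    }
  }
  list(f = f, iters = iters, hist = hist, converged = converged,
       checkpoints = saved)
}

finishRecon <- function(run, P, settings, pixelMm) {
  mkImg <- function(m) {
    dm <- opImageDim(P)
    activityImage(matrix(pmax(m, 0), dm[1], dm[2]), pixelMm = pixelMm)
  }
  new("ReconResult", image = mkImg(run$f), iterations = as.integer(run$iters),
      chi2History = if (settings@recordHistory) run$hist else numeric(0),
      converged = run$converged,
      checkpoints = lapply(run$checkpoints, mkImg))
}

#' MLEM reconstruction
#'
#' Maximum-likelihood expectation-maximization: the multiplicative update
#' `f <- f / s * Pt(g / (P f))` with sensitivity `s = Pt(1)`, which preserves
#' non-negativity and increases the Poisson likelihood of the measured counts
#' at every iteration. Iteration stops at chi-square stationarity
#' ([chi2Stationary()]) or at `maxIterations`. The initial image is a uniform
#' positive constant scaled so the total forward counts match the total
#' measured counts; zero-sensitivity pixels are frozen at zero, and forward
#' denominators are floored at 1e-12 of their maximum.
#'
#' @param g measured [Sinogram-class] (or plain matrix of counts).
#' @param P a [SystemMatrix-class], or a plain `rays x pixels` matrix for
#'   small systems.
#' @param settings a [ReconSettings-class].
#' @param checkpoints integer iteration numbers whose iterates to keep
#'   (returned in the result's `checkpoints` slot).
#' @return a [ReconResult-class].
#' @export
mlem <- function(g, P, settings = reconSettings("mlem"),
                 checkpoints = integer(0)) {
  gv <- sinoValues(g)
  sens <- opAdjoint(P, array(1, dim(gv)))
  live <- sens > 0
  if (!any(live)) stop("system matrix has no sensitivity anywhere")
  if (!all(live))
    message("mlem: ", sum(!live), " zero-sensitivity pixels frozen at 0")
  # uniform positive start, scaled so total forward counts match the data
  f0 <- if (is.matrix(sens)) array(1, dim(sens)) else rep(1, length(sens))
  f0[!live] <- 0
  proj <- opForward(P, f0)
  tot <- sum(proj)
  if (tot > 0 && sum(gv) > 0) {
    f0 <- f0 * (sum(gv) / tot)
    proj <- proj * (sum(gv) / tot)
  }
  var <- sinoVar(g)
  checkpoints <- as.integer(checkpoints)
  f <- f0
  hist <- numeric(0)
  saved <- list()
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(settings@maxIterations)) {
    # proj holds the forward projection of the current iterate
    floorv <- max(1e-12 * max(proj), .Machine$double.xmin)
    ratio <- gv / pmax(proj, floorv)
    f <- f * opAdjoint(P, ratio)
    f[live] <- f[live] / sens[live]
    f[!live] <- 0
    iters <- k
    proj <- opForward(P, f)
    hist <- c(hist, reducedChi2(proj, gv, var))
    if (k %in% checkpoints) saved[[as.character(k)]] <- f
    if (chi2Stationary(hist, settings@chi2Tol, settings@chi2Window)) {
      converged <- TRUE
      break
    }
  }
  run <- list(f = f, iters = iters, hist = hist, converged = converged,
              checkpoints = saved)
  pm <- if (is(P, "SystemMatrix")) P@pixelMm else 1
  finishRecon(run, P, settings, pm)
}

#' ART reconstruction
#'
#' Row-action Kaczmarz updates: for each ray i the current estimate is
#' corrected by `relaxation * (S_i - R_i) / sum_j(P_ij^2) * P_ij`, so the
#' unrelaxed update projects the estimate exactly onto that ray's measurement
#' hyperplane. Rays are visited in an angle-interleaved (stride-permuted)
#' order to reduce streaking; negative pixels are clipped to zero at the end
#' of each full sweep; rays with an all-zero row are skipped with a warning.
#' Iteration (sweep) count stops at chi-square stationarity or
#' `maxIterations`.
#'
#' @inheritParams mlem
#' @return a [ReconResult-class].
#' @export
art <- function(g, P, settings = reconSettings("art"),
                checkpoints = integer(0)) {
  gv <- sinoValues(g)
  warnedSkip <- FALSE
  if (is(P, "SystemMatrix")) {
    nb <- P@nBins; na <- length(P@anglesDeg)
    # angle-interleaved ray order: stride permutation over angles
    stride <- max(1L, floor(sqrt(na)))
    angOrder <- unlist(lapply(0:(stride - 1L), function(r)
      seq.int(r, na - 1L, by = stride)))
    rayOrder <- as.integer(outer(seq_len(nb) - 1L, angOrder * nb, `+`))
    step <- function(f, k) {
      fm <- matrix(f, P@gridN, P@gridN)
      skipped <- art_sweep_cpp(fm, gv, P@mu, P@pixelMm,
                               P@anglesDeg * pi / 180, P@binMm, P@stepFrac,
                               settings@relaxation, rayOrder)
      if (skipped > 0 && !warnedSkip) {
        warning("art: ", skipped, " rays with zero weights skipped")
        warnedSkip <<- TRUE
      }
      pmax(fm, 0) # clip at end of sweep
    }
    f0 <- matrix(0, P@gridN, P@gridN)
  } else {
    rows <- seq_len(nrow(P))
    step <- function(f, k) {
      for (i in rows) {
        w <- P[i, ]
        denom <- sum(w^2)
        if (denom == 0) {
          if (!warnedSkip) {
            warning("art: ray ", i, " has zero weights; skipped")
            warnedSkip <<- TRUE
          }
          next
        }
        f <- f + settings@relaxation * (as.vector(gv)[i] - sum(w * f)) / denom * w
      }
      pmax(f, 0)
    }
    f0 <- numeric(ncol(P))
  }
  run <- runIterative(g, P, settings, step, f0, as.integer(checkpoints))
  pm <- if (is(P, "SystemMatrix")) P@pixelMm else 1
  finishRecon(run, P, settings, pm)
}

#' Reconstruct a sinogram
#'
#' Dispatcher running [art()] or [mlem()] according to
#' `settings@algorithm`.
#'
#' @inheritParams mlem
#' @return a [ReconResult-class].
#' @export
reconstruct <- function(g, P, settings = reconSettings(),
                        checkpoints = integer(0)) {
  switch(settings@algorithm,
         art = art(g, P, settings, checkpoints),
         mlem = mlem(g, P, settings, checkpoints))
}
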