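# Diagnostic metric suite: mean normalization, residual/chi-square maps,
# the Structure and Contrast Index (SCI), global scalar metrics, and
# intensity (gray-value) histogram comparison.

asArray <- function(x) {
  if (is(x, "ActivityImage") || is(x, "Sinogram")) values(x) else as.matrix(x)
}

#' Mean-normalize an array
#'
#' Divides an image or sinogram by its mean intensity, so that compared
#' arrays carry the same total luminosity (the output mean is exactly 1).
#'
#' @param X numeric array (or [ActivityImage-class] / [Sinogram-class]).
#' @return numeric array of the same shape with mean 1.
#' @export
normalizeMean <- function(X) {
  X <- asArray(X)
  m <- mean(X)
  if (!is.finite(m) || m <= 0)
    stop("mean normalization requires a positive mean intensity")
  X / m
}

#' Difference and chi-square maps
#'
#' Computes the signed residual map `X - Y`, its absolute value, the
#' pixel-wise chi-square map `(X - Y)^2 / variance`, and the reduced
#' chi-square (mean of the map over valid pixels). Pixels with non-positive
#' or non-finite variance are excluded from the reduced mean and flagged in
#' `validMask`.
#'
#' @param X,Y numeric arrays of equal shape (test and reference).
#' @param variance per-pixel variance (counting statistics); scalar or array.
#' @return a list of class `ResidualMaps` with elements `signed`, `absolute`,
#'   `chi2Map`, `chi2Reduced`, `validMask`.
#' @export
residualMaps <- function(X, Y, variance) {
  X <- asArray(X); Y <- asArray(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  if (length(variance) == 1) variance <- array(variance, dim(X))
  variance <- asArray(variance)
  valid <- is.finite(variance) & variance > 0
  if (!any(valid)) stop("no pixels with valid variance")
  signed <- X - Y
  chi2 <- array(NA_real_, dim(X))
  chi2[valid] <- signed[valid]^2 / variance[valid]
  structure(list(signed = signed, absolute = abs(signed), chi2Map = chi2,
                 chi2Reduced = mean(chi2[valid]), validMask = valid),
            class = "ResidualMaps")
}

#' @export
print.ResidualMaps <- function(x, ...) {
  cat(sprintf("ResidualMaps: %d x %d, reduced chi2 = %.4g (%d valid pixels)\n",
              nrow(x$signed), ncol(x$signed), x$chi2Reduced, sum(x$validMask)))
  invisible(x)
}

#' Compose an SCI value from its components
#'
#' The Structure and Contrast Index is *defined* as the product of the
#' contrast and structure components; the luminance component is discarded.
#'
#' @param contrast,structure component values.
#' @return `contrast * structure`.
#' @export
sciCompose <- function(contrast, structure) contrast * structure

#' Structure and Contrast Index (SCI) of a residual map
#'
#' Quantifies whether the residual between a reconstruction and its reference
#' still contains organized, recoverable structure. Both inputs are first
#' mean-normalized; the residual `R = Xnorm - Ynorm` is then decomposed into
#' the SSIM-style luminance, contrast and structure components, evaluated
#' globally between `R` and the normalized reference:
#' \deqn{luminance = 2 \mu_R \mu_Y / (\mu_R^2 + \mu_Y^2 + c_1)}
#' \deqn{contrast = 2 \sigma_R \sigma_Y / (\sigma_R^2 + \sigma_Y^2 + c_2)}
#' \deqn{structure = (|cov(R, Y)| + c_3) / (\sigma_R \sigma_Y + c_3)}
#' with stabilizers \eqn{c_1 = (0.01 L)^2}, \eqn{c_2 = (0.03 L)^2},
#' \eqn{c_3 = c_2 / 2}, where `L` is the data range of the normalized
#' reference. The SCI is `contrast * structure`; the luminance of a
#' mean-matched residual is identically 0 (the residual mean vanishes by
#' construction), which is why it is discarded. A perfect reconstruction
#' gives SCI = 0; elevated values indicate coherent residual structure.
#'
#' With `windowed = TRUE`, the components are instead the means of local
#' (11-pixel Gaussian window) contrast and structure fields — an alternative
#' reading provided for comparison.
#'
#' @param X reconstructed array (image or sinogram).
#' @param Y reference array of the same shape.
#' @param normalize mean-normalize both inputs first (default TRUE).
#' @param windowed use windowed component means instead of global moments.
#' @return a list of class `SCIComponents` with elements `luminance`,
#'   `contrast`, `structure`, `sci`.
#' @export
sci <- function(X, Y, normalize = TRUE, windowed = FALSE) {
  X <- asArray(X); Y <- asArray(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  if (normalize) {
    X <- normalizeMean(X)
    Y <- normalizeMean(Y)
  }
  R <- X - Y
  L <- diff(range(Y))
  if (L <= 0) stop("constant reference: structure component undefined")
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2; c3 <- c2 / 2
  # The structure component uses the magnitude of the covariance: the index
  # quantifies the presence of organized residual structure, and a residual
  # anticorrelated with the reference (e.g. underestimated hotspots) is just
  # as organized as a correlated one.
  if (windowed) {
    st <- localStats(R, Y)
    contrast <- mean(2 * st$sx * st$sy / (st$sx^2 + st$sy^2 + c2))
    structure <- mean((abs(st$sxy) + c3) / (st$sx * st$sy + c3))
    muR <- mean(R); muY <- mean(Y)
    luminance <- 2 * muR * muY / (muR^2 + muY^2 + c1)
  } else {
    n <- length(R)
    muR <- mean(R); muY <- mean(Y)
    sR <- sqrt(sum((R - muR)^2) / n)   # population moments
    sY <- sqrt(sum((Y - muY)^2) / n)
    cRY <- sum((R - muR) * (Y - muY)) / n
    luminance <- 2 * muR * muY / (muR^2 + muY^2 + c1)
    contrast <- 2 * sR * sY / (sR^2 + sY^2 + c2)
    structure <- (abs(cRY) + c3) / (sR * sY + c3)
  }
  structure(list(luminance = luminance, contrast = contrast,
                 structure = structure, sci = sciCompose(contrast, structure)),
            class = "SCIComponents")
}

#' @export
print.SCIComponents <- function(x, ...) {
  cat(sprintf("SCI = %.4g (contrast %.4g x structure %.4g; luminance %.4g)\n",
              x$sci, x$contrast, x$structure, x$luminance))
  invisible(x)
}

# Local Gaussian-window moments shared by SSIM and the windowed SCI variant:
# 11 x 11 Gaussian, sigma 1.5, computed separably on the interior (valid)
# region.
gaussianBand <- function(n, half = 5L, sigma = 1.5) {
  g <- exp(-0.5 * ((-half):half / sigma)^2)
  g <- g / sum(g)
  m <- n - 2L * half
  if (m < 1L) stop("array too small for an 11-pixel window")
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + 2L * half)] <- g
  K
}

localStats <- function(X, Y, half = 5L, sigma = 1.5) {
  Kr <- gaussianBand(nrow(X), half, sigma)
  Kc <- gaussianBand(ncol(X), half, sigma)
  sm <- function(M) Kr %*% M %*% t(Kc)
  mx <- sm(X); my <- sm(Y)
  vx <- pmax(sm(X^2) - mx^2, 0)
  vy <- pmax(sm(Y^2) - my^2, 0)
  cxy <- sm(X * Y) - mx * my
  list(mx = mx, my = my, sx = sqrt(vx), sy = sqrt(vy), sxy = cxy)
}

#' Structural similarity index (SSIM)
#'
#' Standard mean SSIM with an 11-pixel Gaussian window (sigma 1.5),
#' stabilizers `K1 = 0.01`, `K2 = 0.03`, and dynamic range taken from the
#' reference `Y`.
#'
#' @param X,Y numeric arrays of equal shape (test and reference).
#' @return mean SSIM over the valid (interior) window positions.
#' @export
ssim <- function(X, Y) {
  X <- asArray(X); Y <- asArray(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  L <- diff(range(Y))
  if (L <= 0) stop("SSIM undefined for a constant reference")
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  st <- localStats(X, Y)
  num <- (2 * st$mx * st$my + c1) * (2 * st$sxy + c2)
  den <- (st$mx^2 + st$my^2 + c1) * (st$sx^2 + st$sy^2 + c2)
  mean(num / den)
}

#' Global scalar metrics between a test and a reference array
#'
#' Computes the baseline global metrics: NMSE `sum((X-Y)^2)/sum(Y^2)`, PSNR
#' `10 log10(max(Y)^2 / MSE)` (infinite for identical inputs), Pearson
#' correlation CC, mean [ssim()], reduced chi-square (when `variance` is
#' given), and CNR `(mean(signal) - mean(background)) / sd(background)` (when
#' both masks are given).
#'
#' @param X,Y numeric arrays of equal shape.
#' @param variance optional per-pixel counting variance for the chi-square.
#' @param signalMask,backgroundMask optional [RoIMask-class]s (or logical
#'   arrays) for the CNR.
#' @param withSSIM set FALSE to skip SSIM (e.g. regions smaller than the
#'   window).
#' @return named list of metric values.
#' @export
globalMetrics <- function(X, Y, variance = NULL, signalMask = NULL,
                          backgroundMask = NULL, withSSIM = TRUE) {
  X <- asArray(X); Y <- asArray(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  if (all(Y == 0)) stop("NMSE undefined: reference is identically zero")
  mse <- mean((X - Y)^2)
  out <- list(
    nmse = sum((X - Y)^2) / sum(Y^2),
    psnr = if (mse == 0) Inf else 10 * log10(max(Y)^2 / mse))
  if (stats::sd(as.vector(X)) == 0 || stats::sd(as.vector(Y)) == 0)
    stop("CC undefined: constant input array")
  out$cc <- stats::cor(as.vector(X), as.vector(Y))
  if (withSSIM) out$ssim <- ssim(X, Y)
  if (!is.null(variance))
    out$chi2Reduced <- residualMaps(X, Y, variance)$chi2Reduced
  if (!is.null(signalMask) && !is.null(backgroundMask)) {
    sm <- if (is(signalMask, "RoIMask")) signalMask@mask else signalMask
    bm <- if (is(backgroundMask, "RoIMask")) backgroundMask@mask else backgroundMask
    out$cnr <- cnr(X, sm, bm)
  }
  out
}

#' Contrast-to-noise ratio
#'
#' `(mean over the signal region - mean over the background region) / sd of
#' the background region`.
#'
#' @param X numeric array.
#' @param signalMask,backgroundMask logical arrays or [RoIMask-class]s.
#' @return the CNR value.
#' @export
cnr <- function(X, signalMask, backgroundMask) {
  X <- asArray(X)
  sm <- if (is(signalMask, "RoIMask")) signalMask@mask else signalMask
  bm <- if (is(backgroundMask, "RoIMask")) backgroundMask@mask else backgroundMask
  sdb <- stats::sd(X[bm])
  if (!is.finite(sdb) || sdb == 0) stop("CNR undefined: background sd is zero")
  (mean(X[sm]) - mean(X[bm])) / sdb
}

#' Intensity (gray-value) histogram
#'
#' Histogram of pixel/bin intensities over equal-width bins. When comparing
#' two arrays, compute shared edges first with [sharedEdges()] so both
#' histograms use a common binning spanning the joint intensity range.
#'
#' @param X numeric array (normally mean-normalized first, see
#'   [normalizeMean()]).
#' @param nb number of bins (default 256).
#' @param edges optional shared bin edges (length `nb + 1`); default spans
#'   `range(X)`.
#' @return list of class `IntensityHistogram` with `edges`, `counts`, `nb`.
#' @export
intensityHistogram <- function(X, nb = 256L, edges = NULL) {
  X <- as.vector(asArray(X))
  nb <- as.integer(nb)
  if (nb < 2L) stop("nb must be at least 2")
  if (is.null(edges)) {
    edges <- seq(min(X), max(X), length.out = nb + 1L)
    if (edges[1] == edges[nb + 1L]) # constant array: widen degenerate range
      edges <- seq(edges[1] - 0.5, edges[1] + 0.5, length.out = nb + 1L)
  }
  if (length(edges) != nb + 1L) stop("edges must have length nb + 1")
  idx <- findInterval(X, edges, rightmost.closed = TRUE, all.inside = TRUE)
  structure(list(edges = edges, counts = tabulate(idx, nbins = nb), nb = nb),
            class = "IntensityHistogram")
}

#' @rdname intensityHistogram
#' @param Y second array for a joint-range binning.
#' @return `sharedEdges` returns bin edges spanning both arrays.
#' @export
sharedEdges <- function(X, Y, nb = 256L) {
  r <- range(c(asArray(X), asArray(Y)))
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = as.integer(nb) + 1L)
}

#' Reduced chi-square between two intensity histograms
#'
#' `(1/NB) * sum((SX_i - SY_i)^2)` over the shared bins, on the raw
#' pixel-count scale. Requires identical binning.
#'
#' @param SX,SY two [intensityHistogram()] results with the same edges.
#' @return the reduced chi-square value.
#' @export
histogramChi2Red <- function(SX, SY) {
  if (SX$nb != SY$nb || !isTRUE(all.equal(SX$edges, SY$edges)))
    stop("histograms must share the same bin edges")
  mean((SX$counts - SY$counts)^2)
}

#' Jackknife value and standard error of a statistic
#'
#' Delete-one jackknife over user-defined resampling units: the statistic is
#' evaluated on the full data and with each unit deleted in turn, and the
#' standard error is `sqrt(((n-1)/n) * sum((theta_(i) - theta_bar)^2))`.
#'
#' @param data a vector, or a list of per-unit data chunks.
#' @param statistic function mapping data (a vector, or concatenation of the
#'   retained chunks) to a scalar.
#' @param units for vector `data`, an optional factor/vector of unit labels
#'   (default: each element its own unit).
#' @return list with `value` (full-sample statistic) and `se`.
#' @export
jackknife <- function(data, statistic, units = NULL) {
  if (is.list(data)) {
    chunks <- data
  } else {
    if (is.null(units)) units <- seq_along(data)
    chunks <- split(data, units)
  }
  n <- length(chunks)
  if (n < 3) stop("jackknife needs at least 3 resampling units")
  full <- statistic(unlist(chunks, use.names = FALSE))
  loo <- vapply(seq_len(n), function(i)
    statistic(unlist(chunks[-i], use.names = FALSE)), numeric(1))
  list(value = full, se = sqrt((n - 1) / n * sum((loo - mean(loo))^2)))
}

#' Jackknife uncertainty of a two-array metric
#'
#' Resamples a metric of (test, reference) arrays by deleting one unit at a
#' time: one projection angle (sinogram row) for sinogram-domain metrics, or
#' one block of `blockRows` image rows for image-domain metrics, and
#' re-evaluating the metric on the retained rows.
#'
#' @param X,Y arrays of equal shape.
#' @param metric function of `(X, Y)` returning a scalar.
#' @param unit `"angles"` (delete single rows) or `"rowBlocks"`.
#' @param blockRows rows per block for `unit = "rowBlocks"` (default 16).
#' @return list with `value` and `se`.
#' @export
jackknifeMetric <- function(X, Y, metric, unit = c("rowBlocks", "angles"),
                            blockRows = 16L) {
  unit <- match.arg(unit)
  X <- asArray(X); Y <- asArray(Y)
  nr <- nrow(X)
  groups <- if (unit == "angles") seq_len(nr)
            else ((seq_len(nr) - 1L) %/% as.integer(blockRows)) + 1L
  ug <- unique(groups)
  n <- length(ug)
  if (n < 3) stop("jackknife needs at least 3 resampling units")
  full <- metric(X, Y)
  loo <- vapply(ug, function(gp) {
    keep <- groups != gp
    metric(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
  }, numeric(1))
  list(value = full, se = sqrt((n - 1) / n * sum((loo - mean(loo))^2)))
}
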