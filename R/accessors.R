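# Constructors, accessors and show methods for the core containers.

#' Create an activity image
#'
#' @param values numeric matrix of non-negative specific activities.
#' @param pixelMm pixel pitch in mm (default 1).
#' @return an [ActivityImage-class].
#' @export
activityImage <- function(values, pixelMm = 1) {
  new("ActivityImage", values = as.matrix(values), pixelMm = as.numeric(pixelMm))
}

#' Create an attenuation map
#'
#' @param mu numeric matrix of linear attenuation coefficients (1/mm).
#' @param pixelMm pixel pitch in mm.
#' @return an [AttenuationMap-class].
#' @export
newAttenuationMap <- function(mu, pixelMm = 1) {
  new("AttenuationMap", mu = as.matrix(mu), pixelMm = as.numeric(pixelMm))
}

#' Create a sinogram
#'
#' @param values `nProjections x nBins` matrix of counts or expected counts.
#' @param anglesDeg projection angles in degrees (one per row).
#' @param binMm detector bin pitch in mm.
#' @param variance per-bin counting variance; defaults to `pmax(values, 1)`,
#'   the Poisson expected-count variance floored at one count.
#' @return a [Sinogram-class].
#' @export
sinogram <- function(values, anglesDeg, binMm = 1, variance = NULL) {
  values <- as.matrix(values)
  if (is.null(variance)) variance <- pmax(values, 1)
  new("Sinogram", values = values, anglesDeg = as.numeric(anglesDeg),
      binMm = as.numeric(binMm), variance = as.matrix(variance))
}

#' Create a region-of-interest mask
#'
#' @param mask logical matrix (TRUE inside the region).
#' @param label short identifier.
#' @param kind `"edge"`, `"hotspot"`, `"background"` or `"custom"`.
#' @return an [RoIMask-class].
#' @export
roiMask <- function(mask, label = "roi", kind = "custom") {
  new("RoIMask", mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
      label = label, kind = kind)
}

#' Create an acquisition configuration
#'
#' Angles are equally spaced over `angularRangeDeg` starting at 0, excluding
#' the endpoint: 128 projections over 360 degrees gives a step of exactly
#' 2.8125 degrees.
#'
#' @param nProjections number of projection angles (default 128).
#' @param nBins detector bins per projection (default `nProjections`-matched
#'   grid, usually the image grid size).
#' @param angularRangeDeg angular coverage in degrees (default 360).
#' @param binMm detector bin pitch in mm (default 1).
#' @param totalCounts expected total detected counts for noisy sinograms
#'   (default 5e6).
#' @param seed integer seed for counting noise (default 1).
#' @param collimator `"ideal"` or `"blurred"` (default `"ideal"`).
#' @param detectorBlurSigmaMm detector blur sigma in mm (default 0).
#' @return an [AcquisitionConfig-class].
#' @export
acquisitionConfig <- function(nProjections = 128L, nBins = 256L,
                              angularRangeDeg = 360, binMm = 1,
                              totalCounts = 5e6, seed = 1L,
                              collimator = "ideal",
                              detectorBlurSigmaMm = 0) {
  new("AcquisitionConfig", nProjections = as.integer(nProjections),
      angularRangeDeg = as.numeric(angularRangeDeg),
      nBins = as.integer(nBins), binMm = as.numeric(binMm),
      totalCounts = as.numeric(totalCounts), seed = as.integer(seed),
      collimator = collimator,
      detectorBlurSigmaMm = as.numeric(detectorBlurSigmaMm))
}

#' Projection angles of an acquisition configuration
#'
#' @param config an [AcquisitionConfig-class].
#' @return numeric vector of angles in degrees.
#' @export
projectionAngles <- function(config) {
  step <- config@angularRangeDeg / config@nProjections
  seq(0, by = step, length.out = config@nProjections)
}

#' Create reconstruction settings
#'
#' @param algorithm `"mlem"` (default) or `"art"`.
#' @param maxIterations iteration cap (default 200).
#' @param chi2Tol relative chi-square stationarity tolerance (default 1e-3).
#' @param chi2Window trailing window for stationarity (default 3).
#' @param relaxation ART damping factor in (0, 1] (default 0.5).
#' @param recordHistory keep the chi-square trace (default TRUE).
#' @return a [ReconSettings-class].
#' @export
reconSettings <- function(algorithm = "mlem", maxIterations = 200L,
                          chi2Tol = 1e-3, chi2Window = 3L,
                          relaxation = 0.5, recordHistory = TRUE) {
  new("ReconSettings", algorithm = algorithm,
      maxIterations = as.integer(maxIterations), chi2Tol = as.numeric(chi2Tol),
      chi2Window = as.integer(chi2Window), relaxation = as.numeric(relaxation),
      recordHistory = as.logical(recordHistory))
}

#' @rdname values
#' @export
setMethod("values", "ActivityImage", function(object) object@values)
#' @rdname values
#' @export
setMethod("values", "Sinogram", function(object) object@values)
#' @rdname values
#' @export
setMethod("values", "AttenuationMap", function(object) object@mu)
#' @rdname values
#' @export
setMethod("values", "RoIMask", function(object) object@mask)

#' @rdname values
#' @export
setMethod("pixelPitch", "ActivityImage", function(object) object@pixelMm)
#' @rdname values
#' @export
setMethod("pixelPitch", "AttenuationMap", function(object) object@pixelMm)
#' @rdname values
#' @export
setMethod("pixelPitch", "Sinogram", function(object) object@binMm)

#' Sinogram variance accessor
#'
#' @param object a [Sinogram-class].
#' @return the per-bin variance matrix.
#' @export
sinogramVariance <- function(object) object@variance

#' Sinogram angles accessor
#'
#' @param object a [Sinogram-class].
#' @return projection angles in degrees.
#' @export
sinogramAngles <- function(object) object@anglesDeg

setMethod("show", "ActivityImage", function(object) {
  v <- object@values
  cat(sprintf("ActivityImage: %d x %d pixels, pitch %.3g mm\n",
              nrow(v), ncol(v), object@pixelMm))
  cat(sprintf("  values in [%.4g, %.4g], total activity %.4g (value * area)\n",
              min(v), max(v), sum(v) * object@pixelMm^2))
})

setMethod("show", "Sinogram", function(object) {
  v <- object@values
  cat(sprintf("Sinogram: %d projections x %d bins, bin pitch %.3g mm\n",
              nrow(v), ncol(v), object@binMm))
  cat(sprintf("  angles %.4g..%.4g deg, total counts %.6g\n",
              min(object@anglesDeg), max(object@anglesDeg), sum(v)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d ellipses, variant %d, FOV %.4g mm, grid %d\n",
              nrow(object@ellipses), object@variant, object@fovMm, object@gridN))
  print(object@ellipses, row.names = FALSE)
})

setMethod("show", "RoIMask", function(object) {
  cat(sprintf("RoIMask '%s' (%s): %d of %d pixels\n", object@label,
              object@kind, sum(object@mask), length(object@mask)))
})

setMethod("show", "SystemMatrix", function(object) {
  cat(sprintf(
    "SystemMatrix (matrix-free): %d rays (%d angles x %d bins) -> %d pixels%s\n",
    length(object@anglesDeg) * object@nBins, length(object@anglesDeg),
    object@nBins, object@gridN^2,
    if (is.null(object@mu)) ", unattenuated" else ", attenuation-weighted"))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %d iterations, %sconverged", object@iterations,
              if (object@converged) "" else "NOT "))
  if (length(object@chi2History))
    cat(sprintf(", final reduced chi2 = %.4g",
                object@chi2History[length(object@chi2History)]))
  cat("\n")
})

setMethod("show", "StandardizedSet", function(object) {
  cat("StandardizedSet: Source / Detector / Ideal / Realistic\n")
  cat(sprintf("  grid %d x %d, %d projections\n", nrow(object@source@values),
              ncol(object@source@values), length(object@idealSinogram@anglesDeg)))
})

#' Reconstruction result accessors
#'
#' @param result a [ReconResult-class].
#' @return `reconImage()` the [ActivityImage-class]; `chi2History()` the
#'   per-iteration reduced chi-square trace; `reconConverged()` logical;
#'   `reconCheckpoints()` named list of intermediate images.
#' @export
reconImage <- function(result) result@image

#' @rdname reconImage
#' @export
chi2History <- function(result) result@chi2History

#' @rdname reconImage
#' @export
reconConverged <- function(result) result@converged

#' @rdname reconImage
#' @export
reconCheckpoints <- function(result) result@checkpoints
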