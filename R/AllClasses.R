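#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Ellipse and phantom specifications
#'
#' `PhantomSpec` describes a 2-D software phantom as an ordered list of
#' constant-activity ellipses rasterized on a square grid. The built-in
#' modified Shepp-Logan phantom ([sheppLoganPhantom()]) lists the large
#' background ellipse (SRC0) first; later ellipses *override* earlier ones
#' where they overlap, so interior structures replace the background value
#' rather than adding to it.
#'
#' @slot ellipses `data.frame` with one row per ellipse and columns `label`,
#'   `xMm`, `yMm` (center), `aMm`, `bMm` (semi-axes along the ellipse's local
#'   x and y before rotation), `angleDeg` (counter-clockwise rotation),
#'   `activityKbq` (total activity), `surfaceAu` (surface in arbitrary units)
#'   and `specificActivity` (activity per surface unit; the rasterized pixel
#'   value).
#' @slot variant integer, 1 (moderate background) or 2 (four-fold background).
#' @slot fovMm field-of-view width in mm.
#' @slot gridN pixels per side of the raster.
#'
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(ellipses = "data.frame", variant = "integer",
                 fovMm = "numeric", gridN = "integer"),
  validity = function(object) {
    need <- c("label", "xMm", "yMm", "aMm", "bMm", "angleDeg",
              "activityKbq", "surfaceAu", "specificActivity")
    if (!all(need %in% names(object@ellipses)))
      return(paste("ellipses must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@ellipses) > 0 &&
        any(object@ellipses$aMm <= 0 | object@ellipses$bMm <= 0))
      return("ellipse semi-axes must be positive")
    if (!object@variant %in% c(1L, 2L)) return("variant must be 1 or 2")
    if (object@gridN < 32L) return("gridN must be at least 32")
    if (object@fovMm <= 0) return("fovMm must be positive")
    TRUE
  })

#' 2-D activity image
#'
#' A square grid of specific activity (emissivity) values, the quantity the
#' reconstruction estimates. Pixel (1,1) is the top-left corner; physical
#' coordinates put the origin at the image center with x increasing to the
#' right (columns) and y increasing upward (decreasing row index).
#'
#' @slot values numeric matrix of non-negative activities.
#' @slot pixelMm pixel pitch in mm.
#'
#' @aliases ActivityImage-class
#' @exportClass ActivityImage
setClass("ActivityImage",
  representation(values = "matrix", pixelMm = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be numeric")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (any(object@values < 0)) return("values must be non-negative")
    if (object@pixelMm <= 0) return("pixelMm must be positive")
    TRUE
  })

#' Linear attenuation map
#'
#' Linear attenuation coefficients (1/mm) on the same grid as the activity
#' image it accompanies.
#'
#' @slot mu numeric matrix of non-negative attenuation coefficients (1/mm).
#' @slot pixelMm pixel pitch in mm.
#'
#' @aliases AttenuationMap-class
#' @exportClass AttenuationMap
setClass("AttenuationMap",
  representation(mu = "matrix", pixelMm = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@mu))) return("mu must be finite")
    if (any(object@mu < 0)) return("mu must be non-negative")
    if (object@pixelMm <= 0) return("pixelMm must be positive")
    TRUE
  })

#' Parallel-beam acquisition configuration
#'
#' Geometry and statistics of a simulated ideal-collimator SPECT acquisition:
#' equally spaced projection angles over a full turn, one detector bin row per
#' angle, an expected total detected count controlling Poisson statistics, and
#' an optional 1-D Gaussian detector blur used for the "Realistic" images.
#'
#' @slot nProjections number of projection angles.
#' @slot angularRangeDeg angular coverage (360 for a full turn).
#' @slot nBins detector bins per projection.
#' @slot binMm detector bin pitch in mm.
#' @slot totalCounts expected total detected counts for noisy sinograms.
#' @slot seed integer seed used when drawing counting noise.
#' @slot collimator `"ideal"` (perpendicular rays only) or `"blurred"`.
#' @slot detectorBlurSigmaMm Gaussian blur sigma along the bin axis, mm.
#'
#' @aliases AcquisitionConfig-class
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(nProjections = "integer", angularRangeDeg = "numeric",
                 nBins = "integer", binMm = "numeric",
                 totalCounts = "numeric", seed = "integer",
                 collimator = "character", detectorBlurSigmaMm = "numeric"),
  validity = function(object) {
    if (object@nProjections < 2L) return("nProjections must be >= 2")
    if (object@nBins < 2L) return("nBins must be >= 2")
    if (object@totalCounts <= 0) return("totalCounts must be positive")
    if (!object@collimator %in% c("ideal", "blurred"))
      return("collimator must be 'ideal' or 'blurred'")
    if (object@detectorBlurSigmaMm < 0) return("detectorBlurSigmaMm must be >= 0")
    TRUE
  })

#' Sinogram
#'
#' Projection data: one row per acquisition angle, one column per detector
#' bin. `values` holds counts (or expected counts for noise-free sinograms);
#' `variance` holds the per-bin counting variance used in chi-square
#' diagnostics (for Poisson data, the expected counts, floored at 1).
#'
#' @slot values numeric matrix, `nProjections x nBins`, non-negative.
#' @slot anglesDeg projection angles in degrees.
#' @slot binMm detector bin pitch in mm.
#' @slot variance per-bin variance, same shape as `values`.
#'
#' @aliases Sinogram-class
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "matrix", anglesDeg = "numeric",
                 binMm = "numeric", variance = "matrix"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("values must be finite")
    if (any(object@values < 0)) return("values must be non-negative")
    if (nrow(object@values) != length(object@anglesDeg))
      return("one angle per sinogram row required")
    if (!all(dim(object@variance) == dim(object@values)))
      return("variance must match values in shape")
    if (any(object@variance < 0)) return("variance must be non-negative")
    TRUE
  })

#' Region-of-interest mask
#'
#' A binary pixel mask selecting a subregion of the image grid on which all
#' metrics can be recomputed locally.
#'
#' @slot mask logical matrix, `TRUE` inside the region.
#' @slot label short identifier.
#' @slot kind one of `"edge"`, `"hotspot"`, `"background"`, `"custom"`.
#'
#' @aliases RoIMask-class
#' @exportClass RoIMask
setClass("RoIMask",
  representation(mask = "matrix", label = "character", kind = "character"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("mask must contain at least one TRUE pixel")
    if (!object@kind %in% c("edge", "hotspot", "background", "custom"))
      return("kind must be edge, hotspot, background or custom")
    TRUE
  })

#' Matrix-free system matrix (projection operator)
#'
#' The projection operator P mapping image pixels to sinogram bins, applied as
#' matched forward (image to sinogram) and adjoint (sinogram to image) maps by
#' an attenuation-aware ray tracer. The forward map agrees with
#' [attenuatedProject()] by construction (same discretization); the adjoint is
#' the exact transpose of the forward discretization. For small grids the
#' operator can be materialized densely with [as.matrix()].
#'
#' @slot gridN image pixels per side.
#' @slot pixelMm pixel pitch in mm.
#' @slot anglesDeg projection angles.
#' @slot nBins detector bins per angle.
#' @slot binMm detector bin pitch in mm.
#' @slot mu attenuation map matrix, or `NULL` for the unattenuated operator.
#' @slot stepFrac ray sampling step as a fraction of the pixel pitch.
#'
#' @aliases SystemMatrix-class
#' @exportClass SystemMatrix
setClass("SystemMatrix",
  representation(gridN = "integer", pixelMm = "numeric", anglesDeg = "numeric",
                 nBins = "integer", binMm = "numeric", mu = "matrixOrNULL",
                 stepFrac = "numeric"),
  validity = function(object) {
    if (!is.null(object@mu) && !all(dim(object@mu) == object@gridN))
      return("mu must be gridN x gridN")
    if (!is.null(object@mu) && any(object@mu < 0)) return("mu must be >= 0")
    if (object@stepFrac <= 0 || object@stepFrac > 1)
      return("stepFrac must be in (0, 1]")
    TRUE
  })

#' Iterative reconstruction settings
#'
#' @slot algorithm `"art"` or `"mlem"`.
#' @slot maxIterations iteration cap.
#' @slot chi2Tol relative chi-square change below which iteration is
#'   considered stationary.
#' @slot chi2Window trailing iterations over which stationarity is assessed.
#' @slot relaxation ART damping factor in (0, 1].
#' @slot recordHistory keep the per-iteration reduced chi-square trace.
#'
#' @aliases ReconSettings-class
#' @exportClass ReconSettings
setClass("ReconSettings",
  representation(algorithm = "character", maxIterations = "integer",
                 chi2Tol = "numeric", chi2Window = "integer",
                 relaxation = "numeric", recordHistory = "logical"),
  validity = function(object) {
    if (!object@algorithm %in% c("art", "mlem"))
      return("algorithm must be 'art' or 'mlem'")
    if (object@maxIterations < 1L) return("maxIterations must be >= 1")
    if (object@chi2Tol <= 0) return("chi2Tol must be positive")
    if (object@chi2Window < 1L) return("chi2Window must be >= 1")
    if (object@relaxation <= 0 || object@relaxation > 1)
      return("relaxation must be in (0, 1]")
    TRUE
  })

#' Reconstruction result
#'
#' @slot image the reconstructed [ActivityImage-class].
#' @slot iterations iterations actually run.
#' @slot chi2History per-iteration reduced chi-square between the forward
#'   projection of the iterate and the measured sinogram.
#' @slot converged whether the chi-square stationarity criterion was met.
#' @slot checkpoints named list of intermediate [ActivityImage-class] iterates
#'   (empty unless checkpoints were requested).
#'
#' @aliases ReconResult-class
#' @exportClass ReconResult
setClass("ReconResult",
  representation(image = "ActivityImage", iterations = "integer",
                 chi2History = "numeric", converged = "logical",
                 checkpoints = "list"))

#' The four standardized reference images and their sinograms
#'
#' Bundles the Source, Detector, Ideal and Realistic images of one phantom /
#' acquisition configuration: `source` is the rasterized emissivity;
#' `detector` weights each pixel by its angle-averaged attenuation survival
#' probability; `idealSinogram` is the noise-free attenuated projection
#' (infinite-statistics, ideal-collimator limit) and `idealImage` its
#' converged MLEM reference reconstruction; `realisticSinogram` adds detector
#' blur (if configured) and Poisson counting noise, and `realisticImage` is
#' the same reconstruction operator applied to it.
#'
#' @slot source,detector,idealImage,realisticImage [ActivityImage-class]s.
#' @slot idealSinogram,realisticSinogram [Sinogram-class]s.
#' @slot config the [AcquisitionConfig-class] used.
#'
#' @aliases StandardizedSet-class
#' @exportClass StandardizedSet
setClass("StandardizedSet",
  representation(source = "ActivityImage", detector = "ActivityImage",
                 idealImage = "ActivityImage", idealSinogram = "Sinogram",
                 realisticImage = "ActivityImage",
                 realisticSinogram = "Sinogram",
                 config = "AcquisitionConfig"))
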