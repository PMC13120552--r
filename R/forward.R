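# Analytic forward model: ideal-collimator parallel-beam (attenuated)
# projection, detector image, Poisson counting noise, standardized image set.
# Serves as a deterministic stand-in for a full Monte Carlo photon-transport
# simulation: attenuation is modeled exactly along each ray, Compton scatter
# and collimator penetration are not (see the methods vignette).

projectCore <- function(img, mu, pixelMm, config, stepFrac = 0.5) {
  angles <- projectionAngles(config) * pi / 180
  v <- forward_project_cpp(img, mu, pixelMm, angles,
                           config@nBins, config@binMm, stepFrac)
  sinogram(v, anglesDeg = projectionAngles(config), binMm = config@binMm,
           variance = pmax(v, 1))
}

#' Ideal-collimator parallel-beam projection
#'
#' Line integrals of the emissivity along rays perpendicular to the detector
#' at each acquisition angle (the unattenuated Radon transform, sampled on
#' the detector bin grid). Linear in the image.
#'
#' @param image an [ActivityImage-class].
#' @param config an [AcquisitionConfig-class] with `collimator = "ideal"`.
#' @param stepFrac ray sampling step as a fraction of the pixel pitch
#'   (default 0.5).
#' @return a noise-free [Sinogram-class] (values in activity x mm units).
#' @export
parallelProject <- function(image, config, stepFrac = 0.5) {
  stopifnot(is(image, "ActivityImage"), is(config, "AcquisitionConfig"))
  if (config@collimator != "ideal")
    stop("parallelProject models the ideal collimator; got '",
         config@collimator, "'")
  projectCore(image@values, NULL, image@pixelMm, config, stepFrac)
}

#' Attenuated parallel-beam projection
#'
#' As [parallelProject()], but each emission point contributes weighted by
#' `exp(-integral of mu)` along the ray segment from the point to the
#' detector (the attenuated Radon transform). Identical to the unattenuated
#' projection when `mu` is zero everywhere.
#'
#' @param image an [ActivityImage-class].
#' @param mu an [AttenuationMap-class] on the same grid.
#' @param config an [AcquisitionConfig-class].
#' @param stepFrac ray sampling step fraction (default 0.5).
#' @return a noise-free [Sinogram-class].
#' @export
attenuatedProject <- function(image, mu, config, stepFrac = 0.5) {
  stopifnot(is(image, "ActivityImage"), is(mu, "AttenuationMap"))
  if (!all(dim(mu@mu) == dim(image@values)))
    stop("image and attenuation map must share one grid")
  projectCore(image@values, mu@mu, image@pixelMm, config, stepFrac)
}

#' Add Poisson counting noise to a sinogram
#'
#' Rescales a noise-free sinogram so its total equals `totalCounts`, then
#' replaces each bin by an independent Poisson draw with that expectation.
#' The variance field is set to the expected counts per bin (floored at one
#' count), the counting-statistics variance used in chi-square diagnostics.
#'
#' @param sino a noise-free [Sinogram-class].
#' @param totalCounts expected total detected counts.
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return a [Sinogram-class] of counts.
#' @export
addCountingNoise <- function(sino, totalCounts, seed = 1L) {
  stopifnot(is(sino, "Sinogram"))
  tot <- sum(sino@values)
  if (tot <= 0) stop("cannot scale a zero-sum sinogram to a count level")
  if (totalCounts <= 0) stop("totalCounts must be positive")
  lambda <- sino@values * (totalCounts / tot)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(lambda), lambda),
                   nrow(lambda), ncol(lambda))
  sinogram(counts, anglesDeg = sino@anglesDeg, binMm = sino@binMm,
           variance = pmax(lambda, 1))
}

#' Gaussian detector blur along the bin axis
#'
#' Convolves each projection (sinogram row) with a 1-D Gaussian of standard
#' deviation `sigmaMm`, renormalized at the detector edges. Models collimator
#' blur / detector response for the "Realistic" images.
#'
#' @param sino a [Sinogram-class].
#' @param sigmaMm blur sigma in mm; 0 returns the input unchanged.
#' @return a [Sinogram-class].
#' @export
blurSinogram <- function(sino, sigmaMm) {
  if (sigmaMm <= 0) return(sino)
  nb <- ncol(sino@values)
  rad <- max(1L, ceiling(3 * sigmaMm / sino@binMm))
  off <- (-rad):rad
  g <- exp(-0.5 * (off * sino@binMm / sigmaMm)^2)
  K <- matrix(0, nb, nb)
  for (j in seq_len(nb)) {
    i <- j + off
    ok <- i >= 1 & i <= nb
    K[i[ok], j] <- g[ok] / sum(g[ok])
  }
  v <- sino@values %*% K
  sinogram(v, anglesDeg = sino@anglesDeg, binMm = sino@binMm,
           variance = pmax(v, 1))
}

#' Detector image: emissivity weighted by detection probability
#'
#' Each pixel of the source is multiplied by the mean over acquisition angles
#' of its attenuation survival probability `exp(-integral of mu)` from the
#' pixel to the detector. The survival probability lies in [0, 1], so the
#' detector image never exceeds the source.
#'
#' @param source the source [ActivityImage-class].
#' @param mu an [AttenuationMap-class] on the same grid.
#' @param config an [AcquisitionConfig-class] (supplies the angles).
#' @param stepFrac ray sampling step fraction (default 0.5).
#' @return an [ActivityImage-class].
#' @export
makeDetectorImage <- function(source, mu, config, stepFrac = 0.5) {
  stopifnot(is(source, "ActivityImage"), is(mu, "AttenuationMap"))
  if (!all(dim(mu@mu) == dim(source@values)))
    stop("source and attenuation map must share one grid")
  p <- detection_probability_cpp(mu@mu, source@pixelMm,
                                 projectionAngles(config) * pi / 180, stepFrac)
  activityImage(source@values * p, pixelMm = source@pixelMm)
}

#' Angle-averaged detection probability map
#'
#' @inheritParams makeDetectorImage
#' @param pixelMm pixel pitch in mm.
#' @return numeric matrix of survival probabilities in [0, 1].
#' @export
detectionProbability <- function(mu, config, pixelMm = mu@pixelMm,
                                 stepFrac = 0.5) {
  detection_probability_cpp(mu@mu, pixelMm,
                            projectionAngles(config) * pi / 180, stepFrac)
}

#' Acquisition configuration matched to a phantom grid
#'
#' Convenience constructor deriving the detector bin count and pitch from the
#' phantom raster (one bin per pixel column).
#'
#' @param spec a [PhantomSpec-class].
#' @param ... passed to [acquisitionConfig()] (e.g. `nProjections`,
#'   `totalCounts`, `seed`, `detectorBlurSigmaMm`).
#' @return an [AcquisitionConfig-class].
#' @export
acquisitionConfigFor <- function(spec, ...) {
  acquisitionConfig(nBins = spec@gridN, binMm = spec@fovMm / spec@gridN, ...)
}

#' Build the standardized Source / Detector / Ideal / Realistic set
#'
#' Generates the four standardized reference images and the two reference
#' sinograms for a phantom and acquisition configuration:
#' \describe{
#'   \item{Source}{the rasterized emissivity (the "reality" being imaged).}
#'   \item{Detector}{source weighted by the angle-averaged attenuation
#'     survival probability.}
#'   \item{Ideal sinogram}{noise-free attenuated ideal-collimator projection —
#'     the infinite-statistics limit.}
#'   \item{Ideal image}{converged MLEM reconstruction of the ideal sinogram
#'     with the attenuation-aware system matrix; the recommended reference
#'     for evaluating reconstructions, differing from the Source only through
#'     the attenuation physics.}
#'   \item{Realistic sinogram}{ideal sinogram with detector blur (if
#'     configured) and Poisson counting noise at `config@totalCounts`.}
#'   \item{Realistic image}{the same reconstruction operator applied to the
#'     realistic sinogram.}
#' }
#'
#' @param spec a [PhantomSpec-class].
#' @param config an [AcquisitionConfig-class]; defaults to
#'   [acquisitionConfigFor()] of the spec.
#' @param settings [ReconSettings-class] for the reference reconstructions
#'   (default: MLEM, chi-square stationarity).
#' @param muWater water attenuation coefficient in 1/mm (default 0.0146).
#' @param stepFrac projector sampling step fraction (default 0.5).
#' @return a [StandardizedSet-class].
#' @export
makeStandardizedSet <- function(spec, config = acquisitionConfigFor(spec),
                                settings = reconSettings(),
                                muWater = 0.0146, stepFrac = 0.5) {
  src <- rasterize(spec)
  mu <- buildAttenuationMap(spec, muWater = muWater)
  det <- makeDetectorImage(src, mu, config, stepFrac)
  idealSino <- attenuatedProject(src, mu, config, stepFrac)
  P <- buildSystemMatrix(spec@gridN, config, mu, pixelMm = src@pixelMm,
                         stepFrac = stepFrac)
  idealRec <- mlem(idealSino, P, settings)
  realSino <- blurSinogram(idealSino, config@detectorBlurSigmaMm)
  realSino <- addCountingNoise(realSino, config@totalCounts, config@seed)
  realRec <- mlem(realSino, P, settings)
  new("StandardizedSet", source = src, detector = det,
      idealImage = idealRec@image, idealSinogram = idealSino,
      realisticImage = realRec@image, realisticSinogram = realSino,
      config = config)
}
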