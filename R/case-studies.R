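# Runnable benchmark recipes: the MLEM convergence study (Case A) and the
# multi-method benchmarking study on the high-background phantom (Case B).

metricsRow <- function(X, Y, variance = NULL, rois = NULL) {
  gm <- globalMetrics(X, Y, variance = variance,
                      signalMask = rois$hotspot, backgroundMask = rois$background)
  sc <- sci(X, Y)
  c(gm, list(sci = sc$sci, contrast = sc$contrast,
             structure = sc$structure, luminance = sc$luminance))
}

writeRunArtifacts <- function(outDir, report, images, sinograms) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "sinograms")) dir.create(file.path(outDir, d),
                                                 showWarnings = FALSE)
  for (nm in names(images))
    writeGridCSV(images[[nm]], file.path(outDir, "images", paste0(nm, ".csv")))
  for (nm in names(sinograms))
    writeSinogram(sinograms[[nm]], file.path(outDir, "sinograms",
                                             paste0(nm, ".csv")))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Case A: MLEM convergence study
#'
#' Generates the variant-1 phantom and its standardized set, reconstructs the
#' Poisson-noised ideal-collimator sinogram with MLEM checkpointed at the
#' requested iteration counts, and evaluates each checkpoint against the
#' Ideal references in both the image and the sinogram domain: global
#' metrics, SCI decomposition (with jackknife uncertainties), and intensity
#' histogram reduced chi-square.
#'
#' @param seed integer seed for the counting noise.
#' @param gridN phantom grid (default 256).
#' @param nProjections projection angles (default 128).
#' @param totalCounts expected detected counts (default 5e6).
#' @param checkpoints MLEM iteration checkpoints (default `c(3, 9, 24, 48)`).
#' @param maxIterations cap for the stationarity run (default 200).
#' @param nb intensity-histogram bins (default 256).
#' @param outDir optional directory; when given, images, sinograms and the
#'   JSON report are written there.
#' @param settings reconstruction settings for the reference and the study
#'   run (default MLEM with chi-square stationarity).
#' @return list with elements `set` (the [StandardizedSet-class]), `recon`
#'   (the checkpointed [ReconResult-class]), `imageMetrics` and
#'   `sinogramMetrics` (one row-list per checkpoint), `histChi2` (image- and
#'   sinogram-domain histogram reduced chi-square per checkpoint), `chi2AtCheckpoints`,
#'   and `config`.
#' @export
runCaseA <- function(seed = 1L, gridN = 256, nProjections = 128,
                     totalCounts = 5e6, checkpoints = c(3, 9, 24, 48),
                     maxIterations = 200, nb = 256L, outDir = NULL,
                     settings = reconSettings("mlem",
                                              maxIterations = maxIterations)) {
  spec <- sheppLoganPhantom(1, gridN = gridN)
  config <- acquisitionConfigFor(spec, nProjections = nProjections,
                                 totalCounts = totalCounts, seed = seed)
  set <- makeStandardizedSet(spec, config, settings = settings)
  mu <- buildAttenuationMap(spec)
  P <- buildSystemMatrix(spec@gridN, config, mu,
                         pixelMm = set@source@pixelMm)
  g <- set@realisticSinogram
  run <- mlem(g, P, settings, checkpoints = checkpoints)
  idealImg <- values(set@idealImage)
  idealSin <- set@idealSinogram
  cps <- reconCheckpoints(run)
  # checkpoints beyond the stationarity stop fall back to the final iterate
  for (cp in as.character(checkpoints))
    if (is.null(cps[[cp]])) cps[[cp]] <- reconImage(run)
  cps <- cps[as.character(sort(as.integer(names(cps))))]

  imageMetrics <- list(); sinogramMetrics <- list(); histChi2 <- list()
  rois <- defaultRois(gridN, spec@fovMm)
  for (cp in names(cps)) {
    X <- values(cps[[cp]])
    reproj <- forwardProject(P, X)
    imRow <- metricsRow(X, idealImg, rois = rois)
    imRow$sciSE <- jackknifeMetric(X, idealImg,
                                   function(a, b) sci(a, b)$sci,
                                   unit = "rowBlocks")$se
    snRow <- metricsRow(values(reproj), values(idealSin),
                        variance = sinogramVariance(g))
    snRow$sciSE <- jackknifeMetric(values(reproj), values(idealSin),
                                   function(a, b) sci(a, b)$sci,
                                   unit = "angles")$se
    edges <- sharedEdges(normalizeMean(X), normalizeMean(idealImg), nb)
    hIm <- histogramChi2Red(
      intensityHistogram(normalizeMean(X), nb, edges),
      intensityHistogram(normalizeMean(idealImg), nb, edges))
    edgesS <- sharedEdges(normalizeMean(values(reproj)),
                          normalizeMean(values(idealSin)), nb)
    hSn <- histogramChi2Red(
      intensityHistogram(normalizeMean(values(reproj)), nb, edgesS),
      intensityHistogram(normalizeMean(values(idealSin)), nb, edgesS))
    imageMetrics[[cp]] <- imRow
    sinogramMetrics[[cp]] <- snRow
    histChi2[[cp]] <- list(image = hIm, sinogram = hSn)
  }
  chi2cp <- chi2History(run)[pmin(as.integer(names(cps)), run@iterations)]
  names(chi2cp) <- names(cps)
  out <- list(set = set, recon = run, imageMetrics = imageMetrics,
              sinogramMetrics = sinogramMetrics, histChi2 = histChi2,
              chi2AtCheckpoints = chi2cp, config = config, rois = rois)
  if (!is.null(outDir)) {
    report <- list(seed = seed, gridN = gridN, nProjections = nProjections,
                   totalCounts = totalCounts,
                   imageMetrics = imageMetrics,
                   sinogramMetrics = sinogramMetrics, histChi2 = histChi2,
                   chi2History = chi2History(run))
    writeRunArtifacts(outDir, report,
                      images = c(list(source = set@source,
                                      detector = set@detector,
                                      ideal = set@idealImage), cps),
                      sinograms = list(ideal = idealSin, measured = g))
  }
  out
}

#' Case B: benchmarking reconstruction methods
#'
#' Uses the more demanding variant-2 phantom (four-fold background activity,
#' region ratio 20:5:10), reconstructs the same noisy sinogram with ART and
#' MLEM (plus any externally supplied reconstructions, treated as opaque
#' inputs), and evaluates every method globally and per RoI against the Ideal
#' Image.
#'
#' @param seed integer seed for the counting noise.
#' @param gridN phantom grid (default 256).
#' @param nProjections projection angles (default 128).
#' @param totalCounts expected detected counts (default 5e6).
#' @param extraRecons named list of [ActivityImage-class] (or matrices) from
#'   external methods to include in the comparison.
#' @param maxIterations iteration cap for both reconstructors.
#' @param outDir optional output directory.
#' @param variant phantom variant (default 2).
#' @return list with `set`, `recons` (named list of images), `metrics`
#'   (per-method [localizedMetrics()] reports), `sinogramChi2` (per-method
#'   reduced chi-square of the re-projected sinogram), `config`.
#' @export
runCaseB <- function(seed = 1L, gridN = 256, nProjections = 128,
                     totalCounts = 5e6, extraRecons = list(),
                     maxIterations = 200, outDir = NULL, variant = 2) {
  spec <- sheppLoganPhantom(variant, gridN = gridN)
  config <- acquisitionConfigFor(spec, nProjections = nProjections,
                                 totalCounts = totalCounts, seed = seed)
  set <- makeStandardizedSet(spec, config,
                             settings = reconSettings("mlem",
                                                      maxIterations = maxIterations))
  mu <- buildAttenuationMap(spec)
  P <- buildSystemMatrix(spec@gridN, config, mu, pixelMm = set@source@pixelMm)
  g <- set@realisticSinogram
  recons <- list(
    art = reconImage(art(g, P, reconSettings("art", maxIterations = maxIterations))),
    mlem = reconImage(mlem(g, P, reconSettings("mlem", maxIterations = maxIterations))))
  for (nm in names(extraRecons)) {
    x <- extraRecons[[nm]]
    m <- if (is(x, "ActivityImage")) x else activityImage(as.matrix(x),
                                                          set@source@pixelMm)
    if (!all(dim(values(m)) == gridN))
      stop("external reconstruction '", nm, "' does not match the ", gridN,
           "x", gridN, " grid")
    recons[[nm]] <- m
  }
  rois <- defaultRois(gridN, spec@fovMm)
  idealImg <- values(set@idealImage)
  metrics <- list(); sinoChi2 <- list()
  for (nm in names(recons)) {
    X <- values(recons[[nm]])
    rep <- localizedMetrics(X, idealImg, rois = rois)
    rep$global$cnr <- cnr(X, rois$hotspot, rois$background)
    rep$global$sci <- sci(X, idealImg)$sci
    metrics[[nm]] <- rep
    reproj <- forwardProject(P, X)
    sinoChi2[[nm]] <- reducedChi2(values(reproj), values(g),
                                  sinogramVariance(g))
  }
  out <- list(set = set, recons = recons, metrics = metrics,
              sinogramChi2 = sinoChi2, config = config, rois = rois)
  if (!is.null(outDir)) {
    report <- list(seed = seed, gridN = gridN, nProjections = nProjections,
                   variant = variant, metrics = metrics,
                   sinogramChi2 = sinoChi2)
    writeRunArtifacts(outDir, report,
                      images = c(list(source = set@source,
                                      ideal = set@idealImage), recons),
                      sinograms = list(ideal = set@idealSinogram, measured = g))
  }
  out
}
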