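# Modified Shepp-Logan phantom: geometry, rasterization, attenuation, RoIs.

# Pixel-center physical coordinates: origin at the image center, x to the
# right along columns, y upward along decreasing rows.
pixelCoords <- function(gridN, fovMm) {
  h <- fovMm / gridN
  ax <- (seq_len(gridN) - (gridN + 1) / 2) * h
  list(x = ax, y = rev(ax), h = h)
}

# Table of the nine emitting regions of the modified Shepp-Logan phantom.
# SRC0 is the water background ellipse (also the attenuating body); the
# cranial bone shell of the classical phantom is removed. Semi-axes are the
# "minor x" / "major y" axes before the counter-clockwise rotation angleDeg.
sheppLoganTable <- function(variant) {
  e <- data.frame(
    label = paste0("SRC", 0:8),
    xMm   = c(0, 24, -24, 0, 0, 0, -11, 0, 9),
    yMm   = c(0, 2, 2, 40, 13, -11, -64, -64, -64),
    aMm   = c(75, 12, 17, 23, 5, 5, 5, 2.5, 2.5),
    bMm   = c(100, 34, 45, 27, 5, 5, 2.5, 2.5, 5),
    angleDeg = c(0, -18, 18, 0, 0, 0, 0, 0, 0),
    surfaceAu = c(1200, 65, 122, 100, 4, 4, 2, 1, 2),
    activityKbq = c(6000, 325, 610, 1000, 40, 40, 20, 10, 20),
    stringsAsFactors = FALSE)
  if (variant == 2L) e$activityKbq[1] <- 24000
  e$specificActivity <- e$activityKbq / e$surfaceAu
  e[c("label", "xMm", "yMm", "aMm", "bMm", "angleDeg",
      "activityKbq", "surfaceAu", "specificActivity")]
}

#' Build the modified Shepp-Logan phantom specification
#'
#' Returns the nine-ellipse modified Shepp-Logan phantom: a large water
#' background ellipse SRC0 plus eight emitting structures SRC1-SRC8. Variant 1
#' has a moderate background specific activity of 5; variant 2 raises the
#' background activity four-fold (specific activity 20), giving the
#' region ratio background : side ellipses : central ellipse and hotspots of
#' 20 : 5 : 10 — a deliberately low-contrast, more demanding scenario.
#' SRC1-SRC8 are identical across variants.
#'
#' @param variant 1 or 2.
#' @param gridN raster grid size (default 256).
#' @param fovMm field-of-view width in mm (default 256, so the pixel pitch is
#'   1 mm at the default grid).
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- sheppLoganPhantom(1)
#' img <- rasterize(spec)
#' @export
sheppLoganPhantom <- function(variant = 1, gridN = 256, fovMm = 256) {
  variant <- as.integer(variant)
  if (!variant %in% c(1L, 2L))
    stop("unknown phantom variant: ", variant, " (must be 1 or 2)")
  new("PhantomSpec", ellipses = sheppLoganTable(variant), variant = variant,
      fovMm = as.numeric(fovMm), gridN = as.integer(gridN))
}

#' Build a custom phantom specification
#'
#' @param ellipses `data.frame` with the columns documented in
#'   [PhantomSpec-class]; listed order matters (later ellipses override
#'   earlier ones where they overlap).
#' @param variant background variant tag (1 or 2, informational for custom
#'   phantoms).
#' @param gridN,fovMm raster geometry.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(ellipses, variant = 1, gridN = 256, fovMm = 256) {
  new("PhantomSpec", ellipses = ellipses, variant = as.integer(variant),
      fovMm = as.numeric(fovMm), gridN = as.integer(gridN))
}

# TRUE for pixel centers inside the (rotated) ellipse.
insideEllipse <- function(X, Y, x0, y0, a, b, angleDeg) {
  th <- angleDeg * pi / 180
  dx <- X - x0; dy <- Y - y0
  u <-  cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

#' @describeIn rasterize Rasterize a phantom: each pixel takes the specific
#'   activity of the *last* listed ellipse whose interior contains the pixel
#'   center (override semantics), and 0 outside all ellipses.
#' @export
setMethod("rasterize", "PhantomSpec", function(spec, ...) {
  n <- spec@gridN
  co <- pixelCoords(n, spec@fovMm)
  X <- matrix(co$x, n, n, byrow = TRUE)
  Y <- matrix(co$y, n, n)
  img <- matrix(0, n, n)
  e <- spec@ellipses
  for (k in seq_len(nrow(e))) {
    inside <- insideEllipse(X, Y, e$xMm[k], e$yMm[k], e$aMm[k], e$bMm[k],
                            e$angleDeg[k])
    img[inside] <- e$specificActivity[k]
  }
  activityImage(img, pixelMm = co$h)
})

#' Build the phantom attenuation map
#'
#' Uniform water attenuation inside the outer body ellipse (the first listed
#' ellipse, SRC0 for the built-in phantom), zero outside. The modified
#' phantom has no bone shell, so the body is homogeneous.
#'
#' @param spec a [PhantomSpec-class].
#' @param muWater linear attenuation coefficient of water in 1/mm
#'   (default 0.0146, water at roughly 159 keV).
#' @return an [AttenuationMap-class].
#' @export
buildAttenuationMap <- function(spec, muWater = 0.0146) {
  if (!is.numeric(muWater) || muWater < 0)
    stop("muWater must be a non-negative attenuation coefficient (1/mm)")
  n <- spec@gridN
  co <- pixelCoords(n, spec@fovMm)
  X <- matrix(co$x, n, n, byrow = TRUE)
  Y <- matrix(co$y, n, n)
  e <- spec@ellipses[1, ]
  mu <- matrix(0, n, n)
  if (nrow(spec@ellipses) > 0) {
    inside <- insideEllipse(X, Y, e$xMm, e$yMm, e$aMm, e$bMm, e$angleDeg)
    mu[inside] <- muWater
  }
  newAttenuationMap(mu, pixelMm = co$h)
}

# Rectangle (in mm, physical coordinates) to pixel mask.
rectMask <- function(gridN, fovMm, xlim, ylim) {
  co <- pixelCoords(gridN, fovMm)
  X <- matrix(co$x, gridN, gridN, byrow = TRUE)
  Y <- matrix(co$y, gridN, gridN)
  X >= xlim[1] & X <= xlim[2] & Y >= ylim[1] & Y <= ylim[2]
}

#' Default diagnostic regions of interest
#'
#' Three pairwise-disjoint rectangular masks probing distinct aspects of
#' reconstruction quality on the Shepp-Logan phantom: an edge region
#' straddling the upper boundary of the large central ellipse SRC3 (spatial
#' resolution / partial volume), a hotspot region enclosing the small-source
#' cluster SRC6-SRC8 (local intensity recovery), and a uniform background
#' patch inside SRC0 away from all sources (noise stability). The geometry is
#' fully configurable via `rects`.
#'
#' @param gridN image grid size (default 256).
#' @param fovMm field of view in mm (default 256).
#' @param rects named list of `list(xlim =, ylim =)` rectangles in mm for the
#'   `edge`, `hotspot` and `background` regions; defaults cover the regions
#'   described above.
#' @return list of three [RoIMask-class] objects named `edge`, `hotspot`,
#'   `background`.
#' @export
defaultRois <- function(gridN = 256, fovMm = 256,
                        rects = list(
                          edge = list(xlim = c(-15, 15), ylim = c(55, 79)),
                          hotspot = list(xlim = c(-20, 20), ylim = c(-72, -56)),
                          background = list(xlim = c(-25, 25), ylim = c(-45, -30)))) {
  masks <- lapply(names(rects), function(nm) {
    r <- rects[[nm]]
    m <- rectMask(gridN, fovMm, r$xlim, r$ylim)
    if (!any(m))
      stop("grid too small to place RoI '", nm, "'")
    roiMask(m, label = nm, kind = if (nm %in% c("edge", "hotspot", "background")) nm else "custom")
  })
  names(masks) <- names(rects)
  masks
}

#' Serialize / deserialize a phantom specification
#'
#' Plain-text JSON round-trip of a [PhantomSpec-class].
#'
#' @param spec a [PhantomSpec-class].
#' @param path file path.
#' @return `readPhantomSpec` returns a [PhantomSpec-class];
#'   `writePhantomSpec` returns `path` invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  jsonlite::write_json(
    list(variant = spec@variant, fovMm = spec@fovMm, gridN = spec@gridN,
         ellipses = spec@ellipses),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantomSpec(as.data.frame(x$ellipses), variant = x$variant,
              gridN = x$gridN, fovMm = x$fovMm)
}
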