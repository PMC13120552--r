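#' Rasterize a phantom specification
#'
#' @param spec a [PhantomSpec-class].
#' @param ... further arguments for methods.
#' @return an [ActivityImage-class].
#' @export
setGeneric("rasterize", function(spec, ...) standardGeneric("rasterize"))

#' Forward-project an image through a system matrix
#'
#' @param object a [SystemMatrix-class] (or plain matrix in internal use).
#' @param image an [ActivityImage-class] or numeric matrix.
#' @return a [Sinogram-class].
#' @export
setGeneric("forwardProject", function(object, image, ...) standardGeneric("forwardProject"))

#' Back-project (adjoint) a sinogram through a system matrix
#'
#' @param object a [SystemMatrix-class].
#' @param sinogram a [Sinogram-class] or numeric matrix.
#' @return a numeric matrix on the image grid.
#' @export
setGeneric("backProject", function(object, sinogram, ...) standardGeneric("backProject"))

#' Extract the pixel/bin values of an image or sinogram
#'
#' @param object an [ActivityImage-class], [Sinogram-class],
#'   [AttenuationMap-class] or [RoIMask-class].
#' @return the underlying numeric (or logical) matrix.
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' @rdname values
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
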