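## DWIStack construction and NIfTI input/output.

#' Construct a DWI stack
#'
#' @param data numeric array with the channel dimension last
#'   (spatial rank 1-3).
#' @param gtab a [GradientTable-class] with one entry per channel.
#' @param voxelSize voxel edge lengths in mm.
#' @return A [DWIStack-class].
#' @export
dwiStack <- function(data, gtab, voxelSize = c(2, 2, 2)) {
  if (is.null(dim(data))) stop("data must be an array (spatial..., M)")
  new("DWIStack", imageData = data, gradients = gtab,
      voxelSize = as.numeric(voxelSize))
}

#' @describeIn dwiStack the image array (spatial..., M).
#' @param stack a [DWIStack-class].
#' @export
dwiData <- function(stack) stack@imageData

#' @describeIn dwiStack the stack's [GradientTable-class].
#' @export
gradients <- function(stack) stack@gradients

#' @describeIn dwiStack spatial dimensions of the voxel grid.
#' @export
spatialDim <- function(stack) {
  dm <- dim(stack@imageData)
  dm[-length(dm)]
}

#' @describeIn dwiStack extract one channel volume.
#' @param m channel index.
#' @export
channelVolume <- function(stack, m) {
  dm <- dim(stack@imageData)
  d <- length(dm) - 1L
  idx <- c(rep(list(quote(expr = )), d), list(m))
  vol <- do.call(`[`, c(list(stack@imageData), idx, list(drop = FALSE)))
  array(vol, dim = dm[-length(dm)])
}

#' @describeIn dwiStack replace the image array, keeping gradients.
#' @param value replacement array of identical shape.
#' @export
setDwiData <- function(stack, value) {
  stopifnot(identical(dim(value), dim(stack@imageData)))
  stack@imageData <- value
  stack
}

setMethod("show", "DWIStack", function(object) {
  dm <- dim(object@imageData)
  M <- dm[length(dm)]
  cat(sprintf("DWIStack: %s voxels x %d channels (%d b0), voxel %s mm\n",
              paste(dm[-length(dm)], collapse = " x "), M,
              sum(object@gradients@b0),
              paste(object@voxelSize, collapse = " x ")))
})

#' Read a diffusion acquisition from NIfTI + bvec/bval
#'
#' @param niftiFile 4-D NIfTI image (x, y, z, channel).
#' @param bvecFile,bvalFile FSL-style gradient files.
#' @param b0Threshold see [gradientTable()].
#' @return A [DWIStack-class].
#' @export
readDWI <- function(niftiFile, bvecFile, bvalFile, b0Threshold = 50) {
  img <- RNifti::readNifti(niftiFile)
  gtab <- readGradientTable(bvecFile, bvalFile, b0Threshold = b0Threshold)
  vox <- RNifti::pixdim(img)
  dwiStack(array(as.numeric(img), dim = dim(img)), gtab,
           voxelSize = vox[seq_len(min(3L, length(vox)))])
}

#' Write a DWI stack as NIfTI + bvec/bval
#'
#' @param stack a [DWIStack-class].
#' @param niftiFile output NIfTI path; \code{bvecFile}/\code{bvalFile}
#'   default to the same stem with \code{.bvec}/\code{.bval}.
#' @param bvecFile,bvalFile optional gradient file paths.
#' @return Invisibly, the written paths.
#' @export
writeDWI <- function(stack, niftiFile, bvecFile = NULL, bvalFile = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", niftiFile)
  if (is.null(bvecFile)) bvecFile <- paste0(stem, ".bvec")
  if (is.null(bvalFile)) bvalFile <- paste0(stem, ".bval")
  img <- RNifti::asNifti(stack@imageData)
  RNifti::pixdim(img) <- c(stack@voxelSize,
                           rep(1, max(0, length(dim(stack@imageData)) -
                                           length(stack@voxelSize))))
  RNifti::writeNifti(img, niftiFile)
  writeGradientTable(stack@gradients, bvecFile, bvalFile)
  invisible(c(niftiFile, bvecFile, bvalFile))
}
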