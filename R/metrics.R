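## Quantitative evaluation: PSNR, SSIM, RMSE maps.

#' Peak signal-to-noise ratio
#'
#' \eqn{\mathrm{PSNR} = 10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})} in
#' dB, with MAX the maximal reference value inside the mask and MSE the
#' masked mean squared error pooled over everything passed in (a whole
#' 4-D stack pools over channels too). Identical inputs give
#' \code{Inf}.
#'
#' @param reference,test numeric arrays or [DWIStack-class]s of equal
#'   shape; \code{reference} supplies MAX.
#' @param mask optional logical array over voxels (recycled across
#'   channels of a stack).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, mask = NULL) {
  ref <- .stackArray(reference); tst <- .stackArray(test)
  if (!identical(dim(ref), dim(tst)))
    stop("reference and test must have identical shape")
  if (!is.null(mask)) {
    keep <- rep(as.logical(mask), length.out = length(ref))
    ref <- ref[keep]; tst <- tst[keep]
  }
  mse <- mean((ref - tst)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(ref)^2 / mse)
}

#' Per-voxel RMSE map over channels
#'
#' @param reference,test [DWIStack-class]s or arrays of equal shape
#'   with the channel dimension last.
#' @return Numeric array over the voxel grid: root mean square of the
#'   channel-wise differences.
#' @export
rmseMap <- function(reference, test) {
  ref <- .stackArray(reference); tst <- .stackArray(test)
  if (!identical(dim(ref), dim(tst)))
    stop("reference and test must have identical shape")
  dm <- dim(ref); M <- dm[length(dm)]
  D <- matrix((ref - tst)^2, ncol = M)
  array(sqrt(rowMeans(D)), dim = dm[-length(dm)])
}

.gaussianKernel <- function(sigma = 1.5, radius = 3L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian smoothing with periodic boundaries (reuses the
## framelet axis filter; a symmetric kernel makes conv == corr).
.gaussSmooth <- function(x, kernel, radius) {
  dm <- as.integer(dim(x))
  for (ax in seq_along(dm)) {
    if (dm[ax] == 1L) next
    x <- .axisFilter(x, dm, kernel, -radius, ax, 1L, FALSE)
  }
  x
}

#' Structural similarity index
#'
#' Mean local SSIM with Gaussian-weighted windows (sigma 1.5, 7 taps
#' per axis, periodic boundaries) and the standard constants
#' \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2} where \eqn{L} is the
#' dynamic range. With the default range taken from \code{reference},
#' pass an explicit \code{dataRange} for a symmetric score.
#'
#' @param reference,test numeric volumes of equal shape.
#' @param dataRange dynamic range L; default
#'   \code{max(reference) - min(reference)}.
#' @param sigma,radius Gaussian window parameters.
#' @return Mean SSIM in [-1, 1].
#' @export
ssim <- function(reference, test, dataRange = NULL, sigma = 1.5,
                 radius = 3L) {
  x <- .asVolume(.stackArray(reference)); y <- .asVolume(.stackArray(test))
  if (!identical(dim(x), dim(y)))
    stop("reference and test must have identical shape")
  if (is.null(dataRange)) dataRange <- max(x) - min(x)
  if (dataRange <= 0) dataRange <- 1
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  k <- .gaussianKernel(sigma, radius)
  mx <- .gaussSmooth(x, k, radius)
  my <- .gaussSmooth(y, k, radius)
  vx <- .gaussSmooth(x * x, k, radius) - mx^2
  vy <- .gaussSmooth(y * y, k, radius) - my^2
  cxy <- .gaussSmooth(x * y, k, radius) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Evaluate a denoised stack against a clean reference
#'
#' @param reference,test [DWIStack-class]s of equal shape.
#' @param mask optional logical voxel mask for the PSNR terms.
#' @param dataRange dynamic range for SSIM; default from the whole
#'   reference stack (equal for both inputs, making the score
#'   symmetric).
#' @return An [EvaluationReport-class].
#' @export
evaluateDenoising <- function(reference, test, mask = NULL,
                              dataRange = NULL) {
  ref <- .stackArray(reference); tst <- .stackArray(test)
  if (!identical(dim(ref), dim(tst)))
    stop("reference and test must have identical shape")
  dm <- dim(ref); M <- dm[length(dm)]
  if (is.null(dataRange)) dataRange <- max(ref) - min(ref)
  dms <- dm[-length(dm)]
  Rm <- matrix(ref, ncol = M); Tm <- matrix(tst, ncol = M)
  chP <- chS <- numeric(M)
  for (m in seq_len(M)) {
    rv <- array(Rm[, m], dms); tv <- array(Tm[, m], dms)
    chP[m] <- psnr(rv, tv, mask = mask)
    chS[m] <- ssim(rv, tv, dataRange = dataRange)
  }
  mk <- if (is.null(mask)) array(TRUE, dms) else array(as.logical(mask),
                                                       dms)
  new("EvaluationReport",
      meanPSNR = psnr(ref, tst, mask = mask), channelPSNR = chP,
      meanSSIM = mean(chS), channelSSIM = chS,
      rmseMap = rmseMap(ref, tst), mask = mk)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(paste0("EvaluationReport: PSNR %.2f dB (pooled; channel ",
                     "mean %.2f), SSIM %.4f\n"),
              object@meanPSNR, mean(object@channelPSNR),
              object@meanSSIM))
})
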