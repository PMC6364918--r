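## Angular grouping of DW channels: Watson-kernel weights over gradient
## directions, and the per-group regularization scales.

#' Construct a gradient table
#'
#' @param bvecs 3 x M matrix (or M x 3, transposed automatically) of
#'   gradient directions; unit vectors for diffusion-weighted channels,
#'   zero vectors allowed for b0 channels.
#' @param bvals numeric vector of M b-values (s/mm^2).
#' @param b0Threshold b-values below this are flagged as b0 channels
#'   (default 50 s/mm^2).
#' @return A [GradientTable-class].
#' @export
gradientTable <- function(bvecs, bvals, b0Threshold = 50) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must be 3 x M or M x 3")
  if (length(bvals) != ncol(bvecs))
    stop("bvals length must match the number of directions")
  new("GradientTable", bvecs = unname(bvecs), bvals = as.numeric(bvals),
      b0 = as.numeric(bvals) < b0Threshold)
}

#' @describeIn gradientTable 3 x M direction matrix.
#' @param gtab a [GradientTable-class].
#' @export
bvecs <- function(gtab) gtab@bvecs

#' @describeIn gradientTable b-values.
#' @export
bvals <- function(gtab) gtab@bvals

#' @describeIn gradientTable number of channels M.
#' @export
nChannels <- function(gtab) ncol(gtab@bvecs)

#' @describeIn gradientTable logical flags of b ~ 0 channels.
#' @export
isB0 <- function(gtab) gtab@b0

setMethod("show", "GradientTable", function(object) {
  cat(sprintf("GradientTable: %d channels (%d b0), b in [%g, %g] s/mm^2\n",
              ncol(object@bvecs), sum(object@b0),
              min(object@bvals), max(object@bvals)))
})

#' Read an FSL-style bvec/bval pair
#'
#' \code{bvec} files are whitespace-separated 3 x M tables (M x 3 is
#' tolerated and detected by shape); \code{bval} files hold M values.
#'
#' @param bvecFile,bvalFile file paths.
#' @inheritParams gradientTable
#' @return A [GradientTable-class].
#' @export
readGradientTable <- function(bvecFile, bvalFile, b0Threshold = 50) {
  v <- as.matrix(utils::read.table(bvecFile))
  b <- unlist(utils::read.table(bvalFile), use.names = FALSE)
  gradientTable(v, b, b0Threshold = b0Threshold)
}

#' Write an FSL-style bvec/bval pair
#'
#' @param gtab a [GradientTable-class].
#' @param bvecFile,bvalFile output paths.
#' @return Invisibly, the two paths.
#' @export
writeGradientTable <- function(gtab, bvecFile, bvalFile) {
  utils::write.table(format(gtab@bvecs, digits = 15), bvecFile,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  cat(paste(gtab@bvals, collapse = " "), "\n", file = bvalFile)
  invisible(c(bvecFile, bvalFile))
}

#' Watson-kernel angular group weights
#'
#' Builds one group per channel (G = M). The weight of channel m in
#' group g is \eqn{w_{g,m} = \exp(\kappa[(\nu_m^\top \nu_g)^2 - 1])}
#' when the angle between the directions (antipodally symmetric, via
#' the absolute dot product) is at most \eqn{\theta}, and 0 otherwise.
#' The kernel is the density of a Watson distribution with
#' concentration \eqn{\kappa}, so \eqn{w_{g,g} = 1} exactly and weights
#' decay with angular dissimilarity. b0 channels form singleton groups
#' and never enter diffusion-weighted groups.
#'
#' @param gtab a [GradientTable-class]; diffusion-weighted directions
#'   must be unit vectors (no silent renormalization).
#' @param kappa Watson concentration, >= 0. The default 2.5 halves the
#'   weight (exp(-kappa/4) ~ 0.54) at the 30 degree gate edge, so every
#'   admitted neighbor still contributes substantially to the pooled
#'   group energy.
#' @param theta angular cutoff in degrees, in (0, 90].
#' @return A [GroupWeights-class].
#' @export
watsonWeights <- function(gtab, kappa = 2.5, theta = 30) {
  stopifnot(is(gtab, "GradientTable"))
  if (kappa < 0) stop("kappa must be >= 0")
  if (theta <= 0 || theta > 90) stop("theta must be in (0, 90] degrees")
  v <- gtab@bvecs
  dw <- !gtab@b0
  nrm <- sqrt(colSums(v^2))
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("diffusion-weighted gradient directions must be unit vectors; ",
         "found norms deviating by more than 1e-6 (no renormalization ",
         "is applied)")
  M <- ncol(v)
  ct <- crossprod(v)                       # nu_m' nu_g
  w <- exp(kappa * (ct^2 - 1))
  w[abs(ct) < cos(theta * pi / 180)] <- 0
  ## b0 channels: singleton groups only
  w[!dw, ] <- 0
  w[, !dw] <- 0
  diag(w) <- 1
  w <- (w + t(w)) / 2                      # symmetrize exact ties
  groups <- lapply(seq_len(M), function(g) which(w[g, ] != 0))
  new("GroupWeights", weights = unname(w), kappa = kappa, theta = theta,
      groups = groups, scale = sqrt(rowSums(w^2)))
}

#' @describeIn watsonWeights the G x M weight matrix.
#' @param w a [GroupWeights-class].
#' @export
groupWeights <- function(w) w@weights

#' @describeIn watsonWeights member channel indices of each group.
#' @export
groupMembers <- function(w) w@groups

#' @describeIn watsonWeights per-group scales
#'   \eqn{s_g = (\sum_m w_{g,m}^2)^{1/2}}.
#' @export
groupScale <- function(w) w@scale

setMethod("show", "GroupWeights", function(object) {
  sizes <- lengths(object@groups)
  cat(sprintf(
    "GroupWeights: %d groups (kappa = %g, theta = %g deg), sizes %d-%d\n",
    length(sizes), object@kappa, object@theta, min(sizes), max(sizes)))
})

#' Per-group regularization parameter of one band
#'
#' \eqn{\lambda_{g,l,r} = \lambda \, s_g} for every high-pass band and
#' 0 for the low-pass band, which is therefore never thresholded.
#'
#' @param w a [GroupWeights-class].
#' @param lambda base penalty, > 0.
#' @param level band level l.
#' @param r band multi-index (integer vector); the all-zero index is
#'   the low-pass band.
#' @return Numeric vector of length G.
#' @export
groupLambda <- function(w, lambda, level, r) {
  stopifnot(lambda > 0)
  if (all(r == 0L)) rep(0, length(w@scale)) else lambda * w@scale
}
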