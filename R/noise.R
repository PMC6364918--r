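## Noncentral-chi noise: simulation, background noise-level estimation,
## and second-moment debiasing.

#' Construct a noncentral-chi noise model
#'
#' @param sigma per-channel Gaussian standard deviation, > 0 (signal
#'   units).
#' @param nCoils number of receiver coils N (default 32); the magnitude
#'   signal then has 2N Gaussian degrees of freedom.
#' @param seed integer seed for reproducible simulation.
#' @return An [NcChiModel-class].
#' @export
ncChiModel <- function(sigma, nCoils = 32L, seed = 1L) {
  new("NcChiModel", sigma = as.numeric(sigma), nCoils = as.integer(nCoils),
      seed = as.integer(seed))
}

setMethod("show", "NcChiModel", function(object) {
  cat(sprintf("NcChiModel: sigma = %g, %d coils (2N = %d dof), seed %d\n",
              object@sigma, object@nCoils, 2L * object@nCoils,
              object@seed))
})

.ncChiDraw <- function(eta, sigma, nCoils) {
  ## root-sum-of-squares magnitude: the true signal sits in one
  ## quadrature component, all 2N components carry iid N(0, sigma^2)
  n <- length(eta)
  m2 <- (eta + stats::rnorm(n, sd = sigma))^2
  for (j in seq_len(2L * nCoils - 1L))
    m2 <- m2 + stats::rnorm(n, sd = sigma)^2
  sqrt(m2)
}

#' Corrupt a clean stack with noncentral-chi noise
#'
#' Per voxel with true value \eqn{\eta} the noisy magnitude is
#' \eqn{M = \sqrt{(\eta + n_1)^2 + \sum_{j=2}^{2N} n_j^2}} with
#' \eqn{n_j \sim N(0, \sigma^2)} iid — the root-sum-of-squares
#' magnitude of an N-coil acquisition. Its second moment is
#' \eqn{E[M^2] = \eta^2 + 2N\sigma^2}, so low-signal regions sit on an
#' elevated noise floor.
#'
#' @param clean a [DWIStack-class] or nonnegative numeric array.
#' @param model an [NcChiModel-class].
#' @return Noisy object of the same class; bit-reproducible under the
#'   model's seed.
#' @export
addNcChiNoise <- function(clean, model) {
  stopifnot(is(model, "NcChiModel"))
  x <- if (is(clean, "DWIStack")) clean@imageData else clean
  if (any(x < 0)) stop("clean signal values must be nonnegative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(model@seed)
  noisy <- array(.ncChiDraw(as.numeric(x), model@sigma, model@nCoils),
                 dim = dim(x))
  if (is(clean, "DWIStack")) setDwiData(clean, noisy) else noisy
}

#' Estimate the noise level from signal-free background
#'
#' In background voxels the magnitude is central chi with 2N degrees of
#' freedom, so \eqn{E[M^2] = 2N\sigma^2} and
#' \eqn{\hat\sigma = \sqrt{\mathrm{mean}(M^2)/(2N)}}.
#'
#' @param noisy a [DWIStack-class] or numeric array of magnitudes.
#' @param backgroundMask logical array over voxels (recycled across
#'   channels for a stack) marking signal-free voxels.
#' @param nCoils number of coils N.
#' @param minVoxels minimum number of masked samples required.
#' @return \eqn{\hat\sigma}.
#' @seealso [backgroundMask()]
#' @export
estimateSigmaBackground <- function(noisy, backgroundMask, nCoils = 32L,
                                    minVoxels = 1000L) {
  x <- if (is(noisy, "DWIStack")) noisy@imageData else noisy
  if (is(noisy, "DWIStack")) {
    M <- dim(x)[length(dim(x))]
    vals <- x[rep(as.logical(backgroundMask), M)]
  } else {
    vals <- x[as.logical(backgroundMask)]
  }
  if (length(vals) < minVoxels)
    stop("background mask selects ", length(vals), " samples; at least ",
         minVoxels, " signal-free voxels are required for a stable ",
         "noise estimate")
  sqrt(mean(vals^2) / (2 * nCoils))
}

## Otsu's threshold on a 256-bin histogram: maximizes between-class
## variance of the foreground/background split.
.otsuThreshold <- function(x, nBins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nBins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nBins]
  bcv <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Derive a background mask from the b0 image
#'
#' Thresholds the mean b0 image (falling back to the channel-mean image
#' when the stack has no b0 channel) with Otsu's method, which
#' separates the elevated-but-low noncentral-chi noise floor of air
#' from tissue signal. A plain intensity fraction of the 99th
#' percentile is available via \code{method = "fraction"}, but note
#' that with many receiver coils the background floor
#' \eqn{\sigma\sqrt{2N}} routinely exceeds 10 percent of the tissue
#' signal, so the fractional rule can select nothing.
#'
#' @param stack a [DWIStack-class].
#' @param method \code{"otsu"} (default) or \code{"fraction"}.
#' @param frac intensity fraction of the 99th percentile used by
#'   \code{method = "fraction"}.
#' @return Logical array over the voxel grid.
#' @export
backgroundMask <- function(stack, method = c("otsu", "fraction"),
                           frac = 0.10) {
  stopifnot(is(stack, "DWIStack"))
  method <- match.arg(method)
  dm <- dim(stack@imageData)
  b0 <- isB0(stack@gradients)
  ch <- if (any(b0)) which(b0) else seq_len(dm[length(dm)])
  acc <- 0
  for (m in ch) acc <- acc + channelVolume(stack, m)
  ref <- acc / length(ch)
  thr <- if (method == "otsu") .otsuThreshold(as.numeric(ref))
         else frac * stats::quantile(ref, 0.99, names = FALSE)
  ref < thr
}

#' Remove the noncentral-chi signal bias
#'
#' Inverts the second-moment relation \eqn{E[M^2] = \eta^2 + 2N\sigma^2}
#' per voxel: \eqn{\hat\eta = \sqrt{\max(\hat u^2 - 2N\sigma^2, 0)}},
#' clamped at zero at the noise floor. Applied after denoising, where
#' \eqn{\hat u} approximates the expected magnitude.
#'
#' @param denoised a [DWIStack-class] or numeric array.
#' @param sigma noise level (>= 0); 0 is the identity.
#' @param nCoils number of coils N.
#' @return Debiased object of the same class.
#' @export
debiasNcChi <- function(denoised, sigma, nCoils = 32L) {
  stopifnot(sigma >= 0)
  x <- if (is(denoised, "DWIStack")) denoised@imageData else denoised
  out <- array(sqrt(pmax(as.numeric(x)^2 - 2 * nCoils * sigma^2, 0)),
               dim = dim(x))
  if (is(denoised, "DWIStack")) setDwiData(denoised, out) else out
}
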