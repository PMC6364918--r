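#' @useDynLib dwiframelet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' B-spline framelet filter bank
#'
#' A finitely supported low-pass refinement mask \eqn{a_0} together with
#' the \eqn{p} high-pass wavelet masks \eqn{a_1,\dots,a_p} of a B-spline
#' tight wavelet frame derived from the unitary extension principle
#' (UEP). The masks act as discrete differential operators of increasing
#' order, which is what gives framelet regularization its
#' edge-preserving, staircasing-free behavior.
#'
#' @slot order B-spline order \eqn{p}; the bank has \eqn{p + 1} masks.
#' @slot masks list of numeric tap vectors \eqn{a_0,\dots,a_p}.
#' @slot offsets integer vector; index of the first tap of each mask
#'   (e.g. -1 for a centered 3-tap mask).
#' @slot frame character tag: \code{"haar"}, \code{"linear"} or
#'   \code{"cubic"}.
#'
#' @seealso [bsplineMasks()], [verifyUEP()]
#' @export
setClass("FilterBank",
  representation(order = "integer", masks = "list",
                 offsets = "integer", frame = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@masks) != object@order + 1L)
      msg <- c(msg, "need order + 1 masks")
    if (length(object@offsets) != length(object@masks))
      msg <- c(msg, "one offset per mask required")
    s <- vapply(object@masks, sum, numeric(1))
    if (abs(s[1] - 1) > 1e-12)
      msg <- c(msg, "low-pass mask a0 must sum to 1")
    if (length(s) > 1 && any(abs(s[-1]) > 1e-12))
      msg <- c(msg, "high-pass masks must sum to 0")
    if (length(msg)) msg else TRUE
  })

#' Undecimated framelet coefficient pyramid
#'
#' The full set of subband coefficient volumes \eqn{W_{l,r}u} of an
#' L-level undecimated (quasi-affine) tensor-product framelet
#' decomposition. Band indices run over levels \eqn{l = 1..L} and
#' d-component multi-indices \eqn{r} over \eqn{\{0..p\}}; the all-zero
#' (pure low-pass) multi-index is cascaded at levels \eqn{l < L} and
#' stored only once, as the final band \eqn{(L, 0)}. Every band has the
#' spatial shape of the source volume.
#'
#' @slot bands list of numeric arrays, one per band, in the order given
#'   by [tensorBands()] level by level, low-pass band last.
#' @slot index integer matrix with columns \code{level} and
#'   \code{r1..rd} identifying each band.
#' @slot levels decomposition depth L.
#' @slot frame filter-bank tag used for the decomposition.
#' @slot order B-spline order p of that bank.
#' @slot spatialDim integer spatial dimensions of the source volume.
#'
#' @seealso [frameletDecompose()], [frameletReconstruct()]
#' @export
setClass("FrameletPyramid",
  representation(bands = "list", index = "matrix", levels = "integer",
                 frame = "character", order = "integer",
                 spatialDim = "integer"),
  validity = function(object) {
    p <- object@order
    d <- length(object@spatialDim)
    L <- object@levels
    expected <- L * ((p + 1L)^d - 1L) + 1L
    if (length(object@bands) != expected)
      return(sprintf("expected %d bands for L = %d, p = %d, d = %d",
                     expected, L, p, d))
    if (nrow(object@index) != length(object@bands))
      return("index rows must match number of bands")
    ok <- vapply(object@bands, function(b) {
      db <- dim(b)
      if (is.null(db)) db <- length(b)
      identical(as.integer(db), object@spatialDim)
    }, logical(1))
    if (!all(ok)) return("every band must have the source spatial shape")
    TRUE
  })

#' Diffusion gradient table
#'
#' Unit gradient directions and b-values of a diffusion acquisition.
#' Channels with \eqn{b} below \code{b0Threshold} are flagged as
#' non-diffusion-weighted (b0) channels; those are excluded from
#' angular grouping.
#'
#' @slot bvecs 3 x M numeric matrix of gradient directions; unit norm
#'   for diffusion-weighted channels.
#' @slot bvals numeric vector of M b-values (s/mm^2).
#' @slot b0 logical vector flagging b ~ 0 channels.
#'
#' @seealso [gradientTable()], [readGradientTable()], [watsonWeights()]
#' @export
setClass("GradientTable",
  representation(bvecs = "matrix", bvals = "numeric", b0 = "logical"),
  validity = function(object) {
    if (nrow(object@bvecs) != 3L) return("bvecs must be 3 x M")
    M <- ncol(object@bvecs)
    if (length(object@bvals) != M || length(object@b0) != M)
      return("bvals/b0 length must match number of directions")
    nrm <- sqrt(colSums(object@bvecs^2))
    dw <- !object@b0
    if (any(abs(nrm[dw] - 1) > 1e-6))
      return("diffusion-weighted directions must be unit vectors (1e-6)")
    TRUE
  })

#' Multi-channel diffusion-weighted image stack
#'
#' A voxel grid with one image channel per diffusion gradient
#' direction. The data array has rank d + 1 with the channel dimension
#' last; d may be 1, 2 or 3 (small 1-D stacks are handy for exhaustive
#' solver checks; acquisitions are 3-D).
#'
#' @slot imageData numeric array of dimension (spatial..., M).
#' @slot gradients the [GradientTable-class] of the M channels.
#' @slot voxelSize numeric voxel edge lengths in mm.
#'
#' @seealso [dwiStack()], [dwiDenoise()]
#' @export
setClass("DWIStack",
  representation(imageData = "array", gradients = "GradientTable",
                 voxelSize = "numeric"),
  validity = function(object) {
    dm <- dim(object@imageData)
    if (length(dm) < 2L || length(dm) > 4L)
      return("imageData must have rank 2..4 (spatial dims + channels)")
    if (dm[length(dm)] != ncol(object@gradients@bvecs))
      return("last data dimension must equal the number of channels")
    TRUE
  })

#' Watson angular group weights
#'
#' The G x M matrix of Watson-kernel weights
#' \eqn{w_{g,m} = \exp(\kappa[(\nu_m^\top\nu_g)^2 - 1])} gated at
#' angular cutoff \eqn{\theta}, with one group per channel (G = M).
#' Channels inside group g are denoised collaboratively; the per-group
#' scale \eqn{s_g = (\sum_m w_{g,m}^2)^{1/2}} multiplies the base
#' penalty to give the band penalties \eqn{\lambda_{g,l,r}}.
#'
#' @slot weights M x M numeric weight matrix, unit diagonal.
#' @slot kappa Watson concentration used.
#' @slot theta angular cutoff in degrees.
#' @slot groups list of integer member indices per group.
#' @slot scale numeric vector of group scales \eqn{s_g}.
#'
#' @seealso [watsonWeights()], [groupLambda()]
#' @export
setClass("GroupWeights",
  representation(weights = "matrix", kappa = "numeric", theta = "numeric",
                 groups = "list", scale = "numeric"),
  validity = function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weight matrix must be square (G = M)")
    if (any(abs(diag(w) - 1) > 0)) return("diagonal weights must be exactly 1")
    if (any(w < 0) || any(w > 1)) return("weights must lie in [0, 1]")
    if (max(abs(w - t(w))) > 1e-12) return("weight matrix must be symmetric")
    if (object@kappa < 0) return("kappa must be >= 0")
    if (object@theta <= 0 || object@theta > 90)
      return("theta must be in (0, 90] degrees")
    TRUE
  })

#' Penalty-decomposition solver configuration
#'
#' Parameters of the penalty-decomposition (PD) scheme that minimizes
#' the group l0 (or l1) framelet objective: the quadratic coupling
#' weight mu grows geometrically (\code{mu0}, \code{delta}) while block
#' coordinate descent (BCD) alternates group thresholding of the frame
#' coefficients with a pointwise data update.
#'
#' @slot lambda base regularization strength.
#' @slot penalty \code{"l0"} (group hard threshold) or \code{"l1"}
#'   (group soft threshold).
#' @slot mu0 initial penalty factor, > 0.
#' @slot delta multiplicative mu growth factor, > 1.
#' @slot epsBCD relative-change stopping tolerance of the inner BCD loop.
#' @slot epsPD relative-change stopping tolerance of the outer PD loop.
#' @slot upsilon safeguard bound on the penalized objective; \code{NA}
#'   means "use the objective of the starting point".
#' @slot maxBCD,maxPD iteration caps.
#' @slot seed reserved; the solver itself is deterministic.
#'
#' @seealso [pdConfig()], [penaltyDecomposition()]
#' @export
setClass("PDConfig",
  representation(lambda = "numeric", penalty = "character", mu0 = "numeric",
                 delta = "numeric", epsBCD = "numeric", epsPD = "numeric",
                 upsilon = "numeric", maxBCD = "integer", maxPD = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@lambda < 0) return("lambda must be >= 0")
    if (!object@penalty %in% c("l0", "l1"))
      return("penalty must be 'l0' or 'l1'")
    if (object@mu0 <= 0) return("mu0 must be > 0")
    if (object@delta <= 1) return("delta must be > 1")
    if (object@epsBCD <= 0 || object@epsPD <= 0)
      return("tolerances must be > 0")
    if (object@maxBCD < 1 || object@maxPD < 1)
      return("iteration caps must be >= 1")
    TRUE
  })

#' Penalty-decomposition fit
#'
#' Result of [penaltyDecomposition()] / [dwiDenoise()]: the denoised
#' stack plus the solver trace needed to audit convergence (outer
#' iterations, mu schedule, objective values, and the per-sweep
#' augmented-objective values of every BCD run, which must be
#' non-increasing).
#'
#' @slot denoised the denoised [DWIStack-class].
#' @slot trace data.frame with one row per outer PD iteration:
#'   \code{k}, \code{mu}, \code{Phi}, \code{bcdIters}, \code{relChange},
#'   \code{safeguarded}.
#' @slot bcdTrace list of numeric vectors; L_mu after each BCD sweep.
#' @slot config the [PDConfig-class] used.
#' @slot weights the [GroupWeights-class] used.
#'
#' @export
setClass("PDFit",
  representation(denoised = "DWIStack", trace = "data.frame",
                 bcdTrace = "list", config = "PDConfig",
                 weights = "GroupWeights"))

#' Noncentral-chi noise model
#'
#' Magnitude images reconstructed from an N-coil acquisition by
#' root-sum-of-squares follow a noncentral chi distribution with 2N
#' Gaussian degrees of freedom of standard deviation sigma. The model
#' carries the parameters needed both to simulate such noise and to
#' invert its signal bias.
#'
#' @slot sigma per-channel Gaussian standard deviation (signal units).
#' @slot nCoils number of receiver coils N (32 for the emulated
#'   acquisition).
#' @slot seed integer seed for reproducible simulation.
#'
#' @seealso [ncChiModel()], [addNcChiNoise()], [debiasNcChi()]
#' @export
setClass("NcChiModel",
  representation(sigma = "numeric", nCoils = "integer", seed = "integer"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@nCoils < 1) return("nCoils must be >= 1")
    TRUE
  })

#' Spiral phantom specification
#'
#' Geometry and signal parameters of the synthetic spiral
#' diffusion-weighted phantom. Defaults emulate a 64 x 64 x 16 voxel,
#' 2 mm isotropic, 48-direction, b = 2000 s/mm^2 acquisition with a
#' white-matter-like tensor along the spiral tangent. The spiral's
#' varying curvature probes denoising across bending severities.
#'
#' @slot dim integer grid shape (nx, ny, nz).
#' @slot voxelSize voxel edge lengths in mm.
#' @slot nDirections number of diffusion gradient directions.
#' @slot bValue diffusion weighting (s/mm^2).
#' @slot eta baseline (non-diffusion-weighted) tissue signal.
#' @slot turns number of spiral turns.
#' @slot r0,rGrowth Archimedean spiral start radius and radius growth
#'   per turn (voxels).
#' @slot tubeRadius fiber tube radius (voxels).
#' @slot eigenWM tensor eigenvalues of fiber tissue (mm^2/s), principal
#'   axis along the local tangent.
#' @slot dIso isotropic background diffusivity (mm^2/s).
#' @slot seed seed for gradient-table generation.
#'
#' @seealso [spiralPhantomSpec()], [makeSpiralPhantom()]
#' @export
setClass("SpiralPhantomSpec",
  representation(dim = "integer", voxelSize = "numeric",
                 nDirections = "integer", bValue = "numeric",
                 eta = "numeric", turns = "numeric", r0 = "numeric",
                 rGrowth = "numeric", tubeRadius = "numeric",
                 eigenWM = "numeric", dIso = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@dim) != 3L || any(object@dim < 1L))
      return("dim must be 3 positive integers")
    if (object@bValue < 0) return("bValue must be >= 0")
    if (object@nDirections < 6L) return("need at least 6 directions")
    if (object@eta <= 0) return("eta must be > 0")
    if (length(object@eigenWM) != 3L) return("eigenWM must have length 3")
    TRUE
  })

#' Denoising evaluation report
#'
#' Per-channel and summary PSNR/SSIM plus the per-voxel RMSE map of a
#' denoised stack against its reference.
#'
#' @slot meanPSNR pooled-MSE PSNR over the whole stack (dB; \code{Inf}
#'   when the stacks are identical).
#' @slot channelPSNR per-channel PSNR (dB).
#' @slot meanSSIM mean per-channel SSIM.
#' @slot channelSSIM per-channel SSIM.
#' @slot rmseMap per-voxel root-mean-square error over channels.
#' @slot mask logical voxel mask used (may be all-TRUE).
#'
#' @seealso [evaluateDenoising()]
#' @export
setClass("EvaluationReport",
  representation(meanPSNR = "numeric", channelPSNR = "numeric",
                 meanSSIM = "numeric", channelSSIM = "numeric",
                 rmseMap = "array", mask = "array"))
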