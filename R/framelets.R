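## B-spline framelet filter banks (UEP) and the undecimated L-level
## tensor-product decomposition W / reconstruction W'.

.tabulatedMasks <- list(
  haar = list(
    masks = list(c(1, 1) / 2, c(1, -1) / 2),
    offsets = c(0L, 0L)),
  linear = list(
    masks = list(c(1, 2, 1) / 4, sqrt(2) / 4 * c(1, 0, -1),
                 c(-1, 2, -1) / 4),
    offsets = c(-1L, -1L, -1L)),
  cubic = list(
    masks = list(c(1, 4, 6, 4, 1) / 16, c(-1, -2, 0, 2, 1) / 8,
                 sqrt(6) / 16 * c(1, 0, -2, 0, 1), c(-1, 2, 0, -2, 1) / 8,
                 c(1, -4, 6, -4, 1) / 16),
    offsets = rep(-2L, 5)))

.frameForOrder <- c("1" = "haar", "2" = "linear", "4" = "cubic")

#' Construct a tabulated B-spline framelet filter bank
#'
#' Returns the refinement mask \eqn{a_0} and the \eqn{p} wavelet masks
#' \eqn{a_1,\dots,a_p} of the B-spline framelet system of order
#' \eqn{p}: Haar (\eqn{p = 1}), piecewise linear (\eqn{p = 2}) or
#' piecewise cubic (\eqn{p = 4}). The masks satisfy both UEP
#' identities, so the derived undecimated system is a tight (Parseval)
#' frame and reconstruction is exact.
#'
#' @param p B-spline order; one of 1, 2, 4. A frame name
#'   (\code{"haar"}, \code{"linear"}, \code{"cubic"}) is also accepted.
#' @return A [FilterBank-class].
#' @examples
#' bank <- bsplineMasks(2)
#' masks(bank)        # 1/4[1,2,1], sqrt(2)/4[1,0,-1], 1/4[-1,2,-1]
#' verifyUEP(bank)
#' @export
bsplineMasks <- function(p) {
  if (is.character(p)) {
    frame <- match.arg(p, names(.tabulatedMasks))
    p <- as.integer(names(.frameForOrder)[match(frame, .frameForOrder)])
  } else {
    if (!p %in% c(1, 2, 4))
      stop("unsupported B-spline order ", p,
           "; supported orders are 1 (haar), 2 (linear), 4 (cubic)")
    p <- as.integer(p)
    frame <- .frameForOrder[[as.character(p)]]
  }
  tab <- .tabulatedMasks[[frame]]
  new("FilterBank", order = p, masks = tab$masks, offsets = tab$offsets,
      frame = frame)
}

#' @describeIn bsplineMasks the mask tap vectors of a bank.
#' @param bank a [FilterBank-class].
#' @export
masks <- function(bank) bank@masks

#' @describeIn bsplineMasks support offsets (index of first tap).
#' @export
maskOffsets <- function(bank) bank@offsets

#' @describeIn bsplineMasks the B-spline order p.
#' @export
frameOrder <- function(bank) bank@order

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank '%s' (B-spline order p = %d, %d masks)\n",
              object@frame, object@order, length(object@masks)))
  for (r in seq_along(object@masks))
    cat(sprintf("  a%d: [%s] @ offset %d\n", r - 1L,
                paste(signif(object@masks[[r]], 6), collapse = ", "),
                object@offsets[r]))
})

## Fourier series of a mask: a_hat(xi) = sum_k a[k] exp(-i k xi)
.maskDFT <- function(taps, offset, xi) {
  k <- offset + seq_along(taps) - 1L
  drop(exp(-1i * outer(xi, k)) %*% taps)
}

#' Verify the unitary extension principle identities of a bank
#'
#' Evaluates, on a uniform frequency grid over \eqn{[-\pi, \pi]}, the
#' two UEP conditions: \eqn{\sum_r |\hat a_r(\xi)|^2 = 1} and
#' \eqn{\sum_r \hat a_r(\xi)\overline{\hat a_r(\xi + \pi)} = 0}. Both
#' must hold (to ~1e-12) for the derived quasi-affine system to be a
#' tight frame.
#'
#' @param bank a [FilterBank-class].
#' @param nFreq number of grid points (>= 2).
#' @return Named numeric vector: \code{partition} = max
#'   \eqn{|\sum_r |\hat a_r|^2 - 1|}, \code{shiftOrth} = max
#'   \eqn{|\sum_r \hat a_r(\xi)\overline{\hat a_r(\xi+\pi)}|}.
#' @export
verifyUEP <- function(bank, nFreq = 1025L) {
  stopifnot(is(bank, "FilterBank"), nFreq >= 2)
  xi <- seq(-pi, pi, length.out = nFreq)
  part <- numeric(nFreq)
  orth <- complex(nFreq)
  for (r in seq_along(bank@masks)) {
    a <- .maskDFT(bank@masks[[r]], bank@offsets[r], xi)
    ash <- .maskDFT(bank@masks[[r]], bank@offsets[r], xi + pi)
    part <- part + Mod(a)^2
    orth <- orth + a * Conj(ash)
  }
  c(partition = max(abs(part - 1)), shiftOrth = max(Mod(orth)))
}

#' Dilate a filter mask for a deeper decomposition level
#'
#' A-trous upsampling: at level \eqn{l} the taps are separated by
#' \eqn{2^{l-1} - 1} zeros (level 1 is the identity), so the
#' undecimated cascade probes coarser scales without downsampling.
#'
#' @param a numeric tap vector.
#' @param l level, >= 1.
#' @return The dilated tap vector.
#' @examples
#' dilateMask(c(1, -1) / 2, 2)       # 1/2 [1, 0, -1]
#' dilateMask(c(1, 2, 1) / 4, 3)     # 1/4 [1,0,0,0,2,0,0,0,1]
#' @export
dilateMask <- function(a, l) {
  stopifnot(l >= 1)
  s <- 2L^(l - 1L)
  if (s == 1L) return(a)
  out <- numeric((length(a) - 1L) * s + 1L)
  out[seq(1L, length(out), by = s)] <- a
  out
}

#' Enumerate the separable tensor-product bands of one level
#'
#' All \eqn{(p+1)^d} d-component multi-indices over \eqn{\{0..p\}}; the
#' all-zero multi-index is the pure low-pass channel used for
#' cascading to the next level.
#'
#' @param bank a [FilterBank-class].
#' @param d spatial dimensionality (1, 2 or 3).
#' @return Integer matrix with \eqn{(p+1)^d} rows and columns
#'   \code{r1..rd}; the first row is the all-zero low-pass index.
#' @export
tensorBands <- function(bank, d) {
  stopifnot(d %in% 1:3)
  p <- bank@order
  g <- do.call(expand.grid, rep(list(0:p), d))
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, paste0("r", seq_len(d)))
  m
}

.minExtent <- function(bank, L) {
  ## deepest dilated support of the longest mask
  len <- max(vapply(bank@masks, length, integer(1)))
  (len - 1L) * 2L^(L - 1L) + 1L
}

.asVolume <- function(x) {
  if (is.null(dim(x))) array(x, dim = length(x)) else x
}

## Apply one level of the analysis bank to the current low-pass volume:
## returns list of (p+1)^d band volumes in tensorBands order.
.analyzeLevel <- function(low, bank, level, bandIdx) {
  dm <- as.integer(dim(low))
  d <- length(dm)
  s <- 2L^(level - 1L)
  p <- bank@order
  ## separable tree: filter along axis 1, then 2, ... sharing prefixes
  cur <- list(low)
  for (ax in seq_len(d)) {
    nxt <- vector("list", length(cur) * (p + 1L))
    for (i in seq_along(cur)) {
      for (r in 0:p) {
        nxt[[(i - 1L) * (p + 1L) + r + 1L]] <-
          .axisFilter(cur[[i]], dm, bank@masks[[r + 1L]],
                      bank@offsets[r + 1L], ax, s, FALSE)
      }
    }
    cur <- nxt
  }
  ## cur is ordered with axis-d index fastest; tensorBands (expand.grid)
  ## has r1 fastest. Reorder.
  ord <- 1L + drop((bandIdx %*% (p + 1L)^((d - 1L):0)))
  cur[ord]
}

## Adjoint of .analyzeLevel: collapse (p+1)^d band volumes into one.
.synthesizeLevel <- function(bandsList, bank, level, bandIdx) {
  dm <- as.integer(dim(bandsList[[1L]]))
  d <- length(dm)
  s <- 2L^(level - 1L)
  p <- bank@order
  ord <- 1L + drop((bandIdx %*% (p + 1L)^((d - 1L):0)))
  cur <- vector("list", (p + 1L)^d)
  cur[ord] <- bandsList
  for (ax in d:1) {
    grp <- length(cur) / (p + 1L)
    nxt <- vector("list", grp)
    for (i in seq_len(grp)) {
      acc <- 0
      for (r in 0:p) {
        acc <- acc + .axisFilter(cur[[(i - 1L) * (p + 1L) + r + 1L]], dm,
                                 bank@masks[[r + 1L]],
                                 bank@offsets[r + 1L], ax, s, TRUE)
      }
      nxt[[i]] <- acc
    }
    cur <- nxt
  }
  cur[[1L]]
}

#' L-level undecimated framelet decomposition
#'
#' Computes every subband \eqn{W_{l,r}u}: at each level the dilated
#' separable filters of the bank are applied to the low-pass output of
#' the previous level (a-trous cascade), with periodic boundary
#' handling on every axis. No downsampling is performed, so all bands
#' share the input's shape and the transform is a Parseval frame:
#' [frameletReconstruct()] inverts it exactly.
#'
#' @param volume numeric array (1-D, 2-D or 3-D).
#' @param bank a [FilterBank-class].
#' @param L number of levels, >= 1.
#' @return A [FrameletPyramid-class].
#' @examples
#' f <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
#' pyr <- frameletDecompose(f, bsplineMasks(2), L = 2)
#' max(abs(frameletReconstruct(pyr) - f))   # ~1e-15
#' @export
frameletDecompose <- function(volume, bank, L = 2L) {
  stopifnot(is(bank, "FilterBank"), L >= 1)
  L <- as.integer(L)
  volume <- .asVolume(volume)
  dm <- as.integer(dim(volume))
  d <- length(dm)
  if (d > 3L) stop("volume must be 1-D, 2-D or 3-D")
  need <- .minExtent(bank, L)
  if (any(dm < need & dm > 1L))   # singleton axes are passed through
    stop(sprintf(paste0("volume extent %s too small for L = %d with the ",
                        "'%s' bank: every axis must be >= %d"),
                 paste(dm, collapse = "x"), L, bank@frame, need))
  bandIdx <- tensorBands(bank, d)
  isLow <- rowSums(bandIdx) == 0L
  bands <- list()
  index <- NULL
  low <- volume
  for (l in seq_len(L)) {
    lev <- .analyzeLevel(low, bank, l, bandIdx)
    low <- lev[[which(isLow)]]
    keep <- which(!isLow)
    bands <- c(bands, lev[keep])
    index <- rbind(index, cbind(level = l, bandIdx[keep, , drop = FALSE]))
  }
  bands <- c(bands, list(low))
  index <- rbind(index, cbind(level = L, bandIdx[isLow, , drop = FALSE]))
  storage.mode(index) <- "integer"
  new("FrameletPyramid", bands = bands, index = index, levels = L,
      frame = bank@frame, order = bank@order, spatialDim = dm)
}

#' Reconstruct a volume from its framelet pyramid
#'
#' Applies the adjoint \eqn{W^\top} of [frameletDecompose()]:
#' correlation with the same dilated cascade filters, summed over
#' bands. Because the bank satisfies the UEP, \eqn{W^\top W = I} and a
#' pyramid produced by decomposition returns the original volume to
#' machine precision.
#'
#' @param pyramid a [FrameletPyramid-class].
#' @param bank optional [FilterBank-class]; defaults to the bank the
#'   pyramid was built with, and must match it.
#' @return Numeric array with the pyramid's spatial shape.
#' @export
frameletReconstruct <- function(pyramid, bank = NULL) {
  stopifnot(is(pyramid, "FrameletPyramid"))
  if (is.null(bank)) bank <- bsplineMasks(pyramid@frame)
  if (!identical(bank@frame, pyramid@frame) ||
      !identical(bank@order, pyramid@order))
    stop("filter bank ('", bank@frame, "') does not match the bank the ",
         "pyramid was decomposed with ('", pyramid@frame, "')")
  .freconCore(pyramid@bands, bank, pyramid@levels,
              length(pyramid@spatialDim))
}

## Reconstruction core shared with the solver: bandsList in stored
## order (levels 1..L high-pass, low-pass last).
.freconCore <- function(bandsList, bank, L, d) {
  bandIdx <- tensorBands(bank, d)
  isLow <- rowSums(bandIdx) == 0L
  nHigh <- sum(!isLow)
  low <- bandsList[[length(bandsList)]]
  for (l in L:1) {
    lev <- vector("list", nrow(bandIdx))
    lev[[which(isLow)]] <- low
    off <- (l - 1L) * nHigh
    lev[which(!isLow)] <- bandsList[off + seq_len(nHigh)]
    low <- .synthesizeLevel(lev, bank, l, bandIdx)
  }
  low
}

#' @describeIn frameletReconstruct band volumes of a pyramid, in the
#'   stored order (levels 1..L high-pass, then the low-pass band).
#' @export
pyramidBands <- function(pyramid) pyramid@bands

#' @describeIn frameletReconstruct integer index matrix
#'   (\code{level}, \code{r1..rd}) identifying each band.
#' @export
bandIndex <- function(pyramid) pyramid@index

setMethod("show", "FrameletPyramid", function(object) {
  cat(sprintf(
    "FrameletPyramid: %d bands ('%s' bank, L = %d, %s volume)\n",
    length(object@bands), object@frame, object@levels,
    paste(object@spatialDim, collapse = " x ")))
})

#' Export pyramid bands as NIfTI volumes (debug aid)
#'
#' Writes each band as \code{<prefix>_l<level>_r<multi-index>.nii.gz}.
#'
#' @param pyramid a [FrameletPyramid-class] of a 3-D volume.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the written file paths.
#' @export
exportPyramid <- function(pyramid, dir, prefix = "band") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- pyramid@index
  paths <- character(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    tag <- paste0("l", idx[i, 1], "_r",
                  paste(idx[i, -1, drop = TRUE], collapse = ""))
    paths[i] <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, tag))
    RNifti::writeNifti(pyramid@bands[[i]], paths[i])
  }
  invisible(paths)
}
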