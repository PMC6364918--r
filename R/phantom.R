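## Synthetic spiral DWI phantom and electrostatic-repulsion gradient
## tables.

#' Generate a gradient table by electrostatic repulsion
#'
#' Distributes n unit vectors over the hemisphere by minimizing the
#' Coulomb energy \eqn{\sum_{i<j} 1/\|x_i - x_j\| + 1/\|x_i + x_j\|}
#' (antipodal mirror charges included, since a gradient direction and
#' its negation are equivalent) with L-BFGS-B from a seed-deterministic
#' random start. For n = 6 this recovers the icosahedral optimum.
#'
#' @param n number of directions, >= 6.
#' @param bValue b-value assigned to every direction (s/mm^2).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param nB0 number of leading b = 0 channels to prepend (default 0).
#' @return A [GradientTable-class].
#' @export
makeGradientTable <- function(n, bValue = 2000, seed = 1L, nB0 = 0L) {
  stopifnot(n >= 6)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x0 <- matrix(stats::rnorm(3 * n), nrow = 3)
  x0 <- x0 / rep(sqrt(colSums(x0^2)), each = 3)

  energyGrad <- function(par) {
    x <- matrix(par, nrow = 3)
    nrm <- sqrt(colSums(x^2))
    u <- x / rep(nrm, each = 3)
    E <- 0
    G <- matrix(0, 3, n)                  # gradient wrt unit vectors
    for (i in seq_len(n - 1L)) {
      ui <- u[, i]
      uj <- u[, (i + 1L):n, drop = FALSE]
      dmin <- ui - uj
      dplus <- ui + uj
      rm2 <- colSums(dmin^2); rp2 <- colSums(dplus^2)
      rm <- sqrt(pmax(rm2, 1e-12)); rp <- sqrt(pmax(rp2, 1e-12))
      E <- E + sum(1 / rm + 1 / rp)
      gm <- -dmin / rep(rm^3, each = 3)   # d(1/rm)/d ui
      gp <- -dplus / rep(rp^3, each = 3)
      G[, i] <- G[, i] + rowSums(gm + gp)
      G[, (i + 1L):n] <- G[, (i + 1L):n] - gm + gp
    }
    ## chain rule through normalization x -> x/|x|
    Gx <- matrix(0, 3, n)
    for (j in seq_len(n)) {
      P <- diag(3) - tcrossprod(u[, j])
      Gx[, j] <- (P %*% G[, j]) / nrm[j]
    }
    list(value = E, gradient = as.numeric(Gx))
  }
  fit <- stats::optim(as.numeric(x0),
                      fn = function(p) energyGrad(p)$value,
                      gr = function(p) energyGrad(p)$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  x <- matrix(fit$par, nrow = 3)
  x <- x / rep(sqrt(colSums(x^2)), each = 3)
  x[, x[3, ] < 0] <- -x[, x[3, ] < 0, drop = FALSE]   # hemisphere
  if (nB0 > 0L) {
    x <- cbind(matrix(0, 3, nB0), x)
    b <- c(rep(0, nB0), rep(bValue, n))
  } else b <- rep(bValue, n)
  gradientTable(x, b)
}

#' Minimal inter-direction angle of a table (degrees)
#'
#' Antipodally symmetric: the angle between directions m and g is
#' \eqn{\arccos|\nu_m^\top\nu_g|}.
#'
#' @param gtab a [GradientTable-class].
#' @return Smallest pairwise angle among diffusion-weighted directions.
#' @export
minPairwiseAngle <- function(gtab) {
  v <- gtab@bvecs[, !gtab@b0, drop = FALSE]
  ct <- abs(crossprod(v))
  diag(ct) <- 0
  acos(pmin(max(ct), 1)) * 180 / pi
}

#' Construct a spiral phantom specification
#'
#' @param dim grid shape, default \code{c(64, 64, 16)}.
#' @param voxelSize voxel edge lengths (mm), default 2 mm isotropic.
#' @param nDirections number of gradient directions, default 48.
#' @param bValue diffusion weighting, default 2000 s/mm^2.
#' @param eta baseline tissue signal, default 150.
#' @param turns,r0,rGrowth spiral turns, start radius and radius growth
#'   per turn, in voxels of the (x, y) plane.
#' @param tubeRadius fiber tube radius in voxels.
#' @param eigenWM fiber tensor eigenvalues (mm^2/s); principal axis
#'   follows the local spiral tangent.
#' @param dIso isotropic background diffusivity (mm^2/s).
#' @param seed seed for the gradient table.
#' @return A [SpiralPhantomSpec-class].
#' @export
spiralPhantomSpec <- function(dim = c(64, 64, 16), voxelSize = c(2, 2, 2),
                              nDirections = 48, bValue = 2000, eta = 150,
                              turns = 2.25, r0 = 4, rGrowth = 10,
                              tubeRadius = 2,
                              eigenWM = c(1.7, 0.3, 0.3) * 1e-3,
                              dIso = 0.8e-3, seed = 1L) {
  new("SpiralPhantomSpec", dim = as.integer(dim),
      voxelSize = as.numeric(voxelSize),
      nDirections = as.integer(nDirections), bValue = bValue, eta = eta,
      turns = turns, r0 = r0, rGrowth = rGrowth, tubeRadius = tubeRadius,
      eigenWM = eigenWM, dIso = dIso, seed = as.integer(seed))
}

setMethod("show", "SpiralPhantomSpec", function(object) {
  cat(sprintf(paste0("SpiralPhantomSpec: %s voxels, %d directions, ",
                     "b = %g s/mm^2, eta = %g\n"),
              paste(object@dim, collapse = " x "), object@nDirections,
              object@bValue, object@eta))
})

#' Generate the synthetic spiral diffusion phantom
#'
#' A tube of \code{tubeRadius} voxels follows a planar Archimedean
#' spiral at mid-slab; inside the tube the signal obeys the
#' single-tensor model \eqn{S(\nu) = \eta \exp(-b\,\nu^\top D \nu)}
#' with the principal tensor axis along the local spiral tangent, so
#' the attenuation of each channel depends on the gradient-to-tangent
#' angle and the fiber curvature varies along the spiral. The
#' surrounding tissue cylinder carries an isotropic signal
#' \eqn{\eta \exp(-b\,d_{iso})}; voxels outside it are signal-free air,
#' usable for background noise estimation.
#'
#' @param spec a [SpiralPhantomSpec-class].
#' @param gtab optional [GradientTable-class]; generated from the spec
#'   when omitted.
#' @return List with \code{stack} (clean [DWIStack-class]),
#'   \code{tangents} (nx x ny x nz x 3 array of true fiber directions,
#'   NA outside the tube), \code{tubeMask}, \code{tissueMask}.
#' @export
makeSpiralPhantom <- function(spec = spiralPhantomSpec(), gtab = NULL) {
  stopifnot(is(spec, "SpiralPhantomSpec"))
  if (is.null(gtab))
    gtab <- makeGradientTable(spec@nDirections, bValue = spec@bValue,
                              seed = spec@seed)
  dm <- spec@dim
  cx <- (dm[1] + 1) / 2; cy <- (dm[2] + 1) / 2; cz <- (dm[3] + 1) / 2
  maxR <- spec@r0 + spec@rGrowth * spec@turns
  if (maxR + spec@tubeRadius + 1 > min(dm[1], dm[2]) / 2)
    stop(sprintf(paste0("spiral exits the grid: final radius %.1f + tube ",
                        "radius %.1f exceeds half extent %.1f; reduce ",
                        "turns/rGrowth or enlarge the grid"),
                 maxR, spec@tubeRadius, min(dm[1], dm[2]) / 2))

  ## dense centerline samples
  tt <- seq(0, 2 * pi * spec@turns, length.out = max(200L,
            ceiling(64 * spec@turns)))
  rr <- spec@r0 + spec@rGrowth * tt / (2 * pi)
  px <- cx + rr * cos(tt)
  py <- cy + rr * sin(tt)
  ## tangent of (r(t) cos t, r(t) sin t)
  dr <- spec@rGrowth / (2 * pi)
  tx <- dr * cos(tt) - rr * sin(tt)
  ty <- dr * sin(tt) + rr * cos(tt)
  tn <- sqrt(tx^2 + ty^2)
  tx <- tx / tn; ty <- ty / tn

  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  M <- nChannels(gtab)
  v <- bvecs(gtab); b <- bvals(gtab)
  ## nearest centerline sample per in-plane voxel
  gx <- rep(seq_len(nx), times = ny)
  gy <- rep(seq_len(ny), each = nx)
  d2 <- matrix(Inf, nx * ny, 1)
  nearest <- integer(nx * ny)
  ## coarse pass over centerline samples (vectorized per sample)
  dist2 <- outer(gx, px, function(a, b) (a - b)^2) +
           outer(gy, py, function(a, b) (a - b)^2)
  nearest <- max.col(-dist2, ties.method = "first")
  d2 <- dist2[cbind(seq_len(nx * ny), nearest)]

  zIdx <- seq_len(nz)
  tubeR2 <- spec@tubeRadius^2
  tube <- array(FALSE, dm)
  tangents <- array(NA_real_, c(dm, 3))
  signal <- array(0, c(dm, M))
  ## attenuation of the isotropic compartment per channel
  attIso <- exp(-b * spec@dIso)
  ## tissue cylinder
  tisR <- min(nx, ny) / 2 - 2
  inTissue2d <- (gx - cx)^2 + (gy - cy)^2 <= tisR^2

  ew <- spec@eigenWM
  for (z in zIdx) {
    dz2 <- (z - cz)^2
    inTube2d <- d2 + dz2 <= tubeR2
    tube[, , z] <- matrix(inTube2d, nx, ny)
    for (m in seq_len(M)) {
      sl <- ifelse(inTissue2d, spec@eta * attIso[m], 0)
      if (any(inTube2d)) {
        id <- nearest[inTube2d]
        ## nu' D nu with D = (e1 - e2) T T' + e2 I (axially symmetric)
        dot <- v[1, m] * tx[id] + v[2, m] * ty[id]
        q <- (ew[1] - ew[2]) * dot^2 + ew[2]
        sl[inTube2d] <- spec@eta * exp(-b[m] * q)
      }
      signal[, , z, m] <- matrix(sl, nx, ny)
    }
    tgx <- rep(NA_real_, nx * ny); tgy <- tgx
    tgx[inTube2d] <- tx[nearest[inTube2d]]
    tgy[inTube2d] <- ty[nearest[inTube2d]]
    tangents[, , z, 1] <- matrix(tgx, nx, ny)
    tangents[, , z, 2] <- matrix(tgy, nx, ny)
    tangents[, , z, 3] <- ifelse(matrix(is.na(tgx), nx, ny), NA_real_, 0)
  }
  tissue <- array(rep(matrix(inTissue2d, nx, ny), nz), dm)
  list(stack = dwiStack(signal, gtab, voxelSize = spec@voxelSize),
       tangents = tangents, tubeMask = tube, tissueMask = tissue)
}
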