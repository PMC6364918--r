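## Independent brute-force oracles and shared fixtures. Everything here
## is deliberately written as direct summation / exhaustive enumeration,
## separate from the package's computational paths.

## Periodic convolution of a 1-D signal with a dilated mask, by direct
## summation: y[n] = sum_k a[k] x[(n - s*(off+k)) mod N].
directConv1D <- function(x, taps, offset, dilation = 1L) {
  N <- length(x)
  y <- numeric(N)
  for (n in seq_len(N)) {
    acc <- 0
    for (k in seq_along(taps)) {
      src <- (n - 1L - dilation * (offset + k - 1L)) %% N
      acc <- acc + taps[k] * x[src + 1L]
    }
    y[n] <- acc
  }
  y
}

## Direct cascade decomposition of a 1-D signal: band (l, r) is the
## level-l dilated filter r applied after l-1 low-pass stages.
bruteDecompose1D <- function(x, bank, L) {
  out <- list()
  idx <- NULL
  low <- x
  for (l in seq_len(L)) {
    for (r in seq_along(masks(bank)) - 1L) {
      if (r == 0L && l < L) next
      band <- directConv1D(low, masks(bank)[[r + 1L]],
                           maskOffsets(bank)[r + 1L], 2L^(l - 1L))
      if (r > 0L) {
        out <- c(out, list(band))
        idx <- rbind(idx, c(l, r))
      }
    }
    low <- directConv1D(low, masks(bank)[[1L]], maskOffsets(bank)[1L],
                        2L^(l - 1L))
    if (l == L) {
      out <- c(out, list(low))
      idx <- rbind(idx, c(l, 0L))
    }
  }
  list(bands = out, index = idx)
}

## Brute-force SSIM with the same convention as ssim(): Gaussian window
## (sigma 1.5, radius 3), periodic boundary, computed voxel by voxel.
bruteSSIM <- function(x, y, dataRange, sigma = 1.5, radius = 3L) {
  dm <- dim(x)
  k1 <- exp(-((-radius):radius)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  offs <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                                dz = -radius:radius))
  wts <- k1[offs[, 1] + radius + 1] * k1[offs[, 2] + radius + 1] *
         k1[offs[, 3] + radius + 1]
  total <- 0
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      xi <- (i - 1 + offs[, 1]) %% dm[1] + 1
      yi <- (j - 1 + offs[, 2]) %% dm[2] + 1
      zi <- (k - 1 + offs[, 3]) %% dm[3] + 1
      px <- x[cbind(xi, yi, zi)]; py <- y[cbind(xi, yi, zi)]
      mx <- sum(wts * px); my <- sum(wts * py)
      vx <- sum(wts * px^2) - mx^2; vy <- sum(wts * py^2) - my^2
      cxy <- sum(wts * px * py) - mx * my
      total <- total + ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  total / prod(dm)
}

## Brute-force group-penalized objective by per-voxel loops.
bruteObjective <- function(ua, fa, w, bank, L, lambda, penalty) {
  dm <- dim(ua); M <- dm[length(dm)]
  dms <- dm[-length(dm)]
  Um <- matrix(ua, ncol = M)
  pyr <- lapply(seq_len(M), function(m)
    frameletDecompose(array(Um[, m], dms), bank, L))
  idx <- bandIndex(pyr[[1]])
  W <- groupWeights(w)
  phi <- sum((ua - fa)^2)
  for (g in seq_len(nrow(W))) {
    lamG <- lambda * sqrt(sum(W[g, ]^2))
    for (b in seq_len(nrow(idx))) {
      if (all(idx[b, -1] == 0L)) next     # low-pass: unpenalized
      h <- 0
      for (m in which(W[g, ] != 0))
        h <- h + W[g, m]^2 * as.numeric(pyramidBands(pyr[[m]])[[b]])^2
      phi <- phi + if (penalty == "l0") lamG * sum(h > 0)
                   else lamG * sum(sqrt(h))
    }
  }
  phi
}

## Exhaustive v-subproblem oracle: per group/band/voxel pick the cheaper
## of {keep the whole weighted group vector, zero it} in the augmented
## objective; ties keep. Returns the same nested structure as
## thresholdUpdate().
bruteThreshold <- function(ua, w, bank, L, lambda, mu) {
  dm <- dim(ua); M <- dm[length(dm)]
  dms <- dm[-length(dm)]
  Um <- matrix(ua, ncol = M)
  pyr <- lapply(seq_len(M), function(m)
    frameletDecompose(array(Um[, m], dms), bank, L))
  idx <- bandIndex(pyr[[1]])
  W <- groupWeights(w)
  lapply(seq_len(nrow(W)), function(g) {
    members <- which(W[g, ] != 0)
    lamG <- lambda * sqrt(sum(W[g, ]^2))
    coef <- lapply(members, function(m) {
      lapply(seq_len(nrow(idx)), function(b)
        array(0, dim(pyramidBands(pyr[[m]])[[b]])))
    })
    nvox <- prod(dms)
    for (b in seq_len(nrow(idx))) {
      low <- all(idx[b, -1] == 0L)
      for (i in seq_len(nvox)) {
        h <- 0
        for (m in members)
          h <- h + (W[g, m] * as.numeric(pyramidBands(pyr[[m]])[[b]])[i])^2
        costKeep <- if (low) 0 else lamG * (h > 0)
        costKill <- (mu / 2) * h
        if (low || costKeep <= costKill) {
          for (j in seq_along(members)) {
            m <- members[j]
            coef[[j]][[b]][i] <-
              W[g, m] * as.numeric(pyramidBands(pyr[[m]])[[b]])[i]
          }
        }
      }
    }
    list(members = members, coef = coef)
  })
}

## Small random DWI stack with a hemispherical direction set.
randomStack <- function(spatial, M, seed, b = 2000) {
  set.seed(seed)
  v <- matrix(rnorm(3 * M), nrow = 3)
  v <- v / rep(sqrt(colSums(v^2)), each = 3)
  v[, v[3, ] < 0] <- -v[, v[3, ] < 0, drop = FALSE]
  gt <- gradientTable(v, rep(b, M))
  dwiStack(array(rnorm(prod(spatial) * M), c(spatial, M)), gt)
}

## Scaled-down spiral phantom used by the end-to-end checks.
smallPhantom <- function(nDirections = 24L) {
  makeSpiralPhantom(spiralPhantomSpec(
    dim = c(32, 32, 8), nDirections = nDirections, turns = 2, r0 = 2,
    rGrowth = 5, tubeRadius = 2, seed = 1))
}

## Shared cache so the expensive end-to-end runs are computed once and
## inspected by several test blocks.
.e2eCache <- new.env(parent = emptyenv())

endToEndRuns <- function() {
  if (!is.null(.e2eCache$runs)) return(.e2eCache$runs)
  ph <- smallPhantom()
  clean <- dwiData(ph$stack)
  sigma <- 5; nCoils <- 32L
  lambdaGrid <- c(0.5, 1, 2, 4)
  pipelinePsnr <- function(noisy, w, lambda) {
    cfg <- pdConfig(lambda = lambda, penalty = "l0")
    fit <- penaltyDecomposition(noisy, w, cfg)
    list(fit = fit,
         psnr = psnr(clean, debiasNcChi(dwiData(denoised(fit)), sigma,
                                        nCoils)))
  }
  noisy1 <- addNcChiNoise(ph$stack, ncChiModel(sigma, nCoils, seed = 1))
  wG <- watsonWeights(gradients(noisy1), kappa = 2.5, theta = 30)
  wU <- watsonWeights(gradients(noisy1), kappa = 2.5, theta = 0.1)
  ## per-mode lambda selection on the first seed (PSNR grid search)
  gridG <- lapply(lambdaGrid, function(l) pipelinePsnr(noisy1, wG, l))
  gridU <- lapply(lambdaGrid, function(l) pipelinePsnr(noisy1, wU, l))
  lamG <- lambdaGrid[which.max(vapply(gridG, `[[`, numeric(1), "psnr"))]
  lamU <- lambdaGrid[which.max(vapply(gridU, `[[`, numeric(1), "psnr"))]
  runs <- data.frame()
  fits <- list()
  for (seed in 1:5) {
    noisy <- if (seed == 1) noisy1 else
      addNcChiNoise(ph$stack, ncChiModel(sigma, nCoils, seed = seed))
    rg <- if (seed == 1) gridG[[match(lamG, lambdaGrid)]] else
      pipelinePsnr(noisy, wG, lamG)
    ru <- if (seed == 1) gridU[[match(lamU, lambdaGrid)]] else
      pipelinePsnr(noisy, wU, lamU)
    runs <- rbind(runs, data.frame(
      seed = seed, noisyPsnr = psnr(clean, dwiData(noisy)),
      grouped = rg$psnr, ungrouped = ru$psnr))
    fits[[seed]] <- rg$fit
  }
  .e2eCache$runs <- list(table = runs, fits = fits, lambdaGrouped = lamG,
                         lambdaUngrouped = lamU)
  .e2eCache$runs
}
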