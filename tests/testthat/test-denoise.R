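bank1 <- bsplineMasks(1)

test_that("objective: zero and constant inputs cost nothing", {
  st <- randomStack(c(12, 1, 1), 3, seed = 1)
  z <- setDwiData(st, array(0, dim(dwiData(st))))
  w <- watsonWeights(gradients(st), kappa = 2.5, theta = 40)
  expect_equal(frameletObjective(z, z, w, bank1, 1L, lambda = 4), 0)
  cst <- setDwiData(st, array(2.5, dim(dwiData(st))))
  expect_equal(frameletObjective(cst, cst, w, bank1, 1L, lambda = 4), 0,
               tolerance = 1e-20)
})

test_that("objective matches the brute-force per-voxel loop", {
  for (seed in 1:3) {
    u <- randomStack(c(12, 1, 1), 3, seed = seed)
    f <- setDwiData(u, dwiData(u) + 0.3)
    w <- watsonWeights(gradients(u), kappa = 2.5, theta = 50)
    for (pen in c("l0", "l1")) {
      expect_equal(
        frameletObjective(u, f, w, bank1, 1L, lambda = 2, penalty = pen),
        bruteObjective(dwiData(u), dwiData(f), w, bank1, 1L, 2, pen),
        tolerance = 1e-12)
    }
  }
})

test_that("threshold update equals exhaustive per-group minimization", {
  set.seed(99)
  for (rep in 1:20) {
    u <- randomStack(c(16, 1, 1), 2, seed = 100 + rep)
    w <- watsonWeights(gradients(u), kappa = 2.5, theta = 90)
    mu <- runif(1, 0.05, 5)
    lam <- runif(1, 0.1, 3)
    v <- thresholdUpdate(u, w, bank1, 1L, lambda = lam, mu = mu,
                         penalty = "l0")
    ref <- bruteThreshold(dwiData(u), w, bank1, 1L, lam, mu)
    for (g in seq_along(ref)) {
      expect_identical(v[[g]]$members, ref[[g]]$members)
      for (j in seq_along(ref[[g]]$coef))
        for (b in seq_along(ref[[g]]$coef[[j]]))
          expect_equal(as.numeric(v[[g]]$coef[[j]][[b]]),
                       as.numeric(ref[[g]]$coef[[j]][[b]]))
    }
  }
})

test_that("threshold limits: lambda = 0 and mu -> Inf keep everything", {
  u <- randomStack(c(16, 1, 1), 2, seed = 5)
  w <- watsonWeights(gradients(u), kappa = 2.5, theta = 90)
  ## lambda = 0 via mu enormous (threshold 2 lambda/mu -> 0)
  v <- thresholdUpdate(u, w, bank1, 1L, lambda = 1e-12, mu = 1e12,
                       penalty = "l0")
  W <- groupWeights(w)
  Um <- matrix(dwiData(u), ncol = 2)
  for (g in seq_along(v)) {
    for (j in seq_along(v[[g]]$members)) {
      m <- v[[g]]$members[j]
      pyr <- frameletDecompose(array(Um[, m], c(16, 1, 1)), bank1, 1L)
      for (b in seq_along(v[[g]]$coef[[j]]))
        expect_equal(as.numeric(v[[g]]$coef[[j]][[b]]),
                     W[g, m] * as.numeric(pyramidBands(pyr)[[b]]),
                     tolerance = 1e-12)
    }
  }
})

test_that("data update: fixed point, closed form, and normal equation", {
  u <- randomStack(c(16, 1, 1), 2, seed = 6)
  w <- watsonWeights(gradients(u), kappa = 2.5, theta = 90)
  ## v = w W f (no thresholding) makes f a fixed point
  v <- thresholdUpdate(u, w, bank1, 1L, lambda = 1e-12, mu = 1e12,
                       penalty = "l0")
  uNew <- dataUpdate(u, v, w, bank1, 1L, mu = 0.7)
  expect_equal(dwiData(uNew), dwiData(u), tolerance = 1e-10)

  ## v identically 0 with singleton groups: u = f / (1 + mu/2)
  wS <- watsonWeights(gradients(u), kappa = 2.5, theta = 0.1)
  vz <- thresholdUpdate(u, wS, bank1, 1L, lambda = 1e12, mu = 1e-12,
                        penalty = "l0")
  vz <- lapply(vz, function(grp) {
    grp$coef <- lapply(grp$coef, function(cf)
      lapply(cf, function(b) array(0, dim(b))))
    grp
  })
  uz <- dataUpdate(u, vz, wS, bank1, 1L, mu = 0.8)
  expect_equal(dwiData(uz), dwiData(u) / (1 + 0.4), tolerance = 1e-10)

  ## random v: plug the solution back into the normal equation
  set.seed(11)
  vr <- lapply(v, function(grp) {
    grp$coef <- lapply(grp$coef, function(cf)
      lapply(cf, function(b) array(rnorm(length(b)), dim(b))))
    grp
  })
  mu <- 1.3
  ur <- dataUpdate(u, vr, w, bank1, 1L, mu = mu)
  W <- groupWeights(w)
  Um <- matrix(dwiData(ur), ncol = 2)
  Fm <- matrix(dwiData(u), ncol = 2)
  for (m in 1:2) {
    rhs <- Fm[, m]
    for (g in seq_along(vr)) {
      j <- match(m, vr[[g]]$members)
      if (is.na(j)) next
      pyr <- frameletDecompose(array(0, c(16, 1, 1)), bank1, 1L)
      slot(pyr, "bands") <- vr[[g]]$coef[[j]]
      rhs <- rhs + (mu / 2) * W[g, m] *
        as.numeric(frameletReconstruct(pyr))
    }
    lhs <- (1 + (mu / 2) * sum(W[, m]^2)) * Um[, m]
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("BCD: monotone augmented objective and block stationarity", {
  u <- randomStack(c(16, 1, 1), 3, seed = 8)
  w <- watsonWeights(gradients(u), kappa = 2.5, theta = 60)
  for (pen in c("l0", "l1")) {
    res <- bcdSolve(u, w, bank1, 1L, lambda = 0.5, mu = 1.5,
                    penalty = pen, epsBCD = 1e-10, maxBCD = 40L)
    expect_true(all(diff(res$lmu) <= 1e-8 * pmax(abs(res$lmu[-1]), 1)))
    ## the limit u solves its data update given the final v
    uFix <- dataUpdate(dwiData(u), res$v, w, bank1, 1L, mu = 1.5)
    expect_equal(res$u, uFix, tolerance = 1e-6)
  }
  ## constant volumes are an immediate fixed point
  cst <- setDwiData(u, array(1.5, dim(dwiData(u))))
  res <- bcdSolve(cst, w, bank1, 1L, lambda = 0.01, mu = 1,
                  penalty = "l0")
  expect_equal(res$iters, 1L)
  expect_equal(res$u, dwiData(cst), tolerance = 1e-10)
})

test_that("penalty decomposition: sparse input passes through, both penalties, determinism", {
  st <- randomStack(c(16, 1, 1), 2, seed = 9)
  cst <- setDwiData(st, array(4, dim(dwiData(st))))
  w <- watsonWeights(gradients(st), kappa = 2.5, theta = 60)
  for (pen in c("l0", "l1")) {
    fit <- penaltyDecomposition(cst, w, pdConfig(lambda = 2,
                                                 penalty = pen))
    expect_equal(dwiData(denoised(fit)), dwiData(cst), tolerance = 1e-8)
  }
  ## lambda -> 0 reproduces the input for both penalties
  for (pen in c("l0", "l1")) {
    fit <- penaltyDecomposition(st, w, pdConfig(lambda = 1e-9,
                                                penalty = pen))
    expect_equal(dwiData(denoised(fit)), dwiData(st), tolerance = 1e-6)
  }
  ## bit-identical determinism
  f1 <- penaltyDecomposition(st, w, pdConfig(lambda = 1))
  f2 <- penaltyDecomposition(st, w, pdConfig(lambda = 1))
  expect_identical(dwiData(denoised(f1)), dwiData(denoised(f2)))
  expect_identical(solverTrace(f1), solverTrace(f2))
})

test_that("solver trace is recorded and guards against bad input", {
  st <- randomStack(c(16, 1, 1), 2, seed = 10)
  w <- watsonWeights(gradients(st), kappa = 2.5, theta = 60)
  fit <- penaltyDecomposition(st, w, pdConfig(lambda = 1, maxPD = 4L))
  tr <- solverTrace(fit)
  expect_equal(tr$mu, 0.1 * 2^(0:(nrow(tr) - 1L)))
  expect_true(all(is.finite(tr$Phi)))
  expect_equal(length(bcdObjectiveTrace(fit)), nrow(tr))
  bad <- setDwiData(st, array(Inf, dim(dwiData(st))))
  expect_error(penaltyDecomposition(bad, w, pdConfig()))
  expect_error(pdConfig(mu0 = -1))
  expect_error(pdConfig(delta = 1))
  expect_error(frameletObjective(st, randomStack(c(12, 1, 1), 2, 1), w,
                                 bank1, 1L), "equal shape")
})
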