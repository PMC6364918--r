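test_that("Watson weights: identity, gate, and kernel limits", {
  gt <- makeGradientTable(24, seed = 3)
  w <- watsonWeights(gt, kappa = 2.5, theta = 30)
  W <- groupWeights(w)
  expect_true(all(diag(W) == 1))                 # exact, not approximate
  ct <- abs(crossprod(bvecs(gt)))
  expect_true(all(W[ct < cos(30 * pi / 180)] == 0))
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(W, t(W))
  ## kappa = 0 inside the gate -> weight exactly 1
  w0 <- watsonWeights(gt, kappa = 0, theta = 30)
  W0 <- groupWeights(w0)
  inGate <- ct >= cos(30 * pi / 180)
  expect_true(all(W0[inGate] == 1))
  ## exact Watson value at a known angle
  v <- cbind(c(0, 0, 1), c(sin(pi / 9), 0, cos(pi / 9)))  # 20 deg apart
  w20 <- watsonWeights(gradientTable(v, c(2000, 2000)), kappa = 2.5,
                       theta = 30)
  expect_equal(groupWeights(w20)[1, 2], exp(2.5 * (cos(pi / 9)^2 - 1)))
})

test_that("increasing kappa never increases an off-diagonal weight", {
  for (seed in 1:5) {
    gt <- makeGradientTable(16, seed = seed)
    kappas <- c(0, 1, 2.5, 5, 10)
    prev <- NULL
    for (k in kappas) {
      W <- groupWeights(watsonWeights(gt, kappa = k, theta = 40))
      if (!is.null(prev)) expect_true(all(W <= prev + 1e-15))
      prev <- W
    }
  }
})

test_that("theta -> 0 reduces every group to its own channel", {
  gt <- makeGradientTable(48, seed = 1)
  w <- watsonWeights(gt, kappa = 2.5, theta = 0.1)
  expect_true(all(lengths(groupMembers(w)) == 1L))
  expect_equal(groupScale(w), rep(1, 48))
  ## at theta = 30 every group contains itself and is nonempty
  w30 <- watsonWeights(gt, kappa = 2.5, theta = 30)
  mem <- groupMembers(w30)
  expect_true(all(vapply(seq_along(mem), function(g) g %in% mem[[g]],
                         logical(1))))
})

test_that("b0 channels are isolated as singleton groups", {
  gt <- makeGradientTable(12, seed = 2, nB0 = 2L)
  w <- watsonWeights(gt, kappa = 2.5, theta = 30)
  W <- groupWeights(w)
  expect_equal(lengths(groupMembers(w))[1:2], c(1L, 1L),
               ignore_attr = TRUE)
  expect_true(all(W[1:2, -(1:2)] == 0))
  expect_equal(diag(W)[1:2], c(1, 1))
})

test_that("non-unit gradient directions are rejected, not renormalized", {
  v <- matrix(c(0, 0, 1, 0, 0, 2), nrow = 3)
  expect_error(new("GradientTable", bvecs = v, bvals = c(2000, 2000),
                   b0 = c(FALSE, FALSE)), "unit")
  gt2 <- makeGradientTable(8, seed = 1)
  scaled <- bvecs(gt2)
  scaled[, 3] <- 2 * scaled[, 3]
  slot(gt2, "bvecs", check = FALSE) <- scaled
  expect_error(watsonWeights(gt2), "unit vectors")
})

test_that("group lambda scales with the group l2 weight norm", {
  ## craft a group with weights {1, 1/2, 1/2}: two neighbors at 20 deg
  ## with kappa chosen so exp(kappa (cos^2 20deg - 1)) = 1/2
  a <- pi / 9
  kap <- log(2) / (1 - cos(a)^2)
  v <- cbind(c(sin(-a), 0, cos(-a)), c(0, 0, 1), c(sin(a), 0, cos(a)))
  gt <- gradientTable(v, rep(2000, 3))
  w <- watsonWeights(gt, kappa = kap, theta = 30)
  expect_equal(groupWeights(w)[2, ], c(0.5, 1, 0.5))
  lam <- groupLambda(w, lambda = 4, level = 1L, r = c(1L, 0L, 0L))
  expect_equal(lam[2], 4 * sqrt(1.5))
  ## low-pass band is never penalized
  expect_equal(groupLambda(w, 4, 2L, c(0L, 0L, 0L)), rep(0, 3))
  ## isolated direction -> lambda * 1
  wIso <- watsonWeights(makeGradientTable(8, seed = 5), kappa = 2.5,
                        theta = 0.1)
  expect_equal(groupLambda(wIso, 4, 1L, c(0L, 1L, 0L)), rep(4, 8))
})

test_that("bvec/bval files round-trip and tolerate transposed layout", {
  gt <- makeGradientTable(10, seed = 4, nB0 = 1L)
  bv <- tempfile(fileext = ".bvec"); bl <- tempfile(fileext = ".bval")
  writeGradientTable(gt, bv, bl)
  rt <- readGradientTable(bv, bl)
  expect_equal(bvecs(rt), bvecs(gt), tolerance = 1e-12)
  expect_equal(bvals(rt), bvals(gt))
  expect_equal(isB0(rt), isB0(gt))
  ## M x 3 layout is sniffed
  write.table(t(bvecs(gt)), bv, row.names = FALSE, col.names = FALSE)
  rt2 <- readGradientTable(bv, bl)
  expect_equal(bvecs(rt2), bvecs(gt), tolerance = 1e-12)
})
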