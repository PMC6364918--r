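test_that("tabulated B-spline masks match the published systems", {
  h <- bsplineMasks(1)
  expect_equal(masks(h), list(c(1, 1) / 2, c(1, -1) / 2))
  lin <- bsplineMasks(2)
  expect_equal(masks(lin)[[1]], c(1, 2, 1) / 4)
  expect_equal(masks(lin)[[2]], sqrt(2) / 4 * c(1, 0, -1))
  expect_equal(masks(lin)[[3]], c(-1, 2, -1) / 4)
  cub <- bsplineMasks(4)
  expect_equal(masks(cub)[[3]], sqrt(6) / 16 * c(1, 0, -2, 0, 1))
  expect_equal(masks(cub)[[5]], c(1, -4, 6, -4, 1) / 16)
  ## low-pass sums to 1, high-pass to 0
  for (p in c(1, 2, 4)) {
    s <- vapply(masks(bsplineMasks(p)), sum, numeric(1))
    expect_equal(s[1], 1)
    expect_true(all(abs(s[-1]) < 1e-15))
  }
  expect_error(bsplineMasks(3), "supported orders")
  expect_error(bsplineMasks(0), "supported orders")
})

test_that("UEP identities hold and a broken bank is detected", {
  for (p in c(1, 2, 4)) {
    dev <- verifyUEP(bsplineMasks(p), nFreq = 257L)
    expect_lt(dev[["partition"]], 1e-12)
    expect_lt(dev[["shiftOrth"]], 1e-12)
  }
  bad <- bsplineMasks(2)
  broken <- masks(bad)
  broken[[1]] <- 2 * broken[[1]]
  slot(bad, "masks", check = FALSE) <- broken
  expect_gte(verifyUEP(bad, 65L)[["partition"]], 1)
})

test_that("a-trous dilation inserts 2^(l-1) - 1 zeros between taps", {
  expect_identical(dilateMask(c(1, -1) / 2, 1), c(1, -1) / 2)
  expect_equal(dilateMask(c(1, -1) / 2, 2), c(1, 0, -1) / 2)
  expect_equal(dilateMask(c(1, 2, 1) / 4, 3),
               c(1, 0, 0, 0, 2, 0, 0, 0, 1) / 4)
})

test_that("decomposition matches the direct-summation cascade in 1-D", {
  set.seed(42)
  for (p in c(1, 2, 4)) {
    bank <- bsplineMasks(p)
    for (L in 1:2) {
      for (rep in 1:5) {
        n <- sample(17:32, 1)
        x <- rnorm(n)
        pyr <- frameletDecompose(x, bank, L)
        ref <- bruteDecompose1D(x, bank, L)
        expect_equal(length(pyramidBands(pyr)), length(ref$bands))
        for (b in seq_along(ref$bands))
          expect_equal(as.numeric(pyramidBands(pyr)[[b]]), ref$bands[[b]],
                       tolerance = 1e-12)
      }
    }
  }
})

test_that("an impulse reproduces the filter taps", {
  x <- numeric(16); x[8] <- 1
  bank <- bsplineMasks(1)
  pyr <- frameletDecompose(x, bank, 1L)
  ## convolution places tap a[k] at position n0 + k
  hp <- as.numeric(pyramidBands(pyr)[[1]])
  expect_equal(hp[8:9], c(1, -1) / 2)
  expect_true(all(hp[-(8:9)] == 0))
})

test_that("perfect reconstruction, Parseval, adjoint and linearity", {
  set.seed(7)
  for (p in c(1, 2, 4)) {
    bank <- bsplineMasks(p)
    L <- if (p == 4) 2L else 3L
    f <- array(rnorm(18 * 17 * 9), c(18, 17, 9))
    g <- array(rnorm(18 * 17 * 9), c(18, 17, 9))
    pf <- frameletDecompose(f, bank, L)
    expect_lt(max(abs(frameletReconstruct(pf) - f)), 1e-10)
    ## Parseval energy
    e <- sum(vapply(pyramidBands(pf), function(b) sum(b^2), numeric(1)))
    expect_equal(e, sum(f^2), tolerance = 1e-8)
    ## linearity
    pg <- frameletDecompose(g, bank, L)
    pl <- frameletDecompose(2 * f - 3 * g, bank, L)
    for (b in seq_along(pyramidBands(pl)))
      expect_equal(pyramidBands(pl)[[b]],
                   2 * pyramidBands(pf)[[b]] - 3 * pyramidBands(pg)[[b]],
                   tolerance = 1e-12)
    ## adjoint: <Wf, c> = <f, W'c> for random coefficients c
    cc <- lapply(pyramidBands(pf), function(b)
      array(rnorm(length(b)), dim(b)))
    lhs <- sum(mapply(function(a, b) sum(a * b), pyramidBands(pf), cc))
    pc <- pf; slot(pc, "bands") <- cc
    rhs <- sum(f * frameletReconstruct(pc))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("constant volumes put all energy in the low-pass band", {
  f <- array(3.25, c(12, 12, 6))
  pyr <- frameletDecompose(f, bsplineMasks(2), 2L)
  bands <- pyramidBands(pyr)
  expect_equal(bands[[length(bands)]], f, tolerance = 1e-12)
  for (b in seq_len(length(bands) - 1L))
    expect_lt(max(abs(bands[[b]])), 1e-12)
})

test_that("band enumeration and pyramid sizes follow (p+1)^d", {
  expect_equal(nrow(tensorBands(bsplineMasks(1), 2)), 4L)
  expect_equal(nrow(tensorBands(bsplineMasks(2), 3)), 27L)
  f <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
  pyr <- frameletDecompose(f, bsplineMasks(4), 2L)
  expect_equal(length(pyramidBands(pyr)), 2L * 124L + 1L)
  idx <- bandIndex(pyr)
  expect_equal(sum(rowSums(idx[, -1, drop = FALSE]) == 0L), 1L)
})

test_that("volumes smaller than the deepest filter support are rejected", {
  f <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_error(frameletDecompose(f, bsplineMasks(4), 2L), ">= 9")
  expect_error(frameletDecompose(array(0, c(4, 4, 4)),
                                 bsplineMasks(2), 3L), ">= 9")
  ## reconstruction rejects a mismatched bank
  pyr <- frameletDecompose(array(rnorm(16^2 * 8), c(16, 16, 8)),
                           bsplineMasks(2), 1L)
  expect_error(frameletReconstruct(pyr, bsplineMasks(1)),
               "does not match")
})
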