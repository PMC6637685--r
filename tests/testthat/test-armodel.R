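test_that("shift set is the 8 canonical lag-2 offsets", {
  s <- buildShiftSet()
  expect_identical(nrow(s), 8L)
  expect_identical(unname(s[, "k"]), c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(unname(s[, "l"]), c(1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L))
  expect_false(any(s[, 1] == 0 & s[, 2] == 0))  # (0,0) excluded
  expect_identical(max(s), 2L)
})

test_that("design matrix vectorizes the valid region in shift order", {
  # 6x6 patch: valid region is 4x4 -> 16 observations
  img <- grayImage(matrix(runif(36), 6, 6))
  sys <- makeDesign(img)
  expect_identical(sys$nObs, 16L)
  expect_identical(dim(sys$regressors), c(16L, 9L))
  expect_true(all(sys$regressors[, 1] == 1))

  # constant image: every regressor column and the response are c
  cimg <- grayImage(matrix(0.7, 6, 6))
  csys <- makeDesign(cimg)
  expect_true(all(csys$response == 0.7))
  expect_true(all(csys$regressors[, -1] == 0.7))

  # column ramp y(i,j) = j: the (0,1) column is response - 1 at every
  # site, the (0,2) column response - 2, and row lags leave it unchanged
  ramp <- grayImage(matrix(rep(1:6, each = 5), 5, 6))
  rsys <- makeDesign(ramp)
  expect_identical(rsys$nObs, 12L)
  expect_identical(rsys$response - 1, unname(rsys$regressors[, "b_0_1"]))
  expect_identical(rsys$response - 2, unname(rsys$regressors[, "b_0_2"]))
  expect_identical(rsys$response, unname(rsys$regressors[, "b_1_0"]))
  # column-major scan order of the valid region
  expect_identical(rsys$response,
                   as.vector(pixels(ramp)[3:5, 3:6]))
})

test_that("tiny patches are rejected", {
  expect_error(makeDesign(grayImage(matrix(1:4 / 4, 2, 2))),
               "at least 3 x 3")
  # 3x4 gives 2 valid sites and 5x5 gives 9, both under the guard
  expect_error(makeDesign(grayImage(matrix(runif(12), 3, 4))),
               "fewer than 10")
  expect_error(makeDesign(grayImage(matrix(runif(25), 5, 5))),
               "fewer than 10")
})

test_that("interior_only keeps exactly the fully in-mask sites", {
  set.seed(5)
  g <- matrix(runif(100), 10, 10)
  mask <- matrix(TRUE, 10, 10); mask[1:4, 1:4] <- FALSE
  img <- grayImage(g, mask = mask)
  sys <- makeDesign(img, maskPolicy = "interior_only")
  s <- buildShiftSet()
  ref <- 0L
  for (i in 3:10) for (j in 3:10) {
    ok <- mask[i, j]
    for (r in seq_len(8)) ok <- ok && mask[i - s[r, 1], j - s[r, 2]]
    ref <- ref + ok
  }
  expect_identical(sys$nObs, ref)

  # an image translated into a larger zero canvas yields identical
  # coefficients under interior_only (valid-site sets coincide)
  f <- smallField(seed = 2, side = 40, burn = 8)
  P <- pixels(f)
  canvas <- matrix(0, 60, 60); canvas[11:50, 11:50] <- P
  cmask <- matrix(FALSE, 60, 60); cmask[11:50, 11:50] <- TRUE
  a <- fitImage(grayImage(P), maskPolicy = "interior_only")
  b <- fitImage(grayImage(canvas, mask = cmask),
                maskPolicy = "interior_only")
  expect_equal(a@b, b@b, tolerance = 1e-12)
  expect_equal(a@intercept, b@intercept, tolerance = 1e-12)
})

test_that("OLS fit matches the normal-equations oracle", {
  set.seed(99)
  maxrel <- 0
  for (i in 1:100) {
    n <- sample(30:80, 1)
    X <- cbind(1, matrix(rnorm(n * 8), n, 8))
    colnames(X) <- c("intercept", rownames(buildShiftSet()))
    y <- rnorm(n)
    fit <- fitOLS(list(response = y, regressors = X, nObs = n,
                       maskPolicy = "zero_fill"))
    beta <- solve(crossprod(X), crossprod(X, y))  # oracle
    rel <- max(abs(coef(fit) - drop(beta))) / max(abs(beta))
    maxrel <- max(maxrel, rel)
    expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
  }
  expect_lt(maxrel, 1e-8)
})

test_that("noiseless lag recursion is recovered exactly", {
  # build a field satisfying the recursion exactly: noise only on the
  # first two rows/columns, zero in the interior
  set.seed(3)
  b <- c(0.2, 0.05, 0.15, 0.1, 0, 0.05, 0, 0.02)
  icpt <- 0.3
  eps <- matrix(0, 40, 40)
  eps[1:2, ] <- rnorm(80, 0, 0.2)
  eps[, 1:2] <- rnorm(80, 0, 0.2)
  y <- finestruct:::.arFieldRecurse(eps, b, icpt, icpt / (1 - sum(b)))
  fit <- fitImage(grayImage(y))
  expect_equal(unname(fit@b), b, tolerance = 1e-6)
  expect_equal(fit@intercept, icpt, tolerance = 1e-6)
  expect_lt(fit@residVar, 1e-20)
})

test_that("random-image fit matches the oracle and residuals are orthogonal", {
  set.seed(21)
  img <- grayImage(matrix(runif(2500), 50, 50))
  sys <- makeDesign(img)
  fit <- fitOLS(sys)
  beta <- solve(crossprod(sys$regressors),
                crossprod(sys$regressors, sys$response))
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
  res <- sys$response - drop(sys$regressors %*% coef(fit))
  expect_lt(max(abs(crossprod(sys$regressors, res))) / sys$nObs, 1e-10)
  # residual variance uses n - 9 degrees of freedom
  expect_equal(fit@residVar, sum(res^2) / (sys$nObs - 9))
})

test_that("degenerate designs raise a singular-fit error naming columns", {
  cimg <- grayImage(matrix(0.5, 8, 8))
  expect_error(fitImage(cimg), "singular fit.*b_")
  bad <- list(response = c(NaN, rnorm(19)),
              regressors = cbind(1, matrix(rnorm(20 * 8), 20, 8)),
              nObs = 20L, maskPolicy = "zero_fill")
  expect_error(fitOLS(bad), "non-finite")
})

test_that("fits are deterministic and scale-equivariant", {
  f <- smallField(seed = 13)
  a <- fitImage(f); b <- fitImage(f)
  expect_identical(coef(a), coef(b))       # bitwise determinism
  expect_identical(a@residVar, b@residVar)

  # multiplying intensities by c scales the intercept, not the lags
  c0 <- 3.7
  scaled <- grayImage(pixels(f) * c0)
  s <- fitImage(scaled)
  expect_equal(s@b, a@b, tolerance = 1e-8)
  expect_equal(s@intercept, a@intercept * c0, tolerance = 1e-8)
})

test_that("a large synthetic ROI fits in one pass with finite output", {
  f <- simulateArField(arFieldSpec(seed = 8, height = 1200, width = 1200,
                                   burnIn = 64))
  fit <- fitImage(f)
  expect_true(all(is.finite(coef(fit))))
  expect_identical(fit@nObs, 1198L * 1198L)
})
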