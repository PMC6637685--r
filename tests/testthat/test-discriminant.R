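test_that("group stacking pools columns in order", {
  g <- makeCoeffGroups(n1 = 16, n2 = 17, seed = 2)
  Bp <- stackGroups(g$B1, g$B2)
  expect_identical(ncol(coeffMatrix(Bp)), 33L)
  expect_identical(coeffMatrix(Bp)[, 1:16], coeffMatrix(g$B1))
  expect_identical(coeffMatrix(Bp)[, 17:33], coeffMatrix(g$B2))
  expect_identical(imageIds(Bp), c(imageIds(g$B1), imageIds(g$B2)))

  self <- stackGroups(g$B1, g$B1)
  expect_identical(ncol(coeffMatrix(self)), 32L)

  short <- groupCoeffMatrix(coeffMatrix(g$B1)[1:8, , drop = FALSE], "s")
  expect_error(stackGroups(g$B1, short), "dimensions differ")
  expect_error(groupCoeffMatrix(matrix(numeric(0), 9, 0), "empty"),
               "at least one image")
})

test_that("coefficient covariance matches definition oracles", {
  # identical columns: zero covariance
  B <- matrix(rep(rnorm(9), 5), 9, 5)
  expect_true(all(coeffCovariance(B) == 0))

  # two columns u, w: covariance is (u-w)(u-w)'/2 by hand expansion
  set.seed(4)
  u <- rnorm(9); w <- rnorm(9)
  expect_equal(coeffCovariance(cbind(u, w)),
               tcrossprod(u - w) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  # random 9x20: two-pass textbook estimator
  B <- matrix(rnorm(180), 9, 20)
  ctr <- B - rowMeans(B)
  expect_equal(coeffCovariance(B), tcrossprod(ctr) / 19,
               tolerance = 1e-12, ignore_attr = TRUE)
  S <- coeffCovariance(B)
  expect_identical(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))

  expect_error(coeffCovariance(matrix(1:9, 9, 1)), "at least 2")
})

test_that("the discriminant direction equals the closed-form Fisher solution", {
  for (seed in 1:5) {
    g <- makeCoeffGroups(n1 = 16, n2 = 17, gapScale = 2, seed = seed)
    fld <- solveFld(g$B1, g$B2)
    # oracle: pooled-within-covariance^{-1} times the mean difference
    N1 <- 16; N2 <- 17
    d <- rowMeans(coeffMatrix(g$B1)) - rowMeans(coeffMatrix(g$B2))
    W <- (N1 - 1) * coeffCovariance(g$B1) + (N2 - 1) * coeffCovariance(g$B2)
    vref <- solve(W, d)
    vref <- vref / sqrt(sum(vref^2))
    angle <- acos(min(1, abs(sum(projectionVector(fld) * vref))))
    expect_lt(angle, 1e-6)
    # rank-one structure: one dominant eigenvalue
    expect_lt(rankOneRatio(fld), 1e-6)
    # gamma1 agrees with a dense generalized-eigensolver oracle
    O1 <- coeffCovariance(g$B1); O2 <- coeffCovariance(g$B2)
    Op <- coeffCovariance(stackGroups(g$B1, g$B2))
    A <- (N1 + N2 - 1) * Op - (N1 - 1) * O1 - (N2 - 1) * O2
    M <- (N1 - 1) * O1 + (N2 - 1) * O2
    ev <- eigen(solve(M, A))$values
    expect_equal(fld@gamma1, max(Re(ev)), tolerance = 1e-8)
  }
})

test_that("identical groups give a vanishing top eigenvalue", {
  g <- makeCoeffGroups(seed = 7)
  fld <- solveFld(g$B1, g$B1)
  expect_lt(abs(fld@gamma1), 1e-8)
  # sign convention: group-1 mean projection is never below group 2
  fld2 <- solveFld(g$B1, g$B2)
  expect_gte(mean(zProjection(g$B1, fld2)),
             mean(zProjection(g$B2, fld2)))
})

test_that("singular within-covariance is reported as such", {
  # 3+3 observations in 9 dimensions cannot support a full-rank within
  g <- makeCoeffGroups(n1 = 3, n2 = 3, seed = 1)
  expect_error(solveFld(g$B1, g$B2), "singular")
  one <- groupCoeffMatrix(matrix(rnorm(9), 9, 1), "one")
  expect_error(solveFld(one, g$B2), "at least 2")
})

test_that("z-projection is the plain inner product", {
  g <- makeCoeffGroups(seed = 3)
  B <- coeffMatrix(g$B1)
  e1 <- c(1, rep(0, 8))
  expect_equal(unname(zProjection(g$B1, e1)), B[1, ], tolerance = 0)

  v <- rnorm(9)
  oracle <- vapply(seq_len(ncol(B)),
                   function(j) sum(B[, j] * v), numeric(1))
  expect_equal(unname(zProjection(g$B1, v)), oracle, tolerance = 1e-12)

  same <- groupCoeffMatrix(matrix(rep(rnorm(9), 4), 9, 4), "same")
  expect_true(all(abs(diff(zProjection(same, v))) < 1e-12))
  expect_error(zProjection(g$B1, rnorm(5)), "does not match")
})

test_that("no direction separates better than the solved one", {
  # equal group sizes so the within weighting is proportional to
  # s1^2 + s2^2, making the Rayleigh quotient the tested statistic
  g <- makeCoeffGroups(n1 = 16, n2 = 16, gapScale = 1.5, seed = 10)
  fld <- solveFld(g$B1, g$B2)
  sepstat <- function(v) {
    z1 <- zProjection(g$B1, v); z2 <- zProjection(g$B2, v)
    abs(mean(z1) - mean(z2)) / sqrt(var(z1) + var(z2))
  }
  best <- sepstat(projectionVector(fld))
  set.seed(20)
  for (i in 1:200) {
    p <- projectionVector(fld) + rnorm(9, sd = runif(1, 0.01, 2))
    expect_lte(sepstat(p / sqrt(sum(p^2))), best + 1e-12)
  }
})

test_that("separation is invariant under common affine maps of the coefficients", {
  g <- makeCoeffGroups(gapScale = 1, seed = 12)
  sep <- function(B1, B2) {
    fld <- solveFld(B1, B2)
    z1 <- zProjection(B1, fld); z2 <- zProjection(B2, fld)
    abs(mean(z1) - mean(z2)) / sqrt(var(z1) + var(z2))
  }
  set.seed(30)
  T <- matrix(rnorm(81), 9, 9) + diag(9)
  expect_gt(abs(det(T)), 1e-6)
  tB <- function(G, lab) groupCoeffMatrix(T %*% coeffMatrix(G), lab)
  expect_equal(sep(g$B1, g$B2), sep(tB(g$B1, "g1"), tB(g$B2, "g2")),
               tolerance = 1e-8)
})

test_that("negating the projection vector leaves discrimination unchanged", {
  g <- makeCoeffGroups(gapScale = 2, seed = 14)
  fld <- solveFld(g$B1, g$B2)
  v <- projectionVector(fld)
  r1 <- classifyCohort(zProjection(g$B1, v), zProjection(g$B2, v))
  r2 <- classifyCohort(zProjection(g$B1, -v), zProjection(g$B2, -v))
  expect_identical(ratePercent(r1), ratePercent(r2))
  expect_identical(perImage(r1)$correct, perImage(r2)$correct)
})

test_that("legacy between-side weighting is available but not default", {
  g <- makeCoeffGroups(gapScale = 2, seed = 16)
  fld <- solveFld(g$B1, g$B2, legacyBetween = TRUE)
  expect_identical(fld@weighting, "legacy")
  expect_identical(solveFld(g$B1, g$B2)@weighting, "corrected")
  # the legacy variant generally loses the rank-one structure
  expect_gt(rankOneRatio(fld), 1e-6)
})
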