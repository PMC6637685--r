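# Shared fixtures: all synthetic, generated in code at test time.

# Gaussian coefficient cloud: dim x n matrix with given mean and a fixed
# well-conditioned covariance factor.
rGaussGroup <- function(n, mean, chol_factor) {
  d <- length(mean)
  t(matrix(rnorm(n * d), n, d) %*% chol_factor + rep(mean, each = n))
}

randomCholFactor <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d, sd = scale), d, d)
  chol(crossprod(A) / d + diag(d) * 0.1 * scale^2)
}

# Two GroupCoeffMatrix objects with shared covariance and a mean gap.
makeCoeffGroups <- function(n1 = 16, n2 = 17, d = 9, gapScale = 1,
                            seed = 1) {
  set.seed(seed)
  U <- randomCholFactor(d)
  mu <- rnorm(d)
  delta <- rnorm(d)
  delta <- gapScale * delta / sqrt(sum(delta^2))
  list(B1 = groupCoeffMatrix(rGaussGroup(n1, mu + delta / 2, U), "group1"),
       B2 = groupCoeffMatrix(rGaussGroup(n2, mu - delta / 2, U), "group2"),
       U = U, delta = delta)
}

# A small AR field that fits quickly.
smallField <- function(seed, side = 64, burn = 16, ...) {
  simulateArField(arFieldSpec(seed = seed, height = side, width = side,
                              burnIn = burn, ...))
}

# End-to-end resubstitution rate for one synthetic cohort.
cohortRate <- function(seed, gap, side = 128, burn = 32,
                       mode = "resubstitution", jitterSd = 0.005) {
  co <- generateCohort(cohortSpec(seed = seed, gap = gap,
    jitterSd = jitterSd,
    class1 = arFieldSpec(seed = 0, height = side, width = side,
                         burnIn = burn)))
  B1 <- groupCoeffMatrix(lapply(co$group1, fitImage), "group1")
  B2 <- groupCoeffMatrix(lapply(co$group2, fitImage), "group2")
  ratePercent(discriminateGroups(B1, B2, mode = mode))
}
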