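#' Pool two group coefficient matrices
#'
#' Concatenates the columns of group 1 and group 2 into the pooled
#' matrix `Bp` (group 1 columns first).
#'
#' @param B1,B2 [GroupCoeffMatrix-class] objects with equal row counts.
#' @return pooled [GroupCoeffMatrix-class] with label
#'   `"<label1>+<label2>"`.
#' @export
stackGroups <- function(B1, B2) {
  stopifnot(is(B1, "GroupCoeffMatrix"), is(B2, "GroupCoeffMatrix"))
  if (nrow(B1@B) != nrow(B2@B))
    stop("coefficient dimensions differ between groups (",
         nrow(B1@B), " vs ", nrow(B2@B), ")")
  new("GroupCoeffMatrix", B = cbind(B1@B, B2@B),
      groupLabel = paste0(B1@groupLabel, "+", B2@groupLabel),
      imageIds = c(B1@imageIds, B2@imageIds))
}

#' Sample covariance of a group's coefficient columns
#'
#' Treats each column (image) as one observation of the coefficient
#' vector and returns the N-1-denominator sample covariance, symmetrized
#' to guard the eigensolver against rounding asymmetry.
#'
#' @param B a [GroupCoeffMatrix-class] with at least 2 columns, or a
#'   plain matrix with observations in columns.
#' @return symmetric covariance matrix (rows/cols = coefficients).
#' @export
coeffCovariance <- function(B) {
  m <- if (is(B, "GroupCoeffMatrix")) B@B else as.matrix(B)
  if (ncol(m) < 2L)
    stop("covariance needs at least 2 images in the group")
  S <- cov(t(m))
  (S + t(S)) / 2
}

#' Solve the weighted Fisher discriminant eigenproblem
#'
#' Finds the direction `v` that maximally separates the two groups'
#' coefficient clouds, as the dominant eigenvector of the generalized
#' problem `A v = gamma M v` with
#' `A = n1*Op - n2*O1 - n3*O2` and `M = n2*O1 + n3*O2`, where `O1`,
#' `O2`, `Op` are the group and pooled covariances, `n1 = N1 + N2 - 1`,
#' `n2 = N1 - 1`, `n3 = N2 - 1`. With these weights `A` equals
#' `N1*N2/(N1+N2) * d d'` for the mean difference `d`, a rank-one
#' matrix, so exactly one eigenvalue is nonzero up to floating-point
#' noise and `v` is parallel to `M^{-1} d` -- the classical two-class
#' Fisher direction under the pooled within-group covariance.
#'
#' `M` is symmetric positive definite for cohorts larger than the
#' coefficient dimension, so the problem is reduced by the Cholesky
#' factor of `M` to an ordinary symmetric eigenproblem (real spectrum
#' guaranteed). The returned vector has unit norm with sign fixed so
#' that the group 1 projection mean is the larger one.
#'
#' `legacyBetween = TRUE` switches the between-side weighting to use the
#' group 1 covariance twice (`A = n1*Op - n2*O1 - n3*O1`), a variant
#' retained only for comparison with legacy implementations; it
#' generally destroys the rank-one structure and is not the default.
#'
#' @param B1,B2 [GroupCoeffMatrix-class] objects, >= 2 columns each.
#' @param legacyBetween use the legacy between-side weighting (see
#'   Details). Default `FALSE`.
#' @return An [FldSolution-class].
#' @export
solveFld <- function(B1, B2, legacyBetween = FALSE) {
  stopifnot(is(B1, "GroupCoeffMatrix"), is(B2, "GroupCoeffMatrix"))
  N1 <- ncol(B1@B); N2 <- ncol(B2@B)
  if (N1 < 2L || N2 < 2L)
    stop("each group needs at least 2 images")
  O1 <- coeffCovariance(B1)
  O2 <- coeffCovariance(B2)
  Op <- coeffCovariance(stackGroups(B1, B2))
  n1 <- N1 + N2 - 1
  n2 <- N1 - 1
  n3 <- N2 - 1
  A <- n1 * Op - n2 * O1 - n3 * (if (legacyBetween) O1 else O2)
  A <- (A + t(A)) / 2
  M <- n2 * O1 + n3 * O2
  M <- (M + t(M)) / 2
  U <- tryCatch(chol(M), error = function(e)
    stop("within-group covariance is singular; add images or reduce ",
         "the coefficient dimension", call. = FALSE))
  Ui <- backsolve(U, diag(nrow(M)))
  S <- t(Ui) %*% A %*% Ui
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  spectrum <- e$values[ord]
  v <- Ui %*% e$vectors[, ord[1L]]
  v <- as.numeric(v) / sqrt(sum(v^2))
  if (mean(crossprod(B1@B, v)) < mean(crossprod(B2@B, v)))
    v <- -v
  names(v) <- rownames(B1@B)
  new("FldSolution", v = v, gamma1 = spectrum[1L], spectrum = spectrum,
      n1 = n1, n2 = n2, n3 = n3,
      weighting = if (legacyBetween) "legacy" else "corrected")
}

#' Project coefficient vectors onto the discriminant axis
#'
#' The z-projection: the inner product of the projection vector with
#' each image's coefficient column, in `imageIds` order.
#'
#' @param B a [GroupCoeffMatrix-class] or plain coefficient matrix
#'   (columns = images).
#' @param v projection vector, or an [FldSolution-class].
#' @return named numeric vector of z values.
#' @export
zProjection <- function(B, v) {
  m <- if (is(B, "GroupCoeffMatrix")) B@B else as.matrix(B)
  if (is(v, "FldSolution")) v <- v@v
  if (length(v) != nrow(m))
    stop("projection vector length (", length(v),
         ") does not match coefficient dimension (", nrow(m), ")")
  z <- drop(crossprod(m, v))
  if (is(B, "GroupCoeffMatrix")) names(z) <- B@imageIds
  z
}

#' Export an FLD solution as JSON
#'
#' @param fld an [FldSolution-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFldJson <- function(fld, path) {
  jsonlite::write_json(
    list(v = unname(fld@v), gamma1 = fld@gamma1,
         spectrum = fld@spectrum,
         n1 = fld@n1, n2 = fld@n2, n3 = fld@n3,
         weighting = fld@weighting,
         rank_one_ratio = rankOneRatio(fld)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
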