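#' @import methods
#' @importFrom stats cov sd rnorm runif ks.test var
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib finestruct, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Circular region-of-interest specification
#'
#' Describes a fovea-centered circular region of interest in pixel
#' coordinates: the circle of radius `radiusPx` around
#' (`centerRow`, `centerCol`), 1-based indices. Physical scale
#' (`mmPerPx`) is carried as metadata only and never enters any
#' computation.
#'
#' @slot centerRow,centerCol center of the circle (1-based pixel indices).
#' @slot radiusPx circle radius in pixels (>= 1).
#' @slot mmPerPx optional millimetres per pixel; `NA` if unknown.
#' @export
setClass("RoiSpec",
  representation(centerRow = "numeric", centerCol = "numeric",
                 radiusPx = "numeric", mmPerPx = "numeric"),
  prototype(mmPerPx = NA_real_),
  validity = function(object) {
    msg <- character()
    if (length(object@centerRow) != 1L || length(object@centerCol) != 1L ||
        length(object@radiusPx) != 1L)
      msg <- c(msg, "centerRow, centerCol and radiusPx must be scalars")
    else {
      if (!is.finite(object@radiusPx) || object@radiusPx < 1)
        msg <- c(msg, "radiusPx must be a finite value >= 1")
      if (!is.na(object@mmPerPx) && object@mmPerPx <= 0)
        msg <- c(msg, "mmPerPx must be positive when given")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname RoiSpec-class
#' @param centerRow,centerCol circle center, 1-based pixel indices.
#' @param radiusPx circle radius in pixels.
#' @param mmPerPx optional physical scale (mm per pixel), metadata only.
#' @return A [RoiSpec-class] object.
#' @examples
#' roiSpec(1025, 1025, radiusPx = 1000)
#' @export
roiSpec <- function(centerRow, centerCol, radiusPx, mmPerPx = NA_real_) {
  new("RoiSpec", centerRow = as.numeric(centerRow),
      centerCol = as.numeric(centerCol), radiusPx = as.numeric(radiusPx),
      mmPerPx = as.numeric(mmPerPx))
}

setClassUnion("RoiSpecOrNULL", c("RoiSpec", "NULL"))

#' Masked grayscale image
#'
#' The unit of analysis: a real-valued pixel matrix together with a
#' same-shape logical mask (`TRUE` inside the region of interest).
#' Pixels outside the mask are held at 0 by construction.
#'
#' @slot pixels numeric matrix (rows = image rows).
#' @slot mask logical matrix of the same shape; at least one `TRUE`.
#' @slot roi the [RoiSpec-class] the patch was cut with, or `NULL` for
#'   full-frame images (e.g. synthetic fields).
#' @slot meta free-form provenance list (source path, rescaling
#'   parameters, generator seed, ...).
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", mask = "matrix",
                 roi = "RoiSpecOrNULL", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@pixels))
      msg <- c(msg, "pixels must be numeric")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (!identical(dim(object@pixels), dim(object@mask)))
      msg <- c(msg, "pixels and mask must have identical shape")
    else {
      if (!any(object@mask))
        msg <- c(msg, "mask must contain at least one TRUE cell")
      if (any(object@pixels[!object@mask] != 0))
        msg <- c(msg, "masked-out pixels must carry value 0")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname GrayImage-class
#' @param pixels numeric matrix of intensities.
#' @param mask logical matrix; defaults to all-`TRUE`.
#' @param roi optional [RoiSpec-class].
#' @param meta optional provenance list.
#' @return A [GrayImage-class] object.
#' @export
grayImage <- function(pixels, mask = NULL, roi = NULL, meta = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  pixels[!mask] <- 0
  new("GrayImage", pixels = pixels, mask = mask, roi = roi, meta = meta)
}

#' @describeIn GrayImage-class pixel matrix accessor.
#' @param object,x a `GrayImage`.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname GrayImage-class
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @describeIn GrayImage-class ROI mask accessor.
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname GrayImage-class
#' @export
setMethod("roiMask", "GrayImage", function(x) x@mask)

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage: %d x %d pixels, %d in mask (%.1f%%)\n",
              d[1], d[2], sum(object@mask),
              100 * mean(object@mask)))
  if (!is.null(object@roi))
    cat(sprintf("  ROI: center (%g, %g), radius %g px\n",
                object@roi@centerRow, object@roi@centerCol,
                object@roi@radiusPx))
  invisible(NULL)
})

#' Fitted autoregressive coefficient vector for one image
#'
#' The 9 parameters of the lag-shifted autoregressive fit: the intercept
#' and the 8 lag coefficients in canonical [buildShiftSet()] order, plus
#' the residual-variance estimate and fit provenance.
#'
#' @slot intercept fitted intercept.
#' @slot b named numeric of length 8, the lag coefficients `b_kl`.
#' @slot residVar residual variance, RSS / (n - 9).
#' @slot nObs number of lattice sites used.
#' @slot maskPolicy `"zero_fill"` or `"interior_only"`.
#' @export
setClass("CoeffVector",
  representation(intercept = "numeric", b = "numeric",
                 residVar = "numeric", nObs = "integer",
                 maskPolicy = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@b) != 8L)
      msg <- c(msg, "b must have exactly 8 entries")
    if (!all(is.finite(c(object@intercept, object@b, object@residVar))))
      msg <- c(msg, "all coefficients must be finite")
    if (length(object@residVar) == 1L && is.finite(object@residVar) &&
        object@residVar < 0)
      msg <- c(msg, "residVar must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' @describeIn CoeffVector-class full 9-vector `(intercept, b)` in
#'   canonical order.
#' @param object a `CoeffVector`.
#' @param ... ignored.
#' @export
setMethod("coef", "CoeffVector", function(object, ...)
  c(intercept = object@intercept, object@b))

setMethod("show", "CoeffVector", function(object) {
  cat(sprintf("CoeffVector (%s, n = %d sites)\n", object@maskPolicy,
              object@nObs))
  print(round(coef(object), 5))
  cat(sprintf("  residual variance: %.4g\n", object@residVar))
  invisible(NULL)
})

#' Per-group coefficient matrix
#'
#' One column per image; rows are the coefficient-vector entries
#' (intercept first when included). These are the `B` matrices whose
#' column covariances drive the discriminant.
#'
#' @slot B numeric matrix, coefficient vectors in columns.
#' @slot groupLabel group name.
#' @slot imageIds image identifiers, one per column.
#' @export
setClass("GroupCoeffMatrix",
  representation(B = "matrix", groupLabel = "character",
                 imageIds = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@B) < 1L)
      msg <- c(msg, "at least one image column required")
    if (!all(is.finite(object@B)))
      msg <- c(msg, "coefficient columns must be finite")
    if (length(object@imageIds) != ncol(object@B))
      msg <- c(msg, "one imageId per column required")
    if (length(msg)) msg else TRUE
  })

#' @rdname GroupCoeffMatrix-class
#' @param coeffs a list of [CoeffVector-class] objects, or a numeric
#'   matrix with coefficient vectors already in columns.
#' @param groupLabel group name.
#' @param imageIds identifiers, one per image; defaults to
#'   `<groupLabel>_<i>`.
#' @param useIntercept keep the intercept row (default) or restrict to
#'   the 8 lag coefficients.
#' @return A [GroupCoeffMatrix-class].
#' @export
groupCoeffMatrix <- function(coeffs, groupLabel, imageIds = NULL,
                             useIntercept = TRUE) {
  if (is.list(coeffs))
    B <- vapply(coeffs, coef, numeric(9))
  else
    B <- as.matrix(coeffs)
  if (!useIntercept && nrow(B) == 9L)
    B <- B[-1L, , drop = FALSE]
  if (is.null(imageIds))
    imageIds <- paste0(groupLabel, "_", seq_len(ncol(B)))
  new("GroupCoeffMatrix", B = B, groupLabel = as.character(groupLabel),
      imageIds = as.character(imageIds))
}

#' @describeIn GroupCoeffMatrix-class underlying matrix accessor.
#' @param x a `GroupCoeffMatrix`.
#' @export
setGeneric("coeffMatrix", function(x) standardGeneric("coeffMatrix"))
#' @rdname GroupCoeffMatrix-class
#' @export
setMethod("coeffMatrix", "GroupCoeffMatrix", function(x) x@B)

#' @describeIn GroupCoeffMatrix-class image identifiers.
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))
#' @rdname GroupCoeffMatrix-class
#' @export
setMethod("imageIds", "GroupCoeffMatrix", function(x) x@imageIds)

setMethod("show", "GroupCoeffMatrix", function(object) {
  cat(sprintf("GroupCoeffMatrix '%s': %d images x %d coefficients\n",
              object@groupLabel, ncol(object@B), nrow(object@B)))
  invisible(NULL)
})

#' Fisher linear discriminant solution
#'
#' The projection direction solving the weighted generalized eigenproblem
#' `A v = gamma M v` with `A = n1*Op - n2*O1 - n3*O2` and
#' `M = n2*O1 + n3*O2`, where `O1`, `O2`, `Op` are the group and pooled
#' coefficient covariances and `n1 = N1 + N2 - 1`, `n2 = N1 - 1`,
#' `n3 = N2 - 1`. `A` is rank one, so a single eigenvalue dominates.
#'
#' @slot v unit-norm projection vector, sign fixed so group 1 projects
#'   above group 2.
#' @slot gamma1 the retained (largest-magnitude) eigenvalue.
#' @slot spectrum all eigenvalues, sorted by decreasing magnitude.
#' @slot n1,n2,n3 the scalar weights actually used.
#' @slot weighting `"corrected"` or `"legacy"` (see [solveFld()]).
#' @export
setClass("FldSolution",
  representation(v = "numeric", gamma1 = "numeric", spectrum = "numeric",
                 n1 = "numeric", n2 = "numeric", n3 = "numeric",
                 weighting = "character"),
  validity = function(object) {
    msg <- character()
    if (abs(sqrt(sum(object@v^2)) - 1) > 1e-8)
      msg <- c(msg, "v must have unit Euclidean norm")
    if (length(object@spectrum) &&
        abs(object@gamma1) + 1e-300 < max(abs(object@spectrum)) * (1 - 1e-12))
      msg <- c(msg, "gamma1 must be the largest-magnitude eigenvalue")
    if (length(msg)) msg else TRUE
  })

#' @describeIn FldSolution-class projection vector accessor.
#' @param x an `FldSolution`.
#' @export
setGeneric("projectionVector", function(x) standardGeneric("projectionVector"))
#' @rdname FldSolution-class
#' @export
setMethod("projectionVector", "FldSolution", function(x) x@v)

#' @describeIn FldSolution-class rank-one diagnostic
#'   `|lambda_2| / |gamma_1|`; near zero when a single direction carries
#'   all between-group separation.
#' @export
setGeneric("rankOneRatio", function(x) standardGeneric("rankOneRatio"))
#' @rdname FldSolution-class
#' @export
setMethod("rankOneRatio", "FldSolution", function(x) {
  if (length(x@spectrum) < 2L) return(0)
  abs(x@spectrum[2L]) / abs(x@gamma1)
})

setMethod("show", "FldSolution", function(object) {
  cat(sprintf("FldSolution (%s weighting): gamma1 = %.5g, |l2|/|g1| = %.3g\n",
              object@weighting, object@gamma1, rankOneRatio(object)))
  cat("  v:", paste(sprintf("%.4f", object@v), collapse = " "), "\n")
  invisible(NULL)
})

#' Two-group discrimination report
#'
#' Per-image z-projections, Kullback-Leibler log-likelihood-ratio scores,
#' predictions and the cohort discrimination rate, plus the per-group
#' Kolmogorov-Smirnov normality diagnostics of the z-projections.
#'
#' @slot perImage data.frame with columns `image_id`, `true_group`, `z`,
#'   `L`, `predicted_group`, `correct`.
#' @slot ratePercent exact discrimination rate, 100 * correct / total.
#' @slot confusion 2x2 count matrix, rows = truth, cols = predicted.
#' @slot mode `"resubstitution"` or `"leave_one_out"`.
#' @slot ks list with `stat1`, `p1`, `stat2`, `p2`.
#' @export
setClass("DiscriminationReport",
  representation(perImage = "data.frame", ratePercent = "numeric",
                 confusion = "matrix", mode = "character", ks = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("image_id", "true_group", "z", "L", "predicted_group",
              "correct")
    if (!all(need %in% names(object@perImage)))
      msg <- c(msg, paste("perImage must have columns:",
                          paste(need, collapse = ", ")))
    if (object@ratePercent < 0 || object@ratePercent > 100)
      msg <- c(msg, "ratePercent must lie in [0, 100]")
    if (sum(object@confusion) != nrow(object@perImage))
      msg <- c(msg, "confusion counts must sum to the image count")
    if (length(msg)) msg else TRUE
  })

#' @describeIn DiscriminationReport-class exact discrimination rate (%).
#' @param x a `DiscriminationReport`.
#' @export
setGeneric("ratePercent", function(x) standardGeneric("ratePercent"))
#' @rdname DiscriminationReport-class
#' @export
setMethod("ratePercent", "DiscriminationReport", function(x) x@ratePercent)

#' @describeIn DiscriminationReport-class per-image results table.
#' @export
setGeneric("perImage", function(x) standardGeneric("perImage"))
#' @rdname DiscriminationReport-class
#' @export
setMethod("perImage", "DiscriminationReport", function(x) x@perImage)

#' @describeIn DiscriminationReport-class 2x2 confusion counts.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname DiscriminationReport-class
#' @export
setMethod("confusionCounts", "DiscriminationReport", function(x) x@confusion)

setMethod("show", "DiscriminationReport", function(object) {
  n <- nrow(object@perImage)
  cat(sprintf("DiscriminationReport (%s): %d/%d correct = %.2f%% (~%d%%)\n",
              object@mode, sum(object@perImage$correct), n,
              object@ratePercent, round(object@ratePercent)))
  print(object@confusion)
  invisible(NULL)
})
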