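#' Canonical lag set of the autoregressive model
#'
#' The 8 (row-lag, column-lag) offsets `{(k, l) : k, l in 0..2, k+l > 0}`
#' in lexicographic order. Every shifted-image regressor, coefficient
#' vector and synthetic-field specification in the package indexes its
#' 8 lag entries in this order.
#'
#' @return integer matrix with columns `k`, `l` and rows named
#'   `b_<k>_<l>`.
#' @examples
#' buildShiftSet()
#' @export
buildShiftSet <- function() {
  g <- expand.grid(l = 0:2, k = 0:2)[, 2:1]
  g <- g[g$k + g$l > 0, ]
  m <- as.matrix(g[order(g$k, g$l), ])
  dimnames(m) <- list(paste0("b_", m[, 1], "_", m[, 2]), c("k", "l"))
  m
}

#' Build the lag-shifted regression system for one image
#'
#' Vectorizes the valid lattice region of the patch (sites whose 8 lagged
#' neighbours all fall inside the patch, i.e. rows and columns >= 3 in
#' 1-based indexing) in column-major order, and assembles the design
#' matrix: a leading column of ones, then one column per lag holding the
#' image shifted by that offset. Under `maskPolicy = "interior_only"`
#' only sites whose own cell and all 8 lagged cells are mask-`TRUE` are
#' kept; the default `"zero_fill"` keeps every valid-region site (pixels
#' outside the mask are 0 by construction).
#'
#' @param img a [GrayImage-class] with patch dimensions at least 3 x 3.
#' @param shifts lag set, normally [buildShiftSet()].
#' @param maskPolicy `"zero_fill"` (default) or `"interior_only"`.
#' @return list with `response` (numeric vector), `regressors` (matrix
#'   with 9 columns, first all ones), `nObs`, `maskPolicy`.
#' @export
makeDesign <- function(img, shifts = buildShiftSet(),
                       maskPolicy = c("zero_fill", "interior_only")) {
  maskPolicy <- match.arg(maskPolicy)
  P <- pixels(img)
  H <- nrow(P); W <- ncol(P)
  if (H < 3L || W < 3L)
    stop("ROI too small for lag-2 model: patch must be at least 3 x 3")
  rows <- 3:H; cols <- 3:W
  X <- matrix(1, length(rows) * length(cols), nrow(shifts) + 1L)
  colnames(X) <- c("intercept", rownames(shifts))
  for (s in seq_len(nrow(shifts)))
    X[, s + 1L] <- P[rows - shifts[s, 1L], cols - shifts[s, 2L]]
  y <- as.vector(P[rows, cols])
  if (maskPolicy == "interior_only") {
    M <- roiMask(img)
    keep <- M[rows, cols]
    for (s in seq_len(nrow(shifts)))
      keep <- keep & M[rows - shifts[s, 1L], cols - shifts[s, 2L]]
    keep <- as.vector(keep)
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
  }
  if (length(y) < 10L)
    stop("ROI too small for lag-2 model: fewer than 10 usable sites")
  list(response = y, regressors = X, nObs = length(y),
       maskPolicy = maskPolicy)
}

#' Ordinary-least-squares fit of the lag-shifted model
#'
#' Solves the regression by QR decomposition (no explicit normal
#' equations) and returns the fitted coefficients, with the residual
#' variance estimated as RSS / (n - 9). A rank-deficient design -- a
#' constant image makes every lag column collinear with the intercept --
#' raises a singular-fit error naming the offending columns.
#'
#' @param sys a design system from [makeDesign()].
#' @return A [CoeffVector-class].
#' @export
fitOLS <- function(sys) {
  X <- sys$regressors; y <- sys$response
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite pixel values in regression system")
  qd <- qr(X)
  p <- ncol(X)
  if (qd$rank < p) {
    bad <- colnames(X)[sort(qd$pivot[(qd$rank + 1L):p])]
    stop("singular fit: collinear design columns (",
         paste(bad, collapse = ", "), ")")
  }
  beta <- qr.coef(qd, y)
  res <- qr.resid(qd, y)
  rv <- sum(res^2) / (length(y) - p)
  new("CoeffVector", intercept = unname(beta[1L]),
      b = beta[-1L], residVar = rv, nObs = as.integer(length(y)),
      maskPolicy = sys$maskPolicy)
}

#' Fit one image end to end
#'
#' Convenience composition of [makeDesign()] and [fitOLS()]. The result
#' is a pure function of the pixel data, mask and options.
#'
#' @inheritParams makeDesign
#' @return A [CoeffVector-class].
#' @examples
#' f <- simulateArField(arFieldSpec(seed = 1, height = 64, width = 64))
#' fitImage(f)
#' @export
fitImage <- function(img, shifts = buildShiftSet(),
                     maskPolicy = c("zero_fill", "interior_only")) {
  fitOLS(makeDesign(img, shifts, maskPolicy))
}
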