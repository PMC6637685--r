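#' Load a raster image from disk
#'
#' Reads a PNG, TIFF or JPEG file and returns the pixel data as a numeric
#' array in row-major orientation: `height x width` for grayscale, or
#' `height x width x channels` for color. Intensities come back on the
#' unit interval (8-bit value v maps to v/255, 16-bit to v/65535); the
#' mapping is injective so integer pixel data survive a write/read
#' round-trip exactly.
#'
#' @param path path to a decodable PNG/TIFF/JPEG file.
#' @return numeric array of pixel intensities with attribute
#'   `sourcePath`.
#' @seealso [toGrayscale()], [extractRoi()]
#' @export
loadImage <- function(path) {
  if (!file.exists(path))
    stop("image file does not exist: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("cannot decode image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  # EBImage stores (x = column, y = row[, channel]); convert to row-major
  a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  d <- dim(a)
  if (d[1] < 1L || d[2] < 1L)
    stop("zero-size image: ", path)
  if (length(d) == 3L && !(d[3] %in% c(1L, 3L, 4L)))
    stop("unsupported channel count (", d[3], ") in ", path)
  attr(a, "sourcePath") <- path
  a
}

#' Convert a raster image to a grayscale matrix
#'
#' Single-channel input is returned as-is (rescaled to the unit interval
#' if it arrives as raw 8/16-bit integers). Three- and four-channel
#' input is combined with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114); an alpha channel is dropped.
#'
#' @param img numeric matrix or `height x width x channels` array, e.g.
#'   from [loadImage()].
#' @return numeric matrix in `[0, 1]`.
#' @export
toGrayscale <- function(img) {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("expected a 2D matrix or height x width x channels array")
  rescale01 <- function(m) {
    mx <- max(m)
    if (mx <= 1) return(m)
    m / if (mx <= 255) 255 else 65535
  }
  if (length(d) == 2L)
    return(rescale01(img))
  nc <- d[3]
  if (nc == 1L)
    return(rescale01(img[, , 1L]))
  if (!(nc %in% c(3L, 4L)))
    stop("unsupported channel count: ", nc)
  w <- c(0.299, 0.587, 0.114)
  g <- w[1] * img[, , 1L] + w[2] * img[, , 2L] + w[3] * img[, , 3L]
  rescale01(g)
}

#' Extract a circular region of interest
#'
#' Cuts the square bounding box of the circle described by `spec`
#' (side `2 * radiusPx + 1`, clipped at the image borders) and builds the
#' in-circle mask `(r - centerRow)^2 + (c - centerCol)^2 <= radiusPx^2`.
#' Pixels outside the mask are set to 0 and retained in the rectangular
#' patch, so the downstream lattice model sees a fixed-shape grid.
#'
#' @param gray numeric matrix, e.g. from [toGrayscale()].
#' @param spec a [RoiSpec-class]; center indices are 1-based.
#' @return A [GrayImage-class] holding the masked patch.
#' @examples
#' g <- matrix(1, 5, 5)
#' extractRoi(g, roiSpec(3, 3, 1))   # 3x3 patch, 5-cell plus-shaped mask
#' @export
extractRoi <- function(gray, spec) {
  stopifnot(is(spec, "RoiSpec"))
  validObject(spec)
  H <- nrow(gray); W <- ncol(gray)
  cr <- spec@centerRow; cc <- spec@centerCol; r <- spec@radiusPx
  # reject circles that cannot touch the image
  if (cr + r < 1 || cr - r > H || cc + r < 1 || cc - r > W)
    stop("ROI circle lies entirely outside the image")
  rows <- max(1, floor(cr - r)):min(H, ceiling(cr + r))
  cols <- max(1, floor(cc - r)):min(W, ceiling(cc + r))
  patch <- gray[rows, cols, drop = FALSE]
  dr <- rows - cr
  dc <- cols - cc
  mask <- outer(dr^2, dc^2, `+`) <= r^2
  if (!any(mask))
    stop("ROI circle lies entirely outside the image")
  grayImage(patch, mask = mask, roi = spec,
            meta = list(rowOffset = rows[1] - 1L, colOffset = cols[1] - 1L))
}
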