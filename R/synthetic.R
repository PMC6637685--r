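#' Specification of a stationary autoregressive random field
#'
#' Parameters of the generative twin of the lag-shifted model: intensity
#' at each lattice site is the intercept plus the coefficient-weighted
#' sum of the 8 already-generated neighbours plus Gaussian noise.
#' Stationarity is enforced through the sufficient (conservative)
#' condition `sum(|b|) < 1`.
#'
#' @param intercept process intercept; the stationary mean is
#'   `intercept / (1 - sum(b))`.
#' @param b numeric of length 8, lag coefficients in [buildShiftSet()]
#'   order.
#' @param noiseSd innovation SD (> 0).
#' @param height,width field dimensions after cropping.
#' @param burnIn margin generated then cropped from the top and left to
#'   remove boundary transients.
#' @param seed integer RNG seed.
#' @return a list of class `ArFieldSpec`.
#' @export
arFieldSpec <- function(intercept = 0.1,
                        b = c(0.20, 0.04, 0.20, 0.10, 0.02,
                              0.04, 0.02, 0.00),
                        noiseSd = 0.05, height = 256L, width = 256L,
                        burnIn = 64L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(length(b) == 8L, noiseSd > 0, height >= 1, width >= 1,
            burnIn >= 0)
  names(b) <- rownames(buildShiftSet())
  spec <- list(intercept = intercept, b = b, noiseSd = noiseSd,
               height = as.integer(height), width = as.integer(width),
               burnIn = as.integer(burnIn), seed = as.integer(seed))
  class(spec) <- "ArFieldSpec"
  checkStability(spec$b)
  spec
}

checkStability <- function(b) {
  s <- sum(abs(b))
  if (!is.finite(s) || s >= 1)
    stop("unstable field specification: sum(|b|) = ", signif(s, 4),
         " must be < 1")
  invisible(s)
}

#' Simulate a stationary autoregressive random field
#'
#' Raster-scan recursion over a `(height + burnIn) x (width + burnIn)`
#' lattice with the boundary (out-of-range lags) seeded at the
#' stationary process mean, then cropped by `burnIn` rows from the top
#' and `burnIn` columns from the left. By default the cropped field is
#' min-max rescaled to `[0, 1]` like a quantized image, with the affine
#' parameters recorded in `meta` (`rawOffset`, `rawScale`, so
#' `raw = rescaled * rawScale + rawOffset`); the lag coefficients are
#' invariant under this affine map, only the recoverable intercept
#' changes. Deterministic given the spec (all noise is drawn from R's
#' RNG under `spec$seed`).
#'
#' @param spec an [arFieldSpec()].
#' @param rescale min-max rescale the output to `[0, 1]` (default).
#' @return A [GrayImage-class] with a full-`TRUE` mask.
#' @export
simulateArField <- function(spec, rescale = TRUE) {
  stopifnot(inherits(spec, "ArFieldSpec"))
  checkStability(spec$b)
  H <- spec$height + spec$burnIn
  W <- spec$width + spec$burnIn
  mu <- spec$intercept / (1 - sum(spec$b))
  # local RNG scope: restore the caller's stream afterwards
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  eps <- matrix(rnorm(H * W, 0, spec$noiseSd), H, W)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  y <- .arFieldRecurse(eps, unname(spec$b), spec$intercept, mu)
  y <- y[(spec$burnIn + 1L):H, (spec$burnIn + 1L):W, drop = FALSE]
  meta <- list(generator = "ar_field", spec = spec)
  if (rescale) {
    lo <- min(y); hi <- max(y)
    if (hi > lo) {
      meta$rawOffset <- lo
      meta$rawScale <- hi - lo
      y <- (y - lo) / (hi - lo)
    } else {
      meta$rawOffset <- lo
      meta$rawScale <- 1
      y <- y - lo
    }
  }
  grayImage(y, meta = meta)
}

#' Simulate a circular vessel-phantom region of interest
#'
#' Draws `nVessels` dark smooth curves of Gaussian cross-section on a
#' bright background inside a circular mask: each curve runs radially
#' outward from the center with a sinusoidal angular perturbation whose
#' amplitude is proportional to `tortuosity` (0 gives straight radial
#' vessels). A qualitative testbed for tortuosity-sensitive analysis;
#' no claim is made that it reproduces real fundus texture.
#'
#' @param radiusPx ROI radius in pixels (>= 32).
#' @param nVessels number of vessels (0 gives pure background + noise).
#' @param tortuosity nonnegative angular-perturbation amplitude scale.
#' @param caliberPx Gaussian cross-section SD of the vessels, pixels.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return A [GrayImage-class] with the circular mask applied.
#' @export
simulateVesselPhantom <- function(radiusPx, nVessels = 6L,
                                  tortuosity = 0.2, caliberPx = 3,
                                  noiseSd = 0.01, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(radiusPx >= 32, nVessels >= 0, tortuosity >= 0,
            caliberPx > 0, noiseSd >= 0)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  side <- 2L * radiusPx + 1L
  ctr <- radiusPx + 1
  bg <- 0.9
  depth <- 0.6
  # squared distance from each pixel to the nearest sampled curve point
  d2 <- matrix(Inf, side, side)
  win <- ceiling(4 * caliberPx)
  if (nVessels > 0) {
    for (vi in seq_len(nVessels)) {
      path <- vesselPath(radiusPx, vi, nVessels, tortuosity,
                         phase = runif(1, 0, 2 * pi))
      for (p in seq_len(nrow(path))) {
        pr <- ctr + path$row[p]
        pc <- ctr + path$col[p]
        rr <- max(1, floor(pr - win)):min(side, ceiling(pr + win))
        cc <- max(1, floor(pc - win)):min(side, ceiling(pc + win))
        loc <- outer((rr - pr)^2, (cc - pc)^2, `+`)
        d2[rr, cc] <- pmin(d2[rr, cc], loc)
      }
    }
  }
  img <- bg - depth * exp(-d2 / (2 * caliberPx^2))
  if (noiseSd > 0)
    img <- img + matrix(rnorm(side * side, 0, noiseSd), side, side)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  img <- pmin(pmax(img, 0), 1)
  dr <- seq_len(side) - ctr
  mask <- outer(dr^2, dr^2, `+`) <= radiusPx^2
  grayImage(img, mask = mask,
            roi = roiSpec(ctr, ctr, radiusPx),
            meta = list(generator = "vessel_phantom", seed = seed,
                        tortuosity = tortuosity, nVessels = nVessels))
}

# Centerline of one phantom vessel: radial path with sinusoidal angular
# perturbation, sampled every 0.5 px of radial extent. Returned in
# center-origin (row, col) offsets; used by the renderer and by arc
# length checks.
vesselPath <- function(radiusPx, index, nVessels, tortuosity,
                       phase = 0, cycles = 3, step = 0.5) {
  theta0 <- 2 * pi * (index - 1) / max(1, nVessels)
  t <- seq(0, radiusPx, by = step)
  theta <- theta0 + tortuosity * sin(2 * pi * cycles * t / radiusPx + phase)
  data.frame(row = t * sin(theta), col = t * cos(theta))
}

#' Specification of a synthetic two-class cohort
#'
#' Two groups of autoregressive fields whose classes differ in their lag
#' coefficients. Per-image coefficients are the class template plus
#' Gaussian jitter (between-image variability within a class), re-checked
#' for stationarity. The convenience argument `gap` builds `class2` from
#' `class1` by adding `gap` to the two first-order lags
#' (`b_0_1` and `b_1_0`).
#'
#' @param n1,n2 group sizes (>= 2); defaults 16 and 17, the cohort
#'   structure of the motivating clinical study.
#' @param class1,class2 [arFieldSpec()] templates. `class2` defaults to
#'   `class1` shifted by `gap`.
#' @param gap class separation added to `b_0_1` and `b_1_0` when
#'   `class2` is not supplied.
#' @param jitterSd SD of per-coefficient between-image jitter.
#' @param roiRadiusPx optional: mask each field to a centered circle of
#'   this radius. `NULL` (default) keeps the full square field.
#' @param seed master integer seed; per-image seeds are derived from it.
#' @return a list of class `CohortSpec`.
#' @export
cohortSpec <- function(n1 = 16L, n2 = 17L,
                       class1 = arFieldSpec(seed = 0L),
                       class2 = NULL, gap = 0.1, jitterSd = 0.005,
                       roiRadiusPx = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n1 >= 2, n2 >= 2, jitterSd >= 0)
  if (is.null(class2)) {
    class2 <- class1
    class2$b[c("b_0_1", "b_1_0")] <- class2$b[c("b_0_1", "b_1_0")] + gap
    checkStability(class2$b)
  }
  spec <- list(n1 = as.integer(n1), n2 = as.integer(n2),
               class1 = class1, class2 = class2,
               jitterSd = jitterSd, roiRadiusPx = roiRadiusPx,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-image lag coefficients (class template + jitter, resampled
#' on stationarity violation, at most 100 attempts), derives one
#' sub-seed per image from the master seed, and simulates every field.
#' Output order and values are a pure function of the spec.
#'
#' @param spec a [cohortSpec()].
#' @return list with `group1`, `group2` (lists of [GrayImage-class]),
#'   and `truth` (data.frame `image_id`, `group`).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n1 + spec$n2
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  subSeeds <- sample.int(.Machine$integer.max, n)
  jitters <- lapply(seq_len(n), function(i) {
    tmpl <- if (i <= spec$n1) spec$class1 else spec$class2
    for (attempt in 1:100) {
      b <- tmpl$b + rnorm(8, 0, spec$jitterSd)
      if (sum(abs(b)) < 1) return(b)
    }
    stop("persistent stationarity violation while jittering coefficients")
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  makeOne <- function(i) {
    tmpl <- if (i <= spec$n1) spec$class1 else spec$class2
    s <- tmpl
    s$b <- jitters[[i]]
    names(s$b) <- names(tmpl$b)
    s$seed <- subSeeds[i]
    img <- simulateArField(s)
    if (!is.null(spec$roiRadiusPx)) {
      ctr <- (dim(pixels(img)) + 1) / 2
      img <- extractRoi(pixels(img),
                        roiSpec(ctr[1], ctr[2], spec$roiRadiusPx))
    }
    img
  }
  g1 <- lapply(seq_len(spec$n1), makeOne)
  g2 <- lapply(spec$n1 + seq_len(spec$n2), makeOne)
  ids <- c(paste0("group1_", seq_len(spec$n1)),
           paste0("group2_", seq_len(spec$n2)))
  list(group1 = g1, group2 = g2,
       truth = data.frame(image_id = ids,
                          group = rep(c("group1", "group2"),
                                      c(spec$n1, spec$n2)),
                          stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Saves each field as an 8-bit PNG and emits the `manifest.csv`
#' consumed by [runDiscrimination()] (`path,group,center_row,center_col,
#' radius_px`, 0-based indices) plus a `truth.json` file.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- c(cohort$group1, cohort$group2)
  rows <- lapply(seq_along(imgs), function(i) {
    img <- imgs[[i]]
    id <- cohort$truth$image_id[i]
    fn <- file.path(dir, paste0(id, ".png"))
    EBImage::writeImage(EBImage::Image(t(pixels(img))), fn, type = "png")
    d <- dim(pixels(img))
    ctr <- if (!is.null(img@roi))
      c(img@roi@centerRow, img@roi@centerCol) else (d + 1) / 2
    rad <- if (!is.null(img@roi)) img@roi@radiusPx
      else ceiling(sqrt(sum(((d - 1) / 2)^2))) + 1  # circumscribed: full frame
    data.frame(path = fn, group = cohort$truth$group[i],
               center_row = ctr[1] - 1, center_col = ctr[2] - 1,
               radius_px = rad, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  invisible(mf)
}
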