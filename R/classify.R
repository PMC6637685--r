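#' Kolmogorov-Smirnov normality check of a projection sample
#'
#' One-sample KS statistic of the standardized values (sample mean and
#' N-1 SD) against the standard normal CDF, with the p-value from the
#' asymptotic KS distribution. The check is reported as a diagnostic for
#' the Gaussian likelihood-ratio scoring; it never gates classification.
#'
#' @param z numeric vector of z-projections.
#' @return list with `stat` and `p` (`p` is `NA` with a warning when
#'   fewer than 5 values are supplied).
#' @export
ksNormality <- function(z) {
  z <- as.numeric(z)
  s <- sd(z)
  if (!is.finite(s) || s <= 0)
    stop("z values have zero variance; KS normality check undefined")
  if (length(z) < 5L) {
    warning("fewer than 5 values: KS p-value reported as undefined")
    zst <- (z - mean(z)) / s
    ks <- suppressWarnings(ks.test(zst, "pnorm"))
    return(list(stat = unname(ks$statistic), p = NA_real_))
  }
  zst <- (z - mean(z)) / s
  ks <- suppressWarnings(ks.test(zst, "pnorm"))
  list(stat = unname(ks$statistic), p = unname(ks$p.value))
}

#' Gaussian Kullback-Leibler discrimination score
#'
#' The log-likelihood ratio of two Gaussian densities at `z`:
#' `L(z) = ln(s2/s1) + (z - m2)^2 / (2 s2^2) - (z - m1)^2 / (2 s1^2)`.
#' Positive scores favour group 1, negative scores group 2, and the
#' magnitude measures the confidence of the call.
#'
#' @param z numeric value(s) at which to evaluate the score.
#' @param m1,s1 mean and SD of the group 1 projection density.
#' @param m2,s2 mean and SD of the group 2 projection density.
#' @return numeric score(s), same length as `z`.
#' @examples
#' kldScore(0, m1 = 0, s1 = 1, m2 = 2, s2 = 1)   # = 2
#' @export
kldScore <- function(z, m1, s1, m2, s2) {
  if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0)
    stop("group SDs must be positive")
  log(s2 / s1) + (z - m2)^2 / (2 * s2^2) - (z - m1)^2 / (2 * s1^2)
}

#' Score and classify a cohort from its z-projections (resubstitution)
#'
#' Fits the per-group Gaussian summaries (mean, N-1 SD) from all z
#' values, scores every image with [kldScore()], and predicts group 1
#' where `L > 0` and group 2 where `L < 0`. An exact tie `L == 0` is
#' assigned to group 2 with a warning (deterministic, conservative for
#' the positive-means-group-1 convention). The discrimination rate is
#' the percentage of images whose score sign matches their true group.
#'
#' @param z1,z2 numeric z-projection vectors for the two groups
#'   (names, when present, become image ids).
#' @param labels length-2 character vector of group labels.
#' @return A [DiscriminationReport-class] with `mode = "resubstitution"`.
#' @examples
#' classifyCohort(c(10, 11, 12), c(-10, -11, -12))  # 100%
#' @export
classifyCohort <- function(z1, z2, labels = c("group1", "group2")) {
  if (length(z1) < 1L || length(z2) < 1L)
    stop("both groups must be nonempty")
  ids1 <- if (!is.null(names(z1))) names(z1) else
    paste0(labels[1], "_", seq_along(z1))
  ids2 <- if (!is.null(names(z2))) names(z2) else
    paste0(labels[2], "_", seq_along(z2))
  m1 <- mean(z1); s1 <- sd(z1)
  m2 <- mean(z2); s2 <- sd(z2)
  L <- kldScore(c(z1, z2), m1, s1, m2, s2)
  buildReport(
    data.frame(image_id = c(ids1, ids2),
               true_group = rep(labels, c(length(z1), length(z2))),
               z = c(unname(z1), unname(z2)), L = L,
               stringsAsFactors = FALSE),
    labels, mode = "resubstitution",
    ks = ksPair(z1, z2))
}

ksPair <- function(z1, z2) {
  one <- function(z) {
    if (length(z) >= 5L && sd(z) > 0) ksNormality(z)
    else list(stat = NA_real_, p = NA_real_)
  }
  k1 <- one(z1); k2 <- one(z2)
  list(stat1 = k1$stat, p1 = k1$p, stat2 = k2$stat, p2 = k2$p)
}

# Shared report assembly: predictions from the sign of L, tie to group 2.
buildReport <- function(df, labels, mode, ks) {
  if (any(df$L == 0, na.rm = TRUE))
    warning("score exactly 0 for ", sum(df$L == 0, na.rm = TRUE),
            " image(s); assigned to ", labels[2])
  keep <- is.finite(df$L)
  df$predicted_group <- ifelse(df$L > 0, labels[1], labels[2])
  df$predicted_group[!keep] <- NA_character_
  df$correct <- df$predicted_group == df$true_group
  nEval <- sum(keep)
  rate <- 100 * sum(df$correct[keep]) / nEval
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(truth = labels, predicted = labels))
  for (i in 1:2) for (j in 1:2)
    confusion[i, j] <- sum(df$true_group == labels[i] &
                           df$predicted_group == labels[j], na.rm = TRUE)
  new("DiscriminationReport", perImage = df, ratePercent = rate,
      confusion = confusion, mode = mode, ks = ks)
}

#' Full-chain two-group discrimination from coefficient matrices
#'
#' Runs the discriminant and classification stages on fitted coefficient
#' matrices. Under `mode = "resubstitution"` (the default, matching the
#' in-sample evaluation of the original method) the FLD is solved once
#' on the full cohort and every image is scored against summaries fitted
#' from all z values. Under `mode = "leave_one_out"` the whole chain is
#' recomputed for each image with that image's column removed -- the FLD
#' direction, the z-projections and the Gaussian summaries all come from
#' the remaining images -- and the held-out image is then projected and
#' scored; a fold whose reduced-group SD degenerates is reported as
#' indeterminate (`L = NA`) and excluded from the rate with a warning.
#'
#' @param B1,B2 [GroupCoeffMatrix-class] objects (>= 2 columns each;
#'   >= 3 for leave-one-out).
#' @param mode `"resubstitution"` or `"leave_one_out"`.
#' @param legacyBetween passed to [solveFld()].
#' @return A [DiscriminationReport-class].
#' @seealso [classifyCohort()] for the z-level scorer.
#' @export
discriminateGroups <- function(B1, B2,
                               mode = c("resubstitution", "leave_one_out"),
                               legacyBetween = FALSE) {
  mode <- match.arg(mode)
  labels <- c(B1@groupLabel, B2@groupLabel)
  if (mode == "resubstitution") {
    fld <- solveFld(B1, B2, legacyBetween = legacyBetween)
    return(classifyCohort(zProjection(B1, fld), zProjection(B2, fld),
                          labels = labels))
  }
  if (ncol(B1@B) < 3L || ncol(B2@B) < 3L)
    stop("leave-one-out needs at least 3 images per group")
  dropCol <- function(G, j) {
    new("GroupCoeffMatrix", B = G@B[, -j, drop = FALSE],
        groupLabel = G@groupLabel, imageIds = G@imageIds[-j])
  }
  scoreHeldOut <- function(own, other, j, ownFirst) {
    red <- dropCol(own, j)
    a <- if (ownFirst) red else other
    b <- if (ownFirst) other else red
    fld <- solveFld(a, b, legacyBetween = legacyBetween)
    za <- zProjection(a, fld); zb <- zProjection(b, fld)
    s1 <- sd(za); s2 <- sd(zb)
    zh <- sum(own@B[, j] * fld@v)
    if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0)
      return(c(zh, NA_real_))
    c(zh, kldScore(zh, mean(za), s1, mean(zb), s2))
  }
  out1 <- vapply(seq_len(ncol(B1@B)),
                 function(j) scoreHeldOut(B1, B2, j, TRUE), numeric(2))
  out2 <- vapply(seq_len(ncol(B2@B)),
                 function(j) scoreHeldOut(B2, B1, j, FALSE), numeric(2))
  if (anyNA(c(out1[2, ], out2[2, ])))
    warning("degenerate group SD in ",
            sum(is.na(c(out1[2, ], out2[2, ]))),
            " leave-one-out fold(s); excluded from the rate")
  df <- data.frame(
    image_id = c(B1@imageIds, B2@imageIds),
    true_group = rep(labels, c(ncol(B1@B), ncol(B2@B))),
    z = c(out1[1, ], out2[1, ]), L = c(out1[2, ], out2[2, ]),
    stringsAsFactors = FALSE)
  buildReport(df, labels, mode = "leave_one_out",
              ks = ksPair(out1[1, ], out2[1, ]))
}

#' Rank images by discrimination confidence
#'
#' Orders the cohort by signed confidence -- `L` for images whose true
#' group is group 1, `-L` for group 2 -- descending, so confidently
#' correct calls come first and misclassified images (negative
#' confidence) come last.
#'
#' @param report a [DiscriminationReport-class].
#' @return the `perImage` table with a `confidence` column, ordered by
#'   decreasing confidence.
#' @export
likelihoodStrength <- function(report) {
  stopifnot(is(report, "DiscriminationReport"))
  df <- report@perImage
  labels <- rownames(report@confusion)
  df$confidence <- ifelse(df$true_group == labels[1L], df$L, -df$L)
  df[order(-df$confidence), ]
}
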