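#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with header
#' `path,group,center_row,center_col,radius_px`, pixel indices 0-based.
#' Exactly two distinct group labels must be present; the first label in
#' file order becomes group 1.
#'
#' @param path manifest CSV path.
#' @return data.frame with an added `image_id` column (file base name).
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    stop("manifest does not exist: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "group", "center_row", "center_col", "radius_px")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (length(unique(m$group)) != 2L)
    stop("manifest must contain exactly 2 distinct group labels, found ",
         length(unique(m$group)))
  m$image_id <- sub("\\.[^.]+$", "", basename(m$path))
  m
}

#' Export a cohort's fitted coefficients as CSV
#'
#' One row per image:
#' `path,group,intercept,b_0_1,...,b_2_2,resid_var,n_obs`. Floating
#' point fields are serialized at 17 significant digits so identical
#' runs produce byte-identical files.
#'
#' @param coeffs list of [CoeffVector-class] objects.
#' @param paths,groups per-image path and group label.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
writeCoeffCsv <- function(coeffs, paths, groups, file) {
  fmt <- function(x) sprintf("%.17g", x)
  rows <- vapply(seq_along(coeffs), function(i) {
    cv <- coeffs[[i]]
    paste(c(paths[i], groups[i], fmt(coef(cv)), fmt(cv@residVar),
            cv@nObs), collapse = ",")
  }, character(1))
  hdr <- paste(c("path", "group", "intercept",
                 rownames(buildShiftSet()), "resid_var", "n_obs"),
               collapse = ",")
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Write a discrimination report as JSON and CSV
#'
#' @param report a [DiscriminationReport-class].
#' @param jsonFile,csvFile output paths (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
writeReport <- function(report, jsonFile = NULL, csvFile = NULL) {
  if (!is.null(jsonFile)) {
    jsonlite::write_json(
      list(mode = report@mode,
           rate_percent = report@ratePercent,
           rate_percent_rounded = round(report@ratePercent),
           n_correct = sum(report@perImage$correct, na.rm = TRUE),
           n_total = nrow(report@perImage),
           confusion = unclass(report@confusion),
           ks = report@ks,
           per_image = report@perImage),
      jsonFile, auto_unbox = TRUE, digits = NA, dataframe = "rows",
      na = "null", matrix = "rowmajor")
  }
  if (!is.null(csvFile)) {
    df <- report@perImage
    fmt <- function(x) sprintf("%.17g", x)
    rows <- paste(df$image_id, df$true_group, fmt(df$z), fmt(df$L),
                  df$predicted_group, tolower(as.character(df$correct)),
                  sep = ",")
    writeLines(c("image_id,true_group,z,L,predicted_group,correct",
                 rows), csvFile)
  }
  invisible(c(json = jsonFile, csv = csvFile))
}

#' Run the full discrimination pipeline on a manifest
#'
#' Orchestrates manifest -> ROI extraction -> per-image autoregressive
#' fits -> Fisher discriminant -> Kullback-Leibler classification, and
#' writes `coefficients.csv`, `fld.json`, `report.json`, `report.csv`
#' and `run.log` to `outputDir`. Unreadable or unfittable images abort
#' the run listing every offending path (dropping images silently would
#' change the cohort weights of the discriminant). Reruns with an
#' identical configuration produce byte-identical outputs.
#'
#' @param manifest manifest CSV path, or a data.frame from
#'   [readManifest()].
#' @param outputDir directory for artifacts (created if absent), or
#'   `NULL` to skip writing.
#' @param maskPolicy passed to [makeDesign()].
#' @param useInterceptInB carry the intercept row into the discriminant
#'   (default) or use the 8 lag coefficients only.
#' @param legacyBetween passed to [solveFld()].
#' @param evaluationMode passed to [discriminateGroups()].
#' @return A [DiscriminationReport-class], invisibly, with the
#'   [FldSolution-class] and coefficient list attached as attributes
#'   `fld` and `coeffs`.
#' @export
runDiscrimination <- function(manifest, outputDir = NULL,
                              maskPolicy = c("zero_fill", "interior_only"),
                              useInterceptInB = TRUE,
                              legacyBetween = FALSE,
                              evaluationMode = c("resubstitution",
                                                 "leave_one_out")) {
  maskPolicy <- match.arg(maskPolicy)
  evaluationMode <- match.arg(evaluationMode)
  m <- if (is.data.frame(manifest)) manifest else readManifest(manifest)
  failures <- character()
  coeffs <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    coeffs[[i]] <- tryCatch({
      gray <- toGrayscale(loadImage(m$path[i]))
      img <- extractRoi(gray, roiSpec(m$center_row[i] + 1,
                                      m$center_col[i] + 1,
                                      m$radius_px[i]))
      fitImage(img, maskPolicy = maskPolicy)
    }, error = function(e) e)
    if (inherits(coeffs[[i]], "error"))
      failures <- c(failures, paste0(m$path[i], ": ",
                                     conditionMessage(coeffs[[i]])))
  }
  if (length(failures))
    stop("pipeline aborted; failing images:\n  ",
         paste(failures, collapse = "\n  "))
  labels <- unique(m$group)
  i1 <- m$group == labels[1]
  B1 <- groupCoeffMatrix(coeffs[i1], labels[1],
                         imageIds = m$image_id[i1],
                         useIntercept = useInterceptInB)
  B2 <- groupCoeffMatrix(coeffs[!i1], labels[2],
                         imageIds = m$image_id[!i1],
                         useIntercept = useInterceptInB)
  fld <- solveFld(B1, B2, legacyBetween = legacyBetween)
  report <- discriminateGroups(B1, B2, mode = evaluationMode,
                               legacyBetween = legacyBetween)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeCoeffCsv(coeffs, m$path, m$group,
                  file.path(outputDir, "coefficients.csv"))
    writeFldJson(fld, file.path(outputDir, "fld.json"))
    writeReport(report, file.path(outputDir, "report.json"),
                file.path(outputDir, "report.csv"))
    writeLines(c(
      sprintf("finestruct %s on R %s.%s",
              as.character(packageVersion("finestruct")),
              R.version$major, R.version$minor),
      sprintf("mask_policy: %s", maskPolicy),
      sprintf("use_intercept_in_B: %s", useInterceptInB),
      sprintf("weighting: %s", fld@weighting),
      sprintf("evaluation_mode: %s", evaluationMode),
      sprintf("n_images: %d (%s: %d, %s: %d)", nrow(m),
              labels[1], sum(i1), labels[2], sum(!i1)),
      sprintf("gamma1: %.17g", fld@gamma1),
      sprintf("rank_one_ratio: %.17g", rankOneRatio(fld)),
      sprintf("rate_percent: %.17g (%d%%)", report@ratePercent,
              round(report@ratePercent))),
      file.path(outputDir, "run.log"))
  }
  attr(report, "fld") <- fld
  attr(report, "coeffs") <- coeffs
  invisible(report)
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [runDiscrimination()]:
#' `manifest`, `output_dir`, `mask_policy`, `use_intercept_in_B`,
#' `legacy_between`, `evaluation_mode`. Missing keys take the function
#' defaults.
#'
#' @param path YAML file.
#' @return named list of arguments for [runDiscrimination()].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$manifest))
    stop("config must name a 'manifest'")
  list(manifest = cfg$manifest,
       outputDir = cfg$output_dir,
       maskPolicy = cfg$mask_policy %||% "zero_fill",
       useInterceptInB = cfg$use_intercept_in_B %||% TRUE,
       legacyBetween = cfg$legacy_between %||% FALSE,
       evaluationMode = cfg$evaluation_mode %||% "resubstitution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
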