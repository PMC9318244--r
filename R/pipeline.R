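#' Simulate a lesion cohort to disk
#'
#' Renders a paired-illumination cohort with [generateCohort()], writes
#' each image as an 8-bit grayscale PNG named
#' `{lesion_id}_{PL|NPL}.png`, and writes a `manifest.csv` (columns
#' `lesion_id`, `group`, `illumination`, `path`, `seed`, plus the key
#' generator parameters) ready for [runPipeline()]. Bit-identical across
#' runs for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param nPerGroup,presets,seed,... passed to [generateCohort()].
#' @return the manifest data.frame, invisibly.
#' @export
simulateCohort <- function(dir, nPerGroup, presets = defaultPresets(),
                           seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(nPerGroup, presets, seed, render = TRUE, ...)
  rows <- list()
  for (rec in cohort) {
    for (il in c("PL", "NPL")) {
      img <- if (il == "PL") rec$imagePL else rec$imageNPL
      p <- if (il == "PL") rec$paramsPL else rec$paramsNPL
      path <- file.path(dir, sprintf("%s_%s.png", rec$lesionId, il))
      writeLesionImage(img, path)
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = rec$lesionId, group = rec$group, illumination = il,
        path = path, seed = rec$seed,
        irregularity_amplitude = p@irregularityAmplitude,
        texture_hurst = p@textureHurst, base_radius = p@baseRadius)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

.logMsg <- function(verbose, ...) if (verbose) message(...)

#' Run the full lesion analysis pipeline
#'
#' For every manifest entry: read the photograph, segment it (grayscale,
#' inversion, divide blend, mask extraction), measure area and perimeter,
#' estimate the shape FD on the divide-blended image with power-series
#' scales, tile ROIs inside the mask and estimate the surface FD of each
#' with block-series scales; then assemble the group-comparison
#' statistics. All outputs are written as CSV files into `outputDir`,
#' together with a `config.yaml` echo of every parameter for provenance.
#' Unreadable or unsegmentable images are skipped with a logged reason;
#' the run fails only on a malformed manifest.
#'
#' The analysis itself uses no random numbers, so a rerun on the same
#' inputs and configuration is bit-identical.
#'
#' @param manifest path to a manifest CSV, or an equivalent data.frame,
#'   with columns `lesion_id`, `group`, `illumination`, `path` and
#'   optionally `stage` (`"in_situ"`/`"invasive"` for melanomas).
#' @param outputDir directory for result tables (created if needed).
#' @param mmPerPixel physical calibration; `NA` reports pixel units.
#' @param roiSize surface-analysis ROI side in pixels (study default 450).
#' @param whiteThreshold,minComponentFraction segmentation cleanup
#'   controls, see [extractMask()].
#' @param gridOffsets grid-offset averaging for FD estimation (default 1 =
#'   off), see [estimateFD()].
#' @param verbose emit progress messages to stderr.
#' @return invisibly, a list with `measurements`, `surface` (data.frames),
#'   `reports` (list of [StatsReport-class] / data.frame objects) and
#'   `skipped`.
#' @export
runPipeline <- function(manifest, outputDir, mmPerPixel = NA_real_,
                        roiSize = 450L, whiteThreshold = 250,
                        minComponentFraction = 0.01, gridOffsets = 1L,
                        verbose = TRUE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("lesion_id", "group", "illumination", "path")
  if (!all(need %in% names(manifest)))
    stop("malformed manifest: need columns ", paste(need, collapse = ", "))
  if (roiSize < 8L) stop("roiSize must be >= 8")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  meas <- list(); surf <- list(); skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- paste(row$lesion_id, row$illumination, sep = "/")
    res <- tryCatch({
      img <- readLesionImage(row$path, mmPerPixel)
      seg <- segmentLesion(img, whiteThreshold, minComponentFraction)
      mor <- withCallingHandlers(
        measureLesion(seg$mask, mmPerPixel),
        warning = function(w) {
          .logMsg(verbose, "  [", id, "] ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      shapeFd <- estimateFD(seg$blended, powerSeriesScales(dim(img)),
                            gridOffsets)
      rois <- suppressMessages(extractROIs(seg$gray, seg$mask, roiSize))
      roiFds <- vapply(patches(rois), function(p)
        fd(estimateFD(p, blockSeriesScales(roiSize), gridOffsets)), numeric(1))
      list(mor = mor, shapeFd = shapeFd, rois = rois, roiFds = roiFds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      .logMsg(verbose, "skipping ", id, ": ", conditionMessage(res))
      skipped[[length(skipped) + 1L]] <-
        data.frame(lesion_id = row$lesion_id, illumination = row$illumination,
                   reason = conditionMessage(res))
      next
    }
    .logMsg(verbose, "processed ", id, ": shape FD ",
            sprintf("%.4f", fd(res$shapeFd)), ", ", length(res$rois), " ROI(s)")
    meas[[length(meas) + 1L]] <- data.frame(
      lesion_id = row$lesion_id, group = row$group,
      illumination = row$illumination,
      stage = if ("stage" %in% names(row)) row$stage else NA_character_,
      area = lesionArea(res$mor), perimeter = lesionPerimeter(res$mor),
      pixel_area = res$mor@pixelArea, pixel_perimeter = res$mor@pixelPerimeter,
      units = res$mor@units,
      shape_fd = fd(res$shapeFd), shape_fd_r2 = rSquared(res$shapeFd),
      n_rois = length(res$rois))
    if (length(res$roiFds))
      surf[[length(surf) + 1L]] <- data.frame(
        lesion_id = row$lesion_id, group = row$group,
        illumination = row$illumination,
        stage = if ("stage" %in% names(row)) row$stage else NA_character_,
        roi_index = seq_along(res$roiFds),
        roi_row = origins(res$rois)[, "row"],
        roi_col = origins(res$rois)[, "col"],
        surface_fd = res$roiFds)
  }
  if (!length(meas)) stop("no lesion could be processed")
  measurements <- do.call(rbind, meas)
  surface <- if (length(surf)) do.call(rbind, surf) else NULL
  reports <- list()
  haveBoth <- all(c("PL", "NPL") %in% measurements$illumination)
  paired <- all(table(measurements$lesion_id) == 2L)
  if (haveBoth && paired)
    for (v in c("area", "perimeter", "shape_fd"))
      reports[[paste0("paired_", v)]] <- pairedIlluminationTest(measurements, v)
  if (length(unique(measurements$group)) >= 2L) {
    for (v in c("area", "perimeter", "shape_fd"))
      reports[[paste0("groups_", v)]] <- groupComparison(measurements, v)
    if (!is.null(surface))
      reports$groups_surface_fd <- groupComparison(surface, "surface_fd")
  }
  enough <- all(table(measurements$group, measurements$illumination) >= 5L)
  if (enough) reports$correlation <- correlationMatrix(measurements)
  if (any(!is.na(measurements$stage)))
    reports$melanoma_stage <- melanomaSubgroupTest(measurements, surface)
  .writeOutputs(outputDir, measurements, surface, reports, skipped,
                list(mmPerPixel = mmPerPixel, roiSize = as.integer(roiSize),
                     whiteThreshold = whiteThreshold,
                     minComponentFraction = minComponentFraction,
                     gridOffsets = as.integer(gridOffsets)))
  invisible(list(measurements = measurements, surface = surface,
                 reports = reports,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL))
}

.flattenReport <- function(rep) {
  if (is.data.frame(rep)) return(rep)
  if (is(rep, "StatsReport")) {
    s <- rep@summary
    if (!is.null(s) && nrow(s)) s$test <- rep@test
    return(s)
  }
  NULL
}

.writeOutputs <- function(outputDir, measurements, surface, reports, skipped,
                          config) {
  w <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(outputDir, name), row.names = FALSE)
  w(measurements, "measurements.csv")
  w(surface, "surface_fd.csv")
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    if (is(rep, "StatsReport")) {
      w(.flattenReport(rep), paste0("stats_", nm, ".csv"))
      pw <- pairwisePValues(rep)
      if (!is.null(pw))
        w(data.frame(group = rownames(pw), pw, check.names = FALSE),
          paste0("stats_", nm, "_pairwise.csv"))
    } else if (is.list(rep) && !is.data.frame(rep)) {
      for (il in names(rep)) {
        w(.flattenReport(rep[[il]]), paste0("stats_", nm, "_", il, ".csv"))
        pw <- pairwisePValues(rep[[il]])
        if (!is.null(pw))
          w(data.frame(group = rownames(pw), pw, check.names = FALSE),
            paste0("stats_", nm, "_", il, "_pairwise.csv"))
      }
    } else {
      w(rep, paste0("stats_", nm, ".csv"))
    }
  }
  if (length(skipped)) w(do.call(rbind, skipped), "skipped.csv")
  yaml::write_yaml(config, file.path(outputDir, "config.yaml"))
}
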