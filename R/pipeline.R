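# End-to-end orchestration: tiles -> stain estimate -> detection ->
# features -> classification -> TILs variables -> cut-point -> survival,
# with GeoJSON/CSV round-tripping and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested named list mirroring every stage's parameter set; the detection
#' block reproduces the standard watershed parameters exactly. Unknown keys
#' in a user-supplied configuration are rejected by
#' [readPipelineConfig()].
#'
#' @return Named list with sections `version`, `seed`, `stain`,
#'   `detection`, `features`, `classifier`, `tils`, `cutpoint`, `survival`.
#' @export
defaultPipelineConfig <- function() {
  list(
    version = "1.0",
    seed = 1L,
    stain = list(od_min = 0.15, angle_percentile = 0.01,
                 estimate_per_image = TRUE),
    detection = list(requested_pixel_size_um = 0.5, background_radius_um = 8,
                     median_radius_um = 0, sigma_um = 1.5,
                     min_cell_area_um2 = 10, max_cell_area_um2 = 400,
                     od_threshold = 0.1, max_background_intensity = 2,
                     cell_expansion_um = 5),
    features = list(smoothing_radii_um = c(25, 50)),
    classifier = list(hidden = 8L, max_iterations = 1000L,
                      learning_rate = 0.01, tolerance = 1e-5),
    tils = list(include_ignore_in_total = FALSE),
    cutpoint = list(variable = "eTILs_pct", min_group_fraction = 0.1),
    survival = list(ties = "efron", tils_threshold = 13.2)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys take their defaults; keys absent from
#' [defaultPipelineConfig()] are rejected.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  merge1 <- function(d, u, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown configuration key: ",
           paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(u[[nm]]))
        merge1(d[[nm]], u[[nm]], paste0(prefix, nm, ".")) else u[[nm]]
    }
    d
  }
  merge1(def, user)
}

#' @describeIn readPipelineConfig build a [DetectionParams-class] from a
#'   configuration list.
#' @param config configuration list.
#' @export
detectionParamsFromConfig <- function(config) {
  d <- config$detection
  DetectionParams(requestedPixelSize = d$requested_pixel_size_um,
                  backgroundRadius = d$background_radius_um,
                  medianRadius = d$median_radius_um, sigma = d$sigma_um,
                  minCellArea = d$min_cell_area_um2,
                  maxCellArea = d$max_cell_area_um2,
                  odThreshold = d$od_threshold,
                  maxBackgroundIntensity = d$max_background_intensity,
                  cellExpansion = d$cell_expansion_um)
}

#' Read a tile image from PNG or TIFF
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return Intensity array `[nx, ny, 3]` on the 0-255 scale (16-bit input
#'   is rescaled to 0-255).
#' @export
readTileImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2, 1, 3)) * 255
}

#' Write / read cell detections as GeoJSON
#'
#' One Feature per cell: the geometry is the cell boundary polygon, the
#' classification name and the nucleus polygon live in `properties`
#' (`classification$name`, `nucleusGeometry`), mirroring the interchange
#' layout digital-pathology tools expect. Coordinates are micrometers.
#'
#' @param detections detection data.frame (see [detectCells()]).
#' @param path output / input file path.
#' @return `path` / the detection data.frame (without label masks).
#' @export
writeDetectionsGeoJSON <- function(detections, path) {
  ring <- function(m) {
    m <- rbind(m, m[1, , drop = FALSE])           # close the ring
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(seq_len(nrow(detections)), function(i) {
    list(
      type = "Feature",
      id = detections$id[i],
      geometry = list(type = "Polygon",
                      coordinates = list(ring(detections$cell_polygon[[i]]))),
      properties = list(
        objectType = "cell",
        classification = list(name = detections$class[i]),
        nucleusGeometry = list(
          type = "Polygon",
          coordinates = list(ring(detections$nucleus_polygon[[i]]))),
        measurements = list(
          centroid_x_um = detections$centroid_x_um[i],
          centroid_y_um = detections$centroid_y_um[i],
          nucleus_area_um2 = detections$nucleus_area_um2[i],
          cell_area_um2 = detections$cell_area_um2[i])
      ))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDetectionsGeoJSON
#' @export
readDetectionsGeoJSON <- function(path) {
  fc <- tryCatch(jsonlite::read_json(path),
                 error = function(e)
                   stop("malformed GeoJSON in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("malformed GeoJSON in ", path, ": not a FeatureCollection",
         call. = FALSE)
  un <- function(coords) {
    m <- do.call(rbind, lapply(coords[[1]], function(p)
      c(p[[1]], p[[2]])))
    m <- m[-nrow(m), , drop = FALSE]              # drop closing vertex
    colnames(m) <- c("x_um", "y_um")
    m
  }
  n <- length(fc$features)
  out <- data.frame(id = integer(n), class = character(n),
                    centroid_x_um = numeric(n), centroid_y_um = numeric(n),
                    nucleus_area_um2 = numeric(n), cell_area_um2 = numeric(n),
                    stringsAsFactors = FALSE)
  nucp <- cellp <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fc$features[[i]]
    out$id[i] <- f$id
    out$class[i] <- f$properties$classification$name
    m <- f$properties$measurements
    out$centroid_x_um[i] <- m$centroid_x_um
    out$centroid_y_um[i] <- m$centroid_y_um
    out$nucleus_area_um2[i] <- m$nucleus_area_um2
    out$cell_area_um2[i] <- m$cell_area_um2
    cellp[[i]] <- un(f$geometry$coordinates)
    nucp[[i]] <- un(f$properties$nucleusGeometry$coordinates)
  }
  out$nucleus_polygon <- nucp
  out$cell_polygon <- cellp
  out
}

#' Run the full TILs quantification pipeline
#'
#' For every tile: optical-density conversion, per-image (or fixed) stain
#' estimation, deconvolution, watershed detection, feature computation with
#' neighborhood smoothing, classification, and the TILs report. When a
#' survival cohort is supplied, per-patient TILs values are joined to it and
#' the cut-point search plus the univariate/multivariate Cox models are
#' run. All stage artifacts are written under `outDir`, together with a
#' manifest (configuration, its MD5 hash, seed, package and R versions)
#' sufficient to reproduce the outputs; a rerun with identical inputs is
#' byte-identical.
#'
#' @param images named list of RGB intensity arrays `[nx, ny, 3]` (0-255)
#'   or a character vector of PNG/TIFF paths; names identify patients.
#' @param classifier a trained [CellClassifier-class]; `NULL` leaves cells
#'   `UNCLASSIFIED` and skips TILs scoring.
#' @param cohort optional survival data.frame with an `id` column matching
#'   image names plus `time_months` and `event`.
#' @param config configuration list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @param rois optional named list of ROI polygons (um); default full tile.
#' @param outDir output directory.
#' @return List with `reports` (per-patient TILs data.frame), `detections`
#'   (list), `cutpoint` ([CutpointResult-class] or NULL), `survival`
#'   (list or NULL), `manifest`.
#' @export
runPipeline <- function(images, classifier = NULL, cohort = NULL,
                        config = defaultPipelineConfig(), rois = NULL,
                        outDir = tempfile("tilquant_run_")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(images)) {
    paths <- images
    nms <- if (!is.null(names(images))) names(images) else
      tools::file_path_sans_ext(basename(images))
    images <- lapply(paths, function(p)
      tryCatch(readTileImage(p), error = function(e)
        stop("stage segment failed on input '", p, "': ",
             conditionMessage(e), call. = FALSE)))
    names(images) <- nms
  }
  if (is.null(names(images)))
    names(images) <- sprintf("tile_%03d", seq_along(images))
  params <- detectionParamsFromConfig(config)
  px <- params@requestedPixelSize
  reports <- list(); detList <- list()
  for (nm in names(images)) {
    img <- images[[nm]]
    roi <- if (!is.null(rois)) rois[[nm]] else NULL
    res <- tryCatch(
      .runTileStages(img, px, params, config, classifier, roi),
      error = function(e)
        stop("stage ", conditionMessage(e), " [input ", nm, "]",
             call. = FALSE))
    detList[[nm]] <- res$detections
    writeDetectionsGeoJSON(res$detections,
                           file.path(outDir, paste0(nm, "_cells.geojson")))
    writeFeatureCSV(res$features,
                    file.path(outDir, paste0(nm, "_features.csv")))
    reports[[nm]] <- cbind(tilsReportRow(res$report, id = nm))
  }
  reportDF <- do.call(rbind, reports)
  rownames(reportDF) <- NULL
  utils::write.csv(reportDF, file.path(outDir, "tils_reports.csv"),
                   row.names = FALSE)

  cutRes <- survRes <- NULL
  if (!is.null(cohort)) {
    merged <- merge(cohort, reportDF, by = "id")
    vr <- config$cutpoint$variable
    cutRes <- findOptimalCutpoint(merged[[vr]], merged$time_months,
                                  merged$event,
                                  config$cutpoint$min_group_fraction)
    utils::write.csv(cutRes@scan, file.path(outDir, "cutpoint_scan.csv"),
                     row.names = FALSE)
    survRes <- runTable2Models(merged, tilsVariable = vr,
                               threshold = cutRes@threshold,
                               ties = config$survival$ties)
    utils::write.csv(survRes$multivariate@table,
                     file.path(outDir, "cox_multivariate.csv"),
                     row.names = FALSE)
  }

  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "TILquant",
    package_version = as.character(utils::packageVersion("TILquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    inputs = names(images))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(reports = reportDF, detections = detList, cutpoint = cutRes,
       survival = survRes, manifest = manifest)
}

.runTileStages <- function(img, px, params, config, classifier, roi) {
  od <- rgbToOD(img, background = NULL, pixelSize = px)
  model <- if (isTRUE(config$stain$estimate_per_image)) {
    tryCatch(estimateStainVectors(od, odMin = config$stain$od_min,
                                  anglePercentile =
                                    config$stain$angle_percentile),
             error = function(e) defaultStainModel())
  } else defaultStainModel()
  ch <- deconvolveStains(od, model)
  det <- detectCells(ch[, , 1], params, roi)
  if (!nrow(det)) stop("segment: no cells detected")
  feat <- computeCellFeatures(det, ch[, , 1], ch[, , 2])
  feat <- smoothFeatures(feat,
                         cbind(det$centroid_x_um, det$centroid_y_um),
                         radii = config$features$smoothing_radii_um)
  if (!is.null(classifier)) {
    det$class <- classifyCells(classifier, feat)$class
  }
  if (is.null(roi)) {
    roi <- cbind(c(0, nrow(img), nrow(img), 0),
                 c(0, 0, ncol(img), ncol(img))) * px
  }
  ca <- countAndArea(det, roi)
  counts <- c(IMMUNE = ca$counts[["IMMUNE"]], TUMOR = ca$counts[["TUMOR"]],
              STROMA = ca$counts[["STROMA"]], IGNORE = ca$counts[["IGNORE"]])
  report <- computeTILsReport(counts, ca$area_mm2,
                              config$tils$include_ignore_in_total)
  list(detections = det, features = feat, report = report)
}
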