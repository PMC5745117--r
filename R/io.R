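# File I/O: images (TIFF/PNG), spectra and band tables (CSV/YAML),
# reports (JSON), and the run configuration.

#' Read an AF image from TIFF or PNG
#'
#' @param path file path (.tif/.tiff or .png).
#' @param pixelSize um per pixel to attach.
#' @param scale multiplier applied to the stored values (PNG stores
#'   normalised 0-1 data; TIFFs written by [writeAFImage()] are 32-bit
#'   float and need none).
#' @return an [AFImage-class].
#' @export
readAFImage <- function(path, pixelSize, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(m)) == 3) m <- m[, , 1]
  newAFImage(m * scale, pixelSize)
}

#' Write an AF image as 32-bit float TIFF
#'
#' Values are stored normalised to [0, 1]; the returned scale (the image
#' maximum) restores the original units on reading, and [writePhantom()]
#' records it in the JSON sidecar.
#'
#' @param image an [AFImage-class].
#' @param path output path.
#' @return the intensity scale, invisibly.
#' @export
writeAFImage <- function(image, path) {
  s <- max(intensities(image), 1e-300)
  tiff::writeTIFF(intensities(image) / s, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(s)
}

#' Read an annotation mask from PNG
#'
#' Grey PNG whose 8-bit values are the integer class codes.
#'
#' @param path PNG path.
#' @param levels class names for the codes (default phantom levels).
#' @return an [AnnotationMask-class]; unknown codes are an error naming
#'   the offending value.
#' @export
readAnnotationMask <- function(path,
    levels = c("background", "stroma", "BCC", "dye")) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  codes <- round(m * 255)
  bad <- setdiff(unique(as.vector(codes)), seq_along(levels) - 1L)
  if (length(bad) > 0)
    stop("annotation contains unknown label value(s): ",
         paste(bad, collapse = ", "))
  new("AnnotationMask", labels = matrix(as.integer(codes), nrow(codes)),
      levels = levels)
}

#' Write an annotation mask as grey PNG
#' @param mask an [AnnotationMask-class].
#' @param path output path.
#' @export
writeAnnotationMask <- function(mask, path) {
  png::writePNG(mask@labels / 255, path)
  invisible(path)
}

#' Write a phantom as image + mask + JSON sidecar
#'
#' @param phantom a [Phantom-class].
#' @param prefix path prefix; writes \code{<prefix>_image.tif},
#'   \code{<prefix>_mask.png}, \code{<prefix>_config.json}.
#' @return the three paths, invisibly.
#' @export
writePhantom <- function(phantom, prefix) {
  pImg <- paste0(prefix, "_image.tif")
  pMask <- paste0(prefix, "_mask.png")
  pCfg <- paste0(prefix, "_config.json")
  scale <- writeAFImage(phantom@image, pImg)
  writeAnnotationMask(phantom@mask, pMask)
  cfg <- phantom@config
  jsonlite::write_json(list(
    intensityScale = scale,
    imageShape = cfg@imageShape, pixelSize = cfg@pixelSize,
    stromaMean = cfg@stromaMean, tumourMean = cfg@tumourMean,
    backgroundMean = cfg@backgroundMean, textureSd = cfg@textureSd,
    nTumourBlobs = cfg@nTumourBlobs,
    blobRadiusRange = cfg@blobRadiusRange, blobShape = cfg@blobShape,
    rimWidthPx = cfg@rimWidthPx,
    dyeFraction = cfg@dyeFraction, seed = cfg@seed), pCfg,
    auto_unbox = TRUE, digits = NA)
  invisible(c(pImg, pMask, pCfg))
}

#' Read a phantom written by [writePhantom()]
#' @param prefix the path prefix used when writing.
#' @return a [Phantom-class].
#' @export
readPhantom <- function(prefix) {
  cfgL <- jsonlite::read_json(paste0(prefix, "_config.json"),
                              simplifyVector = TRUE)
  cfg <- phantomConfig(imageShape = cfgL$imageShape,
    pixelSize = cfgL$pixelSize, stromaMean = cfgL$stromaMean,
    tumourMean = cfgL$tumourMean, backgroundMean = cfgL$backgroundMean,
    textureSd = cfgL$textureSd, nTumourBlobs = cfgL$nTumourBlobs,
    blobRadiusRange = cfgL$blobRadiusRange, blobShape = cfgL$blobShape,
    rimWidthPx = cfgL$rimWidthPx, dyeFraction = cfgL$dyeFraction,
    seed = cfgL$seed)
  img <- readAFImage(paste0(prefix, "_image.tif"), cfgL$pixelSize,
                     scale = cfgL$intensityScale)
  mask <- readAnnotationMask(paste0(prefix, "_mask.png"))
  new("Phantom", image = img, mask = mask, config = cfg)
}

#' Write spectra as CSV
#'
#' Columns: \code{spectrum_id}, \code{patient_id}, \code{class}, then
#' one intensity column per wavenumber (headed \code{wn400}, ...).
#'
#' @param s a [SpectraSet-class].
#' @param path output CSV path.
#' @export
writeSpectraCsv <- function(s, path) {
  meta <- spectraMeta(s)
  df <- data.frame(
    spectrum_id = meta$spectrumId %||% seq_len(nSpectra(s)),
    patient_id = meta$patientId %||% NA,
    class = meta$class %||% NA)
  mat <- intensities(s)
  colnames(mat) <- paste0("wn", wavenumbers(s))
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read spectra from CSV
#'
#' @param path CSV written in the layout of [writeSpectraCsv()].
#' @return a [SpectraSet-class]; a wavenumber axis not covering
#'   400-1800 cm^-1 is an error.
#' @export
readSpectraCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wnCols <- grep("^wn[0-9.]+$", names(df))
  if (length(wnCols) == 0) stop("no wavenumber columns (wn...) found")
  wn <- as.numeric(sub("^wn", "", names(df)[wnCols]))
  if (min(wn) > 400 || max(wn) < 1800)
    stop(sprintf("spectra cover %.0f-%.0f cm^-1; missing part of 400-1800",
                 min(wn), max(wn)))
  meta <- data.frame(spectrumId = as.character(df$spectrum_id),
                     patientId = as.character(df$patient_id),
                     class = as.character(df$class))
  newSpectraSet(wn, as.matrix(df[, wnCols]), meta)
}

#' Read band definitions from YAML
#'
#' Expected layout: a \code{bands} list of \code{centre}/\code{halfWidth}
#' entries.
#'
#' @param path YAML path.
#' @return band data.frame.
#' @export
readBandTable <- function(path) {
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(y$bands, function(b)
    data.frame(centre = b$centre, halfWidth = b$halfWidth)))
  out
}

#' Write the per-segment table and label image of a SegmentMap
#'
#' @param segmap a [SegmentMap-class].
#' @param prefix path prefix; writes \code{<prefix>_labels.tif} (float
#'   TIFF of ids) and \code{<prefix>_segments.csv}.
#' @export
writeSegmentMapFiles <- function(segmap, prefix) {
  tiff::writeTIFF(segmentLabels(segmap) / max(1, nSegments(segmap)),
                  paste0(prefix, "_labels.tif"), bits.per.sample = 32L)
  utils::write.csv(segmentTable(segmap), paste0(prefix, "_segments.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Write the colour-coded diagnosis image as PNG
#'
#' @param image a [DiagnosisImage-class].
#' @param path PNG path.
#' @export
writeDiagnosisPng <- function(image, path) {
  cols <- image@legend[image@classLevels[image@labels + 1L]]
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, c(nrow(image@labels), ncol(image@labels), 3))
  arr[, , 1] <- rgb[1, ]; arr[, , 2] <- rgb[2, ]; arr[, , 3] <- rgb[3, ]
  png::writePNG(arr, path)
  invisible(path)
}

# small polynomial rolling hash for config fingerprinting (hex string)
configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration with mode presets
#'
#' Bundles every pipeline parameter with documented defaults. Modes
#' encode the three measurement regimes: \code{"diagnosis"} (800-point
#' budget, minimum 5 points per segment, SNR >= 4, two rounds),
#' \code{"validation"} (at least 20 points per segment, 1200-spectrum
#' cap, SNR >= 7), \code{"training"} (raster scans, SNR > 15, strict).
#'
#' @param mode one of \code{"diagnosis"}, \code{"validation"},
#'   \code{"training"}.
#' @param ... overrides of individual parameters.
#' @return a list of class \code{"mshConfig"} including a \code{hash}.
#' @export
mshConfig <- function(mode = c("diagnosis", "validation", "training"),
                      ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    backgroundThreshold = 200,
    flattenSigma = NULL,       # default: image width / 10
    gridSize = 256L,
    minSegmentArea = NULL,     # default: defaultMinSegmentArea(pixelSize)
    connectivity = 8L,
    nMin = 5L, nTotal = 800L,
    placement = "config2",
    targetSnr = 15,
    snrMin = 4, snrStrict = FALSE,
    nTh = 8L,
    bands = defaultBands(),
    spectraSeed = 1L, placeSeed = 1L)
  if (mode == "validation") { cfg$nMin <- 20L; cfg$nTotal <- 1200L
    cfg$snrMin <- 7 }
  if (mode == "training") { cfg$snrMin <- 15; cfg$snrStrict <- TRUE }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg$hash <- configHash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "mshConfig"
  cfg
}

#' Read and shape-check pipeline inputs from files
#'
#' @param imagePath AF image path.
#' @param maskPath optional annotation-mask PNG.
#' @param spectraPath optional spectra CSV.
#' @param pixelSize um per pixel of the image.
#' @return list with \code{image}, \code{mask} (or NULL), \code{spectra}
#'   (or NULL); image/mask shape mismatch is an error.
#' @export
readInputs <- function(imagePath, maskPath = NULL, spectraPath = NULL,
                       pixelSize = 40) {
  image <- readAFImage(imagePath, pixelSize)
  mask <- if (!is.null(maskPath)) readAnnotationMask(maskPath)
  if (!is.null(mask) && !identical(dim(mask@labels), dim(image)))
    stop("image and annotation mask have different shapes")
  spectra <- if (!is.null(spectraPath)) readSpectraCsv(spectraPath)
  list(image = image, mask = mask, spectra = spectra)
}

#' Write a diagnosis report as JSON (plus PNG image and CSV tables)
#'
#' @param report report list from [runPipeline()].
#' @param path JSON path; the diagnosis PNG and segment CSV are written
#'   next to it when the report carries the objects.
#' @export
writeReport <- function(report, path) {
  out <- report
  if (!is.null(out$diagnosisImage)) {
    pngPath <- sub("\\.json$", "_diagnosis.png", path)
    writeDiagnosisPng(out$diagnosisImage, pngPath)
    out$diagnosisImagePath <- pngPath
    out$diagnosisImage <- NULL
  }
  if (!is.null(out$segmap)) {
    writeSegmentMapFiles(out$segmap, sub("\\.json$", "", path))
    out$segmap <- NULL
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read back a JSON report
#' @param path JSON path.
#' @return report list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
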