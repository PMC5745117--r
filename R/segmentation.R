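# AF image flattening, adaptive threshold segmentation, and the
# rho / epsilon quality metrics against an annotation.

#' Default minimum segment area in pixels
#'
#' Area of a 60 um diameter disc at the given pixel size (tumours below
#' roughly 100 um are at the detection limit; smaller specks are treated
#' as noise), never less than 2 pixels.
#'
#' @param pixelSize um per pixel.
#' @export
defaultMinSegmentArea <- function(pixelSize) {
  max(2L, ceiling(pi * (30 / pixelSize)^2))
}

#' Flatten an AF image (flat-field correction)
#'
#' Divides the image by its Gaussian-blurred copy and rescales so the
#' mean intensity (over the mask if given) is preserved. This removes
#' slow illumination gradients and stitching-scale intensity trends
#' while keeping local contrast.
#'
#' @param image an [AFImage-class].
#' @param sigma Gaussian sigma in pixels (default: 1/10 of image width);
#'   values below 1 pixel are rejected.
#' @param mask optional logical matrix restricting the blur and rescaling
#'   to foreground pixels; pixels outside the mask are set to 0.
#' @return a flattened [AFImage-class].
#' @export
flattenImage <- function(image, sigma = ncol(intensities(image)) / 10,
                         mask = NULL) {
  x <- intensities(image)
  if (all(x == 0)) stop("cannot flatten an all-zero image")
  if (sigma < 1) stop("sigma must be at least 1 pixel")
  w <- if (is.null(mask)) matrix(1, nrow(x), ncol(x)) else mask * 1
  if (sum(w) == 0) stop("mask is empty")
  blurred <- gaussBlurMasked(x, w, sigma)
  out <- matrix(0, nrow(x), ncol(x))
  inW <- w > 0 & blurred > 0
  m0 <- mean(x[w > 0])
  out[inW] <- x[inW] / blurred[inW] * m0
  out[out < 0] <- 0
  newAFImage(out, pixelSize(image))
}

#' Separate tissue from background by a set intensity threshold
#'
#' Foreground pixels are those at or above \code{backgroundThreshold};
#' connected specks smaller than \code{minSpeckArea} are removed.
#'
#' @param image an [AFImage-class].
#' @param backgroundThreshold intensity threshold.
#' @param minSpeckArea minimum component area retained, in pixels.
#' @param connectivity 4 or 8.
#' @return a logical tissue mask.
#' @export
tissueMask <- function(image, backgroundThreshold, minSpeckArea = 25L,
                       connectivity = 8L) {
  x <- intensities(image)
  fg <- x >= backgroundThreshold
  if (!any(fg)) stop("no tissue detected above the background threshold")
  lab <- ccLabel(fg, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minSpeckArea)
  if (length(keep) == 0) stop("no tissue detected above the background threshold")
  matrix(lab %in% keep, nrow(x), ncol(x))
}

#' Segment the tissue at an intensity threshold
#'
#' Segments are connected components of below-threshold pixels inside the
#' tissue mask (tumour is darker than stroma, so candidate regions are the
#' dark ones); components smaller than \code{minSegmentArea} are dropped
#' and ids are relabelled contiguously 1..k.
#'
#' @param image an [AFImage-class] (normally the flattened image).
#' @param mask logical tissue mask.
#' @param t intensity threshold.
#' @param minSegmentArea minimum segment area in pixels; default from
#'   [defaultMinSegmentArea()].
#' @param connectivity 4 or 8 (default 8).
#' @return a [SegmentMap-class]; an empty segmentation (k = 0) is valid.
#' @export
segmentAtThreshold <- function(image, mask, t, minSegmentArea = NULL,
                               connectivity = 8L) {
  x <- intensities(image)
  if (is.null(minSegmentArea))
    minSegmentArea <- defaultMinSegmentArea(pixelSize(image))
  fg <- mask & x < t
  lab <- ccLabel(fg, as.integer(connectivity))
  k0 <- max(lab)
  if (k0 > 0) {
    areas <- tabulate(lab, nbins = k0)
    keep <- which(areas >= minSegmentArea)
    remap <- integer(k0)
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  k <- max(lab)
  if (k > 0) {
    idx <- which(lab > 0L)
    seg <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    vals <- x[idx]
    areaPx <- tabulate(seg, nbins = k)
    tab <- data.frame(
      id = seq_len(k),
      areaPx = areaPx,
      areaMm2 = areaPx * (pixelSize(image) / 1000)^2,
      variance = as.numeric(tapply(vals, seg, function(v)
        if (length(v) > 1) var(v) else 0)),
      centroidRow = as.numeric(tapply(rows, seg, mean)),
      centroidCol = as.numeric(tapply(cols, seg, mean)))
  } else {
    tab <- data.frame(id = integer(), areaPx = integer(),
      areaMm2 = numeric(), variance = numeric(),
      centroidRow = numeric(), centroidCol = numeric())
  }
  new("SegmentMap", labels = lab, table = tab, thresholdUsed = t,
      connectivity = as.integer(connectivity),
      pixelSize = pixelSize(image))
}

# fast (count, area-fraction) sweep used by the objectives
segmentCountArea <- function(x, mask, t, minSegmentArea, connectivity) {
  lab <- ccLabel(mask & x < t, as.integer(connectivity))
  k0 <- max(lab)
  if (k0 == 0) return(c(N = 0, A = 0))
  areas <- tabulate(lab, nbins = k0)
  areas <- areas[areas >= minSegmentArea]
  c(N = length(areas), A = sum(areas) / sum(mask))
}

#' Threshold-selection objectives f_A and f_B
#'
#' \code{f_A = N}, the number of segments at threshold t, and
#' \code{f_B = N * A} where \code{A} is the fraction of the tissue-mask
#' area captured by the segments. Both have a global maximum as a
#' function of the threshold, which makes them usable as
#' intensity-invariant threshold selectors; \code{f_B} favours larger
#' captured area and hence higher tumour capture.
#'
#' @param image an [AFImage-class].
#' @param mask logical tissue mask.
#' @param t intensity threshold.
#' @param kind \code{"f_A"} or \code{"f_B"}.
#' @param minSegmentArea,connectivity as in [segmentAtThreshold()].
#' @return the objective value (>= 0).
#' @export
thresholdObjective <- function(image, mask, t, kind = c("f_B", "f_A"),
                               minSegmentArea = NULL, connectivity = 8L) {
  kind <- match.arg(kind)
  if (is.null(minSegmentArea))
    minSegmentArea <- defaultMinSegmentArea(pixelSize(image))
  na <- segmentCountArea(intensities(image), mask, t, minSegmentArea,
                         connectivity)
  if (kind == "f_A") unname(na["N"]) else unname(na["N"] * na["A"])
}

#' Optimise the segmentation threshold
#'
#' Sweeps \code{gridSize} evenly spaced thresholds between the minimum and
#' maximum masked intensity, evaluates both objectives, and returns the
#' argmax of the chosen one (ties broken toward the lowest threshold,
#' i.e. the most conservative segmentation) together with the full curve.
#'
#' @inheritParams thresholdObjective
#' @param gridSize number of grid thresholds (>= 2), default 256.
#' @return list with \code{threshold}, \code{kind} and \code{curve}
#'   (data.frame: threshold, f_A, f_B).
#' @export
optimizeThreshold <- function(image, mask, kind = c("f_B", "f_A"),
                              gridSize = 256L, minSegmentArea = NULL,
                              connectivity = 8L) {
  kind <- match.arg(kind)
  stopifnot(gridSize >= 2)
  x <- intensities(image)
  v <- x[mask]
  if (diff(range(v)) == 0)
    stop("degenerate image: constant intensity inside the mask")
  if (is.null(minSegmentArea))
    minSegmentArea <- defaultMinSegmentArea(pixelSize(image))
  grid <- seq(min(v), max(v), length.out = gridSize)
  na <- vapply(grid, function(t)
    segmentCountArea(x, mask, t, minSegmentArea, connectivity),
    numeric(2))
  curve <- data.frame(threshold = grid, f_A = na[1, ],
                      f_B = na[1, ] * na[2, ])
  obj <- curve[[kind]]
  best <- which(obj == max(obj))[1]  # lowest threshold among ties
  list(threshold = grid[best], kind = kind, curve = curve)
}

# annotation helpers: logical BCC / tissue layers from a mask or matrix
annotationLayers <- function(annotation) {
  if (is(annotation, "AnnotationMask")) {
    lev <- annotation@levels
    lab <- annotation@labels
    bccCode <- which(lev == "BCC") - 1L
    bgCode <- which(lev == "background") - 1L
    list(bcc = lab == bccCode, tissue = lab != bgCode)
  } else {
    stop("annotation must be an AnnotationMask")
  }
}

#' Fraction of annotated tumour captured by a segmentation (rho)
#'
#' \code{rho = Area(detected BCC) / (Area(detected BCC) + Area(missed
#' BCC))} where a BCC pixel counts as detected when it lies inside any
#' segment.
#'
#' @param segmap a [SegmentMap-class].
#' @param annotation an [AnnotationMask-class] aligned with the image.
#' @return rho in [0, 1], or \code{NA} (with a warning) when the
#'   annotation contains no BCC.
#' @export
computeRho <- function(segmap, annotation) {
  ly <- annotationLayers(annotation)
  nBccPx <- sum(ly$bcc)
  if (nBccPx == 0) {
    warning("annotation contains no BCC pixels; rho is not applicable")
    return(NA_real_)
  }
  detected <- sum(ly$bcc & segmap@labels > 0L)
  detected / nBccPx
}

#' Histological heterogeneity of a segment (epsilon)
#'
#' \code{epsilon = Area(healthy tissue) / (Area(detected BCC) +
#' Area(healthy tissue))} within one segment; healthy tissue means
#' annotated non-BCC tissue pixels (background is excluded).
#'
#' @param segmap a [SegmentMap-class].
#' @param annotation an [AnnotationMask-class].
#' @param segmentId segment id (1..k).
#' @return epsilon in [0, 1].
#' @export
computeEpsilon <- function(segmap, annotation, segmentId) {
  if (!segmentId %in% segmap@table$id) stop("invalid segment id")
  ly <- annotationLayers(annotation)
  inSeg <- segmap@labels == segmentId
  bcc <- sum(inSeg & ly$bcc)
  healthy <- sum(inSeg & ly$tissue & !ly$bcc)
  if (bcc + healthy == 0)
    stop("segment ", segmentId, " contains no annotated tissue pixels")
  healthy / (bcc + healthy)
}
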