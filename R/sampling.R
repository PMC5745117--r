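# Allocation of Raman sampling points to segments and their placement.

#' Allocate sampling points to segments by area and intensity variance
#'
#' Every segment receives \code{nMin} points; the remaining budget
#' \code{nRest = nTotal - k * nMin} is shared proportionally to
#' \code{Var(i) * Area(i)}, so large, heterogeneous segments are sampled
#' more densely. Fractional shares are rounded by the largest-remainder
#' method, which preserves the total. If even the minima exceed the
#' budget, segments receive \code{nMin} in decreasing-area order until
#' the budget runs out (with a warning).
#'
#' @param segmap a [SegmentMap-class].
#' @param nMin minimum points per segment (default 5).
#' @param nTotal total sampling budget (default 800).
#' @return integer vector of per-segment counts (sums to \code{nTotal}
#'   whenever \code{k * nMin <= nTotal}).
#' @export
#' @examples
#' # two segments with Var*Area weights 0.2 / 0.8 and a budget of 20:
#' # 5 + 0.2 * 10 = 7 and 5 + 0.8 * 10 = 13
allocatePoints <- function(segmap, nMin = 5L, nTotal = 800L) {
  tab <- segmentTable(segmap)
  k <- nrow(tab)
  if (k < 1) stop("segmentation has no segments to allocate to")
  stopifnot(nMin >= 1, nTotal >= 1)
  if (k * nMin > nTotal) {
    warning("budget below k * nMin: allocating minima in decreasing-area ",
            "order until exhausted")
    counts <- integer(k)
    left <- nTotal
    for (i in order(tab$areaPx, decreasing = TRUE)) {
      counts[i] <- min(nMin, left)
      left <- left - counts[i]
      if (left == 0) break
    }
    return(counts)
  }
  rest <- nTotal - k * nMin
  w <- tab$variance * tab$areaPx
  if (all(w == 0)) {
    if (rest > 0)
      warning("all Var*Area weights are zero; distributing the remaining ",
              "budget uniformly")
    w <- rep(1, k)
  }
  share <- w / sum(w) * rest
  base <- floor(share)
  short <- rest - sum(base)
  if (short > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(nMin + base)
}

# candidate pixels not blocked by exclusions
availablePixels <- function(pixels, exclusions, exclusionRadius) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(pixels)
  keep <- rep(TRUE, nrow(pixels))
  for (j in seq_len(nrow(exclusions))) {
    d2 <- (pixels[, 1] - exclusions[j, 1])^2 +
          (pixels[, 2] - exclusions[j, 2])^2
    keep <- keep & d2 >= exclusionRadius^2
  }
  pixels[keep, , drop = FALSE]
}

# farthest-point sampling given already-selected anchor points;
# ties broken toward the lowest row-major pixel index
fpsSelect <- function(pixels, n, anchors) {
  sel <- matrix(numeric(0), 0, 2)
  rowMajor <- (pixels[, 1] - 1) * 1e7 + pixels[, 2]
  mind <- rep(Inf, nrow(pixels))
  if (!is.null(anchors) && nrow(anchors) > 0) {
    for (j in seq_len(nrow(anchors)))
      mind <- pmin(mind, (pixels[, 1] - anchors[j, 1])^2 +
                          (pixels[, 2] - anchors[j, 2])^2)
  }
  for (i in seq_len(n)) {
    if (all(!is.finite(mind))) {
      # no anchors yet: start at the pixel nearest the centroid
      ctr <- colMeans(pixels)
      d2 <- (pixels[, 1] - ctr[1])^2 + (pixels[, 2] - ctr[2])^2
      pick <- which(d2 == min(d2))
    } else {
      pick <- which(mind == max(mind))
    }
    pick <- pick[which.min(rowMajor[pick])]
    p <- pixels[pick, ]
    sel <- rbind(sel, p)
    mind <- pmin(mind, (pixels[, 1] - p[1])^2 + (pixels[, 2] - p[2])^2)
    mind[pick] <- -1  # never reselect
  }
  dimnames(sel) <- list(NULL, c("row", "col"))
  sel
}

#' Place points uniformly within a segment
#'
#' Default placement spreads points evenly over the segment by
#' farthest-point sampling started at the pixel nearest the centroid;
#' this is deterministic and gives even coverage. \code{method =
#' "random"} draws pixels uniformly at random instead (used for
#' Monte-Carlo properties). Points are never placed within
#' \code{exclusionRadius} of an excluded point (second-round placement
#' avoids first-round locations this way).
#'
#' @param pixels matrix of segment pixel coordinates (row, col), e.g.
#'   from \code{whichPixels}-style extraction of a segment.
#' @param n number of points.
#' @param seed seed (used by \code{method = "random"} only).
#' @param exclusions matrix of excluded coordinates or NULL.
#' @param exclusionRadius pixels; default 1 (a distinct pixel required).
#' @param method \code{"fps"} or \code{"random"}.
#' @return matrix of coordinates (row, col); fewer than \code{n} rows
#'   (with a warning) when the segment cannot host that many.
#' @export
placePointsUniform <- function(pixels, n, seed = 1L, exclusions = NULL,
                               exclusionRadius = 1,
                               method = c("fps", "random")) {
  method <- match.arg(method)
  stopifnot(n >= 1, nrow(pixels) >= 1)
  avail <- availablePixels(pixels, exclusions, exclusionRadius)
  if (nrow(avail) < n) {
    warning("segment can host only ", nrow(avail), " of ", n,
            " requested points")
    n <- nrow(avail)
  }
  if (n == 0) return(matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("row", "col"))))
  if (method == "random") {
    idx <- withr::with_seed(as.integer(seed),
                            sample.int(nrow(avail), n))
    out <- avail[idx, , drop = FALSE]
    dimnames(out) <- list(NULL, c("row", "col"))
    return(out)
  }
  fpsSelect(avail, n, exclusions)
}

#' Place points at the intensity extrema, then uniformly (Config 1)
#'
#' The first two points sit at the lowest- and highest-intensity pixels of
#' the segment (ties toward the lowest row-major index); the remaining
#' \code{n - 2} are spread as in [placePointsUniform()].
#'
#' @param pixels matrix of segment pixel coordinates (row, col).
#' @param intens intensity at each pixel (same order).
#' @param n number of points (>= 2).
#' @param seed,exclusions,exclusionRadius as in [placePointsUniform()].
#' @return matrix of coordinates (row, col).
#' @export
placePointsExtrema <- function(pixels, intens, n, seed = 1L,
                               exclusions = NULL, exclusionRadius = 1) {
  if (n < 2) stop("extrema placement needs at least 2 points")
  stopifnot(nrow(pixels) == length(intens))
  rowMajor <- (pixels[, 1] - 1) * 1e7 + pixels[, 2]
  pickBy <- function(keep) {
    cand <- which(keep)
    cand[which.min(rowMajor[cand])]
  }
  iMin <- pickBy(intens == min(intens))
  iMax <- pickBy(intens == max(intens) & seq_along(intens) != iMin)
  sel <- pixels[c(iMin, iMax), , drop = FALSE]
  if (n > 2) {
    more <- placePointsUniform(pixels, n - 2, seed = seed,
      exclusions = rbind(exclusions, sel),
      exclusionRadius = exclusionRadius)
    sel <- rbind(sel, more)
  }
  dimnames(sel) <- list(NULL, c("row", "col"))
  sel
}

#' Build a sampling plan for all segments
#'
#' Allocates the budget with [allocatePoints()] and places the points per
#' segment with Config 2 (uniform) or Config 1 (intensity extrema plus
#' uniform).
#'
#' @param segmap a [SegmentMap-class].
#' @param image the [AFImage-class] the segmentation was computed on
#'   (needed by Config 1 for intensities).
#' @param nMin,nTotal allocation parameters (defaults 5 and 800).
#' @param config \code{"config2"} (default) or \code{"config1"}.
#' @param seed seed passed to the placement routines.
#' @return data.frame with \code{pointId}, \code{segmentId}, \code{row},
#'   \code{col}, \code{round}, \code{config}.
#' @export
buildSamplingPlan <- function(segmap, image, nMin = 5L, nTotal = 800L,
                              config = c("config2", "config1"),
                              seed = 1L) {
  config <- match.arg(config)
  counts <- allocatePoints(segmap, nMin, nTotal)
  x <- intensities(image)
  lab <- segmentLabels(segmap)
  plans <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(NULL)
    px <- whichPixels(lab == i)
    pts <- if (config == "config1" && counts[i] >= 2) {
      placePointsExtrema(px, x[lab == i], counts[i], seed = seed + i)
    } else {
      placePointsUniform(px, counts[i], seed = seed + i)
    }
    data.frame(segmentId = i, row = pts[, 1], col = pts[, 2],
               round = 1L, config = config)
  })
  plan <- do.call(rbind, plans)
  plan <- cbind(pointId = seq_len(nrow(plan)), plan)
  rownames(plan) <- NULL
  plan
}

#' Tumour hit rate of a sampling plan
#'
#' Fraction of points landing on annotated BCC among all points allocated
#' to segments that contain at least one BCC pixel.
#'
#' @param plan sampling-plan data.frame from [buildSamplingPlan()].
#' @param segmap a [SegmentMap-class].
#' @param annotation an [AnnotationMask-class].
#' @return hit rate in [0, 1], or \code{NA} (warning) when no segment
#'   contains BCC.
#' @export
hitRate <- function(plan, segmap, annotation) {
  ly <- annotationLayers(annotation)
  lab <- segmentLabels(segmap)
  bccSegs <- sort(unique(lab[ly$bcc & lab > 0L]))
  inBccSeg <- plan$segmentId %in% bccSegs
  if (!any(inBccSeg)) {
    warning("no sampling points in BCC-containing segments; ",
            "hit rate is not applicable")
    return(NA_real_)
  }
  onBcc <- ly$bcc[cbind(plan$row, plan$col)]
  sum(onBcc & inBccSeg) / sum(inBccSeg)
}

#' Number of BCC-containing segments missed by a plan
#'
#' Segments that contain annotated BCC but received no sampling point on
#' a BCC pixel.
#'
#' @inheritParams hitRate
#' @return integer count in [0, number of BCC segments].
#' @export
missedBccSegments <- function(plan, segmap, annotation) {
  ly <- annotationLayers(annotation)
  lab <- segmentLabels(segmap)
  bccSegs <- sort(unique(lab[ly$bcc & lab > 0L]))
  if (length(bccSegs) == 0) return(0L)
  onBcc <- ly$bcc[cbind(plan$row, plan$col)]
  hitSegs <- unique(plan$segmentId[onBcc])
  sum(!bccSegs %in% hitSegs)
}
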