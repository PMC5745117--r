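# Two-round per-segment diagnosis and assembly of the MSH image.

# Classify the retained spectra of one segment (optionally PCA-denoised).
classifySegmentSpectra <- function(spectra, classifier,
                                   denoiseBasis = NULL) {
  if (!is.null(denoiseBasis))
    spectra <- pcaDenoise(spectra, denoiseBasis)
  feats <- extractFeatures(spectra, classifier@bands)
  as.character(classify(classifier, feats)$class)
}

#' First-round diagnosis of one segment
#'
#' Applies, in order: discard spectra below the SNR threshold; if more
#' than 80\% of the spectra were discarded the segment becomes
#' \code{Unclassified} (terminal, no second round); classify the retained
#' spectra; with no BCC spectra, a single represented class labels the
#' whole segment and several classes trigger nearest-neighbour splitting;
#' exactly one BCC spectrum is ignored and the previous rules reapplied;
#' more than 80\% BCC labels the segment BCC outright; otherwise (at
#' least two BCC spectra but at most 80\%) the segment goes to the
#' second round.
#'
#' @param spectra [SpectraSet-class] measured at the segment's points
#'   (one spectrum per point, same order).
#' @param points data.frame or matrix of point coordinates (row, col).
#' @param classifier a [RamanClassifier-class].
#' @param segmentId integer id recorded in the result.
#' @param snrMin diagnosis-round SNR threshold (default 4).
#' @param denoiseBasis optional PCA denoising basis ([SpectraSet-class]).
#' @param discardFrac fraction of discarded spectra above which the
#'   segment is Unclassified (strict, default 0.8).
#' @param bccFrac fraction of BCC spectra above which the segment is
#'   labelled BCC in round 1 (strict, default 0.8).
#' @return a [SegmentDiagnosis-class].
#' @export
diagnoseSegmentRound1 <- function(spectra, points, classifier,
                                  segmentId = 1L, snrMin = 4,
                                  denoiseBasis = NULL,
                                  discardFrac = 0.8, bccFrac = 0.8) {
  n <- nSpectra(spectra)
  if (n == 0) stop("no spectra supplied for segment ", segmentId)
  points <- as.data.frame(points)
  stopifnot(nrow(points) == n)
  snr <- computeSnr(spectra)
  retained <- snr >= snrMin
  pts <- data.frame(row = points$row, col = points$col, round = 1L,
                    snr = snr, retained = retained,
                    class = NA_character_, ignored = FALSE)
  mk <- function(status, label = NA_character_)
    new("SegmentDiagnosis", segmentId = as.integer(segmentId),
        status = status, label = label, points = pts)

  if (sum(!retained) / n > discardFrac) return(mk("Unclassified"))

  cls <- classifySegmentSpectra(spectra[retained], classifier,
                                denoiseBasis)
  pts$class[retained] <- cls

  if (sum(cls == "BCC") == 1L) {
    pts$ignored[which(retained)[cls == "BCC"]] <- TRUE
    cls <- cls[cls != "BCC"]
  }
  mk <- function(status, label = NA_character_)
    new("SegmentDiagnosis", segmentId = as.integer(segmentId),
        status = status, label = label, points = pts)

  if (length(cls) == 0) return(mk("Unclassified"))
  nBcc <- sum(cls == "BCC")
  if (nBcc == 0) {
    if (length(unique(cls)) == 1L) return(mk("label", cls[1]))
    return(mk("split"))
  }
  if (nBcc / length(cls) > bccFrac) return(mk("label", "BCC"))
  mk("round2")
}

#' Second measurement round for an ambiguous segment
#'
#' Places as many new points as the first round had (avoiding the
#' first-round locations), measures them through \code{sampler},
#' SNR-filters, joins the retained spectra of both rounds, classifies
#' them, and always finalises the segment by nearest-neighbour splitting
#' on a per-spectrum basis.
#'
#' @param diag the round-1 [SegmentDiagnosis-class] with status
#'   \code{"round2"}.
#' @param segPixels matrix of the segment's pixel coordinates (row, col).
#' @param sampler function(points matrix) returning a
#'   [SpectraSet-class] with one spectrum per requested point.
#' @param classifier a [RamanClassifier-class].
#' @param round1Spectra the round-1 [SpectraSet-class] (same order as
#'   the round-1 points).
#' @param snrMin SNR threshold (default 4).
#' @param denoiseBasis optional PCA denoising basis.
#' @param seed placement seed.
#' @return a finalised [SegmentDiagnosis-class] (status \code{"split"},
#'   or \code{"Unclassified"} if nothing was retained).
#' @export
runRound2 <- function(diag, segPixels, sampler, classifier, round1Spectra,
                      snrMin = 4, denoiseBasis = NULL, seed = 1L) {
  if (diag@status != "round2")
    stop("segment ", diag@segmentId, " is not awaiting a second round")
  p1 <- diag@points
  n2 <- nrow(p1)
  newPts <- withCallingHandlers(
    placePointsUniform(segPixels, n2, seed = seed,
                       exclusions = as.matrix(p1[, c("row", "col")])),
    warning = function(w) invokeRestart("muffleWarning"))
  pts <- p1
  if (nrow(newPts) == 0) {
    warning("segment ", diag@segmentId,
            " too small for new points; finalising with round-1 spectra")
    joined <- round1Spectra[p1$retained]
    keepRows <- which(p1$retained)
  } else {
    s2 <- sampler(newPts)
    snr2 <- computeSnr(s2)
    ret2 <- snr2 >= snrMin
    pts <- rbind(p1, data.frame(row = newPts[, 1], col = newPts[, 2],
      round = 2L, snr = snr2, retained = ret2, class = NA_character_,
      ignored = FALSE))
    joined <- bindSpectra(round1Spectra[p1$retained], s2[ret2])
    keepRows <- c(which(p1$retained), nrow(p1) + which(ret2))
  }
  pts$ignored <- FALSE  # round-2 finalisation is per spectrum
  if (length(keepRows) == 0 || nSpectra(joined) == 0)
    return(new("SegmentDiagnosis", segmentId = diag@segmentId,
               status = "Unclassified", label = NA_character_,
               points = pts))
  cls <- classifySegmentSpectra(joined, classifier, denoiseBasis)
  pts$class[keepRows] <- cls
  new("SegmentDiagnosis", segmentId = diag@segmentId, status = "split",
      label = NA_character_, points = pts)
}

#' Nearest-neighbour splitting of a segment
#'
#' Every segment pixel takes the class of its nearest labelled sampling
#' point (Euclidean distance between pixel centres, ties toward the
#' lowest point index), so the labelled subregions partition the segment.
#'
#' @param segPixels matrix of segment pixel coordinates (row, col).
#' @param points data.frame with \code{row}, \code{col}, \code{class}
#'   for the labelled points.
#' @return character vector of per-pixel labels, aligned with
#'   \code{segPixels} rows.
#' @export
nearestNeighbourSplit <- function(segPixels, points) {
  points <- as.data.frame(points)
  if (nrow(points) == 0) stop("no labelled points inside the segment")
  idx <- .nearestPointCpp(as.numeric(segPixels[, 1]),
                          as.numeric(segPixels[, 2]),
                          as.numeric(points$row), as.numeric(points$col))
  as.character(points$class)[idx]
}

#' Assemble the colour-coded MSH diagnosis image
#'
#' Fills every diagnosed segment into a per-pixel label image over the
#' tissue mask (whole-segment labels, nearest-neighbour splits, or
#' Unclassified), leaves unsegmented tissue as \code{"tissue"}, and
#' counts the connected BCC-labelled regions (8-connectivity) as
#' \code{N_BCC} — the quantity the per-sample decision thresholds.
#'
#' @param diagnoses list of finalised [SegmentDiagnosis-class] objects.
#' @param segmap the [SegmentMap-class].
#' @param mask logical tissue mask.
#' @return a [DiagnosisImage-class].
#' @export
assembleDiagnosis <- function(diagnoses, segmap, mask) {
  classLevels <- c("background", "tissue", "BCC", "dermis", "fat", "EMI",
                   "dye", "Unclassified")
  legend <- c(background = "#000000", tissue = "#d9d9d9",
              BCC = "#e31a1c", dermis = "#33a02c", fat = "#ffd92f",
              EMI = "#1f78b4", dye = "#111111", Unclassified = "#808080")
  code <- function(nm) match(nm, classLevels) - 1L
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- code("tissue")
  segLab <- segmentLabels(segmap)
  for (d in diagnoses) {
    inSeg <- segLab == d@segmentId
    if (d@status == "label") {
      lab[inSeg] <- code(d@label)
    } else if (d@status == "Unclassified") {
      lab[inSeg] <- code("Unclassified")
    } else if (d@status %in% c("split", "round2")) {
      pts <- d@points
      pts <- pts[pts$retained & !pts$ignored & !is.na(pts$class), ,
                 drop = FALSE]
      if (nrow(pts) == 0) {
        lab[inSeg] <- code("Unclassified")
      } else {
        px <- whichPixels(inSeg)
        lab[px] <- code(nearestNeighbourSplit(px, pts))
      }
    }
  }
  nB <- max(ccLabel(lab == code("BCC"), 8L))
  new("DiagnosisImage", labels = lab, classLevels = classLevels,
      nBcc = as.integer(nB), legend = legend)
}

#' Per-sample BCC decision
#'
#' A sample is called BCC-positive when the number of connected
#' BCC-labelled regions in the diagnosis image reaches the threshold
#' \code{nTh} (default 8).
#'
#' @param image a [DiagnosisImage-class].
#' @param nTh decision threshold on \code{N_BCC} (>= 1).
#' @return \code{"BCC-positive"} or \code{"BCC-negative"}.
#' @export
#' @examples
#' # N_BCC = 7 against a threshold of 8 stays negative
sampleDecision <- function(image, nTh = 8L) {
  stopifnot(nTh >= 1)
  if (nBcc(image) >= nTh) "BCC-positive" else "BCC-negative"
}
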