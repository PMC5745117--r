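# End-to-end measurement-and-diagnosis pipeline on a phantom (or on a
# measured image with a user-supplied sampler).

#' Run the full MSH pipeline
#'
#' Executes the automated chain: tissue masking on the raw image,
#' flat-field flattening within the mask, threshold optimisation with
#' the f_B objective, segmentation, variance/area-weighted point
#' allocation, placement (Config 2 by default), spectrum acquisition
#' (simulated from the phantom's annotation), SNR filtering, the
#' two-round segment diagnosis, assembly of the colour-coded diagnosis
#' image, and the per-sample decision at \code{nTh}.
#'
#' @param phantom a [Phantom-class]; its annotation drives the simulated
#'   Raman measurements.
#' @param classifier a trained [RamanClassifier-class].
#' @param config an [mshConfig()] list.
#' @param denoiseBasis optional [SpectraSet-class] PCA basis applied
#'   before classification.
#' @param models spectrum models for the simulated measurements.
#' @return a report list: \code{decision}, \code{nBcc},
#'   \code{nSegments}, \code{threshold}, per-segment \code{segments}
#'   data.frame, \code{log} of stage decisions, \code{configHash}, and
#'   the \code{diagnosisImage} / \code{segmap} objects.
#' @export
runPipeline <- function(phantom, classifier, config = mshConfig(),
                        denoiseBasis = NULL, models = spectrumModels()) {
  image <- phantom@image
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  mask <- tissueMask(image, config$backgroundThreshold)
  note("tissue mask: %d px", sum(mask))

  sigma <- config$flattenSigma %||% (ncol(intensities(image)) / 10)
  flat <- flattenImage(image, sigma = sigma, mask = mask)

  opt <- optimizeThreshold(flat, mask, kind = "f_B",
    gridSize = config$gridSize, minSegmentArea = config$minSegmentArea,
    connectivity = config$connectivity)
  segmap <- segmentAtThreshold(flat, mask, opt$threshold,
    minSegmentArea = config$minSegmentArea,
    connectivity = config$connectivity)
  note("segmentation: %d segments at threshold %.4g",
       nSegments(segmap), opt$threshold)

  if (nSegments(segmap) == 0) {
    dx <- assembleDiagnosis(list(), segmap, mask)
    return(list(decision = sampleDecision(dx, config$nTh), nBcc = 0L,
      nSegments = 0L, threshold = opt$threshold,
      segments = data.frame(), log = logLines, configHash = config$hash,
      nTh = config$nTh, diagnosisImage = dx, segmap = segmap))
  }

  plan <- buildSamplingPlan(segmap, flat, nMin = config$nMin,
    nTotal = config$nTotal, config = config$placement,
    seed = config$placeSeed)
  note("sampling plan: %d points over %d segments", nrow(plan),
       nSegments(segmap))

  measureAt <- function(pts, seedBase) {
    sets <- lapply(seq_len(nrow(pts)), function(j)
      simulateMeasurement(phantom, c(pts[j, "row"], pts[j, "col"]),
        targetSnr = config$targetSnr,
        seed = seedBase + j, models = models))
    do.call(bindSpectra, sets)
  }

  segLab <- segmentLabels(segmap)
  diagnoses <- vector("list", nSegments(segmap))
  for (i in seq_len(nSegments(segmap))) {
    sub <- plan[plan$segmentId == i, , drop = FALSE]
    if (nrow(sub) == 0) {  # budget exhausted before this segment
      note("segment %d: no sampling budget, Unclassified", i)
      diagnoses[[i]] <- new("SegmentDiagnosis", segmentId = i,
        status = "Unclassified", label = NA_character_,
        points = data.frame())
      next
    }
    s1 <- measureAt(sub, config$spectraSeed + i * 1013L)
    d <- diagnoseSegmentRound1(s1, sub[, c("row", "col")], classifier,
      segmentId = i, snrMin = config$snrMin,
      denoiseBasis = denoiseBasis)
    if (d@status == "round2") {
      note("segment %d: second round", i)
      segPx <- whichPixels(segLab == i)
      d <- runRound2(d, segPx,
        sampler = function(pts)
          measureAt(as.data.frame(pts),
                    config$spectraSeed + 500000L + i * 1013L),
        classifier = classifier, round1Spectra = s1,
        snrMin = config$snrMin, denoiseBasis = denoiseBasis,
        seed = config$placeSeed + i)
    }
    diagnoses[[i]] <- d
  }

  dx <- assembleDiagnosis(diagnoses, segmap, mask)
  decision <- sampleDecision(dx, config$nTh)
  note("N_BCC = %d, decision %s", nBcc(dx), decision)

  segSummary <- data.frame(
    segmentId = vapply(diagnoses, function(d) d@segmentId, integer(1)),
    status = vapply(diagnoses, function(d) d@status, character(1)),
    label = vapply(diagnoses, function(d)
      if (is.na(d@label)) d@status else d@label, character(1)),
    nPoints = vapply(diagnoses, function(d) nrow(d@points), integer(1)),
    nRetained = vapply(diagnoses, function(d) sum(d@points$retained),
                       integer(1)))

  list(decision = decision, nBcc = nBcc(dx),
       nSegments = nSegments(segmap), threshold = opt$threshold,
       nTh = config$nTh, segments = segSummary, log = logLines,
       configHash = config$hash, diagnosisImage = dx, segmap = segmap)
}
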