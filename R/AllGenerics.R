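#' @rdname AFImage-class
#' @param object,x an object.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname AFImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname SpectraSet-class
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet-class
#' @export
setGeneric("spectraMeta", function(x) standardGeneric("spectraMeta"))

#' @rdname SpectraSet-class
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' @rdname SegmentMap-class
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname SegmentMap-class
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname SegmentMap-class
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname DiagnosisImage-class
#' @export
setGeneric("nBcc", function(x) standardGeneric("nBcc"))

#' @rdname AnnotationMask-class
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

# ---- accessors ----

#' @rdname AFImage-class
#' @export
setMethod("intensities", "AFImage", function(x) x@intensities)

#' @rdname AFImage-class
#' @export
setMethod("pixelSize", "AFImage", function(x) x@pixelSize)

#' @rdname AFImage-class
#' @export
setMethod("dim", "AFImage", function(x) dim(x@intensities))

#' @rdname AnnotationMask-class
#' @export
setMethod("maskLabels", "AnnotationMask", function(x) x@labels)

#' @rdname AnnotationMask-class
#' @export
setMethod("levels", "AnnotationMask", function(x) x@levels)

#' @rdname SpectraSet-class
#' @export
setMethod("intensities", "SpectraSet", function(x) x@intensities)

#' @rdname SpectraSet-class
#' @export
setMethod("wavenumbers", "SpectraSet", function(x) x@wavenumbers)

#' @rdname SpectraSet-class
#' @export
setMethod("spectraMeta", "SpectraSet", function(x) x@meta)

#' @rdname SpectraSet-class
#' @export
setMethod("nSpectra", "SpectraSet", function(x) nrow(x@intensities))

#' Subset a SpectraSet by spectrum index
#' @param x a [SpectraSet-class].
#' @param i spectrum indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SpectraSet", function(x, i, j, ..., drop = FALSE) {
  new("SpectraSet", wavenumbers = x@wavenumbers,
      intensities = x@intensities[i, , drop = FALSE],
      meta = x@meta[i, , drop = FALSE])
})

#' @rdname SegmentMap-class
#' @export
setMethod("segmentLabels", "SegmentMap", function(x) x@labels)

#' @rdname SegmentMap-class
#' @export
setMethod("segmentTable", "SegmentMap", function(x) x@table)

#' @rdname SegmentMap-class
#' @export
setMethod("nSegments", "SegmentMap", function(x) nrow(x@table))

#' @rdname DiagnosisImage-class
#' @export
setMethod("nBcc", "DiagnosisImage", function(x) x@nBcc)

#' @rdname DiagnosisImage-class
#' @export
setMethod("levels", "DiagnosisImage", function(x) x@classLevels)

#' @rdname DiagnosisImage-class
#' @export
setMethod("maskLabels", "DiagnosisImage", function(x) x@labels)

# ---- show methods ----

setMethod("show", "AFImage", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("AFImage: %d x %d px at %.1f um/px (%.1f x %.1f mm)\n",
      d[1], d[2], object@pixelSize,
      d[1] * object@pixelSize / 1000, d[2] * object@pixelSize / 1000))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
      min(object@intensities), max(object@intensities)))
})

setMethod("show", "Phantom", function(object) {
  show(object@image)
  tab <- table(factor(object@mask@labels,
      levels = seq_along(object@mask@levels) - 1L,
      labels = object@mask@levels))
  cat("  mask pixels:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "SegmentMap", function(object) {
  cat(sprintf("SegmentMap: %d segments at threshold %.4g (%d-connectivity)\n",
      nrow(object@table), object@thresholdUsed, object@connectivity))
  if (nrow(object@table) > 0)
    cat(sprintf("  area %.3g-%.3g mm2\n",
        min(object@table$areaMm2), max(object@table$areaMm2)))
})

setMethod("show", "SpectraSet", function(object) {
  cat(sprintf("SpectraSet: %d spectra, %d points (%.0f-%.0f cm-1)\n",
      nrow(object@intensities), length(object@wavenumbers),
      min(object@wavenumbers), max(object@wavenumbers)))
  if ("class" %in% names(object@meta)) {
    tab <- table(object@meta$class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "RamanClassifier", function(object) {
  cat(sprintf(
    "RamanClassifier: %d features -> %d hidden -> %d classes (seed %d)\n",
    nrow(object@bands), object@hidden, length(object@classes), object@seed))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = true, cols = predicted):\n")
  print(object@counts)
  cat("sensitivity:", paste(names(object@sensitivity),
      sprintf("%.3f", object@sensitivity), sep = "=", collapse = ", "), "\n")
  cat("specificity:", paste(names(object@specificity),
      sprintf("%.3f", object@specificity), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "DiagnosisImage", function(object) {
  cat(sprintf("DiagnosisImage: %d x %d px, N_BCC = %d\n",
      nrow(object@labels), ncol(object@labels), object@nBcc))
})

setMethod("show", "PerformanceInputs", function(object) {
  cat(sprintf(
    paste0("PerformanceInputs: hit=%.3f se=%.3f sp=%.3f | %d spectra/segment,",
           " >=%d BCC rule | %d BCC + %d non-BCC segments, N_th=%d\n"),
    object@hitRate, object@se, object@sp, object@nSpectra, object@minBcc,
    object@nBccSegments, object@nNonBccSegments, object@nTh))
})
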