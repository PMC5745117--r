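#' @import methods
NULL

#' Auto-fluorescence image
#'
#' A wide-field auto-fluorescence (AF) intensity image of a resected skin
#' sample. Intensities are in arbitrary units; tumour regions appear darker
#' than the surrounding stroma, which is what the downstream segmentation
#' exploits.
#'
#' @slot intensities numeric matrix of non-negative, finite intensities
#'   (rows x cols, row-major pixel grid).
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @export
setClass("AFImage",
  representation(intensities = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    x <- object@intensities
    if (!is.numeric(x)) return("intensities must be numeric")
    if (any(!is.finite(x))) return("intensities must be finite")
    if (any(x < 0)) return("intensities must be non-negative")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  })

#' Per-pixel tissue annotation mask
#'
#' Integer-coded per-pixel tissue classes aligned with an [AFImage-class].
#' Level names map integer codes (0-based, 0 = first level) onto classes;
#' phantoms use \code{c("background","stroma","BCC","dye")}.
#'
#' @slot labels integer matrix of class codes.
#' @slot levels character vector naming the codes; code i maps to
#'   \code{levels[i + 1]}.
#' @export
setClass("AnnotationMask",
  representation(labels = "matrix", levels = "character"),
  validity = function(object) {
    if (!is.numeric(object@labels)) return("labels must be integer-valued")
    rng <- range(object@labels)
    if (rng[1] < 0 || rng[2] >= length(object@levels))
      return("label codes must index into levels")
    TRUE
  })

#' Phantom generator configuration
#'
#' Parameters of the synthetic AF phantom: a bright textured stroma disc on a
#' dark background, with darker tumour blobs and an optional dye arc along
#' the tissue boundary. The tumour-darker-than-stroma ordering is a class
#' invariant because it is the physical contrast the segmentation relies on.
#'
#' @slot imageShape integer(2), rows and columns in pixels.
#' @slot pixelSize micrometres per pixel.
#' @slot stromaMean,tumourMean,backgroundMean mean intensities (arbitrary
#'   units) with \code{backgroundMean < tumourMean < stromaMean}.
#' @slot textureSd intensity standard deviation of the multiplicative
#'   stroma texture field.
#' @slot nTumourBlobs number of tumour blobs.
#' @slot blobRadiusRange micrometres, min and max blob radius.
#' @slot blobShape \code{"micronodular"} (unions of overlapping discs) or
#'   \code{"infiltrative"} (thin curved strands).
#' @slot rimWidthPx width (pixels) of the bright condensed-stroma rim
#'   drawn around each tumour blob (peritumoral stromal reaction); 0
#'   disables it.
#' @slot dyeFraction fraction of the tissue boundary marked with dye.
#' @slot seed integer seed; phantoms are pure functions of the config.
#' @export
setClass("PhantomConfig",
  representation(imageShape = "integer", pixelSize = "numeric",
    stromaMean = "numeric", tumourMean = "numeric",
    backgroundMean = "numeric", textureSd = "numeric",
    nTumourBlobs = "integer", blobRadiusRange = "numeric",
    blobShape = "character", rimWidthPx = "numeric",
    dyeFraction = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
      return("imageShape must be two dimensions of at least 16 pixels")
    if (object@tumourMean >= object@stromaMean)
      return("tumourMean must be below stromaMean (tumour is darker)")
    if (object@backgroundMean >= object@tumourMean)
      return("backgroundMean must be below tumourMean")
    if (object@nTumourBlobs < 0L) return("nTumourBlobs must be >= 0")
    if (any(object@blobRadiusRange <= 0)) return("blob radii must be > 0")
    if (diff(object@blobRadiusRange) < 0)
      return("blobRadiusRange must be increasing")
    if (!object@blobShape %in% c("micronodular", "infiltrative"))
      return("blobShape must be 'micronodular' or 'infiltrative'")
    if (object@rimWidthPx < 0) return("rimWidthPx must be >= 0")
    if (object@dyeFraction < 0 || object@dyeFraction > 1)
      return("dyeFraction must be in [0, 1]")
    TRUE
  })

#' Synthetic phantom (image + annotation)
#'
#' @slot image the generated [AFImage-class].
#' @slot mask the matching [AnnotationMask-class].
#' @slot config the [PhantomConfig-class] that produced it.
#' @export
setClass("Phantom",
  representation(image = "AFImage", mask = "AnnotationMask",
                 config = "PhantomConfig"))

#' Segment map
#'
#' Labelled partition of below-threshold tissue pixels into connected
#' segments, the spatial unit to which Raman sampling points are allocated
#' and a diagnosis label is ultimately assigned.
#'
#' @slot labels integer matrix, 0 = not in any segment, 1..k = segment id.
#' @slot table data.frame with one row per segment: \code{id},
#'   \code{areaPx}, \code{areaMm2}, \code{variance} (intensity variance),
#'   \code{centroidRow}, \code{centroidCol}.
#' @slot thresholdUsed the intensity threshold that produced the map.
#' @slot connectivity 4 or 8.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("SegmentMap",
  representation(labels = "matrix", table = "data.frame",
    thresholdUsed = "numeric", connectivity = "integer",
    pixelSize = "numeric"),
  validity = function(object) {
    k <- nrow(object@table)
    if (k > 0 && !identical(object@table$id, seq_len(k)))
      return("segment ids must be contiguous 1..k")
    if (max(c(0L, object@labels)) != k)
      return("labels must match the segment table")
    if (!object@connectivity %in% c(4L, 8L))
      return("connectivity must be 4 or 8")
    TRUE
  })

#' A set of Raman spectra
#'
#' Spectra share a common ascending wavenumber axis; after resampling this
#' is the standard 400-1800 cm^-1 grid at 2 cm^-1 spacing (701 points).
#'
#' @slot wavenumbers numeric, ascending, cm^-1.
#' @slot intensities numeric matrix, one spectrum per row.
#' @slot meta data.frame of per-spectrum metadata (same number of rows).
#' @export
setClass("SpectraSet",
  representation(wavenumbers = "numeric", intensities = "matrix",
                 meta = "data.frame"),
  validity = function(object) {
    if (ncol(object@intensities) != length(object@wavenumbers))
      return("intensities columns must match wavenumbers")
    if (is.unsorted(object@wavenumbers, strictly = TRUE))
      return("wavenumbers must be strictly ascending")
    if (nrow(object@meta) != nrow(object@intensities))
      return("meta rows must match spectra")
    TRUE
  })

#' Tissue classifier (13-feature neural network)
#'
#' Single-hidden-layer network (13 band-area inputs, 20 hidden nodes,
#' 5 softmax outputs over BCC, dermis, fat, EMI, dye) with its training
#' seed and band table, so classification is reproducible.
#'
#' @slot fit the fitted \code{nnet} object.
#' @slot classes class levels in output order.
#' @slot bands band definition data.frame (\code{centre}, \code{halfWidth}).
#' @slot hidden hidden-layer size.
#' @slot seed training seed.
#' @export
setClass("RamanClassifier",
  representation(fit = "ANY", classes = "character", bands = "data.frame",
                 hidden = "integer", seed = "integer"))

#' Cross-validation confusion matrix
#'
#' @slot counts counts matrix, rows = true class, columns = predicted.
#' @slot sensitivity,specificity named per-class one-vs-rest rates.
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", sensitivity = "numeric",
                 specificity = "numeric"),
  validity = function(object) {
    if (any(object@sensitivity < 0 | object@sensitivity > 1, na.rm = TRUE))
      return("sensitivities must lie in [0,1]")
    if (any(object@specificity < 0 | object@specificity > 1, na.rm = TRUE))
      return("specificities must lie in [0,1]")
    TRUE
  })

#' Per-segment diagnosis state
#'
#' Result of the two-round segment diagnosis. \code{status} is one of
#' \code{"Unclassified"} (more than 80\% of round-1 spectra discarded),
#' \code{"label"} (whole-segment label in \code{label}), \code{"split"}
#' (finalise by nearest-neighbour splitting over the retained labelled
#' points), or \code{"round2"} (awaiting the second round).
#'
#' @slot segmentId integer segment id.
#' @slot status character, see above.
#' @slot label whole-segment label when \code{status == "label"}.
#' @slot points data.frame of sampling points: \code{row}, \code{col},
#'   \code{round}, \code{snr}, \code{retained}, \code{class}.
#' @export
setClass("SegmentDiagnosis",
  representation(segmentId = "integer", status = "character",
                 label = "character", points = "data.frame"),
  validity = function(object) {
    if (!object@status %in% c("Unclassified", "label", "split", "round2"))
      return("unknown status")
    TRUE
  })

#' MSH diagnosis image
#'
#' Per-pixel tissue-class labels over the tissue mask, the number of
#' connected BCC-labelled regions, and the colour legend used for display.
#'
#' @slot labels integer matrix coded by \code{classLevels} (0 = background).
#' @slot classLevels character; code i maps to \code{classLevels[i + 1]}.
#' @slot nBcc number of connected BCC regions (8-connectivity).
#' @slot legend named character vector of display colours.
#' @export
setClass("DiagnosisImage",
  representation(labels = "matrix", classLevels = "character",
                 nBcc = "integer", legend = "character"),
  validity = function(object) {
    rng <- range(object@labels)
    if (rng[1] < 0 || rng[2] >= length(object@classLevels))
      return("label codes must index into classLevels")
    if (object@nBcc < 0L) return("nBcc must be >= 0")
    TRUE
  })

#' Inputs of the binomial decision model
#'
#' The per-spectrum and geometry parameters from which per-segment and
#' per-sample operating characteristics are derived analytically: tumour
#' hit rate \code{hitRate}, per-spectrum sensitivity/specificity, number
#' of spectra per segment (5), the at-least-\code{minBcc} rule (2), the
#' number of BCC and non-BCC segments, and the decision threshold
#' \code{nTh} on the count of BCC-labelled regions.
#'
#' @slot hitRate,se,sp probabilities in [0, 1].
#' @slot nSpectra,minBcc,nBccSegments,nNonBccSegments,nTh integer counts.
#' @export
setClass("PerformanceInputs",
  representation(hitRate = "numeric", se = "numeric", sp = "numeric",
    nSpectra = "integer", minBcc = "integer", nBccSegments = "integer",
    nNonBccSegments = "integer", nTh = "integer"),
  validity = function(object) {
    pr <- c(object@hitRate, object@se, object@sp)
    if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0,1]")
    if (object@minBcc > object@nSpectra)
      return("minBcc cannot exceed nSpectra")
    if (object@nSpectra < 1L || object@nTh < 1L)
      return("nSpectra and nTh must be >= 1")
    if (object@nBccSegments < 0L || object@nNonBccSegments < 0L)
      return("segment counts must be >= 0")
    TRUE
  })
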