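# Five-class tissue classifier (BCC, dermis, fat, EMI, dye) on the
# 13 band-area features, plus k-means annotation maps for raster scans.

#' Train the tissue neural network
#'
#' Single-hidden-layer network (default 20 hidden nodes) with softmax
#' outputs over the tissue classes, fitted on unit-normed 13-band
#' feature vectors. Class imbalance is handled with inverse-frequency
#' case weights; weight decay provides light regularisation. Training is
#' deterministic for a fixed seed.
#'
#' @param features numeric matrix (spectra x 13 features).
#' @param labels class labels (character or factor), at least 2 classes.
#' @param hidden hidden-layer size (default 20).
#' @param seed training seed.
#' @param decay L2 weight decay (default 1e-3).
#' @param maxit maximum optimiser iterations.
#' @param bands band table recorded with the model.
#' @return a [RamanClassifier-class].
#' @export
trainAnn <- function(features, labels, hidden = 20L, seed = 1L,
                     decay = 1e-3, maxit = 500L, bands = defaultBands()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("training needs at least two classes")
  stopifnot(nrow(features) == length(labels))
  freq <- table(labels)
  w <- as.numeric(1 / freq[labels])
  w <- w * length(labels) / sum(w)
  fit <- withr::with_seed(as.integer(seed),
    nnet::nnet(x = features, y = nnet::class.ind(labels),
               size = hidden, softmax = TRUE, decay = decay,
               maxit = maxit, weights = w, trace = FALSE,
               MaxNWts = 10000L))
  new("RamanClassifier", fit = fit, classes = levels(labels),
      bands = bands, hidden = as.integer(hidden), seed = as.integer(seed))
}

#' Classify feature vectors
#'
#' @param model a [RamanClassifier-class].
#' @param features numeric matrix (spectra x 13) or a single vector.
#' @return list with \code{class} (factor) and \code{prob} (matrix of
#'   class probabilities, rows summing to 1).
#' @export
classify <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != nrow(model@bands))
    stop("feature dimensionality (", ncol(features), ") does not match ",
         "the model (", nrow(model@bands), ")")
  prob <- predict(model@fit, features, type = "raw")
  prob <- prob / rowSums(prob)
  cls <- factor(model@classes[max.col(prob, ties.method = "first")],
                levels = model@classes)
  list(class = cls, prob = prob)
}

#' Patient-grouped k-fold cross-validation
#'
#' Whole groups (patients) are assigned to folds so no group ever appears
#' in both a training and a test fold. Returns the aggregated confusion
#' matrix with one-vs-rest per-class sensitivity and specificity.
#'
#' @param features numeric matrix (spectra x 13).
#' @param labels class labels.
#' @param groupIds grouping unit (patient id) per spectrum.
#' @param k number of folds (default 5); needs at least k groups.
#' @param seed fold-assignment and training seed.
#' @param ... passed to [trainAnn()].
#' @return a [ConfusionMatrix-class].
#' @export
crossValidate <- function(features, labels, groupIds, k = 5L, seed = 1L,
                          ...) {
  labels <- factor(labels)
  groups <- unique(groupIds)
  if (k < 2) stop("k must be at least 2")
  if (length(groups) < k)
    stop("only ", length(groups), " groups for ", k, " folds")
  foldOf <- stats::setNames(rep(seq_len(k), length.out = length(groups)),
    withr::with_seed(as.integer(seed), sample(groups)))
  counts <- matrix(0L, nlevels(labels), nlevels(labels),
                   dimnames = list(levels(labels), levels(labels)))
  for (f in seq_len(k)) {
    test <- foldOf[as.character(groupIds)] == f
    fit <- trainAnn(features[!test, , drop = FALSE], labels[!test],
                    seed = seed + f, ...)
    pred <- classify(fit, features[test, , drop = FALSE])$class
    pred <- factor(as.character(pred), levels = levels(labels))
    tab <- table(labels[test], pred)
    counts <- counts + as.matrix(tab)
  }
  confusionFromCounts(counts)
}

#' Build a ConfusionMatrix with one-vs-rest metrics from counts
#'
#' @param counts square counts matrix, rows = true, cols = predicted.
#' @return a [ConfusionMatrix-class].
#' @export
confusionFromCounts <- function(counts) {
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  tot <- sum(counts)
  sens <- diag(counts) / rowSums(counts)
  fp <- colSums(counts) - diag(counts)
  tn <- tot - rowSums(counts) - colSums(counts) + diag(counts)
  spec <- tn / (tn + fp)
  new("ConfusionMatrix", counts = counts,
      sensitivity = sens, specificity = spec)
}

#' k-means annotation map of a raster scan
#'
#' Clusters the spectra of a rectangular raster into k groups of similar
#' spectra and returns the cluster-index image, the visual scaffold used
#' to annotate spectra against adjacent histology.
#'
#' @param raster 3-D array (rows, cols, spectral points).
#' @param k number of clusters (>= 2 and <= number of spectra; k = 1 is
#'   allowed and returns a single cluster).
#' @param seed seed for the k-means initialisation.
#' @param nstart random restarts (default 5).
#' @return list with \code{labels} (integer matrix rows x cols) and
#'   \code{centers} (k x spectral points).
#' @export
kmeansAnnotationMap <- function(raster, k, seed = 1L, nstart = 5L) {
  if (!is.array(raster) || length(dim(raster)) != 3)
    stop("raster must be a 3-D array")
  d <- dim(raster)
  X <- matrix(raster, d[1] * d[2], d[3])
  if (k > nrow(X)) stop("k exceeds the number of spectra")
  if (k == 1) {
    return(list(labels = matrix(1L, d[1], d[2]),
                centers = matrix(colMeans(X), 1)))
  }
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100))
  list(labels = matrix(km$cluster, d[1], d[2]), centers = km$centers)
}
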