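# Spectral preprocessing: resampling to the standard grid, cosmic-ray
# removal, the SNR statistic, SNR filtering, 3x3 raster averaging, band
# areas with local linear baselines, unit-normed features, PCA denoising.

#' The 13 standard band definitions
#'
#' Band centres (cm^-1) used as classifier features: 675, 680, 786, 870,
#' 906, 944, 952, 1092, 1144, 1298, 1376, 1528, 1744. Integration windows
#' are centre +/- 8 cm^-1, except the adjacent 675 and 680 bands which
#' use +/- 3 cm^-1 so their windows stay disjoint.
#'
#' @return data.frame with \code{centre} and \code{halfWidth}.
#' @export
defaultBands <- function() {
  centre <- c(675, 680, 786, 870, 906, 944, 952, 1092, 1144, 1298, 1376,
              1528, 1744)
  data.frame(centre = centre,
             halfWidth = ifelse(centre %in% c(675, 680), 3, 8))
}

#' Resample spectra onto the standard grid
#'
#' Linear interpolation onto the 400-1800 cm^-1 grid at 2 cm^-1 spacing
#' (701 points). The input must cover the full range.
#'
#' @param s a [SpectraSet-class] on an arbitrary ascending axis.
#' @return a [SpectraSet-class] on the standard grid.
#' @export
resampleSpectrum <- function(s) {
  wn <- wavenumbers(s)
  grid <- ramanGrid()
  if (min(wn) > 400 || max(wn) < 1800)
    stop(sprintf("spectrum covers %.0f-%.0f cm^-1; missing part of 400-1800",
                 min(wn), max(wn)))
  y <- intensities(s)
  out <- t(apply(y, 1, function(v) approx(wn, v, xout = grid)$y))
  newSpectraSet(grid, out, spectraMeta(s))
}

#' Remove cosmic-ray spikes
#'
#' Isolated positive spikes (runs of at most 2 points exceeding the
#' 7-point running median by more than 5 median absolute deviations of
#' the residual) are replaced by the median-filtered value; everything
#' else is untouched, so genuine Raman bands (4 or more points wide) are
#' preserved.
#'
#' @param s a resampled [SpectraSet-class].
#' @param window median-filter window (odd, default 7).
#' @param nMad spike threshold in residual MADs (default 5).
#' @param maxWidth maximum spike width in points (default 2).
#' @return a [SpectraSet-class] with spikes replaced.
#' @export
removeCosmicRays <- function(s, window = 7L, nMad = 5, maxWidth = 2L) {
  y <- intensities(s)
  out <- y
  for (i in seq_len(nrow(y))) {
    v <- y[i, ]
    med <- stats::runmed(v, window, endrule = "median")
    resid <- v - med
    madv <- stats::mad(resid)
    if (madv == 0) next
    flag <- resid > nMad * madv
    if (!any(flag)) next
    runs <- rle(flag)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values & runs$lengths <= maxWidth)) {
      idx <- starts[j]:ends[j]
      out[i, idx] <- med[idx]
    }
  }
  newSpectraSet(wavenumbers(s), out, spectraMeta(s))
}

#' Signal-to-noise ratio of spectra
#'
#' SNR = (height of the CH2 peak near 1450 cm^-1 above the local linear
#' baseline through the window endpoints) / (root-mean-square residual of
#' a linear fit over the empty 1750-1800 cm^-1 region). The detrended
#' noise estimate makes the statistic invariant to affine intensity
#' transforms with positive scale.
#'
#' @param s a resampled [SpectraSet-class].
#' @param peakCentre,halfWindow CH2 window, default 1450 +/- 20 cm^-1.
#' @param noiseRange empty region, default c(1750, 1800).
#' @return numeric vector of SNR values; \code{Inf} where the noise
#'   region is exactly linear.
#' @export
computeSnr <- function(s, peakCentre = 1450, halfWindow = 20,
                       noiseRange = c(1750, 1800)) {
  wn <- wavenumbers(s)
  y <- intensities(s)
  win <- which(wn >= peakCentre - halfWindow & wn <= peakCentre + halfWindow)
  i1 <- win[1]; i2 <- win[length(win)]
  frac <- (wn[win] - wn[i1]) / (wn[i2] - wn[i1])
  base <- outer(y[, i1], 1 - frac) + outer(y[, i2], frac)
  signal <- apply(y[, win, drop = FALSE] - base, 1, max)

  nz <- which(wn >= noiseRange[1] & wn <= noiseRange[2])
  X <- cbind(1, wn[nz])
  hat <- X %*% solve(crossprod(X), t(X))
  residm <- y[, nz, drop = FALSE] -
    y[, nz, drop = FALSE] %*% t(hat)
  noise <- sqrt(rowMeans(residm^2))
  # an exactly linear noise region leaves only rounding error
  eps <- 1e-10 * (apply(abs(y[, nz, drop = FALSE]), 1, max) + 1e-300)
  snr <- ifelse(noise <= eps, Inf, signal / noise)
  unname(snr)
}

#' Partition spectra by an SNR threshold
#'
#' @param s a [SpectraSet-class].
#' @param threshold positive SNR threshold (the training regime uses 15,
#'   validation 7, diagnosis rounds 4).
#' @param strict if TRUE retain only SNR strictly above the threshold
#'   (training rule); default retains SNR >= threshold.
#' @param ... passed to [computeSnr()].
#' @return list with \code{retained}, \code{discarded} (both
#'   [SpectraSet-class]) and the \code{snr} vector.
#' @export
snrFilter <- function(s, threshold, strict = FALSE, ...) {
  stopifnot(threshold > 0)
  snr <- computeSnr(s, ...)
  keep <- if (strict) snr > threshold else snr >= threshold
  list(retained = s[keep], discarded = s[!keep], snr = snr)
}

#' 3x3 moving-average filter over a raster of spectra
#'
#' Each raster position is replaced by the mean of the spectra in its
#' 3x3 neighbourhood; edge positions average the neighbours that exist.
#'
#' @param raster 3-D array (rows, cols, spectral points).
#' @return array of the same shape.
#' @export
movingAverage3x3 <- function(raster) {
  if (!is.array(raster) || length(dim(raster)) != 3)
    stop("raster must be a 3-D array (rows, cols, spectral points)")
  d <- dim(raster)
  acc <- array(0, d)
  cnt <- matrix(0, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    r1 <- max(1, 1 + dr):min(d[1], d[1] + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(d[2], d[2] + dc)
    c0 <- c1 - dc
    acc[r0, c0, ] <- acc[r0, c0, ] + raster[r1, c1, , drop = FALSE]
    cnt[r0, c0] <- cnt[r0, c0] + 1
  }
  sweep(acc, c(1, 2), cnt, "/")
}

#' Band area with local linear baseline subtraction
#'
#' Trapezoidal integral, over the band window, of the intensity minus the
#' straight line through the window's two endpoint intensities. The
#' baseline absorbs any linear trend and constant offset; the area may be
#' negative.
#'
#' @param s a resampled [SpectraSet-class].
#' @param centre band centre, cm^-1.
#' @param halfWidth half-width of the window, cm^-1.
#' @return numeric vector of areas (one per spectrum).
#' @export
bandArea <- function(s, centre, halfWidth) {
  wn <- wavenumbers(s)
  idx <- which(wn >= centre - halfWidth & wn <= centre + halfWidth)
  if (length(idx) < 3 || centre - halfWidth < min(wn) ||
      centre + halfWidth > max(wn))
    stop("band window ", centre, " +/- ", halfWidth,
         " lies outside the spectral grid")
  y <- intensities(s)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  frac <- (wn[idx] - wn[i1]) / (wn[i2] - wn[i1])
  base <- outer(y[, i1], 1 - frac) + outer(y[, i2], frac)
  f <- y[, idx, drop = FALSE] - base
  dx <- diff(wn[idx])
  # trapezoid with (possibly non-uniform) spacing
  mid <- (f[, -1, drop = FALSE] + f[, -ncol(f), drop = FALSE]) / 2
  unname(as.numeric(mid %*% dx))
}

#' Extract the unit-normed 13-band feature vectors
#'
#' Computes the 13 band areas of [defaultBands()] (or custom bands) and
#' normalises each spectrum's area vector to unit Euclidean norm, making
#' the features invariant to intensity scaling and constant offsets.
#'
#' @param s a resampled [SpectraSet-class].
#' @param bands band table (\code{centre}, \code{halfWidth}).
#' @param norm \code{"euclidean"} (default) or \code{"l1"}.
#' @return numeric matrix (spectra x bands), columns named by centre.
#' @export
extractFeatures <- function(s, bands = defaultBands(),
                            norm = c("euclidean", "l1")) {
  norm <- match.arg(norm)
  areas <- vapply(seq_len(nrow(bands)), function(i)
    bandArea(s, bands$centre[i], bands$halfWidth[i]),
    numeric(nSpectra(s)))
  if (nSpectra(s) == 1) areas <- matrix(areas, nrow = 1)
  nrm <- if (norm == "euclidean") sqrt(rowSums(areas^2))
         else rowSums(abs(areas))
  if (any(nrm == 0)) stop("featureless spectrum: all band areas are zero")
  out <- areas / nrm
  colnames(out) <- paste0("b", bands$centre)
  rownames(out) <- spectraMeta(s)$spectrumId
  out
}

#' PCA denoising against an independent basis set
#'
#' Projects each spectrum onto the top principal components of an
#' independent basis set (mean plus the projection of the centred
#' spectrum onto the component span). Projection is idempotent and the
#' residual is orthogonal to the retained components.
#'
#' @param s a [SpectraSet-class] to denoise.
#' @param basis a [SpectraSet-class] or matrix of basis spectra on the
#'   same grid; must contain at least \code{nComponents} spectra.
#' @param nComponents number of principal components (default 50).
#' @return a denoised [SpectraSet-class].
#' @export
pcaDenoise <- function(s, basis, nComponents = 50L) {
  B <- if (is(basis, "SpectraSet")) intensities(basis) else basis
  if (nrow(B) < nComponents)
    stop("basis set has ", nrow(B), " spectra; need at least ", nComponents)
  pc <- stats::prcomp(B, center = TRUE, scale. = FALSE, rank. = nComponents)
  V <- pc$rotation
  Y <- intensities(s)
  Yc <- sweep(Y, 2, pc$center)
  out <- sweep(Yc %*% V %*% t(V), 2, pc$center, "+")
  newSpectraSet(wavenumbers(s), out, spectraMeta(s))
}
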