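# Internal helpers shared across modules.

# Standard Raman grid: 400-1800 cm^-1 at 2 cm^-1 spacing, 701 points.
ramanGrid <- function() seq(400, 1800, by = 2)

# Connected-component labelling (union-find, compiled); fg is a logical
# matrix, connectivity 4 or 8. Returns an integer label matrix 1..k.
ccLabel <- function(fg, connectivity = 8L) {
  stopifnot(is.matrix(fg), connectivity %in% c(4L, 8L))
  .ccLabelCpp(fg, as.integer(connectivity))
}

# Masked Gaussian blur: conv(x * w) / conv(w) with a separable kernel.
gaussBlurMasked <- function(x, w, sigma) {
  .gaussBlurMaskedCpp(x, w, sigma)
}

# pixel coordinates (row, col) of TRUE entries, row-major pixel centres
whichPixels <- function(m) {
  idx <- which(m)
  cbind(row = (idx - 1L) %% nrow(m) + 1L,
        col = (idx - 1L) %/% nrow(m) + 1L)
}

newAFImage <- function(intensities, pixelSize) {
  new("AFImage", intensities = intensities, pixelSize = pixelSize)
}

newSpectraSet <- function(wavenumbers, intensities, meta = NULL) {
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, nrow = 1)
  if (is.null(meta))
    meta <- data.frame(spectrumId = seq_len(nrow(intensities)))
  new("SpectraSet", wavenumbers = wavenumbers, intensities = intensities,
      meta = meta)
}

# Combine SpectraSets sharing a wavenumber axis.
bindSpectra <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  stopifnot(length(sets) > 0)
  wn <- sets[[1]]@wavenumbers
  for (s in sets) stopifnot(isTRUE(all.equal(s@wavenumbers, wn)))
  metas <- lapply(sets, function(s) s@meta)
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (cc in setdiff(cols, names(m))) m[[cc]] <- NA
    m[cols]
  })
  new("SpectraSet", wavenumbers = wn,
      intensities = do.call(rbind, lapply(sets, function(s) s@intensities)),
      meta = do.call(rbind, metas))
}
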