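#' Stylised Raman spectrum models for the five tissue classes
#'
#' Each model is a set of Gaussian bands on a weak linear baseline. The
#' band positions follow the class-characteristic features of skin Raman
#' spectra: BCC carries the intense DNA bands at 788 and 1098 cm^-1;
#' dermis is dominated by collagen bands near 851/950 cm^-1 and the
#' amide III region; fat by lipid bands including the 1745 cm^-1 ester
#' carbonyl; the EMI class (epidermis + muscle + inflammation) by
#' protein bands; and the surgical marker dye by its specific bands at
#' 680, 748, 1144 and 1528 cm^-1. Every tissue class carries the CH2
#' deformation band at ~1450 cm^-1 so that the SNR statistic is defined;
#' dye does not.
#'
#' Heights, widths and baselines are a deliberately stylised design: they
#' make the classes separable through the 13 standard band-area features
#' while leaving realistic overlap (EMI and dermis are closest), and are
#' not fitted to any measured spectra.
#'
#' @return named list of models, each a list with \code{className},
#'   \code{bands} (data.frame \code{centre}, \code{height}, \code{sigma}),
#'   \code{baselineIntercept} and \code{baselineSlope}.
#' @export
#' @examples
#' names(spectrumModels())
spectrumModels <- function() {
  mk <- function(className, centre, height, sigma, b0 = 0.1, slope = 2e-4) {
    list(className = className,
         bands = data.frame(centre = centre, height = height, sigma = sigma),
         baselineIntercept = b0, baselineSlope = slope)
  }
  list(
    BCC = mk("BCC",
      centre = c(788, 1004, 1098, 1340, 1450, 1660),
      height = c(1.00, 0.30, 0.85, 0.30, 0.70, 0.50),
      sigma  = c(5, 3, 6, 8, 8, 10), slope = 3e-4),
    dermis = mk("dermis",
      centre = c(855, 876, 906, 938, 950, 1004, 1248, 1450, 1660),
      height = c(0.80, 0.50, 0.30, 0.60, 0.80, 0.25, 0.60, 0.55, 0.70),
      sigma  = c(6, 5, 5, 6, 6, 3, 10, 8, 10), slope = 2e-4),
    fat = mk("fat",
      centre = c(1066, 1130, 1296, 1440, 1650, 1740),
      height = c(0.40, 0.20, 0.90, 1.00, 0.45, 0.80),
      sigma  = c(6, 6, 6, 9, 8, 3.5), slope = 1e-4),
    EMI = mk("EMI",
      centre = c(757, 1004, 1250, 1336, 1378, 1450, 1615, 1660),
      height = c(0.20, 0.90, 0.50, 0.50, 0.45, 0.80, 0.25, 0.80),
      sigma  = c(5, 3, 10, 8, 6, 8, 6, 10), slope = 2.5e-4),
    dye = mk("dye",
      centre = c(680, 748, 1144, 1230, 1528, 1590),
      height = c(1.00, 0.90, 0.90, 0.30, 1.00, 0.40),
      sigma  = c(3, 4, 5, 6, 5, 6), slope = 4e-4)
  )
}

# Noise-free model spectrum on the standard grid.
cleanSpectrum <- function(model, wn = ramanGrid()) {
  y <- model$baselineIntercept + model$baselineSlope * (wn - 400)
  b <- model$bands
  for (i in seq_len(nrow(b)))
    y <- y + b$height[i] * exp(-0.5 * ((wn - b$centre[i]) / b$sigma[i])^2)
  y
}

# Baseline-subtracted peak height the SNR statistic would see on the clean
# spectrum; for dye (no CH2 band) the tallest model band is used instead.
cleanSignalHeight <- function(model) {
  if (model$className == "dye") return(max(model$bands$height))
  wn <- ramanGrid()
  y <- cleanSpectrum(model, wn)
  win <- wn >= 1430 & wn <= 1470
  i <- which(win)
  base <- approx(x = wn[c(min(i), max(i))], y = y[c(min(i), max(i))],
                 xout = wn[i])$y
  max(y[i] - base)
}

.snrCalCache <- new.env(parent = emptyenv())

# Noise SD such that the measured SNR statistic hits the target in
# expectation. The naive scale S/target reads high: the windowed max picks
# up positive noise excursions and the detrended rms slightly
# under-estimates the noise SD. A fixed-seed probe measures the bias at
# the naive scale and corrects the linear model
# E[SNR] = S/(c2 * sd) + c1/c2 (c2 from the residual degrees of freedom);
# results are memoised per (class, target).
noiseSdFor <- function(model, targetSnr) {
  S <- cleanSignalHeight(model)
  if (model$className == "dye") return(S / targetSnr)
  key <- paste(model$className, signif(targetSnr, 8))
  hit <- get0(key, envir = .snrCalCache)
  if (!is.null(hit)) return(hit)
  wn <- ramanGrid()
  clean <- cleanSpectrum(model, wn)
  sd0 <- S / targetSnr
  nNoise <- sum(wn >= 1750 & wn <= 1800)
  c2 <- sqrt((nNoise - 2) / nNoise)
  probe <- withr::with_seed(9931L, {
    mat <- matrix(rnorm(64 * length(wn), sd = sd0), 64, byrow = TRUE)
    mat <- sweep(mat, 2, clean, "+")
    mean(computeSnr(newSpectraSet(wn, mat)))
  })
  c1 <- c2 * probe - targetSnr
  out <- S / max(c2 * targetSnr - c1, targetSnr / 4)
  assign(key, out, envir = .snrCalCache)
  out
}

#' Generate one synthetic Raman spectrum
#'
#' Gaussian class bands plus a linear baseline plus white Gaussian noise.
#' The noise standard deviation is calibrated (deterministically, with a
#' fixed-seed probe) so that the SNR statistic of [computeSnr()] matches
#' \code{targetSnr} in expectation.
#'
#' @param model one element of [spectrumModels()].
#' @param targetSnr positive target signal-to-noise ratio.
#' @param seed integer seed; output is a pure function of
#'   \code{(model, targetSnr, seed)}.
#' @return a one-spectrum [SpectraSet-class] on the 701-point grid with
#'   metadata \code{class}, \code{targetSnr}, \code{seed}.
#' @export
#' @examples
#' s <- generateSpectrum(spectrumModels()$BCC, targetSnr = 15, seed = 1)
#' computeSnr(s)
generateSpectrum <- function(model, targetSnr, seed = 1L) {
  stopifnot(targetSnr > 0)
  wn <- ramanGrid()
  clean <- cleanSpectrum(model, wn)
  noiseSd <- noiseSdFor(model, targetSnr)
  y <- withr::with_seed(as.integer(seed),
                        clean + rnorm(length(wn), sd = noiseSd))
  newSpectraSet(wn, y,
    data.frame(spectrumId = paste0(model$className, "_", seed),
               class = model$className, targetSnr = targetSnr,
               seed = as.integer(seed)))
}

#' Generate a balanced labelled spectral library
#'
#' Equal numbers of spectra for all five classes, with synthetic patient
#' identifiers so that cross-validation can be grouped by patient.
#'
#' @param nPerClass spectra per class (>= 1).
#' @param snrRange range from which each spectrum's target SNR is drawn
#'   uniformly.
#' @param seed master seed.
#' @param nPatientsPerClass number of synthetic patients per class.
#' @param models list of spectrum models, default [spectrumModels()].
#' @return a [SpectraSet-class] with metadata \code{spectrumId},
#'   \code{patientId}, \code{class}, \code{targetSnr}.
#' @export
generateSpectralLibrary <- function(nPerClass, snrRange = c(15, 40),
                                    seed = 1L, nPatientsPerClass = 10L,
                                    models = spectrumModels()) {
  stopifnot(nPerClass >= 1, length(snrRange) == 2, all(snrRange > 0))
  classes <- names(models)
  draws <- withr::with_seed(as.integer(seed), {
    lapply(classes, function(cl) {
      data.frame(class = cl,
        patientId = sprintf("%s_pat%02d", cl,
          sample.int(nPatientsPerClass, nPerClass, replace = TRUE)),
        targetSnr = runif(nPerClass, snrRange[1], snrRange[2]),
        subSeed = sample.int(.Machine$integer.max - 1L, nPerClass))
    })
  })
  draws <- do.call(rbind, draws)
  wn <- ramanGrid()
  mat <- matrix(0, nrow(draws), length(wn))
  for (i in seq_len(nrow(draws))) {
    m <- models[[draws$class[i]]]
    clean <- cleanSpectrum(m, wn)
    noiseSd <- noiseSdFor(m, draws$targetSnr[i])
    mat[i, ] <- withr::with_seed(draws$subSeed[i],
                                 clean + rnorm(length(wn), sd = noiseSd))
  }
  meta <- data.frame(
    spectrumId = sprintf("lib_%05d", seq_len(nrow(draws))),
    patientId = draws$patientId, class = draws$class,
    targetSnr = draws$targetSnr)
  newSpectraSet(wn, mat, meta)
}

#' Simulate a Raman measurement at a phantom location
#'
#' Looks up the annotated tissue class under the pixel and emits a synthetic
#' spectrum of the matching spectral class (stroma maps to dermis). This is
#' the bridge that lets the full measurement-and-diagnosis pipeline run on
#' phantoms.
#'
#' @param phantom a [Phantom-class].
#' @param location integer c(row, col) pixel coordinate.
#' @param targetSnr target SNR of the simulated spectrum.
#' @param seed integer seed.
#' @param models spectrum models, default [spectrumModels()].
#' @return a one-spectrum [SpectraSet-class].
#' @export
simulateMeasurement <- function(phantom, location, targetSnr, seed = 1L,
                                models = spectrumModels()) {
  lab <- phantom@mask@labels
  r <- location[1]; c <- location[2]
  if (r < 1 || c < 1 || r > nrow(lab) || c > ncol(lab))
    stop("location outside the image")
  cls <- phantom@mask@levels[lab[r, c] + 1L]
  if (cls == "background")
    stop("location lies on background: no tissue to measure")
  spectralClass <- switch(cls, stroma = "dermis", BCC = "BCC", dye = "dye",
                          stop("no spectrum model for mask class ", cls))
  s <- generateSpectrum(models[[spectralClass]], targetSnr, seed)
  s@meta$row <- r
  s@meta$col <- c
  s@meta$maskClass <- cls
  s
}
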