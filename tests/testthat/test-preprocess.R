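grid701 <- RamanMSH:::ramanGrid()

test_that("resampling is exact for on-grid and linear inputs", {
  s <- RamanMSH:::newSpectraSet(grid701, sin(grid701 / 50))
  expect_equal(intensities(resampleSpectrum(s)), intensities(s))

  wn1 <- seq(398, 1802, by = 1)
  ramp <- RamanMSH:::newSpectraSet(wn1, 3 + 0.01 * wn1)
  out <- resampleSpectrum(ramp)
  expect_equal(as.numeric(intensities(out)), 3 + 0.01 * grid701)

  short <- RamanMSH:::newSpectraSet(seq(500, 1800, 2),
                                    numeric(651) + 1)
  expect_error(resampleSpectrum(short), "missing")
})

test_that("resampling matches a two-point interpolation oracle", {
  set.seed(3)
  wn <- sort(runif(900, 395, 1805))
  y <- cumsum(rnorm(900))
  s <- RamanMSH:::newSpectraSet(wn, y)
  out <- as.numeric(intensities(resampleSpectrum(s)))
  oracle <- vapply(grid701, function(x) {
    i <- max(which(wn <= x))
    if (wn[i] == x) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (x - wn[i]) / (wn[i + 1] - wn[i])
  }, numeric(1))
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("cosmic-ray removal strips narrow spikes and keeps bands", {
  set.seed(4)
  base <- 10 + 0.002 * grid701 + rnorm(701, sd = 0.05)
  spiked <- base
  spiked[350] <- spiked[350] + 5
  s <- RamanMSH:::newSpectraSet(grid701, spiked)
  out <- as.numeric(intensities(removeCosmicRays(s)))
  expect_lt(out[350], base[350] + 1)
  expect_equal(out[-350], spiked[-350])

  band <- 1 + exp(-0.5 * ((grid701 - 1000) / 10)^2)  # 5 points sigma
  sBand <- RamanMSH:::newSpectraSet(grid701, band)
  expect_equal(as.numeric(intensities(removeCosmicRays(sBand))), band)

  flat <- RamanMSH:::newSpectraSet(grid701, rep(2, 701))
  expect_equal(as.numeric(intensities(removeCosmicRays(flat))),
               rep(2, 701))
})

test_that("the SNR statistic reads height over detrended noise", {
  set.seed(5)
  # peak of baseline-subtracted height 15 over unit-SD noise: the
  # statistic should average ~15 over noise realisations
  mk <- function() 5 + 0.003 * grid701 + rnorm(701, sd = 1) +
    15 * exp(-0.5 * ((grid701 - 1450) / 6)^2)
  many <- RamanMSH:::newSpectraSet(grid701,
    t(vapply(1:20, function(i) mk(), numeric(701))))
  expect_equal(mean(computeSnr(many)), 15, tolerance = 0.12)

  # invariance under positive affine transforms
  y <- intensities(many)[1, ]
  s <- RamanMSH:::newSpectraSet(grid701, y)
  s10 <- RamanMSH:::newSpectraSet(grid701, 10 * y + 40)
  expect_equal(computeSnr(s10), computeSnr(s), tolerance = 1e-9)

  # pure noise: signal is a noise excursion, SNR small
  sN <- RamanMSH:::newSpectraSet(grid701, rnorm(701, sd = 1))
  expect_lt(computeSnr(sN), 5)

  # exactly linear noise region: flagged infinite
  sL <- RamanMSH:::newSpectraSet(grid701, 1 + 0.001 * grid701)
  expect_true(is.infinite(computeSnr(sL)))
})

test_that("SNR filtering partitions exactly at the threshold", {
  set.seed(6)
  targets <- c(2, 5, 10, 20, 30)
  s <- do.call(RamanMSH:::bindSpectra, lapply(seq_along(targets),
    function(i) generateSpectrum(spectrumModels()$dermis, targets[i],
                                 seed = i)))
  snr <- computeSnr(s)
  for (thr in c(4, 7, 15)) {
    f <- snrFilter(s, thr)
    expect_equal(nSpectra(f$retained), sum(snr >= thr))
    expect_equal(nSpectra(f$discarded), sum(snr < thr))
  }
  expect_equal(nSpectra(snrFilter(s, 1e-9)$retained), 5L)
  expect_equal(nSpectra(snrFilter(s, 1e9)$retained), 0L)
})

test_that("3x3 raster averaging matches the nested-loop oracle", {
  cons <- array(7, c(4, 4, 3))
  expect_equal(movingAverage3x3(cons), cons)

  imp <- array(0, c(5, 5, 2))
  imp[3, 3, ] <- 9
  out <- movingAverage3x3(imp)
  expect_equal(out[2:4, 2:4, 1], matrix(1, 3, 3))
  expect_equal(out[1, 1, 1], 0)

  set.seed(8)
  r <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  out <- movingAverage3x3(r)
  oracle <- array(0, dim(r))
  for (i in 1:5) for (j in 1:5) {
    ri <- max(1, i - 1):min(5, i + 1)
    rj <- max(1, j - 1):min(5, j + 1)
    for (k in 1:4) oracle[i, j, k] <- mean(r[ri, rj, k])
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(movingAverage3x3(matrix(1, 3, 3)), "3-D")
})

test_that("band areas subtract the local linear baseline", {
  lin <- RamanMSH:::newSpectraSet(grid701, 4 + 0.02 * grid701)
  for (b in seq_len(nrow(defaultBands())))
    expect_equal(bandArea(lin, defaultBands()$centre[b],
                          defaultBands()$halfWidth[b]), 0,
                 tolerance = 1e-10)

  # Gaussian of known area on a slope, wide window
  sig <- 4; h <- 2
  y <- 1 + 0.005 * grid701 + h * exp(-0.5 * ((grid701 - 900) / sig)^2)
  s <- RamanMSH:::newSpectraSet(grid701, y)
  expect_equal(bandArea(s, 900, 40), h * sig * sqrt(2 * pi),
               tolerance = 0.02)

  sOff <- RamanMSH:::newSpectraSet(grid701, y + 123)
  expect_equal(bandArea(sOff, 900, 40), bandArea(s, 900, 40),
               tolerance = 1e-9)

  expect_error(bandArea(s, 390, 8), "outside")
})

test_that("feature vectors are unit-normed and scale invariant", {
  s <- generateSpectrum(spectrumModels()$EMI, 20, seed = 9)
  f <- extractFeatures(s)
  expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-9)

  s3 <- RamanMSH:::newSpectraSet(grid701, 3 * intensities(s)[1, ])
  expect_equal(extractFeatures(s3), extractFeatures(s),
               tolerance = 1e-9, ignore_attr = TRUE)

  zero <- RamanMSH:::newSpectraSet(grid701, rep(1, 701))
  expect_error(extractFeatures(zero), "featureless")
})

test_that("PCA denoising is an orthogonal projection", {
  set.seed(10)
  basis <- matrix(rnorm(80 * 701), 80, 701)
  s <- RamanMSH:::newSpectraSet(grid701, matrix(rnorm(5 * 701), 5, 701))
  d1 <- pcaDenoise(s, basis, 50L)
  d2 <- pcaDenoise(d1, basis, 50L)
  expect_equal(intensities(d2), intensities(d1), tolerance = 1e-8)

  pc <- prcomp(basis, center = TRUE, rank. = 50)
  resid <- intensities(s) - intensities(d1)
  expect_lt(max(abs(resid %*% pc$rotation)), 1e-8)

  expect_error(pcaDenoise(s, basis[1:30, ], 50L), "at least 50")
})

test_that("white-noise variance shrinks by the subspace fraction", {
  set.seed(12)
  basis <- matrix(rnorm(120 * 701), 120, 701)
  noise <- matrix(rnorm(60 * 701), 60, 701)
  s <- RamanMSH:::newSpectraSet(grid701, noise)
  den <- intensities(pcaDenoise(s, basis, 50L))
  ratio <- mean(apply(den, 1, var)) / mean(apply(noise, 1, var))
  expect_equal(ratio, 50 / 701, tolerance = 0.25)
})
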