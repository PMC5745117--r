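# Analytic binomial model linking per-spectrum classifier performance to
# per-segment and per-sample operating characteristics, used to choose
# the decision threshold N_th.

#' Construct decision-model inputs
#'
#' Defaults are the model's reference operating point: hit rate 0.6,
#' per-spectrum sensitivity 81.8\% and specificity 96.3\%, 5 spectra per
#' segment with the at-least-2 rule, 150 non-BCC segments per sample,
#' and threshold \code{nTh = 8}.
#'
#' @param hitRate,se,sp per-spectrum probabilities.
#' @param nSpectra spectra per segment (default 5).
#' @param minBcc minimum BCC spectra to label a segment BCC (default 2).
#' @param nBccSegments BCC segments in the sample (default 1, the
#'   worst case).
#' @param nNonBccSegments non-BCC segments (default 150).
#' @param nTh decision threshold on the BCC-segment count.
#' @return a [PerformanceInputs-class].
#' @export
performanceInputs <- function(hitRate = 0.6, se = 0.818, sp = 0.963,
                              nSpectra = 5L, minBcc = 2L,
                              nBccSegments = 1L, nNonBccSegments = 150L,
                              nTh = 8L) {
  new("PerformanceInputs", hitRate = hitRate, se = se, sp = sp,
      nSpectra = as.integer(nSpectra), minBcc = as.integer(minBcc),
      nBccSegments = as.integer(nBccSegments),
      nNonBccSegments = as.integer(nNonBccSegments), nTh = as.integer(nTh))
}

#' Probability that a spectrum in a BCC segment is labelled BCC
#'
#' \code{p = h * se + (1 - h) * (1 - sp)}: the point either hits tumour
#' (probability \code{h}) and is correctly called BCC, or lands on the
#' healthy part of the segment and is falsely called BCC.
#'
#' @param h tumour hit rate.
#' @param se,sp per-spectrum sensitivity and specificity.
#' @return probability in [0, 1].
#' @export
#' @examples
#' perSpectrumBccProb(0.6, 0.818, 0.963)  # 0.5056
perSpectrumBccProb <- function(h, se, sp) {
  stopifnot(h >= 0, h <= 1, se >= 0, se <= 1, sp >= 0, sp <= 1)
  h * se + (1 - h) * (1 - sp)
}

#' Per-segment sensitivity: P(at least m of n spectra labelled BCC)
#'
#' @param p per-spectrum BCC probability in a BCC segment
#'   (see [perSpectrumBccProb()]).
#' @param n spectra per segment (default 5).
#' @param m minimum BCC spectra (default 2).
#' @return \code{P(Binomial(n, p) >= m)}.
#' @export
perSegmentSensitivity <- function(p, n = 5L, m = 2L) {
  stopifnot(p >= 0, p <= 1, m <= n)
  stats::pbinom(m - 1, n, p, lower.tail = FALSE)
}

#' Per-segment specificity: P(fewer than m false-BCC spectra)
#'
#' @param sp per-spectrum specificity.
#' @param n,m as in [perSegmentSensitivity()].
#' @return \code{1 - P(Binomial(n, 1 - sp) >= m)}.
#' @export
perSegmentSpecificity <- function(sp, n = 5L, m = 2L) {
  stopifnot(sp >= 0, sp <= 1, m <= n)
  stats::pbinom(m - 1, n, 1 - sp)
}

# distributions of true detections T and false alarms F implied by inputs
segmentRates <- function(inputs) {
  p <- perSpectrumBccProb(inputs@hitRate, inputs@se, inputs@sp)
  list(
    segSens = perSegmentSensitivity(p, inputs@nSpectra, inputs@minBcc),
    segFp = 1 - perSegmentSpecificity(inputs@sp, inputs@nSpectra,
                                      inputs@minBcc))
}

#' Per-sample operating point by exact convolution
#'
#' With \code{T ~ Binomial(nBccSegments, per-segment sensitivity)} and
#' \code{F ~ Binomial(nNonBccSegments, per-segment FP rate)} independent,
#' the sample sensitivity is \code{P(T + F >= nTh)} (computed by exact
#' convolution over T) and the specificity is \code{P(F < nTh)}.
#'
#' @param inputs a [PerformanceInputs-class].
#' @return named numeric: \code{sensitivity}, \code{specificity}.
#' @export
#' @examples
#' sampleOperatingPoint(performanceInputs(nBccSegments = 10L, nTh = 5L))
sampleOperatingPoint <- function(inputs) {
  r <- segmentRates(inputs)
  nB <- inputs@nBccSegments
  nN <- inputs@nNonBccSegments
  nTh <- inputs@nTh
  pT <- stats::dbinom(0:nB, nB, r$segSens)
  # P(F >= nTh - t) for each t
  tailF <- vapply(0:nB, function(t) {
    need <- nTh - t
    if (need <= 0) 1
    else stats::pbinom(need - 1, nN, r$segFp, lower.tail = FALSE)
  }, numeric(1))
  c(sensitivity = sum(pT * tailF),
    specificity = stats::pbinom(nTh - 1, nN, r$segFp))
}

#' Probability of a positive call built entirely on false positives
#'
#' \code{P(T = 0) * P(F >= nTh)}: the sample's true BCC segments are all
#' missed, yet enough non-BCC segments are falsely labelled BCC to cross
#' the threshold.
#'
#' @param inputs a [PerformanceInputs-class] with
#'   \code{nBccSegments >= 1}.
#' @return probability in [0, 1].
#' @export
fpOnlyDetectionProb <- function(inputs) {
  stopifnot(inputs@nBccSegments >= 1)
  r <- segmentRates(inputs)
  stats::dbinom(0, inputs@nBccSegments, r$segSens) *
    stats::pbinom(inputs@nTh - 1, inputs@nNonBccSegments, r$segFp,
                  lower.tail = FALSE)
}

#' Operating characteristics as a function of the threshold
#'
#' @param inputs a [PerformanceInputs-class].
#' @param nThValues thresholds to tabulate (default 1..15).
#' @return data.frame: \code{nTh}, \code{sensitivity},
#'   \code{specificity}, \code{fpOnly}.
#' @export
operatingCurve <- function(inputs, nThValues = 1:15) {
  rows <- lapply(nThValues, function(th) {
    inp <- inputs
    inp@nTh <- as.integer(th)
    op <- sampleOperatingPoint(inp)
    data.frame(nTh = th, sensitivity = op["sensitivity"],
               specificity = op["specificity"],
               fpOnly = fpOnlyDetectionProb(inp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo validation of the analytic model
#'
#' Simulates per-spectrum Bernoulli outcomes through the segment rule
#' (at least \code{minBcc} of \code{nSpectra}) and the sample rule
#' (\code{T + F >= nTh}) and returns empirical rates with standard
#' errors, for cross-checking the closed forms.
#'
#' @param inputs a [PerformanceInputs-class].
#' @param nSims number of simulated samples (>= 1).
#' @param seed simulation seed.
#' @param chunk simulations per memory chunk.
#' @return list with \code{segmentSensitivity}, \code{sensitivity},
#'   \code{specificity}, \code{fpOnly} (each \code{c(estimate, se)}).
#' @export
monteCarloCheck <- function(inputs, nSims, seed = 1L, chunk = 100000L) {
  stopifnot(nSims >= 1)
  p <- perSpectrumBccProb(inputs@hitRate, inputs@se, inputs@sp)
  q <- 1 - inputs@sp
  nB <- inputs@nBccSegments
  nN <- inputs@nNonBccSegments
  n <- inputs@nSpectra
  m <- inputs@minBcc
  withr::with_seed(as.integer(seed), {
    segHits <- 0; posHits <- 0; negHits <- 0; fpOnlyHits <- 0
    done <- 0
    while (done < nSims) {
      nb <- min(chunk, nSims - done)
      # per-spectrum outcomes aggregated per segment
      tSeg <- matrix(stats::rbinom(nb * nB, n, p) >= m, nb, nB)
      fSeg <- matrix(stats::rbinom(nb * nN, n, q) >= m, nb, nN)
      tCount <- rowSums(tSeg)
      fCount <- rowSums(fSeg)
      segHits <- segHits + sum(tSeg[, 1])
      posHits <- posHits + sum(tCount + fCount >= inputs@nTh)
      negHits <- negHits + sum(fCount < inputs@nTh)
      fpOnlyHits <- fpOnlyHits +
        sum(tCount == 0 & fCount >= inputs@nTh)
      done <- done + nb
    }
    est <- function(hits) {
      ph <- hits / nSims
      c(estimate = ph, se = sqrt(ph * (1 - ph) / nSims))
    }
    list(segmentSensitivity = est(segHits),
         sensitivity = est(posHits),
         specificity = est(negHits),
         fpOnly = est(fpOnlyHits))
  })
}
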