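# spectra helpers: noiseless class spectra (infinite SNR, always retained)
# and zero-SNR spectra (flat signal, alternating "noise" confined to the
# 1750-1800 cm^-1 region: peak height 0, noise rms 0.5 -> SNR exactly 0)
lowSnrSpectrum <- function() {
  wn <- RamanMSH:::ramanGrid()
  y <- rep(1, 701)
  nz <- which(wn >= 1750 & wn <= 1800)
  y[nz] <- 1 + rep_len(c(0.5, -0.5), length(nz))
  RamanMSH:::newSpectraSet(wn, y, data.frame(spectrumId = "low",
                                             class = "low"))
}
classSet <- function(classes) {
  do.call(RamanMSH:::bindSpectra, lapply(seq_along(classes), function(i)
    if (classes[i] == "low") lowSnrSpectrum()
    else noiselessSpectrum(classes[i])))
}
dummyPoints <- function(n) data.frame(row = seq_len(n), col = rep(2, n))

test_that("round-1 labelling follows the class-count rules", {
  clf <- testClassifier()
  run1 <- function(classes)
    diagnoseSegmentRound1(classSet(classes), dummyPoints(length(classes)),
                          clf, segmentId = 1L)

  allDermis <- run1(rep("dermis", 5))
  expect_equal(allDermis@status, "label")
  expect_equal(allDermis@label, "dermis")

  oneBcc <- run1(c("BCC", rep("dermis", 4)))
  expect_equal(oneBcc@status, "label")
  expect_equal(oneBcc@label, "dermis")
  expect_equal(sum(oneBcc@points$ignored), 1L)

  allBcc <- run1(rep("BCC", 5))
  expect_equal(allBcc@status, "label")
  expect_equal(allBcc@label, "BCC")

  # 4/5 = 80% is NOT more than 80%: second round required
  fourBcc <- run1(c(rep("BCC", 4), "dermis"))
  expect_equal(fourBcc@status, "round2")

  mixed <- run1(c("dermis", "dermis", "fat", "fat", "fat"))
  expect_equal(mixed@status, "split")

  expect_error(diagnoseSegmentRound1(classSet("dermis")[0], dummyPoints(0),
                                     clf), "no spectra")
})

test_that("discard-dominated segments become Unclassified", {
  clf <- testClassifier()
  # 5/5 discarded (100% > 80%): Unclassified, terminal
  allLow <- diagnoseSegmentRound1(classSet(rep("low", 5)), dummyPoints(5),
                                  clf, segmentId = 2L)
  expect_equal(allLow@status, "Unclassified")
  expect_true(all(!allLow@points$retained))

  # 4/5 discarded (80%, not more): the single survivor labels the segment
  oneLeft <- diagnoseSegmentRound1(classSet(c(rep("low", 4), "fat")),
                                   dummyPoints(5), clf, segmentId = 3L)
  expect_equal(oneLeft@status, "label")
  expect_equal(oneLeft@label, "fat")
})

test_that("the second round resamples, joins and always splits", {
  clf <- testClassifier()
  segPx <- as.matrix(expand.grid(row = 1:10, col = 1:10))
  colnames(segPx) <- c("row", "col")
  r1 <- diagnoseSegmentRound1(classSet(c(rep("BCC", 4), "dermis")),
    data.frame(row = c(1, 1, 2, 2, 3), col = c(1, 2, 1, 2, 1)),
    clf, segmentId = 4L)
  expect_equal(r1@status, "round2")

  requested <- NULL
  sampler <- function(pts) {
    requested <<- pts
    classSet(rep("BCC", nrow(pts)))
  }
  fin <- runRound2(r1, segPx, sampler, clf, round1Spectra =
    classSet(c(rep("BCC", 4), "dermis")), seed = 5L)
  expect_equal(nrow(requested), 5L)         # equal-count rule
  r1pts <- r1@points[, c("row", "col")]
  overlap <- merge(as.data.frame(requested), r1pts)
  expect_equal(nrow(overlap), 0L)           # never the same locations
  expect_equal(fin@status, "split")

  # 9 of 10 labelled points BCC: splitting still covers the whole segment
  lbl <- nearestNeighbourSplit(segPx,
    fin@points[fin@points$retained, c("row", "col", "class")])
  expect_length(lbl, nrow(segPx))
})

test_that("nearest-neighbour splitting partitions by true distance", {
  segPx <- as.matrix(expand.grid(row = 1:8, col = 1:20))
  colnames(segPx) <- c("row", "col")
  pts <- data.frame(row = c(4, 4), col = c(3, 17),
                    class = c("BCC", "dermis"))
  lbl <- nearestNeighbourSplit(segPx, pts)
  d1 <- (segPx[, 1] - 4)^2 + (segPx[, 2] - 3)^2
  d2 <- (segPx[, 1] - 4)^2 + (segPx[, 2] - 17)^2
  oracle <- ifelse(d1 < d2, "BCC", ifelse(d2 < d1, "dermis", "BCC"))
  expect_equal(lbl, oracle)                 # ties to the lowest index
  expect_false(any(is.na(lbl)))

  one <- nearestNeighbourSplit(segPx, pts[1, ])
  expect_true(all(one == "BCC"))
  expect_error(nearestNeighbourSplit(segPx, pts[0, ]), "no labelled")
})

test_that("assembly counts connected BCC regions across segments", {
  mask <- matrix(TRUE, 12, 12)
  lab <- matrix(0L, 12, 12)
  lab[2, 1:4] <- 1L          # whole-segment BCC
  lab[6, 1:4] <- 2L          # whole-segment dermis
  lab[10, 1:12] <- 3L        # split: BCC at both ends
  tab <- data.frame(id = 1:3, areaPx = c(4L, 4L, 12L),
    areaMm2 = c(4, 4, 12) * 0.0016, variance = 0,
    centroidRow = c(2, 6, 10), centroidCol = c(2.5, 2.5, 6.5))
  sm <- new("SegmentMap", labels = lab, table = tab, thresholdUsed = 0,
            connectivity = 8L, pixelSize = 40)
  mkDiag <- function(id, status, label = NA_character_, points =
      data.frame()) new("SegmentDiagnosis", segmentId = id,
      status = status, label = label, points = points)
  splitPts <- data.frame(row = c(10, 10, 10), col = c(1, 6, 12),
    round = 1L, snr = 99, retained = TRUE,
    class = c("BCC", "dermis", "BCC"), ignored = FALSE)
  dx <- assembleDiagnosis(list(
    mkDiag(1L, "label", "BCC"),
    mkDiag(2L, "label", "dermis"),
    mkDiag(3L, "split", points = splitPts)), sm, mask)
  expect_equal(nBcc(dx), 3L)

  lv <- levels(dx)
  lm <- maskLabels(dx)
  expect_equal(lv[lm[6, 2] + 1L], "dermis")
  expect_equal(lv[lm[10, 6] + 1L], "dermis")
  expect_equal(lv[lm[10, 1] + 1L], "BCC")
  expect_equal(lv[lm[1, 1] + 1L], "tissue")

  # every labelled segment pixel carries exactly one label
  expect_true(all(lm[lab > 0L] > 1L))

  dx0 <- assembleDiagnosis(list(mkDiag(1L, "label", "dermis"),
    mkDiag(2L, "label", "fat"), mkDiag(3L, "Unclassified")), sm, mask)
  expect_equal(nBcc(dx0), 0L)
  expect_equal(lv[maskLabels(dx0)[10, 6] + 1L], "Unclassified")
})

test_that("the sample decision thresholds the BCC region count", {
  mk <- function(n) new("DiagnosisImage", labels = matrix(0L, 2, 2),
    classLevels = c("background"), nBcc = as.integer(n),
    legend = c(background = "#000000"))
  expect_equal(sampleDecision(mk(7), nTh = 8L), "BCC-negative")
  expect_equal(sampleDecision(mk(8), nTh = 8L), "BCC-positive")
  expect_equal(sampleDecision(mk(0), nTh = 1L), "BCC-negative")
  expect_equal(sampleDecision(mk(20), nTh = 5L), "BCC-positive")
  expect_error(sampleDecision(mk(3), nTh = 0L))
})
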