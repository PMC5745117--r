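# build a SegmentMap by hand from a label matrix + intensity image
segmapFrom <- function(lab, img = NULL, pixelSize = 40) {
  k <- max(lab)
  vals <- if (is.null(img)) matrix(0, nrow(lab), ncol(lab)) else img
  tab <- data.frame(
    id = seq_len(k),
    areaPx = as.integer(tabulate(lab[lab > 0], k)),
    areaMm2 = tabulate(lab[lab > 0], k) * (pixelSize / 1000)^2,
    variance = vapply(seq_len(k), function(i) {
      v <- vals[lab == i]; if (length(v) > 1) var(v) else 0
    }, numeric(1)),
    centroidRow = vapply(seq_len(k), function(i)
      mean(row(lab)[lab == i]), numeric(1)),
    centroidCol = vapply(seq_len(k), function(i)
      mean(col(lab)[lab == i]), numeric(1)))
  new("SegmentMap", labels = lab, table = tab, thresholdUsed = 0,
      connectivity = 8L, pixelSize = pixelSize)
}

test_that("allocation follows the variance/area weighting", {
  lab <- matrix(0L, 10, 30)
  lab[2:6, 2:6] <- 1L
  lab[2:6, 20:24] <- 2L
  sm <- segmapFrom(lab)
  # force the Var*Area weights directly
  sm@table$variance <- c(2, 8)
  sm@table$areaPx <- c(10L, 10L)

  expect_equal(allocatePoints(sm, nMin = 5L, nTotal = 20L), c(7L, 13L))

  sm@table$variance <- c(5, 5)
  expect_equal(allocatePoints(sm, nMin = 5L, nTotal = 20L), c(10L, 10L))

  # single segment receives the whole budget (flat segment: zero weight)
  lab1 <- matrix(0L, 5, 5); lab1[2:4, 2:4] <- 1L
  expect_equal(suppressWarnings(allocatePoints(segmapFrom(lab1), 5L, 37L)),
               37L)

  # zero weights: uniform distribution, flagged
  sm@table$variance <- c(0, 0)
  expect_warning(out <- allocatePoints(sm, 5L, 21L), "uniform")
  expect_equal(sum(out), 21L)
  expect_true(all(out >= 5L))

  # over-subscribed budget: minima in decreasing-area order, flagged
  sm@table$variance <- c(1, 1)
  sm@table$areaPx <- c(10L, 30L)
  expect_warning(out <- allocatePoints(sm, 5L, 8L), "budget")
  expect_equal(out, c(3L, 5L))
})

test_that("allocation preserves the total across random cases", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    lab <- matrix(0L, 4, 3 * k)
    for (i in seq_len(k)) lab[2:3, (3 * i - 2):(3 * i - 1)] <- i
    sm <- segmapFrom(lab)
    sm@table$variance <- runif(k)
    sm@table$areaPx <- sample.int(500, k)
    nTotal <- sample(5 * k + 0:50, 1)
    out <- allocatePoints(sm, 5L, as.integer(nTotal))
    expect_equal(sum(out), nTotal)
    expect_true(all(out >= 5L))
  }
})

test_that("uniform placement starts at the centroid and respects exclusions", {
  px <- whichDisc <- as.matrix(expand.grid(row = 1:11, col = 1:11))
  d2 <- (px[, 1] - 6)^2 + (px[, 2] - 6)^2
  px <- px[d2 <= 25, ]
  one <- placePointsUniform(px, 1)
  expect_equal(unname(one[1, ]), c(6, 6))

  excl <- one
  more <- placePointsUniform(px, 5, exclusions = excl)
  expect_false(any(more[, 1] == 6 & more[, 2] == 6))

  # deterministic
  expect_identical(placePointsUniform(px, 5), placePointsUniform(px, 5))

  # shortfall flagged
  tiny <- px[1:3, ]
  expect_warning(got <- placePointsUniform(tiny, 5), "only 3")
  expect_equal(nrow(got), 3L)
})

test_that("farthest-point spreading beats random placement on a strip", {
  px <- cbind(row = rep(1, 100), col = 1:100)
  minPair <- function(pts) {
    d <- as.matrix(dist(pts))
    min(d[upper.tri(d)])
  }
  fps <- minPair(placePointsUniform(px, 5))
  rnd <- mean(vapply(1:100, function(s)
    minPair(placePointsUniform(px, 5, seed = s, method = "random")),
    numeric(1)))
  expect_gte(fps, rnd)
})

test_that("extrema placement pins the intensity min and max first", {
  px <- as.matrix(expand.grid(row = 1:6, col = 1:6))
  intens <- rep(10, nrow(px))
  intens[14] <- 1; intens[29] <- 99
  pts <- placePointsExtrema(px, intens, 5)
  expect_equal(unname(pts[1, ]), unname(px[14, ]))
  expect_equal(unname(pts[2, ]), unname(px[29, ]))
  expect_equal(nrow(pts), 5L)

  # constant intensities: the two lowest row-major pixels
  ptsC <- placePointsExtrema(px, rep(5, nrow(px)), 2)
  expect_equal(unname(ptsC[1, ]), c(1, 1))
  expect_equal(unname(ptsC[2, ]), c(1, 2))

  expect_error(placePointsExtrema(px, intens, 1), "at least 2")
})

test_that("hit rate counts points in BCC-bearing segments only", {
  lab <- matrix(0L, 12, 24)
  lab[2:11, 2:11] <- 1L     # mixed segment, left half BCC
  lab[2:11, 14:23] <- 2L    # healthy segment
  ann <- matrix(1L, 12, 24)
  ann[2:11, 2:6] <- 2L
  annotation <- new("AnnotationMask", labels = ann,
                    levels = c("background", "stroma", "BCC", "dye"))
  sm <- segmapFrom(lab)
  plan <- data.frame(pointId = 1:6, segmentId = c(1, 1, 1, 1, 2, 2),
    row = c(3, 4, 5, 6, 3, 4), col = c(2, 3, 9, 10, 15, 16),
    round = 1L, config = "config2")
  # 2 of 4 points in the BCC segment are on BCC
  expect_equal(hitRate(plan, sm, annotation), 0.5)
  expect_equal(missedBccSegments(plan, sm, annotation), 0L)

  planMiss <- plan
  planMiss$col <- c(9, 9, 9, 10, 15, 16)  # all seg-1 points on healthy px
  expect_equal(hitRate(planMiss, sm, annotation), 0)
  expect_equal(missedBccSegments(planMiss, sm, annotation), 1L)

  annotation0 <- new("AnnotationMask", labels = matrix(1L, 12, 24),
                     levels = c("background", "stroma", "BCC", "dye"))
  expect_warning(h <- hitRate(plan, sm, annotation0), "not applicable")
  expect_true(is.na(h))
  expect_equal(missedBccSegments(plan, sm, annotation0), 0L)
})

test_that("random placement on a half-BCC segment hits about half", {
  lab <- matrix(0L, 20, 20); lab[3:18, 3:18] <- 1L
  ann <- matrix(1L, 20, 20); ann[3:18, 3:10] <- 2L
  annotation <- new("AnnotationMask", labels = ann,
                    levels = c("background", "stroma", "BCC", "dye"))
  sm <- segmapFrom(lab)
  px <- whichPix <- which(lab == 1L, arr.ind = TRUE)
  hits <- vapply(1:300, function(s) {
    pts <- placePointsUniform(px, 10, seed = s, method = "random")
    plan <- data.frame(pointId = seq_len(nrow(pts)), segmentId = 1L,
      row = pts[, 1], col = pts[, 2], round = 1L, config = "config2")
    hitRate(plan, sm, annotation)
  }, numeric(1))
  expect_equal(mean(hits), 0.5, tolerance = 0.05)
})

test_that("plans keep every point inside its segment", {
  ph <- smallPhantom()
  mask <- tissueMask(ph@image, 200)
  flat <- flattenImage(ph@image, mask = mask)
  opt <- optimizeThreshold(flat, mask)
  sm <- segmentAtThreshold(flat, mask, opt$threshold)
  for (cfgName in c("config2", "config1")) {
    plan <- suppressWarnings(buildSamplingPlan(sm, flat, nMin = 5L,
      nTotal = 200L, config = cfgName))
    lab <- segmentLabels(sm)
    expect_true(all(lab[cbind(plan$row, plan$col)] == plan$segmentId))
  }
})
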