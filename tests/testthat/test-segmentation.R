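test_that("flattening preserves constant images and removes gradients", {
  const <- afim(matrix(100, 64, 64))
  out <- flattenImage(const, sigma = 6)
  expect_equal(intensities(out), intensities(const), tolerance = 1e-8)

  # blob pattern multiplied by a linear 2x left-right gradient
  base <- matrix(100, 96, 96)
  base[40:56, 20:36] <- 40
  grad <- matrix(rep(seq(1, 2, length.out = 96), each = 96), 96, 96,
                 byrow = FALSE)
  img <- afim(base * t(grad))
  flat <- intensities(flattenImage(img, sigma = 30))
  left <- mean(flat[1:30, 1:20])
  right <- mean(flat[1:30, 77:96])
  expect_lt(abs(left - right) / right, 0.05)

  expect_error(flattenImage(afim(matrix(0, 8, 8)), sigma = 2), "all-zero")
  expect_error(flattenImage(const, sigma = 0.5), "at least 1 pixel")
})

test_that("tissue masking matches the generator and handles extremes", {
  ph <- smallPhantom()
  mask <- tissueMask(ph@image, 200)
  expect_identical(mask, maskLabels(ph@mask) != 0L)

  img <- afim(matrix(runif(400, 10, 20), 20, 20))
  expect_true(all(tissueMask(img, 0, minSpeckArea = 1L)))
  expect_error(tissueMask(img, 1000), "no tissue")
})

test_that("segmentation at a threshold finds the constructed components", {
  m <- matrix(100, 60, 60)
  ctr <- list(c(15, 15), c(15, 45), c(45, 30))
  rr <- row(m); cc <- col(m)
  for (p in ctr) m[(rr - p[1])^2 + (cc - p[2])^2 <= 16] <- 20
  img <- afim(m)
  mask <- matrix(TRUE, 60, 60)

  sm <- segmentAtThreshold(img, mask, 50, minSegmentArea = 2L)
  expect_equal(nSegments(sm), 3L)
  discArea <- sum((rr - 15)^2 + (cc - 15)^2 <= 16)
  expect_equal(segmentTable(sm)$areaPx, rep(discArea, 3))

  expect_equal(nSegments(segmentAtThreshold(img, mask, 10)), 0L)
  smAll <- segmentAtThreshold(img, mask, 1000)
  expect_equal(nSegments(smAll), 1L)
  expect_equal(segmentTable(smAll)$areaPx, sum(mask))
})

test_that("compiled labelling equals a flood-fill oracle on small images", {
  set.seed(7)
  for (conn in c(4L, 8L)) {
    for (rep in 1:6) {
      fg <- matrix(runif(20 * 20) < 0.45, 20, 20)
      a <- RamanMSH:::ccLabel(fg, conn)
      b <- floodFillLabel(fg, conn)
      expect_equal(max(a), max(b))
      # identical partitions: labels agree up to renaming
      if (max(a) > 0)
        expect_equal(length(unique(paste(a[fg], b[fg]))), max(a))
    }
  }
})

test_that("threshold objectives obey f_B <= f_A and vanish below range", {
  ph <- smallPhantom()
  mask <- tissueMask(ph@image, 200)
  flat <- flattenImage(ph@image, mask = mask)
  v <- intensities(flat)[mask]
  for (t in quantile(v, c(0.05, 0.3, 0.6, 0.9))) {
    fA <- thresholdObjective(flat, mask, t, "f_A")
    fB <- thresholdObjective(flat, mask, t, "f_B")
    expect_gte(fA, fB)
    expect_gte(fB, 0)
  }
  expect_equal(thresholdObjective(flat, mask, min(v) - 1, "f_A"), 0)
  expect_equal(thresholdObjective(flat, mask, min(v) - 1, "f_B"), 0)
})

test_that("captured area is monotone in the threshold", {
  ph <- smallPhantom()
  mask <- tissueMask(ph@image, 200)
  flat <- flattenImage(ph@image, mask = mask)
  v <- intensities(flat)[mask]
  grid <- seq(min(v), max(v), length.out = 20)
  areas <- vapply(grid, function(t)
    sum(mask & intensities(flat) < t), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("threshold optimisation returns the curve argmax, lowest tie", {
  m <- matrix(80, 40, 40)
  m[10:20, 10:20] <- 20
  img <- afim(m)
  mask <- matrix(TRUE, 40, 40)
  opt <- optimizeThreshold(img, mask, "f_B", gridSize = 61L,
                           minSegmentArea = 2L)
  # any grid point in (20, 80] isolates the square; lowest one returned
  expect_equal(opt$threshold, seq(20, 80, length.out = 61)[2])
  expect_equal(max(opt$curve$f_B), opt$curve$f_B[
    which(opt$curve$threshold == opt$threshold)])
  expect_error(optimizeThreshold(afim(matrix(5, 10, 10)),
    matrix(TRUE, 10, 10)), "constant")
})

test_that("f_B recovers at least the tumour fraction f_A does", {
  wins <- 0L
  for (sd in 1:5) {
    ph <- generatePhantom(phantomConfig(imageShape = c(192L, 192L),
      nTumourBlobs = 3L, blobRadiusRange = c(150, 350), seed = sd))
    mask <- tissueMask(ph@image, 200)
    flat <- flattenImage(ph@image, mask = mask)
    rho <- vapply(c("f_B", "f_A"), function(k) {
      opt <- optimizeThreshold(flat, mask, k)
      computeRho(segmentAtThreshold(flat, mask, opt$threshold), ph@mask)
    }, numeric(1))
    wins <- wins + (rho["f_B"] >= rho["f_A"])
  }
  expect_gte(wins, 3L)
})

test_that("rho and epsilon follow their definitions", {
  # constructed 10x10 scene: segment covers left half, BCC is a 4x4 block
  lab <- matrix(0L, 10, 10); lab[, 1:5] <- 1L
  ann <- matrix(1L, 10, 10)
  ann[4:7, 4:7] <- 2L          # BCC: half inside the segment
  annotation <- new("AnnotationMask", labels = ann,
                    levels = c("background", "stroma", "BCC", "dye"))
  tab <- data.frame(id = 1L, areaPx = 50L, areaMm2 = 50 * 0.0016,
    variance = 0, centroidRow = 5.5, centroidCol = 3)
  sm <- new("SegmentMap", labels = lab, table = tab, thresholdUsed = 1,
            connectivity = 8L, pixelSize = 40)
  expect_equal(computeRho(sm, annotation), 0.5)
  # epsilon: 8 BCC px and 42 healthy px inside the segment
  expect_equal(computeEpsilon(sm, annotation, 1L), 42 / 50)

  annB <- new("AnnotationMask", labels = ann * 0L,
              levels = c("background", "stroma", "BCC", "dye"))
  expect_warning(r <- computeRho(sm, annB), "not applicable")
  expect_true(is.na(r))
  expect_error(computeEpsilon(sm, annotation, 5L), "invalid segment")
})
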