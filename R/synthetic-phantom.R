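#' Construct a phantom configuration
#'
#' Defaults describe a 512 x 512 pixel field at 40 um/pixel (about a
#' 2 cm x 2 cm sample area): a bright textured stroma disc on a dark
#' background, darker tumour blobs of 100-500 um radius, and a dye arc
#' along part of the tissue boundary. The intensity ordering
#' \code{backgroundMean < tumourMean < stromaMean} mirrors the observed
#' AF contrast of BCC against stroma and is enforced.
#'
#' @param imageShape integer(2) rows, cols.
#' @param pixelSize um per pixel.
#' @param stromaMean,tumourMean,backgroundMean mean intensities (a.u.).
#' @param textureSd intensity SD of the multiplicative stroma texture.
#' @param nTumourBlobs number of tumour blobs (0 for a tumour-free sample).
#' @param blobRadiusRange um, min and max blob radius.
#' @param blobShape \code{"micronodular"} or \code{"infiltrative"}.
#' @param rimWidthPx width in pixels of the bright condensed-stroma rim
#'   drawn around each blob (the peritumoral stromal reaction seen as
#'   locally increased collagen AF); 0 disables it.
#' @param dyeFraction fraction of the boundary marked with dye.
#' @param seed integer seed.
#' @return a validated [PhantomConfig-class].
#' @export
#' @examples
#' cfg <- phantomConfig(nTumourBlobs = 3, seed = 7)
phantomConfig <- function(imageShape = c(512L, 512L), pixelSize = 40,
                          stromaMean = 1000, tumourMean = 600,
                          backgroundMean = 50, textureSd = 80,
                          nTumourBlobs = 10L,
                          blobRadiusRange = c(150, 500),
                          blobShape = "micronodular",
                          rimWidthPx = 2, dyeFraction = 0.15, seed = 1L) {
  new("PhantomConfig", imageShape = as.integer(imageShape),
      pixelSize = pixelSize, stromaMean = stromaMean,
      tumourMean = tumourMean, backgroundMean = backgroundMean,
      textureSd = textureSd, nTumourBlobs = as.integer(nTumourBlobs),
      blobRadiusRange = blobRadiusRange, blobShape = blobShape,
      rimWidthPx = rimWidthPx, dyeFraction = dyeFraction,
      seed = as.integer(seed))
}

# binary dilation by k pixels (Chebyshev square, separable 3x3 steps)
dilateMask <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(k)) {
    a <- m
    a[-1, ] <- a[-1, ] | m[-nr, ]
    a[-nr, ] <- a[-nr, ] | m[-1, ]
    b <- a
    b[, -1] <- b[, -1] | a[, -nc]
    b[, -nc] <- b[, -nc] | a[, -1]
    m <- b
  }
  m
}

# Rasterise one blob as a logical matrix; guaranteed one connected
# component (largest component containing the centre is kept).
rasteriseBlob <- function(nr, nc, centre, radiusPx, shape) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  blob <- matrix(FALSE, nr, nc)
  if (shape == "micronodular") {
    r0 <- 0.55 * radiusPx
    blob <- blob | ((rr - centre[1])^2 + (cc - centre[2])^2 <= r0^2)
    nDiscs <- sample(2:5, 1)
    for (i in seq_len(nDiscs)) {
      rho <- runif(1, 0.35, 0.7) * radiusPx
      dmax <- min(r0 + 0.8 * rho, radiusPx - rho)
      d <- runif(1, 0, max(dmax, 0))
      th <- runif(1, 0, 2 * pi)
      ctr <- centre + d * c(cos(th), sin(th))
      blob <- blob | ((rr - ctr[1])^2 + (cc - ctr[2])^2 <= rho^2)
    }
  } else { # infiltrative: thickened random walk confined to the radius
    thick <- max(1, 0.15 * radiusPx)
    nSteps <- max(8L, round(3 * radiusPx))
    pos <- centre
    ang <- runif(1, 0, 2 * pi)
    for (s in seq_len(nSteps)) {
      ang <- ang + rnorm(1, sd = 0.35)
      cand <- pos + c(cos(ang), sin(ang))
      if (sqrt(sum((cand - centre)^2)) > radiusPx - thick) {
        ang <- ang + pi / 2  # turn along the boundary
        cand <- pos + c(cos(ang), sin(ang))
      }
      pos <- cand
      blob <- blob | ((rr - pos[1])^2 + (cc - pos[2])^2 <= thick^2)
    }
  }
  lab <- ccLabel(blob, 8L)
  keep <- lab[round(centre[1]), round(centre[2])]
  if (keep == 0) keep <- which.max(tabulate(lab[lab > 0]))
  lab == keep
}

#' Generate a seeded AF phantom with annotation
#'
#' Builds the stroma disc with a multiplicative Gaussian texture field
#' (smoothed at a ~5 pixel scale), carves in \code{nTumourBlobs} darker
#' tumour blobs placed fully inside the tissue with pairwise separation
#' (so the annotation has exactly \code{nTumourBlobs} connected BCC
#' components), surrounds each blob with a thin bright condensed-stroma
#' rim (the locally increased collagen auto-fluorescence of the
#' peritumoral stromal reaction, which keeps tumours locally contrasted
#' against stroma texture), and marks a dye arc along the tissue
#' boundary. Output is a pure function of the configuration, including
#' its seed.
#'
#' @param config a [PhantomConfig-class].
#' @return a [Phantom-class] holding the image, the annotation mask
#'   (levels background, stroma, BCC, dye) and the config.
#' @export
#' @examples
#' ph <- generatePhantom(phantomConfig(imageShape = c(128L, 128L),
#'   nTumourBlobs = 2, blobRadiusRange = c(100, 200), seed = 3))
#' ph
generatePhantom <- function(config) {
  validObject(config)
  nr <- config@imageShape[1]; nc <- config@imageShape[2]
  tissueRadius <- 0.42 * min(nr, nc)
  centre0 <- c((nr + 1) / 2, (nc + 1) / 2)
  radiiPx <- config@blobRadiusRange / config@pixelSize

  withr::with_seed(config@seed, {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    distC <- sqrt((rr - centre0[1])^2 + (cc - centre0[2])^2)
    tissue <- distC <= tissueRadius

    mask <- matrix(0L, nr, nc)
    mask[tissue] <- 1L

    # tumour blobs: rejection placement with pairwise separation
    if (config@nTumourBlobs > 0L) {
      radii <- runif(config@nTumourBlobs, radiiPx[1], radiiPx[2])
      centres <- matrix(NA_real_, config@nTumourBlobs, 2)
      for (b in seq_len(config@nTumourBlobs)) {
        if (radii[b] + 4 >= tissueRadius)
          stop("blob ", b, " radius exceeds the tissue extent")
        ok <- FALSE
        for (try in seq_len(5000L)) {
          maxd <- tissueRadius - radii[b] - 3
          d <- sqrt(runif(1)) * maxd
          th <- runif(1, 0, 2 * pi)
          ctr <- centre0 + d * c(cos(th), sin(th))
          if (b == 1L) { ok <- TRUE }
          else {
            prev <- seq_len(b - 1L)
            sep <- sqrt((centres[prev, 1] - ctr[1])^2 +
                        (centres[prev, 2] - ctr[2])^2)
            ok <- all(sep > radii[prev] + radii[b] + 3)
          }
          if (ok) { centres[b, ] <- ctr; break }
        }
        if (!ok)
          stop("could not place blob ", b,
               " inside the tissue with the required separation")
        blob <- rasteriseBlob(nr, nc, centres[b, ], radii[b],
                              config@blobShape)
        mask[blob] <- 2L
      }
    }

    # dye arc on the tissue boundary (never overlaps blobs: blobs keep a
    # >= 3 px margin from the boundary, the dye ring is 2 px deep)
    if (config@dyeFraction > 0) {
      ring <- tissue & distC > tissueRadius - 2
      ang <- atan2(cc - centre0[2], rr - centre0[1])  # (-pi, pi]
      th0 <- runif(1, -pi, pi)
      span <- 2 * pi * config@dyeFraction
      rel <- (ang - th0) %% (2 * pi)
      mask[ring & rel <= span] <- 3L
    }

    # multiplicative texture smoothed at ~5 px; unit-SD normalised
    g <- gaussBlurMasked(matrix(rnorm(nr * nc), nr, nc),
                         matrix(1, nr, nc), sigma = 5)
    g <- (g - mean(g)) / sd(g)
    cv <- config@textureSd / config@stromaMean
    meanMap <- matrix(config@backgroundMean, nr, nc)
    meanMap[mask == 1L] <- config@stromaMean
    meanMap[mask == 2L] <- config@tumourMean
    meanMap[mask == 3L] <- 0.5 * config@tumourMean
    img <- meanMap * (1 + cv * g)
    img[mask == 0L] <- config@backgroundMean *
      (1 + 0.1 * g[mask == 0L])

    # condensed-stroma rim: smooth, slightly brighter than stroma mean
    if (config@rimWidthPx > 0 && config@nTumourBlobs > 0L) {
      rim <- dilateMask(mask == 2L, ceiling(config@rimWidthPx)) &
        mask != 2L & tissue
      img[rim] <- 1.05 * config@stromaMean
      mask[rim] <- 1L  # annotated as stroma
    }
    img[img < 0] <- 0

    new("Phantom",
        image = newAFImage(img, config@pixelSize),
        mask = new("AnnotationMask", labels = mask,
                   levels = c("background", "stroma", "BCC", "dye")),
        config = config)
  })
}
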