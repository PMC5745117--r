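# Shared fixtures, built once per test run.

fixtureEnv <- new.env(parent = emptyenv())

# small phantom for geometry tests
smallPhantom <- function() {
  if (is.null(fixtureEnv$smallPhantom))
    fixtureEnv$smallPhantom <- generatePhantom(phantomConfig(
      imageShape = c(192L, 192L), nTumourBlobs = 3L,
      blobRadiusRange = c(150, 350), seed = 42L))
  fixtureEnv$smallPhantom
}

# modest labelled library + a trained classifier
testLibrary <- function() {
  if (is.null(fixtureEnv$lib))
    fixtureEnv$lib <- generateSpectralLibrary(60, snrRange = c(15, 40),
                                              seed = 101L)
  fixtureEnv$lib
}

testClassifier <- function() {
  if (is.null(fixtureEnv$clf)) {
    lib <- testLibrary()
    fixtureEnv$clf <- trainAnn(extractFeatures(lib),
                               spectraMeta(lib)$class, seed = 103L)
  }
  fixtureEnv$clf
}

# noiseless spectrum of a class on the standard grid
noiselessSpectrum <- function(className) {
  m <- spectrumModels()[[className]]
  RamanMSH:::newSpectraSet(RamanMSH:::ramanGrid(),
    RamanMSH:::cleanSpectrum(m),
    data.frame(spectrumId = className, class = className))
}

# independent flood-fill connected components (queue-based, pure R);
# oracle for the compiled union-find labeller
floodFillLabel <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  k <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!fg[r0, c0] || lab[r0, c0] != 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        r <- p[1] + nb[j, 1]; c <- p[2] + nb[j, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            fg[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# AFImage shortcut
afim <- function(m, pixelSize = 40) {
  new("AFImage", intensities = m, pixelSize = pixelSize)
}
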