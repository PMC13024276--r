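# Independent oracle implementations and small fixtures, kept deliberately
# naive so they share no code path with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-pairs nearest-background Euclidean distance (exhaustive)
bruteForceDistanceMap <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  out <- matrix(0, nr + 2L, nc + 2L)
  for (p in which(pad)) {
    r <- (p - 1L) %% (nr + 2L) + 1L
    c <- (p - 1L) %/% (nr + 2L) + 1L
    out[r, c] <- sqrt(min((bg[, 1L] - r)^2 + (bg[, 2L] - c)^2))
  }
  out[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# O(n^2) duplicate flagging oracle: all pairs, explicit gates, naive
# label-propagation components, earliest record per component kept
bruteForceDuplicates <- function(df, frameWindow = 5, maxX = 100,
                                 minIou = 0.3, minCos = 0.999) {
  ord <- order(df$SourceImage, df$Id)
  src <- df$SourceImage[ord]; cx <- df$CaptureX[ord]
  cy <- df$CaptureY[ord]; w <- df$ImageW[ord]; h <- df$ImageH[ord]
  fm <- as.matrix(df[ord, duplicateFeatureNames(), drop = FALSE])
  n <- length(src)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(src[j] - src[i]) > frameWindow) next
    if (abs(cx[j] - cx[i]) >= maxX) next
    ix <- max(0, min(cx[i] + w[i], cx[j] + w[j]) - max(cx[i], cx[j]))
    iy <- max(0, min(cy[i] + h[i], cy[j] + h[j]) - max(cy[i], cy[j]))
    inter <- ix * iy
    ov <- inter / (w[i] * h[i] + w[j] * h[j] - inter)
    cs <- sum(fm[i, ] * fm[j, ]) /
      sqrt(sum(fm[i, ]^2) * sum(fm[j, ]^2))
    if (ov >= minIou || cs >= minCos) link[i, j] <- link[j, i] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- c(i, which(link[i, ]))
      m <- min(comp[nb])
      if (any(comp[nb] != m)) {
        comp[nb] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  flagsSorted <- comp != seq_len(n)
  flags <- character(n)
  flags[ord[flagsSorted]] <- "duplicate"
  flags
}

# toy table for the training-set filter checks: 20 rows, 16 labelled
# (6 + 6 + 4), one constant, one character and one date-time column among
# 11 columns, 8 usable numeric features
makeToyTrainingFixture <- function() {
  set.seed(99)
  n <- 20L
  df <- data.frame(
    AbdArea = runif(n, 50, 500), AbdDiameter = runif(n, 5, 30),
    Length = runif(n, 10, 60), Width = runif(n, 5, 30),
    Intensity = runif(n, 80, 200), SigmaIntensity = runif(n, 5, 20),
    Roughness = runif(n, 1, 1.5), Transparency = runif(n, 0.1, 0.9),
    ConstantCol = rep(9, n),
    Timestamp = sprintf("2020-01-01 10:%02d:00", seq_len(n)),
    Note = sample(letters, n, replace = TRUE),
    stringsAsFactors = FALSE)
  tab <- new("ParticleTable", data = df,
             dialect = vspDialects()$canonical, runName = "toy",
             sourcePath = "")
  labels <- labelColumns(n)
  labels$LabelTrue <- c(rep("Alpha", 6), rep("Beta", 6), rep("Gamma", 4),
                        rep("", 4))
  list(table = tab, labels = labels)
}

# deterministic tiny config so classifier unit tests stay fast; the
# acceptance test uses the full-size default configuration
tinyTrainConfig <- function(seed = 1L, maxEpochs = 3L) {
  trainConfig(imageSize = 56L, batchSize = 8L, maxEpochs = maxEpochs,
              stemPool = 2L, convFilters = c(4L, 8L),
              convStride = c(2L, 1L), poolSize = c(2L, 2L),
              denseImage = 16L, denseFeat = c(16L, 8L), headUnits = 16L,
              seed = seed)
}
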