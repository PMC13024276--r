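# Duplicate gates, chain flagging and size thresholds.

test_that("iou matches analytic values", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(50, 50, 10, 10)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 50 / 150)
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("cosineSimilarity is scale invariant and guards zero vectors", {
  u <- c(3, 1, 4, 1, 5)
  expect_equal(cosineSimilarity(u, u), 1)
  expect_equal(cosineSimilarity(u, 2 * u), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_warning(z <- cosineSimilarity(c(0, 0), u[1:2]), "zero")
  expect_identical(z, -Inf)
  expect_error(cosineSimilarity(1:3, 1:4), "equal length")
})

.pairTable <- function(frames, xs) {
  df <- particleData(exampleParticleTable())[1:2, ]
  df$Id <- 1:2
  df$SourceImage <- frames
  df$CaptureX <- xs
  df$CaptureY <- c(300, 305)
  df[2, duplicateFeatureNames()] <- df[1, duplicateFeatureNames()]
  df$ImageW <- 40; df$ImageH <- 40
  df
}

test_that("the four duplicate criteria gate pairs as published", {
  # frames 1 and 3, x 200/210, identical features: all gates pass
  expect_identical(flagDuplicates(.pairTable(c(1L, 3L), c(200, 210))),
                   c("", "duplicate"))
  # frames 1 and 8: outside the five-source-image window
  expect_identical(flagDuplicates(.pairTable(c(1L, 8L), c(200, 210))),
                   c("", ""))
  # x 100 vs 250: 150 px apart, fails the < 100 px gate
  expect_identical(flagDuplicates(.pairTable(c(1L, 3L), c(100, 250))),
                   c("", ""))
  # boundary: exactly 5 frames apart is inside, exactly 100 px is outside
  expect_identical(flagDuplicates(.pairTable(c(1L, 6L), c(200, 210))),
                   c("", "duplicate"))
  expect_identical(flagDuplicates(.pairTable(c(1L, 3L), c(200, 300))),
                   c("", ""))
})

test_that("flagDuplicates equals the brute-force O(n^2) oracle", {
  for (seed in c(5, 17, 29)) {
    spec <- syntheticRunSpec(nParticles = 120, nDuplicatePairs = 10,
                             seed = seed, runName = "oracle")
    r <- generateRun(spec, withr::local_tempdir(), writeImages = FALSE)
    fast <- flagDuplicates(r$table)
    slow <- bruteForceDuplicates(r$table)
    expect_identical(fast, slow, label = paste("seed", seed))
    # every injected duplicate flagged, nothing else
    expect_identical(which(fast == "duplicate"),
                     which(!is.na(r$truth$DuplicateOfId)))
  }
})

test_that("duplicate flags are invariant to row permutation", {
  spec <- syntheticRunSpec(nParticles = 80, nDuplicatePairs = 8, seed = 21,
                           runName = "perm")
  r <- generateRun(spec, withr::local_tempdir(), writeImages = FALSE)
  base <- flagDuplicates(r$table)
  set.seed(1)
  p <- sample(nrow(r$table))
  shuffled <- flagDuplicates(r$table[p, ])
  expect_identical(shuffled, base[p])
})

test_that("similarity gates can be disabled independently", {
  df <- .pairTable(c(1L, 3L), c(200, 210))
  # make boxes overlap so the IoU gate alone links the pair
  df$CaptureY <- c(300, 302)
  expect_identical(flagDuplicates(df, duplicateConfig(useCosine = FALSE)),
                   c("", "duplicate"))
  # now break the boxes: only cosine can link
  df$CaptureY <- c(300, 800)
  expect_identical(flagDuplicates(df, duplicateConfig(useIou = FALSE)),
                   c("", "duplicate"))
  expect_error(duplicateConfig(useIou = FALSE, useCosine = FALSE))
})

test_that("missing required or feature columns are reported", {
  df <- .pairTable(c(1L, 3L), c(200, 210))
  expect_error(flagDuplicates(df[, setdiff(names(df), "CaptureX")]),
               "CaptureX")
  dropped <- df[, setdiff(names(df), "Intensity")]
  expect_warning(flags <- flagDuplicates(dropped), "Intensity")
  expect_identical(flags, c("", "duplicate"))
})

test_that("size thresholds flag small and large with inclusive bounds", {
  df <- data.frame(AbdDiameter = c(5, 8, 12), Length = c(40, 25, 31))
  expect_identical(
    applySizeThreshold(df, sizeThresholdConfig("AbdDiameter", lower = 8)),
    c("small", "", ""))
  expect_identical(
    applySizeThreshold(df, sizeThresholdConfig("Length", lower = 30)),
    c("", "small", ""))
  expect_identical(
    applySizeThreshold(df, sizeThresholdConfig("AbdDiameter", upper = 11)),
    c("", "", "large"))
  expect_error(applySizeThreshold(df, sizeThresholdConfig("Nope")),
               "unknown size parameter")
})

test_that("duplicate flags take precedence over size flags", {
  combined <- combineFlags(c("", "duplicate", ""),
                           c("small", "small", "large"))
  expect_identical(combined, c("small", "duplicate", "large"))
  expect_identical(combineFlags(NULL, c("small", "")), c("small", ""))
  expect_identical(combineFlags(c("", "duplicate"), NULL),
                   c("", "duplicate"))
})
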