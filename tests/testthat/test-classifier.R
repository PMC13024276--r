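# Training-table filters, model mechanics, early stopping, prediction.

test_that("training-table filters drop rows, columns and small classes", {
  fx <- makeToyTrainingFixture()
  ts <- prepareTrainingTable(fx$table, fx$labels, trainConfig())

  expect_equal(nrow(ts$features), 12)  # 6 + 6; the 4-image class removed
  expect_equal(ncol(ts$features), 8)
  expect_setequal(ts$classList, c("Alpha", "Beta"))
  expect_identical(ts$droppedClasses, "Gamma")
  expect_identical(ts$droppedColumns$constant, "ConstantCol")
  expect_identical(ts$droppedColumns$nonNumeric, "Note")
  expect_identical(ts$droppedColumns$dateTime, "Timestamp")

  # standardised on the kept rows
  expect_equal(unname(colMeans(ts$features)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(apply(ts$features, 2, sd)), rep(1, 8),
               tolerance = 1e-9)

  # preprocessing-flagged rows are excluded even when labelled
  flagged <- fx$labels
  flagged$Preprocessing[1] <- "duplicate"
  ts2 <- prepareTrainingTable(fx$table, flagged, trainConfig())
  expect_equal(nrow(ts2$features), 11)

  none <- fx$labels
  none$LabelTrue <- ""
  expect_error(prepareTrainingTable(fx$table, none, trainConfig()),
               "no classes")
})

test_that("the dual-input network has the promised shapes", {
  cfg <- tinyTrainConfig()
  model <- buildModel(nFeatures = 13, nClasses = 3, cfg)
  expect_equal(nrow(model$params$featW1), 13)
  expect_equal(ncol(model$params$outW), 3)
  expect_error(buildModel(13, 1, cfg), "nClasses")

  set.seed(2)
  imgs <- array(runif(56 * 56 * 22), c(56, 56, 22))
  feats <- matrix(rnorm(22 * 13), 22, 13)
  model$classList <- c("a", "b", "c")
  probs <- predictProbabilities(model, imgs, feats)
  expect_identical(dim(probs), c(22L, 3L))
  expect_equal(unname(rowSums(probs)), rep(1, 22), tolerance = 1e-9)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("early stopping fires after exactly the patience window", {
  # validation loss worsening from epoch 1: epoch 1 is the best, epochs
  # 2..7 are six non-improving epochs, so training stops at epoch 7
  expect_identical(earlyStopEpoch(1:10, patience = 6L), 7L)
  # an improvement resets the counter
  expect_identical(earlyStopEpoch(c(5, 4, 6, 6, 6, 3, 4, 4, 4, 4, 4, 4),
                                  patience = 6L), 12L)
  expect_identical(earlyStopEpoch(c(3, 2, 1), patience = 6L), NA_integer_)
})

test_that("training is deterministic under a fixed seed and checkpoints on
           validation improvement", {
  set.seed(31)
  n <- 48
  cl <- factor(rep(c("a", "b"), each = n / 2))
  imgs <- array(runif(56 * 56 * n), c(56, 56, n))
  imgs[, , cl == "b"] <- imgs[, , cl == "b"] + 0.4
  feats <- matrix(rnorm(n * 4), n, 4)
  feats[cl == "b", 1] <- feats[cl == "b", 1] + 4
  sets <- list(images = imgs[, , 1:40], features = feats[1:40, ],
               classes = cl[1:40])
  val <- list(images = imgs[, , 41:48], features = feats[41:48, ],
              classes = cl[41:48])
  cfg <- tinyTrainConfig(seed = 7, maxEpochs = 4L)
  m1 <- trainModel(buildModel(4, 2, cfg), sets, val, cfg)
  m2 <- trainModel(buildModel(4, 2, cfg), sets, val, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 4)
  # the kept parameters correspond to the best validation loss seen
  expect_equal(min(m1$history$valLoss),
               m1$history$valLoss[which.min(m1$history$valLoss)])
})

test_that("predictParticles respects flags and fills scores in [0, 1]", {
  fx <- makeToyTrainingFixture()
  cfg <- tinyTrainConfig(seed = 5, maxEpochs = 2L)
  vigs <- replicate(20, matrix(runif(30 * 30), 30, 30), simplify = FALSE)
  ts <- prepareTrainingTable(fx$table, fx$labels, cfg, images = vigs)
  model <- buildModel(ncol(ts$features), 2, cfg)
  model$classList <- levels(ts$classes)
  model$featureNames <- ts$keptColumns
  model$center <- ts$center
  model$scale <- ts$scale

  labels <- fx$labels
  labels$Preprocessing[c(2, 5)] <- "duplicate"
  out <- predictParticles(model, fx$table, labels, vigs)
  eligible <- !nzchar(labels$Preprocessing)
  expect_true(all(nzchar(out$LabelPredicted[eligible])))
  expect_identical(out$LabelPredicted[c(2, 5)], c("", ""))
  sc <- out$ProbabilityScore[eligible]
  expect_true(all(sc >= 0 & sc <= 1))
  # true labels are never overwritten
  expect_identical(out$LabelTrue, labels$LabelTrue)

  allFlagged <- fx$labels
  allFlagged$Preprocessing <- "duplicate"
  expect_warning(same <- predictParticles(model, fx$table, allFlagged,
                                          vigs),
                 "flagged")
  expect_identical(same, allFlagged)

  bad <- model
  bad$featureNames <- c(model$featureNames, "MissingFeature")
  expect_error(predictParticles(bad, fx$table, labels, vigs),
               "MissingFeature")
})

test_that("confusion counts and the per-class report are consistent", {
  true <- c("a", "a", "a", "b", "b", "c")
  pred <- c("a", "a", "b", "b", "b", "a")
  rep <- classificationReport(pred, true)
  expect_equal(rep$N[rep$Class == "a"], 3)
  expect_equal(rep$Recall[rep$Class == "a"], 2 / 3)
  expect_equal(rep$Precision[rep$Class == "a"], 2 / 3)
  expect_equal(rep$F1[rep$Class == "b"],
               2 * (2 / 3) * 1 / (2 / 3 + 1))
  expect_equal(sum(rep$N), length(true))
})
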