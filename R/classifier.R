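# Dual-input (image + particle properties) classifier.
#
# Two branches: a shallow convolutional stack over the 224x224 vignette and
# a dense stack over the numeric particle properties. The branches are
# concatenated and sent through final dense + dropout layers and a softmax.
# No augmentation layers; overfitting is mitigated by dropout, by keeping
# only checkpoints that improve the validation loss, and by early stopping
# with a fixed patience.

#' Classifier training configuration
#'
#' @param imageSize input image side in pixels (square; vignettes are
#'   resized to this).
#' @param batchSize images/property-row pairs per gradient step.
#' @param patience early-stopping patience in epochs.
#' @param minClassSize classes with fewer labelled images are dropped.
#' @param dropoutRate dropout fraction in the dense layers.
#' @param maxEpochs training epoch cap.
#' @param learningRate Adam step size.
#' @param stemPool fixed average-pooling factor applied to the input image
#'   before the convolutional stack (parameter-free downsampling; 1
#'   disables).
#' @param convFilters,convStride,poolSize per-conv-block filters, stride and
#'   max-pool size (equal lengths).
#' @param denseImage units of the image-branch dense layer.
#' @param denseFeat units of the two feature-branch dense layers.
#' @param headUnits units of the post-concatenation dense layer.
#' @param valFraction stratified validation split fraction.
#' @param seed RNG seed for initialisation, shuffling, dropout and split.
#' @return list of class \code{"TrainConfig"}
#' @export
trainConfig <- function(imageSize = 224L, batchSize = 22L, patience = 6L,
                        minClassSize = 5L, dropoutRate = 0.3,
                        maxEpochs = 25L, learningRate = 1e-3,
                        stemPool = 2L,
                        convFilters = c(8L, 16L, 32L),
                        convStride = c(2L, 2L, 1L),
                        poolSize = c(2L, 2L, 2L),
                        denseImage = 64L, denseFeat = c(64L, 32L),
                        headUnits = 64L, valFraction = 0.2, seed = 1L) {
  stopifnot(imageSize > 0, batchSize > 0, patience >= 1, minClassSize >= 1,
            dropoutRate >= 0, dropoutRate < 1, maxEpochs >= 1,
            length(convFilters) == length(convStride),
            length(convFilters) == length(poolSize))
  structure(list(imageSize = as.integer(imageSize),
                 batchSize = as.integer(batchSize),
                 patience = as.integer(patience),
                 minClassSize = as.integer(minClassSize),
                 dropoutRate = dropoutRate, maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate,
                 stemPool = as.integer(stemPool),
                 convFilters = as.integer(convFilters),
                 convStride = as.integer(convStride),
                 poolSize = as.integer(poolSize),
                 denseImage = as.integer(denseImage),
                 denseFeat = as.integer(denseFeat),
                 headUnits = as.integer(headUnits),
                 valFraction = valFraction, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Prepare a training table from labelled particles
#'
#' Applies the training-set filters: preprocessing-flagged records are
#' excluded first, then rows without a true label are dropped; non-numeric
#' and date/time columns are dropped; columns constant over the remaining
#' rows are dropped; classes with fewer than \code{cfg$minClassSize} images
#' are dropped. Remaining features are standardised (mean 0, sd 1) and the
#' standardisation statistics are returned for reuse at prediction time.
#'
#' @param table a [ParticleTable-class].
#' @param labels label block aligned with the table (see [labelColumns()]).
#' @param cfg a [trainConfig()].
#' @param images optional list of vignette matrices aligned with the table;
#'   filtered and resized alongside the rows when given.
#' @return list with \code{features} (standardised numeric matrix),
#'   \code{classes} (factor of labels), \code{classList}, \code{center},
#'   \code{scale}, \code{keptColumns}, \code{droppedColumns} (named list by
#'   reason), \code{rowIndex} (indices into the original table), and
#'   \code{images} (resized array, when supplied).
#' @export
prepareTrainingTable <- function(table, labels, cfg = trainConfig(),
                                 images = NULL) {
  df <- if (is(table, "ParticleTable")) particleData(table) else table
  .checkLabelColumns(labels, nrow(df))
  keepRow <- !nzchar(labels$Preprocessing) & nzchar(labels$LabelTrue)
  lab <- labels$LabelTrue[keepRow]
  sub <- df[keepRow, , drop = FALSE]
  rowIndex <- which(keepRow)

  dropped <- list(nonNumeric = character(), dateTime = character(),
                  constant = character())
  isDateLike <- function(x, nm) {
    if (inherits(x, c("Date", "POSIXt"))) return(TRUE)
    grepl("date|time|timestamp", nm, ignore.case = TRUE)
  }
  keepCol <- character()
  for (nm in names(sub)) {
    x <- sub[[nm]]
    if (isDateLike(x, nm)) dropped$dateTime <- c(dropped$dateTime, nm)
    else if (!is.numeric(x)) dropped$nonNumeric <- c(dropped$nonNumeric, nm)
    else if (length(unique(x[!is.na(x)])) <= 1L)
      dropped$constant <- c(dropped$constant, nm)
    else keepCol <- c(keepCol, nm)
  }

  counts <- table(lab)
  small <- names(counts)[counts < cfg$minClassSize]
  keepClass <- !(lab %in% small)
  lab <- lab[keepClass]
  sub <- sub[keepClass, keepCol, drop = FALSE]
  rowIndex <- rowIndex[keepClass]
  if (length(unique(lab)) == 0L)
    stop("no classes remain after filtering")

  X <- as.matrix(sub)
  X[is.na(X)] <- 0
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  X <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  out <- list(features = X, classes = factor(lab),
              classList = sort(unique(lab)), center = center, scale = scale,
              keptColumns = keepCol, droppedColumns = dropped,
              droppedClasses = small, rowIndex = rowIndex)
  if (!is.null(images)) {
    sel <- images[rowIndex]
    arr <- array(0, c(cfg$imageSize, cfg$imageSize, length(sel)))
    for (i in seq_along(sel))
      arr[, , i] <- resizeVignette(sel[[i]], cfg$imageSize)
    out$images <- arr
  }
  out
}

#' Resize a vignette to the model input size
#'
#' Bilinear resize to a \code{size x size} grayscale matrix in [0, 1];
#' grayscale input is used as the single image channel.
#'
#' @param vignette numeric matrix.
#' @param size output side length in px.
#' @return numeric \code{size x size} matrix.
#' @export
resizeVignette <- function(vignette, size = 224L) {
  px <- if (is(vignette, "Image")) EBImage::imageData(vignette) else vignette
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  rng <- range(px, finite = TRUE)
  if (diff(rng) > 0 && rng[2L] > 1) px <- px / max(rng[2L], 1)
  EBImage::imageData(EBImage::resize(EBImage::Image(px), w = size, h = size))
}

#' Build the dual-input classifier
#'
#' Constructs the network: a convolutional + relu stack (3x3 kernels, max
#' pooling) over the image, a dense + relu + dropout stack over the
#' \code{nFeatures} particle properties, concatenation, a final dense +
#' dropout layer and a softmax over \code{nClasses}.
#'
#' @param nFeatures number of (standardised) property inputs (>= 1).
#' @param nClasses number of classes (>= 2).
#' @param cfg a [trainConfig()].
#' @return model object (list) with untrained parameters.
#' @export
buildModel <- function(nFeatures, nClasses, cfg = trainConfig()) {
  stopifnot(nFeatures >= 1)
  if (nClasses < 2) stop("nClasses must be >= 2")
  set.seed(cfg$seed)
  geoms <- list()
  H <- cfg$imageSize %/% cfg$stemPool; C <- 1L
  params <- list()
  for (k in seq_along(cfg$convFilters)) {
    g <- .convLayerGeom(H, H, C, cfg$convFilters[k], cfg$convStride[k])
    geoms[[k]] <- g
    params[[paste0("convW", k)]] <- .heInit(9L * C, g$F)
    params[[paste0("convB", k)]] <- numeric(g$F)
    H <- g$Ho %/% cfg$poolSize[k]
    C <- g$F
  }
  flat <- H * H * C
  params$imgW <- .heInit(flat, cfg$denseImage)
  params$imgB <- numeric(cfg$denseImage)
  params$featW1 <- .heInit(nFeatures, cfg$denseFeat[1L])
  params$featB1 <- numeric(cfg$denseFeat[1L])
  params$featW2 <- .heInit(cfg$denseFeat[1L], cfg$denseFeat[2L])
  params$featB2 <- numeric(cfg$denseFeat[2L])
  concat <- cfg$denseImage + cfg$denseFeat[2L]
  params$headW <- .heInit(concat, cfg$headUnits)
  params$headB <- numeric(cfg$headUnits)
  params$outW <- .heInit(cfg$headUnits, nClasses)
  params$outB <- numeric(nClasses)
  structure(list(cfg = cfg, geoms = geoms, params = params,
                 nFeatures = nFeatures, nClasses = nClasses,
                 flat = flat, finalSide = H,
                 idxCache = new.env(parent = emptyenv()),
                 classList = NULL, featureNames = NULL,
                 center = NULL, scale = NULL),
            class = "flowcamModel")
}

# forward pass on one batch; images: array c(S, S, B); feats: B x nFeatures
.modelForward <- function(model, images, feats, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- dim(images)[3L]
  A <- images
  dim(A) <- c(cfg$imageSize, cfg$imageSize, 1L, B)
  if (cfg$stemPool > 1L) A <- .avgPoolStem(A, cfg$stemPool)
  trace <- list()
  for (k in seq_along(model$geoms)) {
    cf <- .convForward(A, model$geoms[[k]], p[[paste0("convW", k)]],
                       p[[paste0("convB", k)]], model$idxCache)
    pf <- .poolForward(cf$out, cfg$poolSize[k])
    trace[[paste0("conv", k)]] <- cf
    trace[[paste0("pool", k)]] <- pf
    A <- aperm(pf$out, c(1L, 2L, 4L, 3L))  # -> c(H, W, C, B)
  }
  flatX <- t(matrix(A, model$flat, B))
  dImg <- .denseForward(flatX, p$imgW, p$imgB)
  f1 <- .denseForward(feats, p$featW1, p$featB1)
  do1 <- .dropoutForward(f1$out, cfg$dropoutRate, training)
  f2 <- .denseForward(do1$out, p$featW2, p$featB2)
  concat <- cbind(dImg$out, f2$out)
  hd <- .denseForward(concat, p$headW, p$headB)
  do2 <- .dropoutForward(hd$out, cfg$dropoutRate, training)
  outZ <- .denseForward(do2$out, p$outW, p$outB, relu = FALSE)
  probs <- .softmax(outZ$out)
  list(trace = trace, flatX = flatX, dImg = dImg, f1 = f1, do1 = do1,
       f2 = f2, concat = concat, hd = hd, do2 = do2, outZ = outZ,
       probs = probs, B = B)
}

.modelBackward <- function(model, fw, yIdx) {
  p <- model$params; cfg <- model$cfg
  B <- fw$B
  grads <- list()
  dZ <- fw$probs
  dZ[cbind(seq_len(B), yIdx)] <- dZ[cbind(seq_len(B), yIdx)] - 1
  dZ <- dZ / B
  g <- .denseBackward(fw$outZ, p$outW, dZ, relu = FALSE)
  grads$outW <- g$dW; grads$outB <- g$db
  dHdOut <- g$dX
  if (!is.null(fw$do2$mask)) dHdOut <- dHdOut * fw$do2$mask
  g <- .denseBackward(fw$hd, p$headW, dHdOut)
  grads$headW <- g$dW; grads$headB <- g$db
  dImgOut <- g$dX[, seq_len(cfg$denseImage), drop = FALSE]
  dF2Out <- g$dX[, cfg$denseImage + seq_len(cfg$denseFeat[2L]),
                 drop = FALSE]
  g <- .denseBackward(fw$f2, p$featW2, dF2Out)
  grads$featW2 <- g$dW; grads$featB2 <- g$db
  dF1Out <- g$dX
  if (!is.null(fw$do1$mask)) dF1Out <- dF1Out * fw$do1$mask
  g <- .denseBackward(fw$f1, p$featW1, dF1Out)
  grads$featW1 <- g$dW; grads$featB1 <- g$db
  g <- .denseBackward(fw$dImg, p$imgW, dImgOut)
  grads$imgW <- g$dW; grads$imgB <- g$db
  # back into the conv stack
  dA <- array(t(g$dX), c(model$finalSide, model$finalSide,
                         model$cfg$convFilters[length(model$geoms)], B))
  dA <- aperm(dA, c(1L, 2L, 4L, 3L))  # -> c(H, W, B, F)
  for (k in rev(seq_along(model$geoms))) {
    pf <- fw$trace[[paste0("pool", k)]]
    cf <- fw$trace[[paste0("conv", k)]]
    dConvOut <- .poolBackward(pf, dA)
    cb <- .convBackward(cf, model$geoms[[k]], p[[paste0("convW", k)]],
                        dConvOut, model$idxCache, needInputGrad = k > 1L)
    grads[[paste0("convW", k)]] <- cb$dW
    grads[[paste0("convB", k)]] <- cb$db
    if (k > 1L) {
      dA <- aperm(cb$dA, c(1L, 2L, 4L, 3L))  # c(H,W,C,B) -> c(H,W,B,C)
    }
  }
  grads
}

#' Epoch at which early stopping fires
#'
#' Given per-epoch validation losses, returns the epoch after which training
#' stops: the first epoch at which the loss has not improved over the
#' running best for \code{patience} consecutive epochs (NA if training runs
#' to the end of the schedule).
#'
#' @param valLosses numeric vector of validation losses by epoch.
#' @param patience non-improving epochs tolerated.
#' @return integer epoch index or NA.
#' @examples
#' earlyStopEpoch(c(1, 2, 3, 4, 5, 6, 7), patience = 6)  # 7
#' @export
earlyStopEpoch <- function(valLosses, patience = 6L) {
  best <- Inf; wait <- 0L
  for (e in seq_along(valLosses)) {
    if (valLosses[e] < best) {
      best <- valLosses[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

#' Train the dual-input classifier
#'
#' Mini-batch Adam with categorical cross-entropy. After every epoch the
#' validation loss is computed; parameters are checkpointed only when it
#' improves, and training stops early after \code{cfg$patience} epochs
#' without improvement (or at \code{cfg$maxEpochs}). Fully seeded: the same
#' seed gives an identical history.
#'
#' @param model a [buildModel()] result.
#' @param trainSet,valSet lists with \code{images} (array c(S, S, N)),
#'   \code{features} (N x P matrix) and \code{classes} (factor); disjoint
#'   splits (see [stratifiedSplit()]).
#' @param cfg a [trainConfig()]; defaults to the model's.
#' @param verbose print per-epoch progress.
#' @return the model with trained parameters (best checkpoint) and a
#'   \code{history} data.frame (epoch, loss, accuracy, valLoss,
#'   valAccuracy).
#' @export
trainModel <- function(model, trainSet, valSet, cfg = model$cfg,
                       verbose = FALSE) {
  nTr <- length(trainSet$classes)
  nVa <- length(valSet$classes)
  if (nTr == 0L || nVa == 0L) stop("empty training or validation split")
  set.seed(cfg$seed)
  yTr <- as.integer(factor(trainSet$classes, levels = model$classList %||%
                             levels(factor(trainSet$classes))))
  if (is.null(model$classList))
    model$classList <- levels(factor(trainSet$classes))
  yTr <- as.integer(factor(trainSet$classes, levels = model$classList))
  yVa <- as.integer(factor(valSet$classes, levels = model$classList))
  opt <- new.env(parent = emptyenv()); opt$m <- list(); opt$v <- list()
  tstep <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     accuracy = numeric(), valLoss = numeric(),
                     valAccuracy = numeric())
  best <- Inf; bestParams <- model$params; wait <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(nTr)
    epLoss <- 0; epHit <- 0L
    starts <- seq(1L, nTr, by = cfg$batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, nTr)]
      fw <- .modelForward(model,
                          trainSet$images[, , idx, drop = FALSE],
                          trainSet$features[idx, , drop = FALSE],
                          training = TRUE)
      pTrue <- fw$probs[cbind(seq_along(idx), yTr[idx])]
      epLoss <- epLoss - sum(log(pmax(pTrue, 1e-12)))
      epHit <- epHit + sum(max.col(fw$probs) == yTr[idx])
      grads <- .modelBackward(model, fw, yTr[idx])
      tstep <- tstep + 1L
      for (nm in names(grads))
        model$params[[nm]] <- model$params[[nm]] -
          .adamStep(opt, nm, grads[[nm]], cfg$learningRate, tstep)
    }
    va <- .evaluateModel(model, valSet$images, valSet$features, yVa,
                         cfg$batchSize)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = epLoss / nTr,
                                   accuracy = epHit / nTr,
                                   valLoss = va$loss,
                                   valAccuracy = va$accuracy))
    if (verbose)
      message(sprintf("epoch %d loss %.4f acc %.3f val %.4f/%.3f", epoch,
                      epLoss / nTr, epHit / nTr, va$loss, va$accuracy))
    if (va$loss < best) {
      best <- va$loss; bestParams <- model$params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- bestParams
  model$history <- hist
  model$stoppedEpoch <- nrow(hist)
  model
}

.evaluateModel <- function(model, images, feats, yIdx, batchSize) {
  n <- length(yIdx)
  loss <- 0; hit <- 0L
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    fw <- .modelForward(model, images[, , idx, drop = FALSE],
                        feats[idx, , drop = FALSE], training = FALSE)
    pTrue <- fw$probs[cbind(seq_along(idx), yIdx[idx])]
    loss <- loss - sum(log(pmax(pTrue, 1e-12)))
    hit <- hit + sum(max.col(fw$probs) == yIdx[idx])
  }
  list(loss = loss / n, accuracy = hit / n)
}

#' Class probabilities for a set of particles
#'
#' @param model a trained [trainModel()] result.
#' @param images array c(S, S, N) of resized vignettes.
#' @param features N x P matrix in the model's feature schema (standardised).
#' @return matrix N x nClasses of softmax probabilities, with the class list
#'   as column names.
#' @export
predictProbabilities <- function(model, images, features) {
  n <- dim(images)[3L]
  out <- matrix(NA_real_, n, model$nClasses)
  bs <- model$cfg$batchSize
  for (s in seq(1L, n, by = bs)) {
    idx <- s:min(s + bs - 1L, n)
    fw <- .modelForward(model, images[, , idx, drop = FALSE],
                        features[idx, , drop = FALSE], training = FALSE)
    out[idx, ] <- fw$probs
  }
  colnames(out) <- model$classList
  out
}

#' Predict labels for unflagged particles
#'
#' Applies the model to every record whose Preprocessing flag is empty and
#' fills \code{LabelPredicted} with the argmax class and
#' \code{ProbabilityScore} with its softmax probability. Flagged rows and
#' non-empty \code{LabelTrue} entries are left untouched.
#'
#' @param model a trained model (with feature schema and standardisation
#'   statistics, as produced by the training pipeline).
#' @param table a [ParticleTable-class].
#' @param labels the run's label block.
#' @param vignettes list of vignette matrices aligned with the table rows.
#' @return the updated label block.
#' @export
predictParticles <- function(model, table, labels, vignettes) {
  df <- if (is(table, "ParticleTable")) particleData(table) else table
  .checkLabelColumns(labels, nrow(df))
  eligible <- which(!nzchar(labels$Preprocessing))
  if (length(eligible) == 0L) {
    warning("all rows are preprocessing-flagged; nothing to predict")
    return(labels)
  }
  missing <- setdiff(model$featureNames, names(df))
  if (length(missing) > 0L)
    stop("table lacks feature column(s) the model was trained on: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(df[eligible, model$featureNames, drop = FALSE])
  X[is.na(X)] <- 0
  X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  arr <- array(0, c(model$cfg$imageSize, model$cfg$imageSize,
                    length(eligible)))
  for (i in seq_along(eligible))
    arr[, , i] <- resizeVignette(vignettes[[eligible[i]]],
                                 model$cfg$imageSize)
  probs <- predictProbabilities(model, arr, X)
  labels$LabelPredicted[eligible] <- model$classList[max.col(probs)]
  labels$ProbabilityScore[eligible] <- apply(probs, 1L, max)
  labels
}

#' Stratified train/validation split
#'
#' @param classes factor (or character) of class labels.
#' @param valFraction fraction per class assigned to validation.
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{val}.
#' @export
stratifiedSplit <- function(classes, valFraction = 0.2, seed = 1L) {
  set.seed(seed)
  val <- integer()
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    nVal <- max(1L, round(length(idx) * valFraction))
    val <- c(val, sample(idx, nVal))
  }
  list(train = setdiff(seq_along(classes), val), val = sort(val))
}

#' Per-class classification report
#'
#' Precision, recall and F1 per class plus support, from predicted and true
#' labels.
#'
#' @param predicted,true character/factor vectors of equal length.
#' @return data.frame with columns \code{Class}, \code{Precision},
#'   \code{Recall}, \code{F1}, \code{N}.
#' @export
classificationReport <- function(predicted, true) {
  classes <- sort(unique(c(as.character(predicted), as.character(true))))
  out <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & true == cl)
    fp <- sum(predicted == cl & true != cl)
    fn <- sum(predicted != cl & true == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(Class = cl, Precision = prec, Recall = rec, F1 = f1,
               N = sum(true == cl), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
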