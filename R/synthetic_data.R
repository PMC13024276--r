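# Synthetic FlowCam run generator.
#
# Produces a complete run directory: collage mosaics of rendered particle
# silhouettes, a property CSV in a chosen VSP dialect, a ground-truth CSV
# and a JSON spec capturing every parameter and the seed. All particle
# properties are measured from the rendered masks/vignettes, so the
# generator and the estimators are independent code paths.
#
# Ground-truth consistency is enforced by construction: records that the
# truth lists as non-duplicates are laid out so that at least one duplicate
# gate fails for every candidate pair, and injected duplicate pairs are
# verified to pass all gates (the properties the truth asserts are
# guaranteed, not merely probable).

#' Specification of a synthetic run
#'
#' @param nParticles total CSV rows, duplicates included.
#' @param shapeMix named proportions over disk/rod/filament/star (sum 1).
#' @param sizeRange particle size range in um (disk/star diameter, rod and
#'   filament length).
#' @param calibrationFactor um per pixel.
#' @param nDuplicatePairs injected duplicate pairs (<= nParticles / 2).
#' @param nClasses number of (intensity-separated) classes.
#' @param dialect VSP dialect id for the written CSV (see [vspDialects()]).
#' @param runName sample run name.
#' @param seed RNG seed; the whole run is a deterministic function of the
#'   spec.
#' @param particlesPerFrame mean particles per source image.
#' @param frameWidth,frameHeight source-frame extent in px (CaptureX/Y
#'   range).
#' @param collageWidth collage mosaic width in px.
#' @param noiseSd additive Gaussian pixel noise of the rendered vignettes.
#' @return list of class \code{"SyntheticRunSpec"}
#' @export
syntheticRunSpec <- function(nParticles = 120L,
                             shapeMix = c(disk = 0.4, rod = 0.3,
                                          filament = 0.2, star = 0.1),
                             sizeRange = c(10, 60),
                             calibrationFactor = 0.595,
                             nDuplicatePairs = 0L, nClasses = 3L,
                             dialect = "canonical", runName = "synthetic",
                             seed = 1L, particlesPerFrame = 6L,
                             frameWidth = 1800, frameHeight = 900,
                             collageWidth = 960L, noiseSd = 0.02) {
  stopifnot(nParticles >= 1L, abs(sum(shapeMix) - 1) < 1e-8,
            all(shapeMix >= 0), sizeRange[1L] > 0,
            sizeRange[1L] <= sizeRange[2L], calibrationFactor > 0,
            nClasses >= 1L)
  if (nDuplicatePairs > nParticles / 2)
    stop("infeasible spec: nDuplicatePairs exceeds nParticles / 2")
  if (!dialect %in% names(vspDialects()))
    stop("unknown dialect '", dialect, "'")
  structure(list(nParticles = as.integer(nParticles), shapeMix = shapeMix,
                 sizeRange = sizeRange,
                 calibrationFactor = calibrationFactor,
                 nDuplicatePairs = as.integer(nDuplicatePairs),
                 nClasses = as.integer(nClasses), dialect = dialect,
                 runName = runName, seed = as.integer(seed),
                 particlesPerFrame = as.integer(particlesPerFrame),
                 frameWidth = frameWidth, frameHeight = frameHeight,
                 collageWidth = as.integer(collageWidth),
                 noiseSd = noiseSd),
            class = "SyntheticRunSpec")
}

# render one particle: mask + vignette + measured properties
.renderParticle <- function(shape, sizeUm, classMean, cal, noiseSd) {
  sizePx <- sizeUm / cal
  mask <- switch(shape,
    disk = rasterDisk(sizePx / 2),
    rod = rasterRect(sizePx, max(3, sizePx * runif(1, 0.2, 0.35))),
    filament = rasterFilament(steps = max(10L, round(sizePx)),
                              thickness = max(1L, round(sizePx / 18))),
    star = rasterStar(sizePx / 2, points = sample(5:7, 1L)))
  mask <- .cropMask(mask)
  img <- matrix(0.85, nrow(mask), ncol(mask))
  level <- min(max(classMean + rnorm(1, 0, 0.05), 0.05), 0.75)
  img[mask] <- level
  img <- img + matrix(rnorm(length(img), 0, noiseSd), nrow(img))
  img <- pmin(pmax(img, 0), 1)

  st <- shapeStats(mask)
  fg <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(fg)
  hullPts <- fg[c(h, h[1L]), , drop = FALSE]
  hullPerim <- sum(sqrt(rowSums(diff(hullPts)^2)))
  inten <- mean(img[mask]) * 255
  feats <- c(
    EdgeGradient = abs(0.85 - level) * 255 * runif(1, 0.85, 1),
    AbdArea = st$areaPx * cal^2,
    AbdDiameter = st$ecdPx * cal,
    AvgBlue = inten * runif(1, 0.98, 1.02),
    AvgGreen = inten * runif(1, 0.98, 1.02),
    AvgRed = inten * runif(1, 0.98, 1.02),
    Intensity = inten,
    Length = st$majorAxisPx * cal,
    Width = st$minorAxisPx * cal,
    Perimeter = st$perimeterPx * cal,
    Roughness = max(1, st$perimeterPx / max(hullPerim, 1e-6)),
    SigmaIntensity = stats::sd(img[mask]) * 255,
    Transparency = level / 0.85)
  list(mask = mask, img = img, feats = feats, stats = st)
}

.gatesAgainst <- function(i, j, rec, cfg) {
  # returns TRUE if the pair (i, j) would be duplicate-linked
  if (abs(rec$SourceImage[i] - rec$SourceImage[j]) > cfg$frameWindow)
    return(FALSE)
  if (abs(rec$CaptureX[i] - rec$CaptureX[j]) >= cfg$maxXOffset)
    return(FALSE)
  ov <- iou(c(rec$CaptureX[i], rec$CaptureY[i], rec$ImageW[i], rec$ImageH[i]),
            c(rec$CaptureX[j], rec$CaptureY[j], rec$ImageW[j], rec$ImageH[j]))
  if (ov >= cfg$minIou) return(TRUE)
  u <- as.numeric(rec[i, duplicateFeatureNames()])
  v <- as.numeric(rec[j, duplicateFeatureNames()])
  sum(u * v) / sqrt(sum(u^2) * sum(v^2)) >= cfg$minCosine
}

#' Generate a synthetic FlowCam run
#'
#' Writes collage TIFFs, a property CSV in the requested dialect, a
#' ground-truth CSV (\code{<run>_groundtruth.csv}: shape, true size,
#' analytic volume where a closed form exists, class, duplicate partner) and
#' a JSON spec file. Duplicate pairs are injected as near-copies in nearby
#' source frames at x-offsets under 100 px that pass all four duplicate
#' gates; with \code{nearMissGate} set, injected pairs instead violate
#' exactly the named gate and the truth marks them non-duplicates.
#'
#' @param spec a [syntheticRunSpec()].
#' @param outDir output directory (created).
#' @param nearMissGate NULL, \code{"frame_window"}, \code{"x_offset"} or
#'   \code{"iou_and_cosine"}.
#' @param writeImages write collage TIFFs (disable for CSV-only fixtures).
#' @return invisibly, a list: \code{csv}, \code{groundTruth}, \code{specFile},
#'   \code{collageFiles}, \code{table} (canonical data.frame), \code{truth}
#'   (data.frame), \code{masks} and \code{vignettes} (lists, in row order).
#' @export
generateRun <- function(spec, outDir, nearMissGate = NULL,
                        writeImages = TRUE) {
  stopifnot(inherits(spec, "SyntheticRunSpec"))
  if (!is.null(nearMissGate))
    nearMissGate <- match.arg(nearMissGate,
                              c("frame_window", "x_offset",
                                "iou_and_cosine"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  dcfg <- duplicateConfig()
  nDup <- spec$nDuplicatePairs
  nBase <- spec$nParticles - nDup
  cal <- spec$calibrationFactor

  shapes <- sample(names(spec$shapeMix), nBase, replace = TRUE,
                   prob = spec$shapeMix)
  classes <- sample(rep_len(seq_len(spec$nClasses), nBase))  # balanced
  classMeans <- seq(0.2, 0.7, length.out = spec$nClasses)
  sizes <- runif(nBase, spec$sizeRange[1L], spec$sizeRange[2L])

  parts <- vector("list", nBase)
  rec <- NULL
  for (i in seq_len(nBase)) {
    p <- .renderParticle(shapes[i], sizes[i], classMeans[classes[i]], cal,
                         spec$noiseSd)
    parts[[i]] <- p
    row <- data.frame(SourceImage = (i - 1L) %/% spec$particlesPerFrame + 1L,
                      CaptureX = runif(1, 0, spec$frameWidth),
                      CaptureY = runif(1, 0, spec$frameHeight),
                      ImageW = nrow(p$mask), ImageH = ncol(p$mask),
                      t(p$feats), stringsAsFactors = FALSE)
    rec <- rbind(rec, row)
    # enforce: this original must not duplicate-link to any earlier one
    tries <- 0L
    # only records few frames back can be in the window (frames are
    # assigned sequentially), so the scan is bounded
    jFrom <- max(1L, i - (dcfg$frameWindow + 1L) * spec$particlesPerFrame)
    while (tries < 50L) {
      conflict <- FALSE
      for (j in jFrom:max(jFrom, i - 1L)) {
        if (j < i && .gatesAgainst(i, j, rec, dcfg)) {
          conflict <- TRUE
          break
        }
      }
      if (!conflict) break
      rec$CaptureX[i] <- runif(1, 0, spec$frameWidth)
      rec$CaptureY[i] <- runif(1, 0, spec$frameHeight)
      tries <- tries + 1L
    }
    if (tries == 50L)
      stop("could not lay out non-duplicate particles; ",
           "frame too crowded for the requested run")
  }
  truth <- data.frame(Row = seq_len(nBase), Shape = shapes, Class = classes,
                      SizeUm = sizes,
                      AnalyticVolumeUm3 = ifelse(shapes == "disk",
                        4 / 3 * pi * (sizes / 2)^3, NA_real_),
                      DuplicateOfRow = NA_integer_,
                      NearMissOfRow = NA_integer_,
                      stringsAsFactors = FALSE)
  # analytic cylinder volume for rods: width measured from the mask
  for (i in which(shapes == "rod")) {
    wid <- sum(parts[[i]]$mask) / max(1, nrow(parts[[i]]$mask) - 4L)
    truth$AnalyticVolumeUm3[i] <- pi * (wid * cal / 2)^2 * sizes[i]
  }

  # inject duplicate (or near-miss) partners; if a source particle sits in
  # a neighbourhood too crowded to place a conforming partner, move on to
  # another source
  srcPool <- if (nDup > 0L) sample(seq_len(nBase)) else integer()
  nInjected <- 0L
  for (s in srcPool) {
    if (nInjected == nDup) break
    i <- nrow(rec) + 1L
    jitter <- function(x, a) x * (1 + runif(length(x), -a, a))
    gate <- if (is.null(nearMissGate)) "pass" else nearMissGate
    featJitter <- if (gate == "iou_and_cosine") 0.15 else 1e-5
    fn <- duplicateFeatureNames()
    tries <- 0L
    placed <- FALSE
    repeat {
      dFrame <- if (gate == "frame_window")
        dcfg$frameWindow + sample(1:3, 1L) else sample(1:2, 1L)
      dx <- if (gate == "x_offset") sample(c(-1, 1), 1L) *
        runif(1, dcfg$maxXOffset, dcfg$maxXOffset + 80)
        else runif(1, -60, 60)
      cand <- rec[s, , drop = FALSE]
      cand$SourceImage <- cand$SourceImage + dFrame
      cand$CaptureX <- min(max(cand$CaptureX + dx, 0),
                           spec$frameWidth + 200)
      cand$CaptureY <- if (gate == "iou_and_cosine")
        (cand$CaptureY + cand$ImageH + 50) %% spec$frameHeight
        else cand$CaptureY + runif(1, -5, 5)
      cand[fn] <- jitter(as.numeric(rec[s, fn]), featJitter)
      rec2 <- rbind(rec, cand)
      u <- as.numeric(rec2[s, fn]); v <- as.numeric(rec2[i, fn])
      cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      ov <- iou(c(rec2$CaptureX[s], rec2$CaptureY[s], rec2$ImageW[s],
                  rec2$ImageH[s]),
                c(rec2$CaptureX[i], rec2$CaptureY[i], rec2$ImageW[i],
                  rec2$ImageH[i]))
      xdiff <- abs(rec2$CaptureX[s] - rec2$CaptureX[i])
      ok <- switch(gate,
        pass = xdiff < dcfg$maxXOffset && cs >= dcfg$minCosine,
        frame_window = xdiff < dcfg$maxXOffset && cs >= dcfg$minCosine,
        x_offset = xdiff >= dcfg$maxXOffset && cs >= dcfg$minCosine,
        iou_and_cosine = xdiff < dcfg$maxXOffset &&
          cs < dcfg$minCosine && ov < dcfg$minIou)
      # the partner must not link to any third record
      third <- setdiff(seq_len(nrow(rec2) - 1L), s)
      clash <- any(vapply(third, function(j)
        .gatesAgainst(nrow(rec2), j, rec2, dcfg), logical(1)))
      if (ok && !clash) {
        rec <- rec2
        placed <- TRUE
        break
      }
      tries <- tries + 1L
      if (tries > 60L) break
    }
    if (!placed) next
    parts[[i]] <- parts[[s]]
    nInjected <- nInjected + 1L
    truth <- rbind(truth, data.frame(Row = i, Shape = shapes[s],
      Class = classes[s], SizeUm = sizes[s],
      AnalyticVolumeUm3 = truth$AnalyticVolumeUm3[s],
      DuplicateOfRow = if (gate == "pass") s else NA_integer_,
      NearMissOfRow = if (gate == "pass") NA_integer_ else s,
      stringsAsFactors = FALSE))
  }
  if (nInjected < nDup)
    stop("could not inject the requested number of duplicate pairs; ",
         "the run is too crowded")

  # final row order: by source image (stable), then re-id
  ord <- order(rec$SourceImage)
  rec <- rec[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  parts <- parts[ord]
  n <- nrow(rec)
  rowOfOld <- match(seq_len(n), ord)  # old row -> new row
  truth$DuplicateOfRow <- rowOfOld[truth$DuplicateOfRow]
  truth$NearMissOfRow <- rowOfOld[truth$NearMissOfRow]
  rec$Id <- seq_len(n)
  truth$Id <- seq_len(n)
  truth$DuplicateOfId <- truth$DuplicateOfRow
  truth$NearMissOfId <- truth$NearMissOfRow
  truth$Class <- paste0("Class", LETTERS[truth$Class])
  truth$Row <- truth$DuplicateOfRow <- truth$NearMissOfRow <- NULL

  # pack vignettes into collage mosaics
  rec$CollageFile <- ""
  rec$ImageX <- 0L; rec$ImageY <- 0L
  collages <- list()
  cw <- spec$collageWidth
  curW <- 0L; curRowH <- 0L; curY <- 0L; pageRows <- list(); page <- 1L
  placed <- list()
  for (i in seq_len(n)) {
    w <- nrow(parts[[i]]$mask); h <- ncol(parts[[i]]$mask)
    if (curW + w > cw && curW > 0L) {
      curY <- curY + curRowH; curW <- 0L; curRowH <- 0L
    }
    if (curY + h > 600L && curY > 0L) {
      collages[[page]] <- placed; placed <- list()
      page <- page + 1L; curY <- 0L; curW <- 0L; curRowH <- 0L
    }
    placed[[length(placed) + 1L]] <- list(i = i, x = curW, y = curY)
    rec$CollageFile[i] <- sprintf("%s_%06d.tif", spec$runName, page)
    rec$ImageX[i] <- curW; rec$ImageY[i] <- curY
    curW <- curW + w
    curRowH <- max(curRowH, h)
  }
  collages[[page]] <- placed

  collageFiles <- character()
  if (writeImages) {
    for (pg in seq_along(collages)) {
      pl <- collages[[pg]]
      if (length(pl) == 0L) next
      hMax <- max(vapply(pl, function(z)
        z$y + ncol(parts[[z$i]]$mask), numeric(1)))
      canvas <- matrix(0.85, cw, hMax)
      for (z in pl) {
        p <- parts[[z$i]]
        canvas[(z$x + 1L):(z$x + nrow(p$img)),
               (z$y + 1L):(z$y + ncol(p$img))] <- p$img
      }
      f <- file.path(outDir, sprintf("%s_%06d.tif", spec$runName, pg))
      EBImage::writeImage(EBImage::Image(canvas), f, type = "tiff",
                          compression = "none")
      collageFiles <- c(collageFiles, f)
    }
  }

  rec$CalibrationFactor <- cal
  cols <- canonicalColumns()
  table <- rec[, cols]
  rownames(table) <- NULL

  # write the CSV in the requested dialect
  d <- vspDialects()[[spec$dialect]]
  inv <- setNames(names(d@columnMap), d@columnMap)
  out <- table
  names(out) <- ifelse(names(out) %in% names(inv), inv[names(out)],
                       names(out))
  csvPath <- file.path(outDir, paste0(spec$runName, ".csv"))
  data.table::fwrite(out, csvPath, sep = ",", dec = ".", quote = "auto",
                     na = "")
  gtPath <- file.path(outDir, paste0(spec$runName, "_groundtruth.csv"))
  data.table::fwrite(truth, gtPath, sep = ",", na = "")
  specPath <- file.path(outDir, paste0(spec$runName, "_spec.json"))
  jsonlite::write_json(c(unclass(spec),
                         list(nearMissGate = nearMissGate)),
                       specPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv = csvPath, groundTruth = gtPath, specFile = specPath,
                 collageFiles = collageFiles, table = table, truth = truth,
                 masks = lapply(parts, `[[`, "mask"),
                 vignettes = lapply(parts, `[[`, "img")))
}

#' Generate a run whose injected pairs violate exactly one duplicate gate
#'
#' Negative-control fixture: every injected pair fails only the named gate
#' (\code{"frame_window"}: 6+ frames apart; \code{"x_offset"}: >= 100 px
#' apart; \code{"iou_and_cosine"}: IoU < 0.30 and cosine < 0.999) and the
#' ground truth marks them as non-duplicates.
#'
#' @inheritParams generateRun
#' @param whichGate the gate to violate.
#' @return as [generateRun()].
#' @export
generateNearMissDuplicates <- function(spec, outDir, whichGate,
                                       writeImages = TRUE) {
  generateRun(spec, outDir, nearMissGate = whichGate,
              writeImages = writeImages)
}
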