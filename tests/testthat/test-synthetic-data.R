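# The synthetic run generator: determinism, ground-truth consistency,
# dialect round trips, near-miss negative controls.

test_that("the same spec and seed give byte-identical outputs", {
  spec <- syntheticRunSpec(nParticles = 30, nDuplicatePairs = 3, seed = 9,
                           runName = "det")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generateRun(spec, d1)
  r2 <- generateRun(spec, d2)
  for (f in c("det.csv", "det_groundtruth.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
  expect_identical(basename(r1$collageFiles), basename(r2$collageFiles))
  for (f in basename(r1$collageFiles))
    expect_identical(readBin(file.path(d1, f), "raw", 1e8),
                     readBin(file.path(d2, f), "raw", 1e8), label = f)
})

test_that("row counts, sizes and truth alignment are as requested", {
  spec <- syntheticRunSpec(nParticles = 50, nDuplicatePairs = 4, seed = 2,
                           runName = "n50")
  r <- generateRun(spec, withr::local_tempdir(), writeImages = FALSE)
  expect_equal(nrow(r$table), 50)
  expect_equal(nrow(r$truth), 50)
  expect_identical(r$table$Id, r$truth$Id)
  expect_equal(sum(!is.na(r$truth$DuplicateOfId)), 4)

  # measured ABD diameter tracks the true disk diameter to about a pixel
  disks <- which(r$truth$Shape == "disk")
  cal <- spec$calibrationFactor
  expect_true(all(abs(r$table$AbdDiameter[disks] -
                        r$truth$SizeUm[disks]) <= 1.5 * cal))
  expect_error(syntheticRunSpec(nParticles = 10, nDuplicatePairs = 6),
               "infeasible")
})

test_that("generated CSVs pass dialect detection and round-trip", {
  for (id in c("v1_8", "v4_19", "v6_0", "canonical")) {
    dir <- withr::local_tempdir()
    spec <- syntheticRunSpec(nParticles = 15, seed = 4, dialect = id,
                             runName = paste0("rt", id))
    r <- generateRun(spec, dir, writeImages = FALSE)
    tab <- readRun(r$csv)
    expect_identical(dialect(tab)@versionId, id)
    expect_true(all(canonicalColumns() %in% names(particleData(tab))))
    # unified values identical to the canonical in-memory table
    expect_equal(particleData(tab)[, canonicalColumns()],
                 r$table[, canonicalColumns()], tolerance = 1e-12)
  }
})

test_that("near-miss fixtures violate exactly the named gate", {
  cfgD <- duplicateConfig()
  for (gate in c("frame_window", "x_offset", "iou_and_cosine")) {
    spec <- syntheticRunSpec(nParticles = 40, nDuplicatePairs = 5,
                             seed = 8, runName = gate)
    r <- generateNearMissDuplicates(spec, withr::local_tempdir(), gate,
                                    writeImages = FALSE)
    expect_true(all(is.na(r$truth$DuplicateOfId)))
    pairs <- which(!is.na(r$truth$NearMissOfId))
    expect_length(pairs, 5)
    for (i in pairs) {
      j <- which(r$truth$Id == r$truth$NearMissOfId[i])
      frameDiff <- abs(r$table$SourceImage[i] - r$table$SourceImage[j])
      xDiff <- abs(r$table$CaptureX[i] - r$table$CaptureX[j])
      u <- as.numeric(r$table[i, duplicateFeatureNames()])
      v <- as.numeric(r$table[j, duplicateFeatureNames()])
      cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      ov <- iou(unlist(r$table[i, c("CaptureX", "CaptureY", "ImageW",
                                    "ImageH")]),
                unlist(r$table[j, c("CaptureX", "CaptureY", "ImageW",
                                    "ImageH")]))
      if (gate == "frame_window") {
        expect_gt(frameDiff, cfgD$frameWindow)
        expect_lt(xDiff, cfgD$maxXOffset)
        expect_gte(cs, cfgD$minCosine)
      } else if (gate == "x_offset") {
        expect_lte(frameDiff, cfgD$frameWindow)
        expect_gte(xDiff, cfgD$maxXOffset)
        expect_gte(cs, cfgD$minCosine)
      } else {
        expect_lte(frameDiff, cfgD$frameWindow)
        expect_lt(xDiff, cfgD$maxXOffset)
        expect_lt(cs, cfgD$minCosine)
        expect_lt(ov, cfgD$minIou)
      }
    }
    # and the detector flags nothing
    expect_identical(unique(flagDuplicates(r$table)), "")
  }
})

test_that("ground-truth analytic volumes agree with the estimators", {
  spec <- syntheticRunSpec(nParticles = 24, seed = 6, runName = "vol",
                           shapeMix = c(disk = 0.5, rod = 0.5,
                                        filament = 0, star = 0))
  r <- generateRun(spec, withr::local_tempdir(), writeImages = FALSE)
  cal <- spec$calibrationFactor
  for (i in seq_len(nrow(r$truth))) {
    est <- computeBiovolume(r$masks[[i]], calibration = cal)
    expect_equal(est$volume, r$truth$AnalyticVolumeUm3[i],
                 tolerance = 0.07,
                 label = paste(r$truth$Shape[i], "row", i))
  }
})
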