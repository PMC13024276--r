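# Biovolume estimators, routing, calibration scaling.

sphereVol <- function(r) 4 / 3 * pi * r^3
sphereSurf <- function(r) 4 * pi * r^2

test_that("selectMethod follows the hull-ratio and eccentricity criteria", {
  mk <- function(hullRatio, ecc, ecdMajor)
    list(areaPx = 1000, convexAreaPx = 1000 * hullRatio,
         eccentricity = ecc, majorAxisPx = 100,
         ecdPx = 100 * ecdMajor, perimeterPx = 100)
  expect_identical(selectMethod(mk(1.05, 0.95, 0.3)), "SOR")  # gate 1
  expect_identical(selectMethod(mk(1.5, 0.95, 0.3)), "DM")    # both fail
  expect_identical(selectMethod(mk(1.3, 0.5, 0.9)), "SOR")    # gate 2
  expect_identical(selectMethod(mk(1.3, 0.5, 0.7)), "DM")
  expect_identical(selectMethod(mk(1.3, 0.9, 0.9)), "DM")
})

test_that("solid of revolution reproduces cylinder and sphere volumes", {
  cyl <- biovolumeSor(rasterRect(100, 10))
  expect_equal(cyl$volumePx3, pi * 25 * 100, tolerance = 0.02)

  sph <- biovolumeSor(rasterDisk(50))
  expect_equal(sph$volumePx3, sphereVol(50), tolerance = 0.02)
  expect_equal(sph$surfacePx2, sphereSurf(50), tolerance = 0.03)

  expect_equal(biovolumeSor(matrix(FALSE, 4, 4)),
               list(volumePx3 = 0, surfacePx2 = 0))
})

test_that("solid of revolution is rotation invariant within 3 percent", {
  rect <- rasterRect(100, 10)
  ref <- biovolumeSor(rect)$volumePx3
  for (deg in c(10, 45, 60)) {
    rot <- biovolumeSor(rotateMask(rect, deg))$volumePx3
    expect_equal(rot, ref, tolerance = 0.03,
                 label = paste("rotation", deg, "deg"))
  }
})

test_that("distance-map estimator satisfies the sphere identities", {
  disk <- rasterDisk(50)
  dm <- biovolumeDm(disk)
  expect_equal(dm$volumePx3, sphereVol(50), tolerance = 0.02)
  expect_equal(dm$surfacePx2, sphereSurf(50), tolerance = 0.02)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(biovolumeDm(single)$volumePx3, 4)

  expect_equal(biovolumeDm(matrix(FALSE, 3, 3)),
               list(volumePx3 = 0, surfacePx2 = 0))
})

test_that("DM volume is 4x the exhaustive distance-map sum", {
  set.seed(4)
  mask <- rasterStar(14, points = 5)
  expect_equal(biovolumeDm(mask)$volumePx3,
               4 * sum(bruteForceDistanceMap(mask)), tolerance = 1e-12)
})

test_that("both estimators converge on spheres as radius grows", {
  errSor <- errDm <- numeric()
  for (r in c(10, 20, 50, 100)) {
    disk <- rasterDisk(r)
    errSor <- c(errSor, abs(biovolumeSor(disk)$volumePx3 / sphereVol(r) - 1))
    errDm <- c(errDm, abs(biovolumeDm(disk)$volumePx3 / sphereVol(r) - 1))
  }
  expect_lt(errSor[4], 0.01)
  expect_lt(errDm[4], 0.01)
  expect_true(all(diff(errDm) < 0))  # strictly shrinking discretization bias
})

test_that("volume scales as c^3 and surface as c^2 under calibration", {
  disk <- rasterDisk(30)
  base <- computeBiovolume(disk, calibration = 1)
  scaled <- computeBiovolume(disk, calibration = 2)
  expect_equal(scaled$volume, base$volume * 8, tolerance = 1e-12)
  expect_equal(scaled$surfaceArea, base$surfaceArea * 4, tolerance = 1e-12)
  expect_identical(base$method, "SOR")

  uncal <- computeBiovolume(disk, calibration = NA)
  expect_false(uncal$unitsCalibrated)
  expect_equal(uncal$volume, base$volume)
})

test_that("estimators are translation invariant", {
  star <- rasterStar(12, points = 5)
  big <- matrix(FALSE, 64, 64)
  big[3:(2 + nrow(star)), 3:(2 + ncol(star))] <- star
  moved <- matrix(FALSE, 64, 64)
  moved[25:(24 + nrow(star)), 30:(29 + ncol(star))] <- star
  expect_equal(biovolumeDm(big), biovolumeDm(moved), tolerance = 1e-12)
  expect_equal(biovolumeSor(big)$volumePx3, biovolumeSor(moved)$volumePx3,
               tolerance = 1e-9)
})

test_that("routing on constructed rasters: disk to SOR, spiky star to DM", {
  stD <- shapeStats(rasterDisk(40))
  expect_lt(stD$convexAreaPx / stD$areaPx, 1.2)
  expect_identical(computeBiovolume(rasterDisk(40), 1)$method, "SOR")

  star <- rasterStar(40, points = 5)
  stS <- shapeStats(star)
  expect_gte(stS$convexAreaPx / stS$areaPx, 1.2)
  expect_false(stS$eccentricity < 0.8 &&
                 stS$ecdPx / stS$majorAxisPx > 0.8)
  expect_identical(computeBiovolume(star, 1)$method, "DM")
})

test_that("run-level biovolume from collages tracks analytic volumes", {
  dir <- withr::local_tempdir()
  spec <- syntheticRunSpec(nParticles = 30, seed = 13, runName = "bv",
                           shapeMix = c(disk = 0.6, rod = 0.4,
                                        filament = 0, star = 0))
  r <- generateRun(spec, dir)
  tab <- readRun(r$csv)
  bv <- computeRunBiovolume(tab, dir)
  ok <- !is.na(r$truth$AnalyticVolumeUm3)
  relErr <- abs(bv$Biovolume[ok] / r$truth$AnalyticVolumeUm3[ok] - 1)
  expect_lt(stats::median(relErr), 0.03)
  expect_lt(max(relErr), 0.10)
  expect_true(all(bv$UnitsCalibrated[ok]))
  expect_true(all(bv$SurfaceArea[ok] > 0))
})
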