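# CSV dialect detection, unification, LabelChecker round trips and class
# codes.

test_that("detectDialect handles canonical, unknown and degenerate headers", {
  d <- detectDialect(canonicalColumns())
  expect_s4_class(d, "VspDialect")
  expect_identical(d@versionId, "canonical")
  expect_identical(unname(d@columnMap), names(d@columnMap))

  expect_warning(d2 <- detectDialect(c(canonicalColumns(), "Foo")),
                 "Foo")
  expect_identical(d2@versionId, "canonical")
  expect_identical(attr(d2, "unknownColumns"), "Foo")

  expect_error(detectDialect(character()), "empty header")
  expect_error(detectDialect(c("Banana", "Apple")), "unknown dialect")
})

test_that("every shipped dialect is detected from its own alias header", {
  dialects <- vspDialects()
  for (id in setdiff(names(dialects), "canonical")) {
    hdr <- names(dialects[[id]]@columnMap)
    got <- detectDialect(hdr)
    expect_identical(got@versionId, id, label = paste("dialect", id))
    expect_setequal(unifyHeader(hdr, got),
                    unname(dialects[[id]]@columnMap))
  }
})

test_that("header unification is idempotent", {
  hdr <- names(vspDialects()$v1_8@columnMap)
  once <- unifyHeader(hdr)
  expect_identical(unifyHeader(once), once)
})

test_that("readRun unifies aliases, preserves order and never writes", {
  dir <- withr::local_tempdir()
  spec <- syntheticRunSpec(nParticles = 40, dialect = "v1_8", seed = 3,
                           runName = "aliasrun")
  r <- generateRun(spec, dir, writeImages = FALSE)
  before <- tools::md5sum(r$csv)

  tab <- readRun(r$csv)
  expect_s4_class(tab, "ParticleTable")
  expect_identical(dialect(tab)@versionId, "v1_8")
  expect_equal(nParticles(tab), 40)
  expect_true(all(canonicalColumns() %in% names(particleData(tab))))
  expect_identical(particleData(tab)$Id, 1:40)  # order preserved

  expect_identical(tools::md5sum(r$csv), before)  # non-destructive
  expect_error(readRun(file.path(dir, "missing.csv")), "not found")
})

test_that("LabelChecker write/read round trip is lossless", {
  dir <- withr::local_tempdir()
  tab <- exampleParticleTable()
  labels <- labelColumns(nParticles(tab))
  labels$Preprocessing[2] <- "duplicate"
  labels$LabelTrue[3] <- "BacAstfor_3192686"
  labels$LabelPredicted[4] <- "ChlPanmor_0000000"
  labels$ProbabilityScore[4] <- 0.93
  labels$Biovolume <- (1:6) * 1234.56789
  labels$SurfaceArea <- (1:6) * 98.7654321

  out <- writeLabelCheckerCsv(tab, labels, dir)
  expect_identical(basename(out), "LabelChecker_example.csv")

  z <- readLabelCheckerCsv(out)
  expect_equal(particleData(z$table), particleData(tab))
  expect_equal(z$labels, labels)
  expect_equal(z$labels$ProbabilityScore[4], 0.93)

  # output column count = input + 7
  raw <- read.csv(out, check.names = FALSE)
  expect_equal(ncol(raw), ncol(particleData(tab)) + 7L)
  expect_identical(tail(names(raw), 7L), labelColumnNames())

  # write-after-read reproduces the file byte for byte
  out2 <- writeLabelCheckerCsv(z$table, z$labels, withr::local_tempdir())
  expect_identical(readBin(out, "raw", 1e6), readBin(out2, "raw", 1e6))
})

test_that("LabelChecker format violations are rejected with clear errors", {
  dir <- withr::local_tempdir()
  tab <- exampleParticleTable()
  expect_error(writeLabelCheckerCsv(tab, labelColumns(3), dir),
               "aligned 1:1")

  out <- writeLabelCheckerCsv(tab, labelColumns(nParticles(tab)), dir)
  df <- read.csv(out, check.names = FALSE)
  df$Biovolume <- NULL
  broken <- file.path(dir, "LabelChecker_broken.csv")
  write.csv(df, broken, row.names = FALSE)
  expect_error(readLabelCheckerCsv(broken), "Biovolume")

  bad <- labelColumns(nParticles(tab))
  bad$LabelPredicted[1] <- "x"  # prediction without probability
  expect_error(writeLabelCheckerCsv(tab, bad, dir), "ProbabilityScore")
})

test_that("class codes follow the 3+3+3 letter and fallback rules", {
  expect_identical(
    makeClassCode("Bacillariophyceae", "Asterionella", "formosa",
                  "3192686"),
    "BacAstfor_3192686")
  expect_identical(makeClassCode("Bacillariophyceae", "Navicula", "",
                                 "1234567"),
                   "BacNav000_1234567")
  expect_identical(makeClassCode("Chlorophyceae", "Pandorina", "morum", ""),
                   "ChlPanmor_0000000")
  expect_error(makeClassCode("Ba"), "3 letters")
  expect_error(makeClassCode("Bacillariophyceae", gbifId = "12x"), "digits")
})
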