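test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulationConfig(nPolymers = 8, seed = 5)
  a <- generatePolymerLibrary(cfg)
  b <- generatePolymerLibrary(cfg)
  expect_identical(descriptorValues(a$descriptors), descriptorValues(b$descriptors))
  expect_identical(a$truth$amounts, b$truth$amounts)
  expect_identical(a$truth$coefficients, b$truth$coefficients)
})

test_that("with all noise disabled the replicates are identical (SNR infinite)", {
  cfg <- noiselessConfig(simulationConfig(nPolymers = 5, seed = 9))
  g <- generatePolymerLibrary(cfg)
  expect_identical(g$truth$amounts[, , 1], g$truth$amounts[, , 2])
  expect_identical(g$truth$amounts[, , 1], g$truth$amounts[, , 3])
  expect_equal(log10(g$truth$amounts[, , 1]),
               unclass(g$truth$logAdsorption), tolerance = 1e-12)
})

test_that("empirical noise levels match the configured values within 5%", {
  # log10 noise, replicate noise off
  cfg <- simulationConfig(nPolymers = 4000, nReplicates = 3,
                          noiseSdLog10 = 0.15, replicateCv = 0,
                          dropoutProb = 0, seed = 31)
  g <- generatePolymerLibrary(cfg, proteins = "insulin")
  dev <- log10(g$truth$amounts[, 1, ]) -
    replicate(3, g$truth$logAdsorption[, 1])
  expect_equal(sd(dev), 0.15, tolerance = 0.05)
  # replicate CV, log10 noise off
  cfg2 <- simulationConfig(nPolymers = 4000, nReplicates = 3,
                           noiseSdLog10 = 0, replicateCv = 0.2,
                           dropoutProb = 0, seed = 32)
  g2 <- generatePolymerLibrary(cfg2, proteins = "insulin")
  ratio <- g2$truth$amounts[, 1, ] / replicate(3, 10^g2$truth$logAdsorption[, 1])
  expect_equal(sd(ratio) / mean(ratio), 0.2, tolerance = 0.05)
  # dropout rate
  cfg3 <- simulationConfig(nPolymers = 4000, dropoutProb = 0.1, seed = 33)
  g3 <- generatePolymerLibrary(cfg3, proteins = "insulin")
  expect_equal(mean(g3$truth$amounts == 0), 0.1, tolerance = 0.05)
})

test_that("a noiseless DIA run closes the loop exactly", {
  cfg <- noiselessConfig(simulationConfig(nPolymers = 2, seed = 13))
  sim <- simulateStudy(cfg)
  entry <- sim$runs[[1]]
  res <- identifyRun(entry$run, sim$library)
  expect_true(all(res$accepted))
  tg <- sim$scheme$targets
  amounts <- sim$truth$amounts[entry$polymer_id, , entry$replicate]
  for (i in seq_len(nrow(tg))) {
    got <- extractMs1Intensity(entry$run, tg$precursor_mz[i], 10)
    expect_equal(got, amounts[[tg$protein_id[i]]] * tg$response[i],
                 tolerance = 1e-12)
  }
})

test_that("a dropped-out protein quantifies at the imputation floor", {
  cfg <- noiselessConfig(simulationConfig(nPolymers = 1, nReplicates = 1,
                                          seed = 2))
  sim <- simulateStudy(cfg)
  amounts <- as.list(sim$truth$amounts[1, , 1])
  amounts$insulin <- 0    # force a dropout
  set.seed(1)
  run <- simulateDiaRun("P001_r1", amounts, sim$library, sim$scheme, cfg)
  m <- identifyRun(run, sim$library)
  q <- quantifyRun(run, m, sim$scheme)
  expect_equal(q$log10_intensity[q$protein_id == "insulin"], 3.0)
  expect_gt(q$log10_intensity[q$protein_id == "fgf2"], 3.0)
})

test_that("insulin is targeted only through GFFYTPK at charges 1 and 2", {
  cfg <- simulationConfig(nPolymers = 1)
  sim <- simulateStudy(cfg)
  tg <- sim$scheme$targets
  ins <- tg[tg$protein_id == "insulin", ]
  expect_identical(unique(ins$peptide_id), "insulin_GFFYTPK")
  expect_setequal(ins$charge, 1:2)
  expect_equal(sum(ins$response), 1)
  # every protein's response factors sum to 1
  for (p in unique(tg$protein_id))
    expect_equal(sum(tg$response[tg$protein_id == p]), 1)
  # all targets inside the MS1 range
  expect_true(all(tg$precursor_mz >= 400 & tg$precursor_mz <= 900))
})

test_that("droplet spherical-cap volume follows the closed form", {
  expect_equal(dropletCapVolume(1, 90), 2 * pi / 3 * 1000, tolerance = 1e-9)
  # theta -> 0 limit: volume vanishes linearly in the contact angle
  expect_lt(dropletCapVolume(0.7, 0.001), 0.01)
  expect_lt(dropletCapVolume(0.7, 0.01), dropletCapVolume(0.7, 1))
  expect_equal(dropletCapVolume(0.7, 5.2), 24.5, tolerance = 0.01)
  expect_error(dropletCapVolume(-1, 45), "radius")
  expect_error(dropletCapVolume(1, 200), "angle")
})

test_that("fixture sets write the expected files and regenerate identically", {
  cfg <- simulationConfig(nPolymers = 2, nReplicates = 2, nCycles = 2,
                          seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- writeFixtureSet(cfg, d1)
  expect_length(f1, 2 * 2 + 4)
  f2 <- writeFixtureSet(cfg, d2)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  # manifest round-trips the configuration
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  for (nm in names(cfg))
    expect_equal(man$config[[nm]], unclass(cfg)[[nm]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  # run tables re-read as valid runs
  run <- readRun(f1[1])
  expect_s4_class(run, "MsRun")
  expect_length(cycles(run), 2L)
})

test_that("end-to-end recovery beats Spearman 0.9 at the default noise level", {
  cfg <- simulationConfig(nPolymers = 30, seed = 17)
  sim <- simulateStudy(cfg)
  proc <- processStudy(sim)
  # recovery is assessed on the rows that survive the pipeline's own
  # replicate-SNR filter; dropout-corrupted rows are what it removes
  ft <- adsorptionValues(snrFilter(proc$adsorption, quiet = TRUE))
  for (p in unique(ft$protein_id)) {
    sub <- ft[ft$protein_id == p, ]
    tru <- sim$truth$logAdsorption[sub$polymer_id, p]
    expect_gte(cor(log10(sub$geomean), tru, method = "spearman"), 0.9)
  }
})
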