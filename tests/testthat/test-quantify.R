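ms1Run <- function(peakSets, runIdText = "P001_r1") {
  specs <- lapply(seq_along(peakSets), function(i)
    Spectrum(i, 1, peakSets[[i]]$mz, peakSets[[i]]$intensity,
             scanRange = c(400, 900)))
  MsRun(runIdText, specs, 10L)
}

test_that("MS1 extraction sums in-window peaks and takes the scan median", {
  one <- ms1Run(list(list(mz = 500.0, intensity = 1234)))
  expect_equal(extractMs1Intensity(one, 500.0, 10), 1234)
  # +10.1 ppm is outside a 10 ppm window
  off <- ms1Run(list(list(mz = 500.0 * (1 + 10.1e-6), intensity = 10)))
  expect_true(is.na(extractMs1Intensity(off, 500.0, 10)))
  # median across scans with at least one in-window peak
  three <- ms1Run(list(list(mz = 500.0, intensity = 90),
                       list(mz = 500.0, intensity = 100),
                       list(mz = c(500.0, 500.001), intensity = c(120, 80))))
  expect_equal(extractMs1Intensity(three, 500.0, 10), 100)
  # no MS1 scans at all
  ms2only <- MsRun("x", list(Spectrum(1, 2, 100, 1, precursorMz = 500,
                                      isolationWidth = 1)), 10L)
  expect_warning(v <- extractMs1Intensity(ms2only, 500, 10), "no MS1")
  expect_true(is.na(v))
})

test_that("protein log intensity, imputation and their composition", {
  expect_equal(proteinLogIntensity(1000), 3.0)
  expect_equal(proteinLogIntensity(c(1000, 9000)), 4.0)
  expect_true(is.na(proteinLogIntensity(c(NA_real_, NA_real_))))
  expect_equal(imputeMissing(NA_real_), 1000)
  expect_equal(imputeMissing(500), 500)
  # imputation precedes summation: one observed + one missing peptide
  expect_equal(proteinLogIntensity(imputeMissing(c(9000, NA))), 4.0)
})

test_that("geometric mean follows the closed form and rejects non-positive input", {
  expect_equal(geometricMean(c(10, 1000)), 100)
  expect_equal(geometricMean(c(7, 7, 7)), 7)
  expect_equal(geometricMean(c(2, 4, 8)), 4)
  expect_error(geometricMean(c(1, 0)), "> 0")
  # AM-GM on random positive inputs
  set.seed(5)
  for (k in 1:25) {
    v <- rexp(sample(2:6, 1)) + 1e-6
    expect_lte(geometricMean(v), mean(v) + 1e-12)
  }
})

test_that("replicate SNR is mean/sd with n-1 denominator and scale-invariant", {
  expect_equal(replicateSnr(c(100, 200, 300)), 2.0)
  expect_identical(replicateSnr(c(5, 5, 5)), Inf)
  expect_equal(replicateSnr(c(0, 1000)), 0.70710678, tolerance = 1e-6)
  expect_error(replicateSnr(7), "2 replicates")
  set.seed(9)
  for (k in 1:20) {
    v <- rlnorm(3, 10, 1)
    c <- runif(1, 0.1, 50)
    expect_equal(replicateSnr(c * v), replicateSnr(v), tolerance = 1e-9)
  }
})

test_that("CV is 100/SNR and requires a positive mean", {
  expect_equal(coefficientOfVariation(c(4, 4)), 0)
  expect_equal(coefficientOfVariation(c(100, 200, 300)), 50)
  v <- c(12, 99, 57)
  expect_equal(coefficientOfVariation(v), 100 / replicateSnr(v))
  expect_error(coefficientOfVariation(c(-2, 1)), "positive mean")
})

test_that("adsorption table aggregation and the strict SNR filter", {
  quant <- expand.grid(replicate = 1:3, polymer_id = sprintf("P%02d", 1:4),
                       protein_id = "insulin", stringsAsFactors = FALSE)
  # construct linear replicates {a, a, a + d}: mean a + d/3, sd d/sqrt(3),
  # so d = 3a / (snr * sqrt(3) - 1) hits a target SNR exactly
  a <- 100; d <- 3 * a / (1.5 * sqrt(3) - 1)
  p02 <- c(a, a, a + d)
  expect_equal(mean(p02) / sd(p02), 1.5, tolerance = 1e-12)
  # P01: identical replicates (SNR Inf); P02: SNR exactly at the threshold;
  # P03: clearly below; P04: clearly above
  vals <- list(P01 = log10(c(1e5, 1e5, 1e5)),
               P02 = log10(p02),
               P03 = log10(c(10, 4000, 90000)),
               P04 = log10(c(90000, 100000, 110000)))
  quant$log10_intensity <- NA_real_
  for (p in names(vals))
    quant$log10_intensity[quant$polymer_id == p] <- vals[[p]]
  tab <- buildAdsorptionTable(quant, snrThreshold = 1.5)
  t <- adsorptionValues(tab)
  t <- t[order(t$polymer_id), ]
  expect_identical(t$passed_filter, c(TRUE, FALSE, FALSE, TRUE))
  # geometric mean equals the closed form per polymer
  expect_equal(t$geomean[t$polymer_id == "P01"], 1e5)
  expect_equal(t$geomean[t$polymer_id == "P02"], exp(mean(log(p02))))
  # strict inequality at the boundary: snr == 1.5 is removed
  expect_equal(t$snr[t$polymer_id == "P02"], 1.5, tolerance = 1e-9)
  filt <- snrFilter(tab, quiet = TRUE)
  ft <- adsorptionValues(filt)
  expect_setequal(ft$polymer_id, c("P01", "P04"))
  # filter agrees with a brute-force subset
  expect_identical(sort(ft$polymer_id),
                   sort(t$polymer_id[!is.na(t$snr) & t$snr > 1.5]))
})

test_that("protein log intensity is monotone in every peptide intensity", {
  set.seed(17)
  for (k in 1:20) {
    v <- runif(4, 10, 1e5)
    idx <- sample(4, 1)
    w <- v; w[idx] <- v[idx] + runif(1, 1, 1e4)
    expect_gte(proteinLogIntensity(w), proteinLogIntensity(v))
  }
})

test_that("quantifyRun honors identify-then-quantify and imputes absent proteins", {
  peps <- data.frame(sequence = "GFFYTPK", protein_id = "insulin", chain = 1L,
                     start = 1L, end = 7L, missed_cleavages = 0L,
                     monoisotopic_mass = monoisotopicMass("GFFYTPK"))
  lib <- buildLibraryFromTruth(peps, charges = 1L)
  e <- libraryEntries(lib)
  scheme <- acquisitionScheme(data.frame(
    peptide_id = e$peptide_id, protein_id = "insulin", charge = 1L,
    precursor_mz = e$precursor_mz, response = 1))
  ms2 <- Spectrum(1, 2, e$fragment_mz[[1]], e$fragment_intensity[[1]],
                  precursorMz = e$precursor_mz, isolationWidth = 1)
  ms1 <- Spectrum(2, 1, e$precursor_mz, 5e4, scanRange = c(400, 900))
  run <- MsRun("P001_r1", list(ms2, ms1), 1L)
  matches <- identifyRun(run, lib)
  q <- quantifyRun(run, matches, scheme)
  expect_equal(q$log10_intensity, log10(5e4))
  # if the peptide is not accepted, the protein imputes at log10(1000)
  matches$accepted <- FALSE
  q2 <- quantifyRun(run, matches, scheme)
  expect_equal(q2$log10_intensity, 3.0)
})
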