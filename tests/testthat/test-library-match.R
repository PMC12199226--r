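toyPeptides <- function(seqs, protein = "prot") {
  data.frame(sequence = seqs, protein_id = protein, chain = 1L,
             start = 1L, end = nchar(seqs), missed_cleavages = 0L,
             monoisotopic_mass = vapply(seqs, monoisotopicMass, numeric(1),
                                        USE.NAMES = FALSE))
}

querySpectrum <- function(mz, intensity, scanId = 1, precursorMz = 500,
                          isolationWidth = 1) {
  Spectrum(scanId, 2, mz, intensity, precursorMz = precursorMz,
           isolationWidth = isolationWidth)
}

test_that("library construction from truth realizes b/y fragment entries", {
  lib <- buildLibraryFromTruth(toyPeptides("GFFYTPK"), charges = 1L)
  e <- libraryEntries(lib)
  expect_equal(nrow(e), 1L)
  expect_length(e$fragment_mz[[1]], 12L)  # 2(n-1) for n = 7
  expect_equal(e$precursor_mz, 859.43485, tolerance = 1e-4)

  expect_length(buildLibraryFromTruth(toyPeptides("GFFYTPK"),
                                      charges = integer()), 0L)
  lib4 <- buildLibraryFromTruth(toyPeptides(c("GFFYTPK", "LVEALYLVK")),
                                charges = c(1L, 2L))
  expect_length(lib4, 4L)
  expect_warning(buildLibraryFromTruth(toyPeptides(c("G", "GFFYTPK")),
                                       charges = 1L), "skipped")
})

test_that("library CSV and MSP import round-trip and reject bad entries", {
  lib <- buildLibraryFromTruth(toyPeptides(c("GFFYTPK", "LVEALYLVK")),
                               charges = 1:2, fragmentModel = "triangular")
  f <- withr::local_tempfile(fileext = ".csv")
  exportLibrary(lib, f)
  back <- importLibrary(f)
  expect_equal(libraryEntries(back)$peptide_id, libraryEntries(lib)$peptide_id)
  expect_equal(libraryEntries(back)$fragment_mz, libraryEntries(lib)$fragment_mz,
               tolerance = 1e-9)

  msp <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: GFFYTPK/1", "PrecursorMZ: 859.4349", "Num peaks: 2",
               "147.1128 55.5", "205.0972 12.0"), msp)
  m <- importLibrary(msp)
  e <- libraryEntries(m)
  expect_equal(e$charge, 1L)
  expect_equal(e$fragment_mz[[1]], c(147.1128, 205.0972))
  expect_equal(e$provenance, "imported")

  bad <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: X/1", "PrecursorMZ: 500", "Num peaks: 1",
               "oops line"), bad)
  expect_error(importLibrary(bad), "malformed peak line")
})

test_that("cosine matches hand-derived values on the worked example", {
  entry <- list(peptide_id = "e", charge = 1L,
                fragment_mz = list(c(100.0, 200.0, 300.0)),
                fragment_intensity = list(c(1, 2, 2)))
  q <- querySpectrum(c(100.005, 200.010, 400.0), c(2, 4, 1))
  m <- matchSpectrum(q, entry, fragTol = 0.02)
  expect_identical(m$n_matched, 2L)
  expect_equal(m$cosine, 10 / (3 * sqrt(21)), tolerance = 1e-6)
  expect_false(m$accepted)
  # self-similarity and disjoint sets
  self <- querySpectrum(c(100, 200, 300), c(1, 2, 2))
  ms <- matchSpectrum(self, entry)
  expect_equal(ms$cosine, 1.0)
  expect_identical(ms$n_matched, 3L)
  far <- querySpectrum(c(150, 250), c(5, 5))
  mf <- matchSpectrum(far, entry)
  expect_equal(mf$cosine, 0)
  expect_identical(mf$n_matched, 0L)
  # empty query
  m0 <- matchSpectrum(querySpectrum(numeric(), numeric()), entry)
  expect_equal(m0$cosine, 0)
  expect_false(m0$accepted)
})

test_that("acceptance uses strict cosine and >= fragment count", {
  expect_false(acceptMatch(0.95, 10))
  expect_false(acceptMatch(0.99, 4))
  expect_true(acceptMatch(0.99, 5))
})

test_that("cosine is symmetric, scale-invariant and degrades monotonically", {
  set.seed(23)
  for (k in 1:50) {
    a <- randomPeakList(sample(3:10, 1))
    b <- randomPeakList(sample(3:10, 1))
    ea <- list(peptide_id = "a", charge = 1L, fragment_mz = list(a$mz),
               fragment_intensity = list(a$intensity))
    eb <- list(peptide_id = "b", charge = 1L, fragment_mz = list(b$mz),
               fragment_intensity = list(b$intensity))
    qa <- querySpectrum(a$mz, a$intensity)
    qb <- querySpectrum(b$mz, b$intensity)
    c1 <- matchSpectrum(qa, eb)$cosine
    c2 <- matchSpectrum(qb, ea)$cosine
    expect_equal(c1, c2, tolerance = 1e-12)
    # scale invariance
    qscaled <- querySpectrum(a$mz, a$intensity * 37.5)
    expect_equal(matchSpectrum(qscaled, eb)$cosine, c1, tolerance = 1e-12)
    # adding unmatched noise peaks never increases the cosine
    noise <- randomPeakList(3, mzRange = c(1500, 2000))
    qnoisy <- querySpectrum(c(a$mz, noise$mz), c(a$intensity, noise$intensity))
    expect_lte(matchSpectrum(qnoisy, eb)$cosine, c1 + 1e-12)
  }
})

test_that("greedy pairing equals the exhaustive optimal pairing oracle", {
  set.seed(31)
  for (k in 1:300) {
    nl <- sample(1:8, 1); nq <- sample(1:8, 1)
    lib <- randomPeakList(nl, mzRange = c(100, 500))
    # query: shifted copies of a library subset plus off-grid extras
    take <- sample(nl, sample(0:nl, 1))
    qmz <- c(lib$mz[take] + rnorm(length(take), 0, 0.006),
             runif(nq, 600, 900))
    qint <- runif(length(qmz), 1, 100)
    o <- order(qmz)
    qmz <- qmz[o]; qint <- qint[o]
    entry <- list(peptide_id = "e", charge = 1L, fragment_mz = list(lib$mz),
                  fragment_intensity = list(lib$intensity))
    got <- matchSpectrum(querySpectrum(qmz, qint), entry, fragTol = 0.02)
    want <- oraclePairing(qmz, qint, lib$mz, lib$intensity, 0.02)
    expect_identical(got$n_matched, want$n)
    expect_equal(got$cosine, want$cosine, tolerance = 1e-10)
  }
})

test_that("identifyRun restricts to the half-open isolation window", {
  peps <- toyPeptides("GFFYTPK")
  lib <- buildLibraryFromTruth(peps, charges = 1L)
  e <- libraryEntries(lib)
  prec <- e$precursor_mz[1]
  mkRun <- function(center) MsRun("r", list(
    Spectrum(1, 2, e$fragment_mz[[1]], e$fragment_intensity[[1]],
             precursorMz = center, isolationWidth = 1)), 10L)
  # entry inside the window: matched and accepted (12 identical peaks)
  hit <- identifyRun(mkRun(prec), lib)
  expect_true(hit$accepted)
  expect_equal(hit$cosine, 1.0)
  # entry 0.51 Th above the window centre: outside [c - 0.5, c + 0.5)
  miss <- identifyRun(mkRun(prec - 0.51), lib)
  expect_false(miss$accepted)
  expect_true(is.na(miss$peptide_id))
  # lower edge closed, upper edge open
  expect_true(identifyRun(mkRun(prec + 0.5), lib)$accepted)      # c - 0.5 = prec
  expect_false(identifyRun(mkRun(prec - 0.5), lib)$accepted)     # c + 0.5 = prec
})

test_that("noise-only scans are never accepted and exact copies always are", {
  set.seed(41)
  peps <- toyPeptides(c("GFFYTPK", "LVEALYLVK"))
  lib <- buildLibraryFromTruth(peps, charges = 1L,
                               fragmentModel = "triangular")
  e <- libraryEntries(lib)
  specs <- list(); scan <- 0L
  for (i in seq_len(nrow(e))) {
    scan <- scan + 1L
    specs[[scan]] <- Spectrum(scan, 2, e$fragment_mz[[i]],
                              e$fragment_intensity[[i]],
                              precursorMz = e$precursor_mz[i],
                              isolationWidth = 1)
  }
  res <- identifyRun(MsRun("exact", specs, 10L), lib)
  expect_true(all(res$accepted))
  # noise spectra with peaks off-grid by construction
  noise <- lapply(1:4, function(i) {
    mz <- sort(runif(8, 1000, 1300))  # far from any library fragment
    Spectrum(i, 2, mz, runif(8, 1, 100),
             precursorMz = e$precursor_mz[1], isolationWidth = 1)
  })
  resN <- identifyRun(MsRun("noise", noise, 10L), lib)
  expect_false(any(resN$accepted))
})
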