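# Ground-truthed synthetic data for every stage: polymer libraries whose
# log-adsorption is a sparse linear function of descriptors, and per-spot
# targeted-DIA runs whose MS1 peptide-ion intensities encode those
# adsorption levels.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 208 homopolymers in
#' triplicate, the four E8 proteins, DIA cycles of 10 one-Th-window MS2
#' scans plus one MS1 scan over m/z 400-900.
#'
#' @param nPolymers polymer library size (default 208).
#' @param nReplicates spots per polymer (default 3).
#' @param nDescriptors descriptor count (default 120; 80% small
#'   non-negative counts, Poisson with mean 1, the rest standard normal).
#' @param nTrueFeatures nonzero coefficients per protein (default 5).
#' @param coefficientScale true |coefficients| are drawn uniformly from
#'   `[coefficientScale, 2 * coefficientScale]` with random sign
#'   (default 0.5, i.e. at least ~3x the log10 noise sd).
#' @param interceptLog10 baseline log10 adsorption (default 5).
#' @param noiseSdLog10 per-replicate Gaussian noise on log10 adsorption
#'   (default 0.15).
#' @param replicateCv multiplicative lognormal replicate noise, as a
#'   coefficient of variation (default 0.2).
#' @param dropoutProb probability that a replicate's protein drops out
#'   entirely (default 0.1).
#' @param nCycles DIA cycles per run (default 10).
#' @param ms1Range MS1 scan range in Th (default `c(400, 900)`).
#' @param isolationWidth MS2 isolation width in Th (default 1).
#' @param cycleLength MS2 scans per cycle (default 10).
#' @param fragNoiseCv multiplicative lognormal noise on fragment and MS1
#'   peak intensities (default 0.1).
#' @param nNoisePeaks random noise peaks added per scan (default 5).
#' @param ms1JitterPpm uniform m/z jitter on MS1 peptide peaks, ppm
#'   (default 3).
#' @param peptidesPerProtein targeted peptide ions per protein (default 5;
#'   insulin contributes only GFFYTPK, at charges 1-2).
#' @param charges precursor charges realized in the library (default 1:2).
#' @param seed integer seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nPolymers = 208L, nReplicates = 3L,
                             nDescriptors = 120L, nTrueFeatures = 5L,
                             coefficientScale = 0.5, interceptLog10 = 5,
                             noiseSdLog10 = 0.15, replicateCv = 0.2,
                             dropoutProb = 0.1, nCycles = 10L,
                             ms1Range = c(400, 900), isolationWidth = 1.0,
                             cycleLength = 10L, fragNoiseCv = 0.1,
                             nNoisePeaks = 5L, ms1JitterPpm = 3,
                             peptidesPerProtein = 5L, charges = 1:2,
                             seed = 1L) {
  stopifnot(dropoutProb >= 0, dropoutProb <= 1, noiseSdLog10 >= 0,
            replicateCv >= 0, fragNoiseCv >= 0, coefficientScale > 0,
            nTrueFeatures <= nDescriptors, isolationWidth > 0,
            nPolymers >= 1, nReplicates >= 1, ms1JitterPpm >= 0)
  structure(list(nPolymers = as.integer(nPolymers),
                 nReplicates = as.integer(nReplicates),
                 nDescriptors = as.integer(nDescriptors),
                 nTrueFeatures = as.integer(nTrueFeatures),
                 coefficientScale = coefficientScale,
                 interceptLog10 = interceptLog10,
                 noiseSdLog10 = noiseSdLog10, replicateCv = replicateCv,
                 dropoutProb = dropoutProb, nCycles = as.integer(nCycles),
                 ms1Range = as.numeric(ms1Range),
                 isolationWidth = isolationWidth,
                 cycleLength = as.integer(cycleLength),
                 fragNoiseCv = fragNoiseCv,
                 nNoisePeaks = as.integer(nNoisePeaks),
                 ms1JitterPpm = ms1JitterPpm,
                 peptidesPerProtein = as.integer(peptidesPerProtein),
                 charges = as.integer(charges), seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' A noise-free variant of a simulation configuration
#'
#' Disables every stochastic element (log noise, replicate noise, dropout,
#' fragment noise, noise peaks, m/z jitter) so that the full pipeline must
#' recover the ground truth exactly.
#'
#' @param config a [simulationConfig()].
#' @return modified config.
#' @export
noiselessConfig <- function(config = simulationConfig()) {
  config$noiseSdLog10 <- 0
  config$replicateCv <- 0
  config$dropoutProb <- 0
  config$fragNoiseCv <- 0
  config$nNoisePeaks <- 0L
  config$ms1JitterPpm <- 0
  config
}

# lognormal multiplicative noise with unit mean and given CV
.rlnormCv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.polymerIds <- function(n) sprintf("P%03d", seq_len(n))

#' Generate the polymer library with ground truth
#'
#' Draws a descriptor matrix (80% Poisson(1) count columns named `FD*`,
#' 20% standard-normal columns named `CD*`), then per protein a sparse
#' coefficient vector with `nTrueFeatures` nonzero entries. The true
#' log10 adsorption is `intercept + X w`; each replicate's realized linear
#' amount is `10^(true + N(0, noiseSdLog10))`, scaled by multiplicative
#' lognormal replicate noise (`replicateCv`), with a `dropoutProb` chance
#' of dropping out (amount 0).
#'
#' @param config a [simulationConfig()].
#' @param proteins character vector of protein ids (default the E8 panel).
#' @return list with `descriptors` (a [DescriptorMatrix-class]) and
#'   `truth`: `coefficients` (descriptor x protein), `logAdsorption`
#'   (polymer x protein), `amounts` (polymer x protein x replicate linear
#'   amounts, 0 = dropout), `config`.
#' @export
generatePolymerLibrary <- function(config = simulationConfig(),
                                   proteins = c("insulin", "transferrin",
                                                "fgf2", "tgfb1")) {
  set.seed(config$seed)
  nP <- config$nPolymers; nD <- config$nDescriptors
  nCount <- round(0.8 * nD)
  X <- cbind(
    matrix(stats::rpois(nP * nCount, lambda = 1), nP, nCount),
    matrix(stats::rnorm(nP * (nD - nCount)), nP, nD - nCount))
  dimnames(X) <- list(.polymerIds(nP),
                      c(sprintf("FD%03d", seq_len(nCount)),
                        sprintf("CD%03d", seq_len(nD - nCount))))
  W <- matrix(0, nD, length(proteins),
              dimnames = list(colnames(X), proteins))
  for (p in proteins) {
    idx <- sample.int(nD, config$nTrueFeatures)
    W[idx, p] <- sample(c(-1, 1), config$nTrueFeatures, replace = TRUE) *
      stats::runif(config$nTrueFeatures, config$coefficientScale,
                   2 * config$coefficientScale)
  }
  logAds <- config$interceptLog10 + X %*% W
  amounts <- array(0, dim = c(nP, length(proteins), config$nReplicates),
                   dimnames = list(rownames(X), proteins, NULL))
  for (r in seq_len(config$nReplicates)) {
    noise <- matrix(stats::rnorm(nP * length(proteins), 0, config$noiseSdLog10),
                    nP, length(proteins))
    repNoise <- matrix(.rlnormCv(nP * length(proteins), config$replicateCv),
                       nP, length(proteins))
    a <- 10^(logAds + noise) * repNoise
    drop <- matrix(stats::runif(nP * length(proteins)) < config$dropoutProb,
                   nP, length(proteins))
    a[drop] <- 0
    amounts[, , r] <- a
  }
  list(descriptors = DescriptorMatrix(X, source = "computed"),
       truth = list(coefficients = W, logAdsorption = logAds,
                    amounts = amounts, config = config))
}

#' Build the targeted acquisition scheme from a spectral library
#'
#' Selects per protein up to `peptidesPerProtein` peptide ions whose
#' precursor m/z lies inside the MS1 range and whose reference spectrum
#' carries at least `minFrag` fragments (so an exact match is acceptable),
#' ranked by descending precursor m/z. Each selected ion receives an MS1
#' response factor; the factors of one protein sum to 1, so the summed
#' peptide-ion intensity of a protein equals its adsorbed amount.
#'
#' @param library a [SpectralLibrary-class].
#' @param config a [simulationConfig()].
#' @param minFrag minimum fragments per entry (default 5, matching the
#'   acceptance rule).
#' @return an [acquisitionScheme()] whose targets carry a `response`
#'   column.
#' @export
buildScheme <- function(library, config = simulationConfig(), minFrag = 5L) {
  e <- library@entries
  ok <- e$precursor_mz >= config$ms1Range[1] &
        e$precursor_mz <= config$ms1Range[2] &
        lengths(e$fragment_mz) >= minFrag
  e <- e[ok, , drop = FALSE]
  rows <- list()
  for (p in unique(e$protein_id)) {
    sub <- e[e$protein_id == p, , drop = FALSE]
    sub <- sub[order(-sub$precursor_mz), , drop = FALSE]
    sub <- utils::head(sub, config$peptidesPerProtein)
    rows[[p]] <- data.frame(peptide_id = sub$peptide_id,
                            protein_id = p, charge = sub$charge,
                            precursor_mz = sub$precursor_mz,
                            response = 1 / nrow(sub))
  }
  targets <- do.call(rbind, rows)
  rownames(targets) <- NULL
  acquisitionScheme(targets, isolationWidth = config$isolationWidth,
                    ms1Range = config$ms1Range,
                    cycleLength = config$cycleLength)
}

#' Simulate one DIA run for one polymer spot
#'
#' Produces `nCycles` DIA cycles. MS2 scans walk the target list
#' round-robin; each scan is the target's library fragment spectrum scaled
#' by the adsorbed amount, with multiplicative lognormal peak noise
#' (`fragNoiseCv`) and `nNoisePeaks` uniform-random noise peaks. Each MS1
#' scan carries one peak per targeted peptide ion at its precursor m/z
#' (uniform jitter of `ms1JitterPpm`) with intensity
#' `amount x response factor x lognormal noise`, plus low-level background
#' peaks kept at least 20 ppm away from any target. A dropped-out protein
#' (amount 0) contributes no peaks at all.
#'
#' Uses the caller's RNG stream; seed before calling for reproducibility.
#'
#' @param runIdText run identifier.
#' @param amounts named numeric: linear adsorbed amount per protein
#'   (0 = dropout).
#' @param library a [SpectralLibrary-class].
#' @param scheme a [buildScheme()] result (targets need `response`).
#' @param config a [simulationConfig()].
#' @return an [MsRun-class].
#' @export
simulateDiaRun <- function(runIdText, amounts, library, scheme,
                           config = simulationConfig()) {
  tg <- scheme$targets
  e <- library@entries
  key <- paste(e$peptide_id, e$charge)
  nT <- nrow(tg)
  specs <- list()
  scan <- 0L
  tPos <- 0L
  for (cyc in seq_len(config$nCycles)) {
    for (s in seq_len(scheme$cycleLength)) {
      scan <- scan + 1L
      tPos <- tPos %% nT + 1L
      t <- tg[tPos, ]
      amt <- amounts[[t$protein_id]]
      entry <- e[match(paste(t$peptide_id, t$charge), key), ]
      mz <- numeric(); int <- numeric()
      if (amt > 0) {
        mz <- entry$fragment_mz[[1]]
        int <- entry$fragment_intensity[[1]] * amt *
          .rlnormCv(length(mz), config$fragNoiseCv)
      }
      if (config$nNoisePeaks > 0) {
        nmz <- stats::runif(config$nNoisePeaks, 100, 1300)
        base <- if (length(int)) max(int) else 1000
        mz <- c(mz, nmz)
        int <- c(int, stats::runif(config$nNoisePeaks, 0, 0.05 * base))
      }
      if (anyDuplicated(mz)) {
        keep <- !duplicated(mz)
        mz <- mz[keep]; int <- int[keep]
      }
      specs[[scan]] <- Spectrum(scan, 2L, mz, int,
                                precursorMz = t$precursor_mz,
                                isolationWidth = scheme$isolationWidth)
    }
    scan <- scan + 1L
    mz <- numeric(); int <- numeric()
    for (ti in seq_len(nT)) {
      t <- tg[ti, ]
      amt <- amounts[[t$protein_id]]
      if (amt <= 0) next
      jit <- if (config$ms1JitterPpm > 0)
        stats::runif(1, -config$ms1JitterPpm, config$ms1JitterPpm) else 0
      mz <- c(mz, t$precursor_mz * (1 + jit * 1e-6))
      int <- c(int, amt * t$response * .rlnormCv(1, config$fragNoiseCv))
    }
    if (config$nNoisePeaks > 0) {
      bg <- numeric()
      while (length(bg) < config$nNoisePeaks) {
        cand <- stats::runif(1, config$ms1Range[1], config$ms1Range[2])
        if (all(abs(cand - tg$precursor_mz) / cand * 1e6 > 20))
          bg <- c(bg, cand)
      }
      mz <- c(mz, bg)
      int <- c(int, stats::runif(config$nNoisePeaks, 0, 1000))
    }
    if (anyDuplicated(mz)) {
      keep <- !duplicated(mz)
      mz <- mz[keep]; int <- int[keep]
    }
    specs[[scan]] <- Spectrum(scan, 1L, mz, int,
                              scanRange = config$ms1Range)
  }
  MsRun(runIdText, specs, scheme$cycleLength)
}

#' Simulate a full study
#'
#' Digests the protein panel (complete digestion, disulfide-aware free
#' peptides), builds the ground-truth spectral library and acquisition
#' scheme, draws the polymer library, and simulates one DIA run per
#' polymer x replicate. Per-run seeds derive deterministically from the
#' configuration seed.
#'
#' @param config a [simulationConfig()].
#' @param proteins named list of [ProteinEntry-class] (default
#'   [e8Proteins()]).
#' @return list: `runs` (data.frame-like list with `polymer_id`,
#'   `replicate`, `run`), `library`, `scheme`, `descriptors`, `truth`,
#'   `peptides`.
#' @export
simulateStudy <- function(config = simulationConfig(),
                          proteins = e8Proteins()) {
  peps <- do.call(rbind, lapply(proteins, function(pr)
    freePeptides(pr, trypticDigest(pr, maxMissed = 0L), minLength = 2L)))
  rownames(peps) <- NULL
  lib <- buildLibraryFromTruth(peps, charges = config$charges,
                               fragmentModel = "triangular")
  scheme <- buildScheme(lib, config)
  gen <- generatePolymerLibrary(config,
                                proteins = unique(scheme$targets$protein_id))
  polymers <- rownames(gen$truth$logAdsorption)
  runs <- list()
  for (pi in seq_along(polymers)) {
    for (r in seq_len(config$nReplicates)) {
      set.seed((config$seed + 7919L * pi + 104729L * r) %% 2147483647L)
      amounts <- gen$truth$amounts[pi, , r]
      runs[[length(runs) + 1L]] <- list(
        polymer_id = polymers[pi], replicate = r,
        run = simulateDiaRun(sprintf("%s_r%d", polymers[pi], r),
                             as.list(amounts), lib, scheme, config))
    }
  }
  list(runs = runs, library = lib, scheme = scheme,
       descriptors = gen$descriptors, truth = gen$truth, peptides = peps)
}

#' Identify and quantify a set of simulated runs
#'
#' Runs [identifyRun()] and [quantifyRun()] on every run and aggregates
#' replicates into an [AdsorptionTable-class]. This is the computational
#' half of the workflow applied to (simulated or imported) runs.
#'
#' @param sim result of [simulateStudy()] (or a list with the same
#'   `runs`/`library`/`scheme` fields).
#' @param fragTol,cosMin,minFrag identification parameters (study values
#'   0.02 Da, 0.95, 5).
#' @param ppmTol,imputeThreshold quantification parameters (study values
#'   10 ppm, 1000).
#' @param snrThreshold replicate SNR threshold (study value 1.5).
#' @return list: `quant` (long per-run table), `matches` (identification
#'   rows), `adsorption` (an `AdsorptionTable`).
#' @export
processStudy <- function(sim, fragTol = 0.02, cosMin = 0.95, minFrag = 5L,
                         ppmTol = 10, imputeThreshold = 1000,
                         snrThreshold = 1.5) {
  quant <- list(); matches <- list()
  for (entry in sim$runs) {
    m <- identifyRun(entry$run, sim$library, fragTol = fragTol,
                     cosMin = cosMin, minFrag = minFrag)
    q <- quantifyRun(entry$run, m, sim$scheme, ppmTol = ppmTol,
                     imputeThreshold = imputeThreshold)
    q$polymer_id <- entry$polymer_id
    q$replicate <- entry$replicate
    matches[[length(matches) + 1L]] <- m
    quant[[length(quant) + 1L]] <- q
  }
  quant <- do.call(rbind, quant)
  matches <- do.call(rbind, matches)
  list(quant = quant, matches = matches,
       adsorption = buildAdsorptionTable(quant, snrThreshold = snrThreshold))
}

#' Spherical-cap droplet volume
#'
#' Volume of a sessile droplet modelled as a spherical cap with contact
#' radius `a` (mm) and contact angle `theta` (degrees):
#' `V = (pi a^3 / 3) (1 - cos t)^2 (2 + cos t) / sin^3 t`, returned in nL
#' (1 mm^3 = 1 uL = 1000 nL). With a 0.7 mm contact radius and the
#' study's 5.2 degree contact angle this evaluates to about 24.5 nL; see
#' the vignette for the discussion of this geometry.
#'
#' @param contactRadius contact-line radius in mm (> 0).
#' @param contactAngle contact angle in degrees, in (0, 180).
#' @return volume in nL.
#' @export
dropletCapVolume <- function(contactRadius, contactAngle) {
  if (any(contactRadius <= 0)) stop("contact radius must be positive")
  if (any(contactAngle <= 0 | contactAngle >= 180))
    stop("contact angle must be in (0, 180) degrees")
  t <- contactAngle * pi / 180
  vMm3 <- (pi * contactRadius^3 / 3) *
    (1 - cos(t))^2 * (2 + cos(t)) / sin(t)^3
  vMm3 * 1000
}

#' Write a complete simulated fixture set
#'
#' One run table per polymer x replicate, plus the spectral library CSV,
#' the descriptor CSV, a ground-truth CSV (true log10 adsorption long
#' format) and a YAML manifest carrying the full configuration. The file
#' count is `nPolymers * nReplicates + 4`; regenerating with the same
#' seed is bit-identical.
#'
#' @param config a [simulationConfig()].
#' @param outDir writable output directory (created if absent).
#' @param proteins named list of [ProteinEntry-class].
#' @return character vector of the files written, invisibly.
#' @export
writeFixtureSet <- function(config, outDir, proteins = e8Proteins()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateStudy(config, proteins)
  files <- character()
  for (entry in sim$runs) {
    f <- file.path(outDir, sprintf("run_%s.csv", entry$run@runId))
    writeRun(entry$run, f)
    files <- c(files, f)
  }
  f <- file.path(outDir, "library.csv")
  exportLibrary(sim$library, f); files <- c(files, f)
  f <- file.path(outDir, "descriptors.csv")
  writeDescriptorCsv(sim$descriptors, f); files <- c(files, f)
  f <- file.path(outDir, "ground_truth.csv")
  la <- sim$truth$logAdsorption
  gt <- data.frame(polymer_id = rep(rownames(la), ncol(la)),
                   protein_id = rep(colnames(la), each = nrow(la)),
                   true_log10_adsorption = as.vector(la))
  utils::write.csv(gt, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(list(config = unclass(config)), f); files <- c(files, f)
  invisible(files)
}
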