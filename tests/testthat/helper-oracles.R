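# Independent oracles used across the suite.

# Residue masses recomputed from elemental composition and monoisotopic
# element masses -- an independent route to the package's residue table.
oracleElementMasses <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                         O = 15.9949146221, S = 31.97207069)

oracleResidueFormulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

oracleFormulaMass <- function(formula) {
  sum(oracleElementMasses[names(formula)] * formula)
}

oracleResidueMass <- vapply(oracleResidueFormulas, oracleFormulaMass, numeric(1))
oracleWater <- oracleFormulaMass(c(H = 2, O = 1))
oracleProton <- 1.00727646688

oraclePeptideMass <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  sum(oracleResidueMass[res]) + oracleWater
}

# Brute-force tryptic digestion: enumerate every substring and keep those
# whose boundaries are chain termini or non-suppressed K/R cleavage sites
# and whose internal non-suppressed site count is within the budget.
oracleDigest <- function(chain, maxMissed) {
  res <- strsplit(chain, "")[[1]]
  n <- length(res)
  isSite <- function(i)  # cleavage after position i allowed
    i >= 1 && i < n && res[i] %in% c("K", "R") && res[i + 1] != "P"
  out <- character()
  for (i in seq_len(n)) for (j in i:n) {
    okStart <- i == 1 || isSite(i - 1)
    okEnd <- j == n || isSite(j)
    if (!okStart || !okEnd) next
    internal <- if (j > i)
      sum(vapply(i:(j - 1), isSite, logical(1))) else 0L
    if (internal <= maxMissed)
      out <- c(out, substr(chain, i, j))
  }
  sort(out)
}

# Exhaustive optimal peak pairing: maximize matched-pair count, then the
# union-vector cosine, over all one-to-one pairings within tolerance.
oraclePairing <- function(qmz, qint, lmz, lint, tol) {
  best <- list(n = 0L, cross = 0)
  recurse <- function(qi, usedL, n, cross) {
    if (qi > length(qmz)) {
      if (n > best$n || (n == best$n && cross > best$cross))
        best <<- list(n = n, cross = cross)
      return(invisible())
    }
    recurse(qi + 1L, usedL, n, cross)        # leave query peak unmatched
    for (li in seq_along(lmz)) {
      if (usedL[li]) next
      if (abs(qmz[qi] - lmz[li]) <= tol) {
        usedL[li] <- TRUE
        recurse(qi + 1L, usedL, n + 1L, cross + qint[qi] * lint[li])
        usedL[li] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(lmz)), 0L, 0)
  qn <- sqrt(sum(qint^2)); ln <- sqrt(sum(lint^2))
  list(n = best$n,
       cosine = if (qn > 0 && ln > 0) best$cross / (qn * ln) else 0)
}

# Random centroided peak list; peptide fragment spectra are sparse, so a
# minimum peak spacing well above twice the matching tolerance is enforced.
randomPeakList <- function(nPeaks, mzRange = c(100, 1000), minSpacing = 0.05) {
  repeat {
    mz <- sort(runif(nPeaks, mzRange[1], mzRange[2]))
    if (nPeaks < 2 || all(diff(mz) > minSpacing)) break
  }
  list(mz = mz, intensity = runif(nPeaks, 1, 100))
}

randomResidueChain <- function(len) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}
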