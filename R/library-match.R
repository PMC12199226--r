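# Spectral-library construction, import/export, and cosine-correlation
# identification of targeted DIA MS2 scans. Acceptance follows the study
# rule: cosine > 0.95 and at least five matched fragment ions.

#' Build a spectral library from known peptides
#'
#' Realizes reference spectra from sequence alone: b/y fragment m/z from
#' [fragmentIons()] and intensities from a deterministic model. This stands
#' in for a search-engine-built library when working from synthetic ground
#' truth.
#'
#' @param peptides digest table ([trypticDigest()] / [freePeptides()]).
#' @param charges integer vector of precursor charges to realize.
#' @param fragmentModel `"uniform"` (all fragments intensity 1) or
#'   `"triangular"` (intensity rises towards mid-series, a crude mimic of
#'   real b/y patterns).
#' @param fragmentCharge highest fragment charge in the entries (default 1).
#' @param table a [massTable()].
#' @return a [SpectralLibrary-class]; peptides shorter than 2 residues are
#'   skipped with a warning.
#' @export
buildLibraryFromTruth <- function(peptides, charges = c(1L, 2L),
                                  fragmentModel = c("uniform", "triangular"),
                                  fragmentCharge = 1L, table = massTable()) {
  fragmentModel <- match.arg(fragmentModel)
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, ]
    if (nchar(p$sequence) < 2L) {
      warning(sprintf("peptide '%s' shorter than 2 residues: skipped", p$sequence))
      next
    }
    fr <- fragmentIons(p$sequence, maxCharge = fragmentCharge, table = table)
    int <- switch(fragmentModel,
      uniform = rep(1, nrow(fr)),
      triangular = 1 + pmin(fr$index, nchar(p$sequence) - fr$index))
    o <- order(fr$mz)
    for (z in charges) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = sprintf("%s_%s", p$protein_id, p$sequence),
        protein_id = p$protein_id, sequence = p$sequence, charge = z,
        precursor_mz = precursorMzFromMass(p$monoisotopic_mass, z, table),
        provenance = "ground-truth")
      rows[[length(rows)]]$fragment_mz <- list(fr$mz[o])
      rows[[length(rows)]]$fragment_intensity <- list(int[o])
    }
  }
  if (!length(rows))
    return(SpectralLibrary(data.frame(
      peptide_id = character(), protein_id = character(), sequence = character(),
      charge = integer(), precursor_mz = numeric(), provenance = character(),
      fragment_mz = I(list()), fragment_intensity = I(list()))))
  SpectralLibrary(do.call(rbind, rows))
}

#' Export a spectral library as CSV
#'
#' Columns `peptide_id`, `protein_id`, `sequence`, `charge`,
#' `precursor_mz`, `provenance`, `fragment_mz`, `fragment_intensity`
#' (peak arrays semicolon-joined).
#'
#' @param library a [SpectralLibrary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportLibrary <- function(library, path) {
  e <- library@entries
  df <- data.frame(peptide_id = e$peptide_id, protein_id = e$protein_id,
                   sequence = e$sequence, charge = e$charge,
                   precursor_mz = e$precursor_mz, provenance = e$provenance,
                   fragment_mz = vapply(e$fragment_mz, .joinArr, character(1)),
                   fragment_intensity = vapply(e$fragment_intensity, .joinArr,
                                               character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a spectral library (CSV or MSP-style text)
#'
#' CSV follows the [exportLibrary()] layout. MSP-style blocks are
#' `Name: <peptide>/<charge>`, `PrecursorMZ: <mz>`, `Num peaks: <n>`
#' followed by `<mz> <intensity>` lines.
#'
#' @param path input file.
#' @return a [SpectralLibrary-class]; entries without peaks are rejected.
#' @export
importLibrary <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\"?peptide_id", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$fragment_mz <- lapply(df$fragment_mz, .splitArr)
    df$fragment_intensity <- lapply(df$fragment_intensity, .splitArr)
    bad <- lengths(df$fragment_mz) == 0L
    if (any(bad))
      stop(sprintf("library entries without peaks: %s",
                   paste(df$peptide_id[bad], collapse = ", ")))
    return(SpectralLibrary(df))
  }
  .importMsp(path)
}

.importMsp <- function(path) {
  lines <- readLines(path)
  rows <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!grepl("^Name:", ln)) { i <- i + 1L; next }
    name <- trimws(sub("^Name:", "", ln))
    pep <- sub("/.*$", "", name)
    z <- suppressWarnings(as.integer(sub("^.*/", "", name)))
    if (is.na(z)) z <- 1L
    prec <- NA_real_; npk <- NA_integer_
    i <- i + 1L
    while (i <= length(lines) && !grepl("^Num peaks:", lines[i], ignore.case = TRUE)) {
      if (grepl("^PrecursorMZ:", lines[i], ignore.case = TRUE))
        prec <- as.numeric(trimws(sub("^PrecursorMZ:", "", lines[i], ignore.case = TRUE)))
      i <- i + 1L
    }
    if (i > length(lines)) stop("MSP block for '", name, "' lacks 'Num peaks:'")
    npk <- as.integer(trimws(sub("^Num peaks:", "", lines[i], ignore.case = TRUE)))
    if (is.na(npk) || npk < 1L)
      stop("MSP entry '", name, "' has no peaks")
    mz <- numeric(npk); int <- numeric(npk)
    for (k in seq_len(npk)) {
      i <- i + 1L
      parts <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
      if (length(parts) < 2L || anyNA(parts[1:2]))
        stop(sprintf("malformed peak line %d in %s", i, path))
      mz[k] <- parts[1L]; int[k] <- parts[2L]
    }
    row <- data.frame(peptide_id = pep, protein_id = NA_character_,
                      sequence = NA_character_, charge = z,
                      precursor_mz = prec, provenance = "imported")
    row$fragment_mz <- list(mz); row$fragment_intensity <- list(int)
    rows[[length(rows) + 1L]] <- row
    i <- i + 1L
  }
  if (!length(rows)) stop("no MSP entries found in ", path)
  SpectralLibrary(do.call(rbind, rows))
}

# Greedy one-to-one peak pairing by ascending |delta m/z|; a pair is
# admitted iff |delta| <= tol. Returns a 2-column index matrix (query, lib).
.pairPeaks <- function(qmz, lmz, tol) {
  if (!length(qmz) || !length(lmz))
    return(matrix(integer(), ncol = 2L))
  d <- abs(outer(qmz, lmz, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(integer(), ncol = 2L))
  # deterministic order: by distance, then query index, then lib index
  o <- order(d[cand], cand[, 1L], cand[, 2L])
  cand <- cand[o, , drop = FALSE]
  usedQ <- logical(length(qmz)); usedL <- logical(length(lmz))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    qi <- cand[r, 1L]; li <- cand[r, 2L]
    if (!usedQ[qi] && !usedL[li]) {
      usedQ[qi] <- TRUE; usedL[li] <- TRUE; keep[r] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

.applyWeighting <- function(x, weighting) {
  switch(weighting, raw = x, sqrt = sqrt(x), log = log1p(x))
}

#' Match an MS2 scan against one library entry
#'
#' Peaks are paired greedily by ascending m/z distance with one-to-one use;
#' a pair is admitted iff |delta m/z| <= `fragTol` (study tolerance
#' 0.02 Da). The cosine is computed over the union vector: matched pairs
#' contribute to the cross term, unmatched peaks of either side contribute
#' only to their own norm (so extraneous or missing peaks penalize the
#' score). A matched-peaks-only vectorization and sqrt/log intensity
#' weighting are available as options.
#'
#' @param query an MS2 [Spectrum-class].
#' @param entry one-row slice of [libraryEntries()] (or a list with
#'   `fragment_mz`, `fragment_intensity`, `peptide_id`, `charge`).
#' @param fragTol fragment tolerance in Da (default 0.02).
#' @param cosMin,minFrag acceptance thresholds (defaults 0.95, 5).
#' @param vectorization `"union"` (default) or `"matched"`.
#' @param weighting `"raw"` (default), `"sqrt"` or `"log"`.
#' @return one-row data.frame: `query_scan`, `peptide_id`, `charge`,
#'   `cosine`, `n_matched`, `accepted`.
#' @export
matchSpectrum <- function(query, entry, fragTol = 0.02,
                          cosMin = 0.95, minFrag = 5L,
                          vectorization = c("union", "matched"),
                          weighting = c("raw", "sqrt", "log")) {
  vectorization <- match.arg(vectorization)
  weighting <- match.arg(weighting)
  stopifnot(fragTol > 0)
  lmz <- entry$fragment_mz[[1]]
  lint <- .applyWeighting(entry$fragment_intensity[[1]], weighting)
  qmz <- query@mz
  qint <- .applyWeighting(query@intensity, weighting)
  pairs <- .pairPeaks(qmz, lmz, fragTol)
  nM <- nrow(pairs)
  cross <- if (nM) sum(qint[pairs[, 1L]] * lint[pairs[, 2L]]) else 0
  if (vectorization == "union") {
    qn <- sqrt(sum(qint^2)); ln <- sqrt(sum(lint^2))
  } else {
    qn <- sqrt(sum(qint[pairs[, 1L]]^2)); ln <- sqrt(sum(lint[pairs[, 2L]]^2))
  }
  cosine <- if (qn > 0 && ln > 0) cross / (qn * ln) else 0
  data.frame(query_scan = query@scanId,
             peptide_id = entry$peptide_id[[1]],
             charge = entry$charge[[1]],
             cosine = cosine, n_matched = nM,
             accepted = acceptMatch(cosine, nM, cosMin, minFrag))
}

#' Identification acceptance rule
#'
#' Accept iff cosine strictly exceeds `cosMin` and at least `minFrag`
#' fragment peaks matched (the study rule: cos theta > 0.95 and a minimum
#' of five fragment ions).
#'
#' @param cosine cosine similarity in `[0, 1]`.
#' @param nMatched matched fragment count.
#' @param cosMin,minFrag thresholds (defaults 0.95, 5).
#' @return logical.
#' @export
acceptMatch <- function(cosine, nMatched, cosMin = 0.95, minFrag = 5L) {
  cosine > cosMin & nMatched >= minFrag
}

#' Identify every MS2 scan of a run against a spectral library
#'
#' Each MS2 scan is matched only against entries whose precursor m/z falls
#' inside the scan's isolation window, taken half-open:
#' `[precursorMz - w/2, precursorMz + w/2)`. Per scan the winner is the
#' highest-cosine accepted entry (ties broken by higher matched-fragment
#' count, then lexicographic peptide id); when nothing is accepted, the
#' best-cosine candidate is reported with `accepted = FALSE`, and a scan
#' with no in-window entry yields an unmatched row.
#'
#' @param run an [MsRun-class].
#' @param library a [SpectralLibrary-class].
#' @param fragTol fragment tolerance (Da).
#' @param cosMin,minFrag acceptance thresholds.
#' @param vectorization,weighting passed to [matchSpectrum()].
#' @return data.frame, one row per MS2 scan, columns as in
#'   [matchSpectrum()] plus `run_id`.
#' @export
identifyRun <- function(run, library, fragTol = 0.02, cosMin = 0.95,
                        minFrag = 5L, vectorization = c("union", "matched"),
                        weighting = c("raw", "sqrt", "log")) {
  vectorization <- match.arg(vectorization)
  weighting <- match.arg(weighting)
  e <- library@entries
  out <- list()
  for (s in run@spectra) {
    if (s@msLevel != 2L) next
    w <- s@isolationWidth
    inWin <- which(e$precursor_mz >= s@precursorMz - w / 2 &
                   e$precursor_mz < s@precursorMz + w / 2)
    if (!length(inWin)) {
      out[[length(out) + 1L]] <- data.frame(
        query_scan = s@scanId, peptide_id = NA_character_,
        charge = NA_integer_, cosine = 0, n_matched = 0L, accepted = FALSE)
      next
    }
    cands <- do.call(rbind, lapply(inWin, function(i)
      matchSpectrum(s, e[i, ], fragTol, cosMin, minFrag,
                    vectorization, weighting)))
    pool <- if (any(cands$accepted)) cands[cands$accepted, , drop = FALSE] else cands
    pool <- pool[order(-pool$cosine, -pool$n_matched, pool$peptide_id), , drop = FALSE]
    out[[length(out) + 1L]] <- pool[1L, ]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(query_scan = integer(), peptide_id = character(),
               charge = integer(), cosine = numeric(), n_matched = integer(),
               accepted = logical())
  res <- cbind(run_id = run@runId, res)
  rownames(res) <- NULL
  res
}
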