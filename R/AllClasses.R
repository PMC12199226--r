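#' @import methods
NULL

.AA_CODES <- c("A","R","N","D","C","E","Q","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")

#' ProteinEntry: a (possibly multi-chain) protein with disulfide topology
#'
#' Container for one protein as it enters in-silico digestion: one or more
#' chains given as 1-letter residue strings, plus a table of disulfide
#' bridges. Disulfides matter because tryptic peptides that remain tethered
#' through a disulfide bridge are not released as free linear species and
#' therefore never appear in the MS data.
#'
#' @slot id single identifier string.
#' @slot name human-readable name.
#' @slot chains character vector of residue strings (canonical 20 codes).
#' @slot disulfides data.frame with columns `chain_a`, `pos_a`, `chain_b`,
#'   `pos_b` (1-based residue positions; both endpoints must be cysteines).
#' @export
setClass("ProteinEntry",
  representation(id = "character", name = "character",
                 chains = "character", disulfides = "data.frame"))

setValidity("ProteinEntry", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "'id' must be a single non-empty string")
  for (k in seq_along(object@chains)) {
    res <- strsplit(object@chains[[k]], "")[[1]]
    bad <- setdiff(unique(res), .AA_CODES)
    if (length(bad))
      msgs <- c(msgs, sprintf("chain %d contains non-canonical residue code(s): %s",
                              k, paste(bad, collapse = ", ")))
  }
  ds <- object@disulfides
  need <- c("chain_a", "pos_a", "chain_b", "pos_b")
  if (!all(need %in% names(ds))) {
    msgs <- c(msgs, sprintf("disulfide table must have columns %s",
                            paste(need, collapse = ", ")))
  } else if (nrow(ds)) {
    ends <- rbind(cbind(ds$chain_a, ds$pos_a), cbind(ds$chain_b, ds$pos_b))
    for (r in seq_len(nrow(ends))) {
      ch <- ends[r, 1L]; pos <- ends[r, 2L]
      if (ch < 1L || ch > length(object@chains)) {
        msgs <- c(msgs, sprintf("disulfide endpoint references chain %d (out of bounds)", ch))
      } else if (pos < 1L || pos > nchar(object@chains[[ch]])) {
        msgs <- c(msgs, sprintf("disulfide position %d out of bounds for chain %d", pos, ch))
      } else if (substr(object@chains[[ch]], pos, pos) != "C") {
        msgs <- c(msgs, sprintf("disulfide endpoint chain %d pos %d is not a cysteine", ch, pos))
      }
    }
    key <- paste(ends[, 1L], ends[, 2L])
    if (anyDuplicated(key))
      msgs <- c(msgs, "a residue participates in more than one disulfide")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinEntry
#'
#' @param id,name identifier and display name.
#' @param chains character vector of 1-letter residue strings.
#' @param disulfides data.frame (`chain_a`, `pos_a`, `chain_b`, `pos_b`),
#'   1-based; defaults to none.
#' @return a validated [ProteinEntry-class] object.
#' @examples
#' ins <- ProteinEntry("insulin", "mature human insulin",
#'   chains = c("GIVEQCCTSICSLYQLENYCN", "FVNQHLCGSHLVEALYLVCGERGFFYTPKT"),
#'   disulfides = data.frame(chain_a = c(1, 1, 1), pos_a = c(6, 7, 20),
#'                           chain_b = c(1, 2, 2), pos_b = c(11, 7, 19)))
#' @export
ProteinEntry <- function(id, name = id, chains, disulfides = NULL) {
  if (is.null(disulfides))
    disulfides <- data.frame(chain_a = integer(), pos_a = integer(),
                             chain_b = integer(), pos_b = integer())
  disulfides[] <- lapply(disulfides, as.integer)
  new("ProteinEntry", id = as.character(id), name = as.character(name),
      chains = toupper(chains), disulfides = disulfides)
}

setMethod("show", "ProteinEntry", function(object) {
  cat(sprintf("ProteinEntry '%s' (%s): %d chain(s), %d residues, %d disulfide(s)\n",
              object@id, object@name, length(object@chains),
              sum(nchar(object@chains)), nrow(object@disulfides)))
})

#' @describeIn ProteinEntry chain residue strings.
#' @param x a `ProteinEntry`.
#' @export
chains <- function(x) x@chains

#' @describeIn ProteinEntry disulfide table.
#' @export
disulfides <- function(x) x@disulfides

#' Spectrum: one centroided scan
#'
#' A single centroided mass spectrum. MS2 scans carry their precursor
#' isolation target and window width; MS1 scans carry the acquired scan
#' range. Peaks are stored as parallel `mz` (strictly ascending, Th) and
#' `intensity` (>= 0, arbitrary units) vectors.
#'
#' @slot scanId integer scan number.
#' @slot msLevel 1 or 2.
#' @slot mz,intensity parallel peak vectors.
#' @slot precursorMz,isolationWidth MS2 isolation target and width (Th).
#' @slot scanLow,scanHigh MS1 scan range (Th).
#' @export
setClass("Spectrum",
  representation(scanId = "integer", msLevel = "integer",
                 mz = "numeric", intensity = "numeric",
                 precursorMz = "numeric", isolationWidth = "numeric",
                 scanLow = "numeric", scanHigh = "numeric"))

setValidity("Spectrum", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msgs <- c(msgs, sprintf("scan %d: m/z values must be strictly ascending",
                            object@scanId))
  if (any(object@intensity < 0))
    msgs <- c(msgs, sprintf("scan %d: negative intensity", object@scanId))
  if (!object@msLevel %in% c(1L, 2L))
    msgs <- c(msgs, "msLevel must be 1 or 2")
  if (object@msLevel == 2L && (is.na(object@precursorMz) || is.na(object@isolationWidth)))
    msgs <- c(msgs, sprintf("MS2 scan %d lacks precursorMz/isolationWidth", object@scanId))
  if (object@msLevel == 1L && (is.na(object@scanLow) || is.na(object@scanHigh)))
    msgs <- c(msgs, sprintf("MS1 scan %d lacks scan range", object@scanId))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Spectrum
#'
#' @param scanId integer scan number.
#' @param msLevel 1 or 2.
#' @param mz,intensity peak vectors; re-sorted ascending by m/z.
#' @param precursorMz,isolationWidth MS2 metadata (Th).
#' @param scanRange length-2 MS1 range (Th).
#' @return a validated [Spectrum-class].
#' @export
Spectrum <- function(scanId, msLevel, mz = numeric(), intensity = numeric(),
                     precursorMz = NA_real_, isolationWidth = NA_real_,
                     scanRange = c(NA_real_, NA_real_)) {
  o <- order(mz)
  new("Spectrum", scanId = as.integer(scanId), msLevel = as.integer(msLevel),
      mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      precursorMz = as.numeric(precursorMz),
      isolationWidth = as.numeric(isolationWidth),
      scanLow = as.numeric(scanRange[1L]), scanHigh = as.numeric(scanRange[2L]))
}

setMethod("show", "Spectrum", function(object) {
  extra <- if (object@msLevel == 2L)
    sprintf("precursor %.4f (±%.2f)", object@precursorMz, object@isolationWidth / 2)
  else sprintf("range %.0f-%.0f", object@scanLow, object@scanHigh)
  cat(sprintf("Spectrum scan %d MS%d, %d peaks, %s\n",
              object@scanId, object@msLevel, length(object@mz), extra))
})

#' @describeIn Spectrum peak table (`mz`, `intensity`).
#' @param x a `Spectrum`.
#' @export
peaks <- function(x) data.frame(mz = x@mz, intensity = x@intensity)

#' @describeIn Spectrum MS level (1 or 2).
#' @export
msLevel <- function(x) x@msLevel

#' @describeIn Spectrum precursor m/z (MS2) or NA.
#' @export
precursorMz <- function(x) x@precursorMz

#' MsRun: an ordered DIA acquisition
#'
#' One LESA-MS/MS acquisition on one polymer spot, i.e. an ordered list of
#' [Spectrum-class] scans organised as DIA cycles: `cycleLength` targeted
#' MS2 scans followed by one MS1 survey scan, repeating.
#'
#' @slot runId identifier, conventionally `<polymer>_r<replicate>`.
#' @slot spectra list of `Spectrum`, ordered by scan id.
#' @slot cycleLength MS2 scans per MS1 scan (the study design uses 10).
#' @export
setClass("MsRun",
  representation(runId = "character", spectra = "list", cycleLength = "integer"))

setValidity("MsRun", function(object) {
  msgs <- character()
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    msgs <- c(msgs, "all elements of 'spectra' must be Spectrum objects")
  else {
    ids <- vapply(object@spectra, function(s) s@scanId, integer(1))
    if (length(ids) > 1L && any(diff(ids) <= 0))
      msgs <- c(msgs, "spectra must be ordered by strictly increasing scan id")
  }
  if (object@cycleLength < 1L) msgs <- c(msgs, "cycleLength must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an MsRun
#' @param runId run identifier.
#' @param spectra list of [Spectrum-class] scans, ordered by scan id.
#' @param cycleLength MS2 scans per DIA cycle (default 10).
#' @return a validated [MsRun-class].
#' @export
MsRun <- function(runId, spectra = list(), cycleLength = 10L) {
  new("MsRun", runId = as.character(runId), spectra = spectra,
      cycleLength = as.integer(cycleLength))
}

setMethod("show", "MsRun", function(object) {
  lv <- vapply(object@spectra, msLevel, integer(1))
  cat(sprintf("MsRun '%s': %d scans (%d MS2, %d MS1), cycle length %d\n",
              object@runId, length(object@spectra), sum(lv == 2L),
              sum(lv == 1L), object@cycleLength))
})

setMethod("length", "MsRun", function(x) length(x@spectra))

#' @describeIn MsRun run identifier.
#' @param x an `MsRun`.
#' @export
runId <- function(x) x@runId

#' @describeIn MsRun list of spectra.
#' @export
spectra <- function(x) x@spectra

#' SpectralLibrary: reference fragment spectra per peptide ion
#'
#' One row per (peptide, charge): sequence, precursor m/z and the reference
#' fragment peak list used for cosine identification. Fragment peaks are
#' stored as list-columns of ascending m/z and matching intensity vectors.
#'
#' @slot entries data.frame with columns `peptide_id`, `protein_id`,
#'   `sequence`, `charge`, `precursor_mz`, `provenance` and list-columns
#'   `fragment_mz`, `fragment_intensity`.
#' @export
setClass("SpectralLibrary", representation(entries = "data.frame"))

setValidity("SpectralLibrary", function(object) {
  e <- object@entries
  need <- c("peptide_id", "protein_id", "sequence", "charge", "precursor_mz",
            "fragment_mz", "fragment_intensity", "provenance")
  if (!all(need %in% names(e)))
    return(sprintf("library entries need columns %s", paste(need, collapse = ", ")))
  msgs <- character()
  for (i in seq_len(nrow(e))) {
    fmz <- e$fragment_mz[[i]]; fint <- e$fragment_intensity[[i]]
    if (length(fmz) < 1L)
      msgs <- c(msgs, sprintf("entry %s/%d has no fragments", e$peptide_id[i], e$charge[i]))
    if (length(fmz) != length(fint))
      msgs <- c(msgs, sprintf("entry %s/%d fragment arrays differ in length",
                              e$peptide_id[i], e$charge[i]))
    if (length(fmz) > 1L && any(diff(fmz) <= 0))
      msgs <- c(msgs, sprintf("entry %s/%d fragment m/z not strictly ascending",
                              e$peptide_id[i], e$charge[i]))
    if (any(fint < 0))
      msgs <- c(msgs, sprintf("entry %s/%d has negative fragment intensity",
                              e$peptide_id[i], e$charge[i]))
    sq <- e$sequence[i]
    if (!is.na(sq) && nzchar(sq)) {
      expect <- precursorMzFromMass(monoisotopicMass(sq), e$charge[i])
      if (abs(e$precursor_mz[i] - expect) / expect * 1e6 > 20)
        msgs <- c(msgs, sprintf("entry %s/%d precursor m/z inconsistent with sequence (>20 ppm)",
                                e$peptide_id[i], e$charge[i]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectralLibrary from an entry table
#' @param entries data.frame as described in [SpectralLibrary-class].
#' @return a validated `SpectralLibrary`.
#' @export
SpectralLibrary <- function(entries) {
  entries$charge <- as.integer(entries$charge)
  o <- lapply(entries$fragment_mz, order)
  entries$fragment_mz <- Map(function(v, i) as.numeric(v[i]), entries$fragment_mz, o)
  entries$fragment_intensity <- Map(function(v, i) as.numeric(v[i]),
                                    entries$fragment_intensity, o)
  rownames(entries) <- NULL
  new("SpectralLibrary", entries = entries)
}

setMethod("show", "SpectralLibrary", function(object) {
  e <- object@entries
  cat(sprintf("SpectralLibrary: %d entries, %d peptides, %d proteins\n",
              nrow(e), length(unique(e$peptide_id)), length(unique(e$protein_id))))
})

setMethod("length", "SpectralLibrary", function(x) nrow(x@entries))

#' @describeIn SpectralLibrary the entry table.
#' @param x a `SpectralLibrary`.
#' @export
libraryEntries <- function(x) x@entries

#' AdsorptionTable: polymer x protein relative adsorption
#'
#' One row per (polymer, protein): per-replicate log10 summed peptide
#' intensities, their geometric mean on the linear scale, the replicate
#' signal-to-noise ratio (mean / sd of linear intensities) and the SNR
#' filter verdict.
#'
#' @slot table data.frame with columns `polymer_id`, `protein_id`,
#'   replicate columns `log10_rep<i>`, `geomean`, `snr`, `passed_filter`.
#' @slot snrThreshold threshold used for `passed_filter` (study value 1.5).
#' @export
setClass("AdsorptionTable",
  representation(table = "data.frame", snrThreshold = "numeric"))

setValidity("AdsorptionTable", function(object) {
  t <- object@table
  need <- c("polymer_id", "protein_id", "geomean", "snr", "passed_filter")
  if (!all(need %in% names(t)))
    return(sprintf("adsorption table needs columns %s", paste(need, collapse = ", ")))
  msgs <- character()
  if (any(t$snr < 0, na.rm = TRUE)) msgs <- c(msgs, "snr must be >= 0")
  if (any(t$geomean <= 0, na.rm = TRUE))
    msgs <- c(msgs, "geometric means must be positive (imputation guarantees this)")
  ok <- !is.na(t$snr) & t$snr > object@snrThreshold
  if (!identical(as.logical(t$passed_filter), as.logical(ok)))
    msgs <- c(msgs, "passed_filter inconsistent with snr > threshold")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AdsorptionTable", function(object) {
  t <- object@table
  cat(sprintf("AdsorptionTable: %d polymer x protein rows, %d pass SNR > %.2f\n",
              nrow(t), sum(t$passed_filter), object@snrThreshold))
  for (p in unique(t$protein_id)) {
    sub <- t[t$protein_id == p, ]
    cat(sprintf("  %-12s %3d/%3d polymers retained\n", p,
                sum(sub$passed_filter), nrow(sub)))
  }
})

#' @describeIn AdsorptionTable the underlying data.frame.
#' @param x an `AdsorptionTable`.
#' @export
adsorptionValues <- function(x) x@table

#' DescriptorMatrix: polymer x molecular-descriptor values
#'
#' Numeric matrix of molecular descriptors (atom-signature fragment counts
#' and/or imported tables such as Dragon descriptors), rows named by
#' polymer id, columns by descriptor name. Absent signatures are stored as
#' 0, never NA.
#'
#' @slot values numeric matrix with dimnames.
#' @slot source "computed" or "imported".
#' @slot constantColumns names of columns flagged as constant.
#' @export
setClass("DescriptorMatrix",
  representation(values = "matrix", source = "character",
                 constantColumns = "character"))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have polymer row names and descriptor column names")
  else if (anyDuplicated(colnames(v)))
    msgs <- c(msgs, "descriptor names must be unique")
  if (anyNA(v)) msgs <- c(msgs, "descriptor matrix must have no missing cells")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DescriptorMatrix
#' @param values numeric matrix (polymers x descriptors, dimnames required).
#' @param source provenance label, `"computed"` or `"imported"`.
#' @return a validated `DescriptorMatrix`; constant columns are flagged in
#'   the `constantColumns` slot (inspect with [constantColumns()]).
#' @export
DescriptorMatrix <- function(values, source = c("computed", "imported")) {
  source <- match.arg(source)
  cc <- colnames(values)[apply(values, 2L, function(x) length(unique(x)) == 1L)]
  new("DescriptorMatrix", values = values, source = source,
      constantColumns = as.character(cc))
}

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix (%s): %d polymers x %d descriptors (%d constant)\n",
              object@source, nrow(object@values), ncol(object@values),
              length(object@constantColumns)))
})

setMethod("dim", "DescriptorMatrix", function(x) dim(x@values))

#' @describeIn DescriptorMatrix the numeric matrix.
#' @param x a `DescriptorMatrix`.
#' @export
descriptorValues <- function(x) x@values

#' @describeIn DescriptorMatrix names of constant (zero-variance) columns.
#' @export
constantColumns <- function(x) x@constantColumns

#' SparseFit: a sparse linear model fitted by EM
#'
#' Result of [emSparseRegression()]: exactly-sparse coefficients on the
#' original descriptor scale, the intercept (fit on unstandardized response)
#' and the EM trace. The `objective` slot records the penalized
#' log-likelihood at each iteration; it is non-decreasing by construction.
#'
#' @slot selected names of descriptors retained (|coef| >= prune tolerance).
#' @slot coefficients named numeric, original scale; only selected names.
#' @slot intercept numeric.
#' @slot converged logical; `nIter` iterations used.
#' @slot nIter integer.
#' @slot objective numeric vector, penalized log-likelihood per iteration.
#' @slot xCenter,xScale standardization parameters of the training design.
#' @export
setClass("SparseFit",
  representation(selected = "character", coefficients = "numeric",
                 intercept = "numeric", converged = "logical",
                 nIter = "integer", objective = "numeric",
                 xCenter = "numeric", xScale = "numeric"))

setValidity("SparseFit", function(object) {
  if (!identical(sort(as.character(names(object@coefficients))),
                 sort(object@selected)))
    return("coefficient names must equal the selected descriptor set")
  TRUE
})

setMethod("show", "SparseFit", function(object) {
  cat(sprintf("SparseFit: %d nonzero coefficients, %sconverged in %d iterations\n",
              length(object@coefficients),
              if (object@converged) "" else "NOT ", object@nIter))
  if (length(object@coefficients)) {
    co <- sort(object@coefficients, decreasing = TRUE)
    for (nm in names(co)) cat(sprintf("  %+9.4f  %s\n", co[[nm]], nm))
  }
  cat(sprintf("  intercept %.4f\n", object@intercept))
})

#' Predict from a SparseFit
#' @param object a [SparseFit-class].
#' @param newdata numeric matrix with (at least) the selected columns.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "SparseFit", function(object, newdata, ...) {
  if (!length(object@coefficients))
    return(rep(object@intercept, nrow(newdata)))
  as.numeric(object@intercept +
    newdata[, names(object@coefficients), drop = FALSE] %*% object@coefficients)
})

#' BootstrapResult: repeated-split evaluation of the sparse model
#'
#' Per-split test RMSE and R^2 for `nBoot` random 80/20 splits, the
#' per-feature selection frequency and the individual [SparseFit-class]
#' models.
#'
#' @slot rmse,r2 numeric vectors of length `nBoot` (R^2 may be NA when a
#'   test split has zero response variance; such splits are excluded from
#'   summaries).
#' @slot selectionFrequency named numeric in `[0, 1]`.
#' @slot fits list of `SparseFit`.
#' @slot seeds integer vector of per-split seeds; `testIndices` the splits.
#' @export
setClass("BootstrapResult",
  representation(rmse = "numeric", r2 = "numeric",
                 selectionFrequency = "numeric", fits = "list",
                 seeds = "integer", testIndices = "list"))

setValidity("BootstrapResult", function(object) {
  n <- length(object@rmse)
  if (length(object@r2) != n || length(object@fits) != n)
    return("rmse, r2 and fits must all have length nBoot")
  if (any(object@rmse < 0, na.rm = TRUE)) return("rmse must be >= 0")
  TRUE
})

setMethod("show", "BootstrapResult", function(object) {
  r2 <- object@r2[!is.na(object@r2)]
  cat(sprintf("BootstrapResult: %d splits\n", length(object@rmse)))
  cat(sprintf("  test RMSE %.3f +/- %.3f\n", mean(object@rmse), stats::sd(object@rmse)))
  cat(sprintf("  test R^2  %.3f +/- %.3f (%d valid)\n",
              mean(r2), stats::sd(r2), length(r2)))
  top <- sort(object@selectionFrequency, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5L, sum(top > 0)))]
  if (length(top))
    cat("  top selected:", paste(sprintf("%s (%.0f%%)", names(top), 100 * top),
                                 collapse = ", "), "\n")
})

#' @describeIn BootstrapResult per-split metric table.
#' @param x a `BootstrapResult`.
#' @export
bootstrapMetrics <- function(x)
  data.frame(split = seq_along(x@rmse), rmse = x@rmse, r2 = x@r2)

#' @describeIn BootstrapResult named selection-frequency vector.
#' @export
selectionFrequency <- function(x) x@selectionFrequency

#' MolecularGraph: a hydrogen-suppressed molecule
#'
#' Minimal molecular graph for signature descriptors: heavy atoms with an
#' element symbol and aromatic flag, and bonds with order 1, 2, 3 or
#' `"ar"` (aromatic). Hydrogens are implicit.
#'
#' @slot atoms data.frame with columns `element`, `aromatic`.
#' @slot bonds data.frame with columns `i`, `j`, `order`.
#' @export
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  if (!all(c("element", "aromatic") %in% names(a)))
    msgs <- c(msgs, "atoms need columns element, aromatic")
  if (!all(c("i", "j", "order") %in% names(b)))
    msgs <- c(msgs, "bonds need columns i, j, order")
  else if (nrow(b)) {
    n <- nrow(a)
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n))
      msgs <- c(msgs, "bond endpoint out of bounds")
    if (any(b$i == b$j)) msgs <- c(msgs, "bond endpoints must be distinct")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond")
    if (!all(b$order %in% c("1", "2", "3", "ar")))
      msgs <- c(msgs, "bond order must be 1, 2, 3 or 'ar'")
    if (nrow(a) > 1L) {
      # connectivity check by label propagation
      comp <- seq_len(nrow(a))
      repeat {
        new <- comp
        for (r in seq_len(nrow(b))) {
          m <- min(new[b$i[r]], new[b$j[r]])
          new[b$i[r]] <- m; new[b$j[r]] <- m
        }
        if (identical(new, comp)) break
        comp <- new
      }
      if (length(unique(comp)) > 1L)
        msgs <- c(msgs, "molecular graph must be connected")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MolecularGraph
#' @param elements character vector of element symbols.
#' @param bonds data.frame (`i`, `j`, `order`); order coerced to character.
#' @param aromatic logical vector (default all FALSE).
#' @return a validated `MolecularGraph`.
#' @export
MolecularGraph <- function(elements, bonds = NULL, aromatic = NULL) {
  if (is.null(aromatic)) aromatic <- rep(FALSE, length(elements))
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.character(bonds$order)
  new("MolecularGraph",
      atoms = data.frame(element = as.character(elements), aromatic = aromatic),
      bonds = bonds)
}

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d heavy atoms (%s), %d bonds\n",
              nrow(object@atoms),
              paste(names(table(object@atoms$element)), table(object@atoms$element),
                    sep = "", collapse = " "),
              nrow(object@bonds)))
})
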