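# Readers/writers for centroided DIA runs. Canonical on-disk format is a
# "run table" CSV (one row per scan, peak arrays semicolon-joined), because
# MGF cannot carry MS1 scans and mzML writing is out of scope. MGF export
# and mzML import are interop conveniences.

.joinArr <- function(x) paste(sprintf("%.10g", x), collapse = ";")
.splitArr <- function(s) {
  s <- as.character(s)
  if (is.na(s) || !nzchar(s)) return(numeric())
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Write a run table CSV
#'
#' Columns: `scan_id`, `ms_level`, `precursor_mz`, `isolation_width`,
#' `scan_low`, `scan_high`, `mz_array`, `intensity_array` (arrays
#' semicolon-joined). An empty run writes the header only.
#'
#' @param run an [MsRun-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRun <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  rows <- lapply(run@spectra, function(s) data.frame(
    scan_id = s@scanId, ms_level = s@msLevel,
    precursor_mz = s@precursorMz, isolation_width = s@isolationWidth,
    scan_low = s@scanLow, scan_high = s@scanHigh,
    mz_array = .joinArr(s@mz), intensity_array = .joinArr(s@intensity)))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan_id = integer(), ms_level = integer(),
               precursor_mz = numeric(), isolation_width = numeric(),
               scan_low = numeric(), scan_high = numeric(),
               mz_array = character(), intensity_array = character())
  attr(df, "run_id") <- run@runId
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# run_id=%s cycle_length=%d", run@runId, run@cycleLength), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a run from a run table CSV or an mzML file
#'
#' Dispatches on the file extension: `.mzML` is parsed through the
#' Bioconductor `mzR` reader, anything else as the package's run table CSV.
#'
#' @param path input file.
#' @param runId run identifier; for run tables defaults to the id recorded
#'   in the file header, for mzML to the file name.
#' @param cycleLength MS2 scans per DIA cycle when the file does not record
#'   it (default 10).
#' @return an [MsRun-class] with peaks sorted ascending.
#' @export
readRun <- function(path, runId = NULL, cycleLength = 10L) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE))
    return(.readMzml(path, runId, cycleLength))
  head1 <- readLines(path, n = 1L)
  if (grepl("^# run_id=", head1)) {
    if (is.null(runId)) runId <- sub("^# run_id=([^ ]+).*$", "\\1", head1)
    cl <- suppressWarnings(as.integer(sub("^.*cycle_length=([0-9]+).*$", "\\1", head1)))
    if (!is.na(cl)) cycleLength <- cl
    df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mz <- .splitArr(r$mz_array); int <- .splitArr(r$intensity_array)
    if (length(mz) != length(int))
      stop(sprintf("scan %s: mz and intensity arrays differ in length", r$scan_id))
    if (anyDuplicated(mz))
      stop(sprintf("scan %s: duplicate m/z values", r$scan_id))
    Spectrum(r$scan_id, r$ms_level, mz, int,
             precursorMz = r$precursor_mz, isolationWidth = r$isolation_width,
             scanRange = c(r$scan_low, r$scan_high))
  })
  MsRun(runId, specs, cycleLength)
}

.readMzml <- function(path, runId, cycleLength) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML import requires the 'mzR' package")
  if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  specs <- lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(f, i)
    lvl <- h$msLevel[i]
    width <- h$isolationWindowUpperOffset[i] + h$isolationWindowLowerOffset[i]
    if (lvl == 2L && (is.null(width) || is.na(width) || width <= 0)) width <- 1
    Spectrum(h$acquisitionNum[i], lvl, pk[, 1L], pk[, 2L],
             precursorMz = if (lvl == 2L) h$precursorMZ[i] else NA_real_,
             isolationWidth = if (lvl == 2L) width else NA_real_,
             scanRange = if (lvl == 1L) c(h$lowMZ[i], h$highMZ[i])
                         else c(NA_real_, NA_real_))
  })
  MsRun(runId, specs, cycleLength)
}

#' Export the MS2 scans of a run as MGF
#'
#' MGF cannot represent MS1 survey scans, so only MS2 scans are written,
#' one `BEGIN IONS`/`END IONS` block each with
#' `TITLE=<run_id>.<scan_id>` and `PEPMASS` set to the isolation target.
#'
#' @param run an [MsRun-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(run, path) {
  stopifnot(is(run, "MsRun"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in run@spectra) {
    if (s@msLevel != 2L) next
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s.%d", run@runId, s@scanId),
                 sprintf("PEPMASS=%.6f", s@precursorMz),
                 sprintf("%.6f %.6f", s@mz, s@intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Partition a run into DIA cycles
#'
#' A cycle is `cycleLength` MS2 scans followed by one MS1 scan. A trailing
#' group without its MS1 scan (or with fewer MS2 scans) is retained and
#' flagged incomplete; an MS1 scan arriving mid-cycle splits the cycle at
#' that point with a structural warning.
#'
#' @param run an [MsRun-class].
#' @return list of cycles, each `list(ms2 = <list of Spectrum>,
#'   ms1 = <Spectrum or NULL>, complete = <logical>)`.
#' @export
cycles <- function(run) {
  stopifnot(is(run, "MsRun"))
  out <- list()
  ms2 <- list()
  for (s in run@spectra) {
    if (s@msLevel == 2L) {
      ms2[[length(ms2) + 1L]] <- s
    } else {
      if (length(ms2) != run@cycleLength)
        warning(sprintf("run %s: MS1 scan %d closes a cycle of %d MS2 scans (expected %d)",
                        run@runId, s@scanId, length(ms2), run@cycleLength))
      out[[length(out) + 1L]] <- list(ms2 = ms2, ms1 = s,
                                      complete = length(ms2) == run@cycleLength)
      ms2 <- list()
    }
  }
  if (length(ms2))
    out[[length(out) + 1L]] <- list(ms2 = ms2, ms1 = NULL, complete = FALSE)
  out
}

#' DIA acquisition scheme
#'
#' The target list of a targeted-DIA method: one row per monitored peptide
#' ion, plus the isolation width, the MS1 scan range and the cycle length.
#' The study design isolates each target in a 1 Th window and surveys
#' m/z 400-900 after every 10 DIA scans.
#'
#' @param targets data.frame with columns `peptide_id`, `protein_id`,
#'   `charge`, `precursor_mz` and optionally `response` (per-ion MS1
#'   response factor used by the simulator).
#' @param isolationWidth Th, default 1.
#' @param ms1Range length-2 numeric, default `c(400, 900)`.
#' @param cycleLength MS2 scans per cycle, default 10.
#' @return object of class `AcquisitionScheme` (a list).
#' @export
acquisitionScheme <- function(targets, isolationWidth = 1.0,
                              ms1Range = c(400, 900), cycleLength = 10L) {
  stopifnot(all(c("peptide_id", "protein_id", "charge", "precursor_mz") %in%
                names(targets)),
            isolationWidth > 0, length(ms1Range) == 2L)
  if (any(targets$precursor_mz <= 0))
    stop("target precursor m/z must be positive")
  structure(list(targets = targets, isolationWidth = isolationWidth,
                 ms1Range = as.numeric(ms1Range),
                 cycleLength = as.integer(cycleLength)),
            class = "AcquisitionScheme")
}
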