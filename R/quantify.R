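# MS1 extracted-intensity label-free quantification, per-protein
# aggregation, imputation at the peak-intensity threshold, replicate
# statistics and the SNR reproducibility filter.

#' Extract an MS1 intensity for one target ion
#'
#' For every MS1 scan, sums the peak intensities within `ppmTol` of
#' `targetMz` (study tolerance 10 ppm); the run-level value is the median
#' over the MS1 scans that contain at least one in-window peak, which is
#' robust to single-scan spray instability. Returns `NA` when no MS1 scan
#' has an in-window peak (and warns when the run has no MS1 scans at all).
#'
#' @param run an [MsRun-class].
#' @param targetMz target m/z (Th).
#' @param ppmTol tolerance in ppm (default 10).
#' @return intensity, or `NA_real_` when missing.
#' @export
extractMs1Intensity <- function(run, targetMz, ppmTol = 10) {
  stopifnot(ppmTol > 0)
  ms1 <- Filter(function(s) s@msLevel == 1L, run@spectra)
  if (!length(ms1)) {
    warning(sprintf("run %s has no MS1 scans", run@runId))
    return(NA_real_)
  }
  sums <- vapply(ms1, function(s) {
    sel <- abs(s@mz - targetMz) / targetMz * 1e6 <= ppmTol
    if (any(sel)) sum(s@intensity[sel]) else NA_real_
  }, numeric(1))
  sums <- sums[!is.na(sums)]
  if (!length(sums)) return(NA_real_)
  stats::median(sums)
}

#' Impute a missing intensity at the peak-intensity threshold
#'
#' Missing peptide intensities are replaced with the instrument's peak
#' intensity threshold, 1000 on the linear scale (3.0 after log10);
#' present values pass through unchanged.
#'
#' @param value numeric (vector); `NA` entries are replaced.
#' @param threshold linear-scale replacement value (default 1000).
#' @return numeric of the same length.
#' @export
imputeMissing <- function(value, threshold = 1000) {
  value[is.na(value)] <- threshold
  value
}

#' Per-protein log10 summed peptide intensity
#'
#' Log10 of the sum of the present peptide-ion intensities of one protein
#' in one run; `NA` when no peptide is present.
#'
#' @param intensities numeric vector of peptide-ion intensities (may
#'   contain `NA`).
#' @return log10 intensity or `NA_real_`.
#' @export
proteinLogIntensity <- function(intensities) {
  x <- intensities[!is.na(intensities)]
  if (!length(x)) return(NA_real_)
  log10(sum(x))
}

#' Geometric mean
#'
#' `exp(mean(log(x)))`; used to aggregate replicates because adsorption
#' intensities vary multiplicatively between replicate spots.
#'
#' @param values positive numeric vector.
#' @return positive scalar.
#' @export
geometricMean <- function(values) {
  if (any(values <= 0)) stop("geometric mean requires all values > 0")
  exp(mean(log(values)))
}

#' Replicate signal-to-noise ratio
#'
#' Arithmetic mean divided by the sample standard deviation (n-1
#' denominator) of the replicate linear-scale intensities; `Inf` when the
#' replicates are identical. Used as a reproducibility filter at the study
#' threshold of 1.5.
#'
#' @param values numeric vector, length >= 2.
#' @return non-negative scalar (possibly `Inf`).
#' @export
replicateSnr <- function(values) {
  if (length(values) < 2L) stop("replicate SNR requires at least 2 replicates")
  s <- stats::sd(values)
  if (s == 0) return(Inf)
  mean(values) / s
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; requires a
#' positive mean. Identical information to the replicate SNR
#' (CV = 100 / SNR).
#'
#' @param values numeric vector, length >= 2.
#' @return percent CV.
#' @export
coefficientOfVariation <- function(values) {
  m <- mean(values)
  if (m <= 0) stop("CV requires a positive mean")
  100 * stats::sd(values) / m
}

#' Quantify one run from its identification results
#'
#' For every target ion of the scheme whose peptide was accepted at least
#' once in this run ([identifyRun()]), extracts the MS1 intensity at the
#' target precursor m/z; ions of non-accepted peptides are excluded
#' (identify-then-quantify order). Per protein the present ion intensities
#' are summed and log10-transformed; a protein with no accepted ion, or
#' whose accepted ions all lack an MS1 peak, is imputed at the
#' peak-intensity threshold.
#'
#' @param run an [MsRun-class].
#' @param matches result of [identifyRun()] on this run.
#' @param scheme an [acquisitionScheme()].
#' @param ppmTol MS1 extraction tolerance (ppm).
#' @param imputeThreshold linear-scale imputation value (default 1000).
#' @param proteins protein ids to report (default: all in the scheme).
#' @return data.frame: `run_id`, `protein_id`, `log10_intensity`.
#' @export
quantifyRun <- function(run, matches, scheme, ppmTol = 10,
                        imputeThreshold = 1000, proteins = NULL) {
  tg <- scheme$targets
  if (is.null(proteins)) proteins <- unique(tg$protein_id)
  accKey <- unique(paste(matches$peptide_id[matches$accepted],
                         matches$charge[matches$accepted]))
  out <- lapply(proteins, function(p) {
    ions <- tg[tg$protein_id == p, , drop = FALSE]
    ions <- ions[paste(ions$peptide_id, ions$charge) %in% accKey, , drop = FALSE]
    val <- if (nrow(ions)) {
      ints <- vapply(ions$precursor_mz, function(mz)
        extractMs1Intensity(run, mz, ppmTol), numeric(1))
      proteinLogIntensity(ints)
    } else NA_real_
    if (is.na(val)) val <- log10(imputeThreshold)
    data.frame(run_id = run@runId, protein_id = p, log10_intensity = val)
  })
  do.call(rbind, out)
}

#' Build the adsorption table from per-run protein intensities
#'
#' Takes the long quantification table (one row per run x protein, with
#' `polymer_id` and `replicate` parsed from or supplied with the run id)
#' and aggregates replicates: geometric mean of the linear intensities and
#' the replicate SNR, with the `passed_filter` verdict at `snrThreshold`
#' (study value 1.5, strict inequality). SNR is computed on the linear
#' scale by default; `snrScale = "log10"` is available as a variant.
#'
#' @param quant data.frame with columns `polymer_id`, `replicate`,
#'   `protein_id`, `log10_intensity`.
#' @param snrThreshold SNR threshold (default 1.5).
#' @param snrScale `"linear"` (default) or `"log10"`.
#' @return an [AdsorptionTable-class].
#' @export
buildAdsorptionTable <- function(quant, snrThreshold = 1.5,
                                 snrScale = c("linear", "log10")) {
  snrScale <- match.arg(snrScale)
  need <- c("polymer_id", "replicate", "protein_id", "log10_intensity")
  stopifnot(all(need %in% names(quant)))
  combos <- unique(quant[, c("polymer_id", "protein_id")])
  maxRep <- max(quant$replicate)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- quant[quant$polymer_id == combos$polymer_id[i] &
                 quant$protein_id == combos$protein_id[i], ]
    sub <- sub[order(sub$replicate), ]
    lg <- rep(NA_real_, maxRep)
    lg[sub$replicate] <- sub$log10_intensity
    lin <- 10^lg
    linOk <- lin[!is.na(lin)]
    snr <- if (length(linOk) >= 2L) {
      v <- if (snrScale == "linear") linOk else log10(linOk)
      replicateSnr(v)
    } else NA_real_
    row <- data.frame(polymer_id = combos$polymer_id[i],
                      protein_id = combos$protein_id[i])
    for (r in seq_len(maxRep)) row[[sprintf("log10_rep%d", r)]] <- lg[r]
    row$geomean <- geometricMean(linOk)
    row$snr <- snr
    row$passed_filter <- !is.na(snr) && snr > snrThreshold
    row
  })
  new("AdsorptionTable", table = do.call(rbind, rows),
      snrThreshold = snrThreshold)
}

#' Apply the SNR reproducibility filter
#'
#' Retains rows with `snr > threshold` (strict) and reports per protein how
#' many polymers were removed.
#'
#' @param table an [AdsorptionTable-class].
#' @param threshold SNR threshold (default: the table's own).
#' @param quiet suppress the per-protein removal message.
#' @return a filtered `AdsorptionTable`.
#' @export
snrFilter <- function(table, threshold = NULL, quiet = FALSE) {
  stopifnot(is(table, "AdsorptionTable"))
  if (is.null(threshold)) threshold <- table@snrThreshold
  t <- table@table
  keep <- !is.na(t$snr) & t$snr > threshold
  if (!quiet) {
    for (p in unique(t$protein_id)) {
      sel <- t$protein_id == p
      message(sprintf("%s: %d of %d polymers retained (SNR > %.2f)",
                      p, sum(keep & sel), sum(sel), threshold))
    }
  }
  out <- t[keep, , drop = FALSE]
  out$passed_filter <- TRUE
  rownames(out) <- NULL
  new("AdsorptionTable", table = out, snrThreshold = threshold)
}

#' Write the adsorption table as CSV
#' @param table an [AdsorptionTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAdsorptionCsv <- function(table, path) {
  utils::write.csv(table@table, path, row.names = FALSE)
  invisible(path)
}
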