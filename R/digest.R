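# In-silico tryptic digestion, disulfide-aware free-peptide determination,
# and monoisotopic mass / m/z arithmetic.

#' Monoisotopic mass table
#'
#' Monoisotopic masses (Da) of the 20 canonical amino-acid residues plus
#' the water and proton constants used by every m/z equation in the
#' package. Average masses appear nowhere in the computation.
#'
#' @return list with elements `residues` (named numeric, 20 entries),
#'   `water` and `proton`.
#' @export
massTable <- function() {
  list(
    residues = c(
      G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
      V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
      I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
      K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
      F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313),
    water = 18.010565,
    proton = 1.007276)
}

.residues <- function(sequence, table = massTable()) {
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), names(table$residues))
  if (length(bad))
    stop(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")))
  res
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water (the termini).
#'
#' @param sequence 1-letter residue string (may be empty: returns the water
#'   mass).
#' @param table a [massTable()].
#' @return mass in Da.
#' @examples
#' monoisotopicMass("GFFYTPK")  # 858.4276
#' @export
monoisotopicMass <- function(sequence, table = massTable()) {
  if (!nzchar(sequence)) return(table$water)
  sum(table$residues[.residues(sequence, table)]) + table$water
}

#' Precursor m/z from neutral mass and charge
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param charge positive integer.
#' @param table a [massTable()].
#' @return (mass + charge * proton) / charge, in Th.
#' @export
precursorMzFromMass <- function(mass, charge, table = massTable()) {
  if (any(charge <= 0)) stop("charge must be >= 1")
  (mass + charge * table$proton) / charge
}

#' Fully tryptic digestion of a protein
#'
#' Cleaves each chain C-terminal to K or R, suppressed when the following
#' residue is proline (the Keil rule for sequencing-grade trypsin), and
#' enumerates every fully tryptic peptide with 0..`maxMissed` internal
#' missed cleavage sites. Chain termini are always peptide boundaries.
#'
#' @param protein a [ProteinEntry-class].
#' @param maxMissed maximum internal missed cleavages (>= 0). The study's
#'   identification search space uses 2.
#' @param table a [massTable()].
#' @return data.frame with one row per peptide: `sequence`, `protein_id`,
#'   `chain`, `start`, `end`, `missed_cleavages`, `monoisotopic_mass`.
#' @examples
#' b <- ProteinEntry("insB", chains = "FVNQHLCGSHLVEALYLVCGERGFFYTPKT")
#' trypticDigest(b, maxMissed = 0)$sequence
#' @export
trypticDigest <- function(protein, maxMissed = 2L, table = massTable()) {
  stopifnot(is(protein, "ProteinEntry"), maxMissed >= 0)
  out <- list()
  for (k in seq_along(protein@chains)) {
    chain <- protein@chains[[k]]
    res <- .residues(chain, table)
    n <- length(res)
    # internal cleavage sites: after K/R not followed by P
    sites <- which(res %in% c("K", "R"))
    sites <- sites[sites < n & res[pmin(sites + 1L, n)] != "P"]
    bounds <- c(0L, sites, n)              # 0-based peptide boundaries
    nb <- length(bounds)
    for (a in seq_len(nb - 1L)) {
      for (m in 0:maxMissed) {
        b <- a + 1L + m
        if (b > nb) break
        start <- bounds[a] + 1L; end <- bounds[b]
        out[[length(out) + 1L]] <- data.frame(
          sequence = substr(chain, start, end),
          protein_id = protein@id, chain = k,
          start = start, end = end, missed_cleavages = m)
      }
    }
  }
  pep <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(), protein_id = character(),
               chain = integer(), start = integer(), end = integer(),
               missed_cleavages = integer())
  pep$monoisotopic_mass <- vapply(pep$sequence, monoisotopicMass,
                                  numeric(1), table = table, USE.NAMES = FALSE)
  rownames(pep) <- NULL
  pep
}

#' Free peptides after disulfide bookkeeping
#'
#' Peptides containing a disulfide-bonded cysteine remain tethered to the
#' rest of the protein after digestion and are not released as free linear
#' species, so they never appear in the spectra. This filter keeps peptides
#' of length >= `minLength` whose span contains no bonded cysteine. For
#' mature insulin under complete digestion this leaves exactly GFFYTPK.
#'
#' @param protein a [ProteinEntry-class] carrying the disulfide table.
#' @param peptides digest table from [trypticDigest()] on the same protein.
#' @param minLength minimum peptide length retained (default 2; single
#'   residues are not informative precursors).
#' @return subset of `peptides`.
#' @export
freePeptides <- function(protein, peptides, minLength = 2L) {
  stopifnot(is(protein, "ProteinEntry"))
  if (!nrow(peptides)) return(peptides)
  if (any(peptides$protein_id != protein@id))
    stop("peptides do not derive from this protein")
  ds <- protein@disulfides
  bonded <- rbind(cbind(ds$chain_a, ds$pos_a), cbind(ds$chain_b, ds$pos_b))
  keep <- vapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    if (nchar(p$sequence) < minLength) return(FALSE)
    if (nrow(bonded) == 0L) return(TRUE)
    !any(bonded[, 1L] == p$chain & bonded[, 2L] >= p$start & bonded[, 2L] <= p$end)
  }, logical(1))
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' b/y fragment ion m/z values
#'
#' All b_i and y_i ions (i = 1..n-1) of a peptide for charges
#' 1..`maxCharge`: b_i is the sum of the first i residues plus one proton
#' per charge; y_i the sum of the last i residues plus water plus protons.
#'
#' @param sequence peptide residue string, length >= 2.
#' @param maxCharge highest fragment charge (default 1).
#' @param table a [massTable()].
#' @return data.frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`.
#' @export
fragmentIons <- function(sequence, maxCharge = 1L, table = massTable()) {
  res <- .residues(sequence, table)
  n <- length(res)
  if (n < 2L) stop("fragment ions require a peptide of length >= 2")
  m <- table$residues[res]
  bsum <- cumsum(m)[-n]                 # neutral b fragment residue sums
  ysum <- cumsum(rev(m))[-n] + table$water
  out <- list()
  for (z in seq_len(maxCharge)) {
    out[[length(out) + 1L]] <- data.frame(
      series = "b", index = seq_len(n - 1L), charge = z,
      mz = (bsum + z * table$proton) / z)
    out[[length(out) + 1L]] <- data.frame(
      series = "y", index = seq_len(n - 1L), charge = z,
      mz = (ysum + z * table$proton) / z)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read protein chains from FASTA with a disulfide sidecar table
#'
#' FASTA ids follow the convention `<protein>|chain<k>`; consecutive chain
#' records of the same protein are collected into one [ProteinEntry-class].
#' The optional sidecar CSV (`protein_id`, `chain_a`, `pos_a`, `chain_b`,
#' `pos_b`, 1-based) supplies disulfide bridges.
#'
#' @param fasta path to a FASTA file.
#' @param disulfideCsv optional path to the sidecar CSV.
#' @return named list of `ProteinEntry`.
#' @export
readProteinFasta <- function(fasta, disulfideCsv = NULL) {
  lines <- readLines(fasta)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records in ", fasta)
  ids <- sub("^>([^ ]+).*$", "\\1", lines[heads])
  names <- sub("^>[^ ]+ ?", "", lines[heads])
  seqs <- vapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    gsub("[ \t]", "", paste(lines[from:to], collapse = ""))
  }, character(1))
  prot <- sub("\\|.*$", "", ids)
  chainIdx <- suppressWarnings(as.integer(sub("^.*\\|chain", "", ids)))
  if (anyNA(chainIdx)) chainIdx[is.na(chainIdx)] <- 1L
  dsAll <- if (!is.null(disulfideCsv))
    utils::read.csv(disulfideCsv, stringsAsFactors = FALSE)
  else NULL
  out <- list()
  for (p in unique(prot)) {
    sel <- prot == p
    ch <- toupper(seqs[sel][order(chainIdx[sel])])
    ds <- if (!is.null(dsAll)) dsAll[dsAll$protein_id == p,
                                     c("chain_a", "pos_a", "chain_b", "pos_b")]
          else NULL
    nm <- names[sel][1L]
    out[[p]] <- ProteinEntry(p, if (nzchar(nm)) nm else p, ch, ds)
  }
  out
}

#' The bundled E8 protein panel
#'
#' Loads the packaged fixture with the four proteins of the Essential 8
#' stem-cell medium (insulin, transferrin, FGF2, TGF-beta-1) and the
#' insulin disulfide topology. The insulin A/B chains are the exact mature
#' human sequences; the transferrin chain is a clearly-labelled synthetic
#' surrogate sequence (see the FASTA header), adequate for digestion and
#' simulation but not the human serotransferrin sequence.
#'
#' @return named list of [ProteinEntry-class].
#' @export
e8Proteins <- function() {
  readProteinFasta(
    system.file("extdata", "e8_proteins.fasta", package = "lesaQuant"),
    system.file("extdata", "e8_disulfides.csv", package = "lesaQuant"))
}
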