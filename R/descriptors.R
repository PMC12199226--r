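# Atom-signature fragment descriptors and constitutional counts computed
# on monomer structures, plus ingestion of external descriptor tables
# (e.g. Dragon descriptors, which are proprietary and never computed here).

#' Parse a molecule into a MolecularGraph
#'
#' SMILES input is delegated to the ChemmineR/ChemmineOB toolkit (which
#' kekulizes aromatic rings); alternatively the package's minimal
#' adjacency format is parsed directly:
#' ```
#' atoms C C C C O
#' bond 1 2 1
#' bond 2 3 1
#' ```
#' with bond order `1`, `2`, `3` or `ar`, and an optional
#' `aromatic 2 3 4` line listing aromatic atom indices.
#'
#' @param text a SMILES string or adjacency-format text (possibly
#'   multi-line).
#' @param format `"auto"` (adjacency if the text starts with `atoms`),
#'   `"smiles"` or `"adjacency"`.
#' @return a [MolecularGraph-class] (hydrogens suppressed).
#' @export
parseMolecule <- function(text, format = c("auto", "smiles", "adjacency")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("^\\s*atoms\\b", text)) "adjacency" else "smiles"
  if (format == "adjacency") return(.parseAdjacency(text))
  text <- trimws(text)
  if (grepl("^[A-IK-Za-ik-z][a-z]?$", text))   # single-atom molecule
    return(MolecularGraph(toupper(substr(text, 1, 1))))
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SMILES parsing requires the 'ChemmineR' package; ",
         "use the adjacency format otherwise")
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(text)),
                  error = function(e)
                    stop("unparsable SMILES '", text, "': ", conditionMessage(e)))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  el <- sub("_.*$", "", rownames(ab))
  if (!all(grepl("^[A-Za-z]+$", el)))
    stop("unparsable SMILES '", text, "'")
  heavy <- which(el != "H")
  remap <- match(seq_along(el), heavy)
  bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    b <- data.frame(i = remap[bb[, 1L]], j = remap[bb[, 2L]],
                    order = as.character(bb[, 3L]))
    b[!is.na(b$i) & !is.na(b$j), , drop = FALSE]
  } else NULL
  MolecularGraph(el[heavy], bonds)
}

.parseAdjacency <- function(text) {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  atomLine <- grep("^atoms\\b", lines, value = TRUE)
  if (length(atomLine) != 1L) stop("adjacency format needs exactly one 'atoms' line")
  elements <- strsplit(sub("^atoms\\s+", "", atomLine), "\\s+")[[1]]
  aromatic <- rep(FALSE, length(elements))
  arLine <- grep("^aromatic\\b", lines, value = TRUE)
  if (length(arLine))
    aromatic[as.integer(strsplit(sub("^aromatic\\s+", "", arLine[1]), "\\s+")[[1]])] <- TRUE
  bondLines <- grep("^bond\\b", lines, value = TRUE)
  bonds <- if (length(bondLines)) {
    parts <- lapply(bondLines, function(l) strsplit(sub("^bond\\s+", "", l), "\\s+")[[1]])
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) stop("malformed bond line: '", bondLines[bad[1]], "'")
    data.frame(i = vapply(parts, function(p) as.integer(p[1]), integer(1)),
               j = vapply(parts, function(p) as.integer(p[2]), integer(1)),
               order = vapply(parts, function(p) p[3], character(1)))
  } else NULL
  MolecularGraph(elements, bonds, aromatic)
}

.writeAdjacency <- function(graph) {
  a <- graph@atoms; b <- graph@bonds
  out <- paste("atoms", paste(a$element, collapse = " "))
  if (any(a$aromatic))
    out <- c(out, paste("aromatic", paste(which(a$aromatic), collapse = " ")))
  if (nrow(b))
    out <- c(out, sprintf("bond %d %d %s", b$i, b$j, b$order))
  paste(out, collapse = "\n")
}

.neighbors <- function(graph, atom) {
  b <- graph@bonds
  c(b$j[b$i == atom], b$i[b$j == atom])
}

.atomLabel <- function(graph, atom, aromaticLower) {
  el <- graph@atoms$element[atom]
  if (aromaticLower && graph@atoms$aromatic[atom]) tolower(el) else el
}

#' Canonical atom signature
#'
#' Atom-centered substructure string in the printed descriptor notation:
#' the root element followed by its parenthesized neighbor subtrees, sorted
#' lexicographically at every level. At height 1 the neighbors appear as
#' bare element symbols (tert-butanol's central carbon gives `C(CCCO)`);
#' at height 2 each neighbor that itself has further neighbors (excluding
#' the edge back to the root) is expanded one level, e.g.
#' `C(C(CFF)C(FFF)FF)` for the backbone carbon of a perfluorinated side
#' chain. Bond orders are not encoded; aromatic atoms are optionally
#' lowercased.
#'
#' @param graph a [MolecularGraph-class].
#' @param atom 1-based atom index.
#' @param height 1 or 2.
#' @param aromaticLower lowercase aromatic atoms (default FALSE).
#' @return signature string.
#' @export
atomSignature <- function(graph, atom, height = 1L, aromaticLower = FALSE) {
  stopifnot(height %in% c(1L, 2L),
            atom >= 1L, atom <= nrow(graph@atoms))
  root <- .atomLabel(graph, atom, aromaticLower)
  nb <- .neighbors(graph, atom)
  sub <- vapply(nb, function(n) {
    lab <- .atomLabel(graph, n, aromaticLower)
    if (height == 1L) return(lab)
    nn <- setdiff(.neighbors(graph, n), atom)
    if (!length(nn)) return(lab)
    inner <- sort(vapply(nn, .atomLabel, character(1),
                         graph = graph, aromaticLower = aromaticLower),
                  method = "radix")
    paste0(lab, "(", paste(inner, collapse = ""), ")")
  }, character(1))
  paste0(root, "(", paste(sort(sub, method = "radix"), collapse = ""), ")")
}

#' Count atom signatures in a molecule
#'
#' Maps each signature string to the number of atoms bearing it; the
#' counts over any molecule sum to its heavy-atom count.
#'
#' @param graph a [MolecularGraph-class].
#' @param height 1 or 2.
#' @param aromaticLower lowercase aromatic atoms.
#' @return named integer vector.
#' @export
countSignatures <- function(graph, height = 1L, aromaticLower = FALSE) {
  sig <- vapply(seq_len(nrow(graph@atoms)), atomSignature, character(1),
                graph = graph, height = height, aromaticLower = aromaticLower)
  tab <- table(sig)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Count aliphatic tertiary amines
#'
#' Structural proxy for the Dragon constitutional descriptor nRNR2:
#' non-aromatic nitrogens bonded to exactly three carbons by single bonds
#' (and nothing else), excluding nitrogens adjacent to a carbonyl carbon
#' (amides). Used only in synthetic studies, under the name
#' `nRNR2_proxy`; the Dragon descriptor itself is never computed.
#'
#' @param graph a [MolecularGraph-class].
#' @return integer count.
#' @export
countTertiaryAmines <- function(graph) {
  a <- graph@atoms; b <- graph@bonds
  isCarbonyl <- function(cAtom) {
    rows <- which((b$i == cAtom | b$j == cAtom) & b$order == "2")
    any(vapply(rows, function(r) {
      other <- if (b$i[r] == cAtom) b$j[r] else b$i[r]
      a$element[other] == "O"
    }, logical(1)))
  }
  count <- 0L
  for (n in which(a$element == "N" & !a$aromatic)) {
    rows <- which(b$i == n | b$j == n)
    if (length(rows) != 3L) next
    if (!all(b$order[rows] == "1")) next
    nb <- vapply(rows, function(r) if (b$i[r] == n) b$j[r] else b$i[r], integer(1))
    if (!all(a$element[nb] == "C")) next
    if (any(vapply(nb, isCarbonyl, logical(1)))) next
    count <- count + 1L
  }
  count
}

#' Compute a signature DescriptorMatrix for a monomer library
#'
#' Counts signatures at the requested heights for every molecule; the
#' descriptor columns are the union of signatures over the library, with
#' absent signatures stored as 0.
#'
#' @param molecules named list of [MolecularGraph-class] (names = polymer
#'   ids).
#' @param heights integer vector from {1, 2} (default both).
#' @param aromaticLower lowercase aromatic atoms in signatures.
#' @return a [DescriptorMatrix-class] with `source = "computed"`.
#' @export
computeSignatureDescriptors <- function(molecules, heights = c(1L, 2L),
                                        aromaticLower = FALSE) {
  stopifnot(length(molecules) > 0, !is.null(names(molecules)))
  counts <- lapply(molecules, function(g) {
    v <- integer()
    for (h in heights) v <- c(v, countSignatures(g, h, aromaticLower))
    # a signature can coincide across heights only for terminal atoms;
    # collapse duplicates by summing is wrong, so keep the max (identical)
    tapply(v, names(v), max)
  })
  cols <- sort(unique(unlist(lapply(counts, names))), method = "radix")
  m <- matrix(0, nrow = length(molecules), ncol = length(cols),
              dimnames = list(names(molecules), cols))
  for (i in seq_along(counts)) m[i, names(counts[[i]])] <- counts[[i]]
  DescriptorMatrix(m, source = "computed")
}

#' Load an external descriptor table
#'
#' CSV with a `polymer_id` column and numeric descriptor columns (the
#' ingestion route for Dragon descriptors). Non-numeric cells are an
#' error naming the row and column; constant columns are flagged.
#'
#' @param path CSV file.
#' @return a [DescriptorMatrix-class] with `source = "imported"`.
#' @export
loadDescriptorTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"polymer_id" %in% names(df))
    stop("descriptor table needs a 'polymer_id' column")
  ids <- as.character(df$polymer_id)
  df$polymer_id <- NULL
  for (cn in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'", bad[1L], cn))
    if (anyNA(v))
      stop(sprintf("missing cell in column '%s'", cn))
    df[[cn]] <- v
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  dm <- DescriptorMatrix(m, source = "imported")
  if (length(dm@constantColumns))
    message("constant descriptor column(s): ",
            paste(dm@constantColumns, collapse = ", "))
  dm
}

#' Merge two descriptor matrices column-wise
#'
#' Requires identical polymer sets (rows are aligned by id) and disjoint
#' descriptor names; name collisions are an error.
#'
#' @param a,b [DescriptorMatrix-class] objects.
#' @return a merged `DescriptorMatrix` (source `"computed"` only if both
#'   inputs were computed).
#' @export
mergeDescriptors <- function(a, b) {
  stopifnot(is(a, "DescriptorMatrix"), is(b, "DescriptorMatrix"))
  if (!setequal(rownames(a@values), rownames(b@values)))
    stop("descriptor matrices cover different polymer sets")
  clash <- intersect(colnames(a@values), colnames(b@values))
  if (length(clash))
    stop("descriptor name collision: ", paste(clash, collapse = ", "))
  vb <- b@values[rownames(a@values), , drop = FALSE]
  src <- if (a@source == "computed" && b@source == "computed") "computed" else "imported"
  DescriptorMatrix(cbind(a@values, vb), source = src)
}

#' Write a DescriptorMatrix as CSV
#' @param x a [DescriptorMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDescriptorCsv <- function(x, path) {
  df <- data.frame(polymer_id = rownames(x@values), x@values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
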