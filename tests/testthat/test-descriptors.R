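# hand-built perfluorinated fragment: root C bonded to CF2(C), CF3 and two F
perfluoroGraph <- function() {
  MolecularGraph(
    elements = c("C", "C", "C", "F", "F", "C", "F", "F", "F", "F", "F"),
    bonds = data.frame(i = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3),
                       j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11),
                       order = "1"))
}

test_that("SMILES parsing yields the expected heavy-atom graphs", {
  skip_if_not_installed("ChemmineR")
  methane <- parseMolecule("C")
  expect_equal(nrow(methane@atoms), 1L)
  expect_equal(nrow(methane@bonds), 0L)
  tb <- parseMolecule("CC(C)(C)O")
  expect_equal(nrow(tb@atoms), 5L)
  expect_equal(nrow(tb@bonds), 4L)
  expect_setequal(tb@atoms$element, c("C", "O"))
  expect_error(parseMolecule("not-a-smiles(("), "unparsable")
})

test_that("adjacency format round-trips and validates", {
  txt <- "atoms C C O\nbond 1 2 1\nbond 2 3 1"
  g <- parseMolecule(txt)
  expect_equal(g@atoms$element, c("C", "C", "O"))
  expect_equal(nrow(g@bonds), 2L)
  g2 <- parseMolecule(lesaQuant:::.writeAdjacency(g))
  expect_identical(g2@atoms, g@atoms)
  expect_identical(g2@bonds$i, g@bonds$i)
  expect_error(parseMolecule("atoms C C\nbond 1 2"), "malformed bond")
  expect_error(MolecularGraph(c("C", "C"),
                              data.frame(i = 1, j = 3, order = "1")),
               "out of bounds")
  expect_error(MolecularGraph(c("C", "C", "C"),
                              data.frame(i = 1, j = 2, order = "1")),
               "connected")
})

test_that("atom signatures reproduce the printed descriptor strings", {
  tb <- parseMolecule("atoms C C C C O\nbond 2 1 1\nbond 2 3 1\nbond 2 4 1\nbond 2 5 1")
  expect_identical(atomSignature(tb, 2, height = 1), "C(CCCO)")
  expect_identical(atomSignature(MolecularGraph("C"), 1, height = 1), "C()")
  pf <- perfluoroGraph()
  expect_identical(atomSignature(pf, 1, height = 2), "C(C(CFF)C(FFF)FF)")
  # ethylene-glycol-like unit: C with neighbors C(O) and O(C)
  eg <- parseMolecule("atoms C C O O C\nbond 1 2 1\nbond 2 3 1\nbond 1 4 1\nbond 4 5 1")
  expect_identical(atomSignature(eg, 1, height = 2), "C(C(O)O(C))")
})

test_that("signature counts partition the heavy atoms", {
  ethane <- parseMolecule("atoms C C\nbond 1 2 1")
  expect_identical(countSignatures(ethane, 1), c("C(C)" = 2L))
  skip_if_not_installed("ChemmineR")
  benzene <- parseMolecule("c1ccccc1")
  cs <- countSignatures(benzene, 2)
  expect_length(cs, 1L)       # all six carbons share one signature class
  expect_identical(unname(cs), 6L)
  for (smi in c("CC(C)(C)O", "CCN(CC)CC", "CC(=O)OC")) {
    g <- parseMolecule(smi)
    for (h in 1:2)
      expect_identical(sum(countSignatures(g, h)), nrow(g@atoms))
  }
})

test_that("signatures are invariant under atom-index permutation", {
  set.seed(3)
  for (k in 1:20) {
    n <- sample(4:9, 1)
    # random connected graph: a spanning chain plus extra random edges
    bonds <- data.frame(i = 1:(n - 1), j = 2:n, order = "1")
    extra <- sample(n, 2)
    if (extra[1] != extra[2] &&
        !any(pmin(bonds$i, bonds$j) == min(extra) &
             pmax(bonds$i, bonds$j) == max(extra)))
      bonds <- rbind(bonds, data.frame(i = extra[1], j = extra[2], order = "1"))
    els <- sample(c("C", "N", "O", "F"), n, replace = TRUE)
    g <- MolecularGraph(els, bonds)
    perm <- sample(n)
    inv <- order(perm)
    gp <- MolecularGraph(els[perm],
                         data.frame(i = inv[bonds$i], j = inv[bonds$j],
                                    order = "1"))
    for (h in 1:2)
      expect_identical(sort(names(countSignatures(g, h))),
                       sort(names(countSignatures(gp, h))))
  }
})

test_that("different height-1 signatures never share a height-2 signature", {
  set.seed(11)
  for (k in 1:15) {
    n <- sample(4:9, 1)
    bonds <- data.frame(i = 1:(n - 1), j = 2:n, order = "1")
    g <- MolecularGraph(sample(c("C", "N", "O"), n, replace = TRUE), bonds)
    h1 <- vapply(1:n, atomSignature, character(1), graph = g, height = 1)
    h2 <- vapply(1:n, atomSignature, character(1), graph = g, height = 2)
    for (sig2 in unique(h2))
      expect_length(unique(h1[h2 == sig2]), 1L)
  }
})

test_that("aliphatic tertiary amine counting excludes amides and aromatics", {
  skip_if_not_installed("ChemmineR")
  expect_identical(countTertiaryAmines(parseMolecule("CCN(CC)CC")), 1L)
  expect_identical(countTertiaryAmines(parseMolecule("Nc1ccccc1")), 0L)
  expect_identical(countTertiaryAmines(parseMolecule("CC(=O)N(C)C")), 0L)
  # DMAEA-like monomer: acrylate ester with a dimethylaminoethyl tail
  expect_identical(countTertiaryAmines(parseMolecule("C=CC(=O)OCCN(C)C")), 1L)
})

test_that("descriptor tables load, flag constants and merge safely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("polymer_id,D1,D2", "P1,1,5", "P2,2,5", "P3,3,5"), f)
  expect_message(dm <- loadDescriptorTable(f), "constant")
  expect_equal(dim(dm), c(3L, 2L))
  expect_identical(constantColumns(dm), "D2")
  expect_equal(descriptorValues(dm)["P2", "D1"], 2)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("polymer_id,D1", "P1,1", "P2,oops"), bad)
  expect_error(loadDescriptorTable(bad), "row 2, column 'D1'")

  g1 <- parseMolecule("atoms C C\nbond 1 2 1")
  g2 <- parseMolecule("atoms C O\nbond 1 2 1")
  comp <- computeSignatureDescriptors(list(P1 = g1, P2 = g2, P3 = g1),
                                      heights = 1L)
  expect_equal(rownames(descriptorValues(comp)), c("P1", "P2", "P3"))
  expect_true(all(!is.na(descriptorValues(comp))))
  # merge with imported table; collision rejected
  merged <- mergeDescriptors(comp, dm)
  expect_equal(ncol(descriptorValues(merged)),
               ncol(descriptorValues(comp)) + 2L)
  expect_error(mergeDescriptors(comp, comp), "collision")
})
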