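# Triple mapping, Turtle round trips, and the canonical queries.

# Triple count derived by hand from the documented mapping table:
# 4 + n_species + n_fragments + arity + 18 P
# + per species (3 + [smiles] + 4 N) + per fitting (4 + 4 p)
expectedTripleCount <- function(P, arity, speciesAtoms, smiles, fittingParams,
                                nFragments = 0) {
  4 + length(speciesAtoms) + nFragments + arity + 18 * P +
    sum(3 + smiles + 4 * speciesAtoms) +
    sum(ifelse(length(fittingParams), 4 + 4 * fittingParams, 0))
}

test_that("triple count follows the documented mapping table", {
  scan <- makeDiatomicScan(c(1.4, 1.6), c(-1.0, -1.1))
  g <- toGraph(scan)
  expect_identical(nrow(graphTriples(g)),
                   as.integer(expectedTripleCount(
                     P = 2, arity = 2, speciesAtoms = 2, smiles = 0,
                     fittingParams = integer(0))))

  eth <- makeEthanolLikeScan()   # 12 points, 9 atoms, SMILES present
  expect_identical(nrow(graphTriples(toGraph(eth))),
                   as.integer(expectedTripleCount(
                     P = 12, arity = 2, speciesAtoms = 9, smiles = 1,
                     fittingParams = integer(0))))
})

test_that("a Morse fitting record contributes exactly its documented triples", {
  scan <- makeDiatomicScan(c(1.4, 1.6), c(-1.0, -1.1))
  rec <- FittingRecord(
    methodName = "MorsePotential", methodSource = "ref",
    parameters = data.frame(name = c("De", "re", "a"),
                            value = c(350, 1.53, 1.9),
                            unit = c("kJ/mol", "angstrom", "1/angstrom")))
  scan@fittings <- list(rec)
  g <- toGraph(scan)
  df <- graphTriples(g)
  vocab <- defaultVocabulary()
  expect_identical(sum(df$p == vocab@terms[["hasFittingMethod"]]), 1L)
  expect_identical(sum(df$p == vocab@terms[["hasFittingMethodSource"]]), 1L)
  paramNodes <- df$o[df$p == vocab@terms[["hasFittingParameters"]]]
  expect_length(paramNodes, 3)
  valueTriples <- df[df$p == vocab@terms[["hasValue"]] &
                       df$s %in% paramNodes, ]
  expect_identical(nrow(valueTriples), 3L)

  # empty fittings list -> zero fitting triples
  g0 <- toGraph(makeDiatomicScan(c(1.4, 1.6), c(-1.0, -1.1)))
  expect_identical(sum(graphTriples(g0)$p ==
                         vocab@terms[["hasFittingMethod"]]), 0L)
})

test_that("fromGraph inverts toGraph field for field", {
  for (scan in list(makeDiatomicScan(c(1.4, 1.5, 1.6), c(-1, -1.2, -1.1)),
                    makeEthanolLikeScan())) {
    g <- toGraph(scan)
    back <- fromGraph(g, iri(scan))
    expect_scan_identical(back, scan)
  }
})

test_that("incomplete or ambiguous graphs are rejected with their cause", {
  scan <- makeDiatomicScan(c(1.4, 1.6), c(-1.0, -1.1))
  g <- toGraph(scan)
  vocab <- defaultVocabulary()
  df <- graphTriples(g)

  noCoord <- new("TripleGraph",
                 triples = df[df$p != vocab@terms[["hasScanCoordinate"]], ])
  expect_error(fromGraph(noCoord, iri(scan)),
               class = "evbscan_incomplete_error")

  extra <- df[df$p == vocab@terms[["hasScanCoordinate"]], ][1, ]
  extra$o <- paste0(extra$o, "2")
  twoCoord <- new("TripleGraph", triples = rbind(df, extra))
  expect_error(fromGraph(twoCoord, iri(scan)),
               class = "evbscan_ambiguous_error")

  expect_error(fromGraph(emptyGraph(), iri(scan)),
               class = "evbscan_incomplete_error")
})

test_that("Turtle write/read round trip preserves graph isomorphism", {
  eth <- makeEthanolLikeScan()
  eth@fittings <- list(FittingRecord(
    methodName = "EVB-2state-constant", methodSource = "ref",
    parameters = data.frame(name = c("A", "s1", "s2"),
                            value = c(25, 0.1, -0.2),
                            unit = rep("kJ/mol", 3))))
  g <- toGraph(eth)
  path <- withr::local_tempfile(fileext = ".ttl")
  writeTurtle(g, path)
  g2 <- readTurtle(path)
  expect_true(graphsIsomorphic(g, g2))
  # and the rebuilt scan still matches
  expect_scan_identical(fromGraph(g2, iri(eth)), eth)
})

test_that("InChI lookup returns exactly the asserted scans, sorted", {
  eth <- makeEthanolLikeScan()
  g <- toGraph(eth)
  hit <- findScansByInChI(g, eth@species[[1]]@inchi)
  expect_identical(hit, iri(eth))
  expect_identical(findScansByInChI(g, "InChI=1S/CO2/c2-1-3"), character(0))

  # two scans on the same species
  other <- makeDiatomicScan(c(1.3, 1.5), c(-1, -1.1))
  other@iri <- paste0(KB, "scan/zz_other")
  other@species <- eth@species
  other@coordinate <- ScanCoordinate("distance",
                                     eth@species[[1]]@atoms$iri[1:2])
  g2 <- graphUnion(g, toGraph(other))
  both <- findScansByInChI(g2, eth@species[[1]]@inchi)
  expect_identical(both, sort(c(iri(eth), iri(other))))
})

test_that("InChI lookup agrees with a brute-force scan over many models", {
  set.seed(31)
  inchis <- paste0("InChI=1S/TEST", 1:4)
  scans <- list()
  for (k in 1:5) {
    spIdx <- sample(4, 1)
    s <- makeDiatomicScan(sort(runif(2, 1, 3)), c(-1, -1.1),
                          label = paste0("s", k),
                          inchi = inchis[spIdx])
    scans[[k]] <- list(scan = s, inchi = inchis[spIdx])
  }
  g <- Reduce(graphUnion, lapply(scans, function(x) toGraph(x$scan)))
  for (inchi in inchis) {
    expected <- sort(vapply(
      Filter(function(x) x$inchi == inchi, scans),
      function(x) iri(x$scan), character(1)))
    expect_identical(findScansByInChI(g, inchi), expected)
  }
})

test_that("point energies retrieve stored literals in ascending order", {
  eth <- makeEthanolLikeScan()
  g <- toGraph(eth)
  pe <- pointEnergies(g, iri(eth))
  expect_identical(nrow(pe), 12L)
  expect_equal(pe$value, coordinateValues(eth))
  expect_identical(pe$scfText,
                   vapply(scanPoints(eth),
                          function(p) p@calculation@scfText, character(1)))

  two <- makeDiatomicScan(c(1.51, 1.71), c(-1.0, -1.1))
  pe2 <- pointEnergies(toGraph(two), iri(two))
  expect_equal(pe2$value[1], 1.51)
  expect_identical(pe2$unit[1], "angstrom")

  expect_error(pointEnergies(emptyGraph(), iri(eth)),
               class = "evbscan_incomplete_error")
})

test_that("attachFitting is idempotent and checks scan existence", {
  scan <- makeDiatomicScan(c(1.4, 1.6), c(-1.0, -1.1))
  g <- toGraph(scan)
  rec <- FittingRecord(
    methodName = "EVB-2state-constant", methodSource = "ref",
    parameters = data.frame(name = c("A", "s1", "s2"),
                            value = c(25, 0, 0), unit = rep("kJ/mol", 3)))
  g1 <- attachFitting(g, iri(scan), rec)
  expect_identical(nrow(graphTriples(g1)) - nrow(graphTriples(g)),
                   as.integer(4 + 4 * 3))
  paramValueTriples <- graphTriples(g1)
  g2 <- attachFitting(g1, iri(scan), rec)
  expect_true(graphsIsomorphic(g1, g2))
  expect_error(attachFitting(g, "https://example.org/kb/scan/none", rec),
               class = "evbscan_not_found_error")
})

test_that("SPARQL templates agree with the direct query implementations", {
  eth <- makeEthanolLikeScan()
  g <- toGraph(eth)
  byInchi <- sparqlSelect(g, queryScansByInChI(eth@species[[1]]@inchi))
  expect_identical(byInchi$scan, findScansByInChI(g, eth@species[[1]]@inchi))

  tab <- sparqlSelect(g, queryPointEnergies(iri(eth)))
  pe <- pointEnergies(g, iri(eth))
  expect_identical(nrow(tab), nrow(pe))
  expect_setequal(as.numeric(tab$value), pe$value)
  expect_setequal(tab$energy, pe$scfText)

  expect_error(sparqlSelect(g, "SELECT ?x WHERE { FILTER(?x > 1) }"),
               class = "evbscan_sparql_error")
})

test_that("emitted Turtle is valid for an independent RDF parser", {
  # rdflib (Python) as the external oracle: it must parse the file and
  # agree on the triple count
  g <- toGraph(makeEthanolLikeScan())
  path <- withr::local_tempfile(fileext = ".ttl")
  writeTurtle(g, path)
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import rdflib; gg = rdflib.Graph(); ",
      "gg.parse('", path, "', format='turtle'); print(len(gg))"))),
    stdout = TRUE, stderr = TRUE))
  expect_identical(utils::tail(out, 1), as.character(nrow(graphTriples(g))))
})
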