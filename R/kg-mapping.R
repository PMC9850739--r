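## Scan <-> triple mapping.
##
## Mapping table (one row per emitted triple; P = number of points,
## k = coordinate arity, N_s = atoms of species s, p_f = parameters of
## fitting f):
##
##   scan    rdf:type ps:PotentialEnergySurfaceScan            1
##   scan    ps:onSpecies <species>                            per species
##   scan    ps:hasFragment <fragment>                         per fragment
##   scan    ps:hasScanCoordinate <coord>                      1
##   coord   rdf:type ps:{Distance,Angle,DihedralAngle}Coordinate  1
##   coord   ps:hasScanAtom <atom>                             k
##   coord   ps:hasScanAtomOrder "iri,iri,..."                 1
##   point   (per point, 9 triples)
##     scan  ps:hasScanPoint <point>
##     point rdf:type ps:ScanPoint
##     point ps:hasScanCoordinateValue <value>
##     value rdf:type ps:ScanCoordinateValue
##     value gc:hasValue "<v>"^^xsd:double
##     value gc:hasUnitOfMeasure qu:{Angstrom,Degree}
##     point ps:hasInputAtomIDs "i,j,..."
##     point ps:hasProvenance "<tag>"
##     point ps:hasCalculation <calc>
##   calc    (per point, 9 triples)
##     rdf:type oc:GaussianCalculation; oc:hasSCFEnergy (lexical = the
##     energy exactly as printed); oc:hasGeometryXYZ; oc:hasProgram;
##     oc:hasMethod; oc:hasBasisSet; oc:hasCharge; oc:hasSpinMultiplicity;
##     oc:hasJobKind
##   species (per species/fragment: 3 + [has SMILES] + 4 * N_s)
##     rdf:type os:Species; os:hasInChI; rdfs:label; [os:hasSMILES];
##     per atom: os:hasAtom; atom os:hasElement; os:hasAtomIndex;
##     os:hasPosition "x y z"
##   fitting (per record: 4 + 4 * p_f)
##     scan ps:hasFitting <fit>; fit rdf:type ps:FittingRecord;
##     fit ps:hasFittingMethod; ps:hasFittingMethodSource;
##     per parameter: fit ps:hasFittingParameters <par>;
##     par ps:parameterName; gc:hasValue; ps:parameterUnit
##
## Total: 4 + n_species + n_fragments + k + 18 P
##        + sum_s (3 + [smiles_s] + 4 N_s) + sum_f (4 + 4 p_f)

xsdDouble <- function() paste0(XSD, "double")
xsdInteger <- function() paste0(XSD, "integer")

triB <- function() {
  rows <- list()
  list(
    iri = function(s, p, o) rows[[length(rows) + 1L]] <<-
        data.frame(s = s, p = p, o = o, lit = FALSE, dt = NA_character_,
                   stringsAsFactors = FALSE),
    lit = function(s, p, o, dt = NA_character_) rows[[length(rows) + 1L]] <<-
        data.frame(s = s, p = p, o = o, lit = TRUE, dt = dt,
                   stringsAsFactors = FALSE),
    graph = function() new("TripleGraph",
                           triples = unique(do.call(rbind, rows)))
  )
}

geometryToText <- function(geom)
  paste(sprintf("%s %s %s %s", geom$element, formatShortest(geom$x),
                formatShortest(geom$y), formatShortest(geom$z)),
        collapse = "\n")

geometryFromText <- function(txt) {
  rows <- strsplit(strsplit(txt, "\n", fixed = TRUE)[[1]], " ", fixed = TRUE)
  do.call(rbind, lapply(rows, function(f)
    data.frame(element = f[1], x = as.numeric(f[2]), y = as.numeric(f[3]),
               z = as.numeric(f[4]), stringsAsFactors = FALSE)))
}

speciesTriples <- function(b, sp, vocab) {
  t <- function(x) termIri(vocab, x)
  b$iri(sp@iri, RDF_TYPE, t("Species"))
  b$lit(sp@iri, t("hasInChI"), sp@inchi)
  b$lit(sp@iri, t("label"), sp@label)
  if (!is.na(sp@smiles)) b$lit(sp@iri, t("hasSMILES"), sp@smiles)
  for (k in seq_len(nrow(sp@atoms))) {
    a <- sp@atoms[k, ]
    b$iri(sp@iri, t("hasAtom"), a$iri)
    b$lit(a$iri, t("hasElement"), a$element)
    b$lit(a$iri, t("hasAtomIndex"), as.character(a$index), xsdInteger())
    b$lit(a$iri, t("hasPosition"),
          paste(formatShortest(c(a$x, a$y, a$z)), collapse = " "))
  }
}

fittingTriples <- function(b, scanIri, rec, vocab) {
  t <- function(x) termIri(vocab, x)
  key <- paste(rec@methodName, rec@methodSource,
               paste(rec@parameters$name, formatShortest(rec@parameters$value),
                     rec@parameters$unit, collapse = ";"), sep = "|")
  fitIri <- paste0(scanIri, "/fitting/", sanitizeId(rec@methodName), "-",
                   fnv1a32(key))
  b$iri(scanIri, t("hasFitting"), fitIri)
  b$iri(fitIri, RDF_TYPE, t("FittingRecord"))
  b$lit(fitIri, t("hasFittingMethod"), rec@methodName)
  b$lit(fitIri, t("hasFittingMethodSource"), rec@methodSource)
  for (k in seq_len(nrow(rec@parameters))) {
    p <- rec@parameters[k, ]
    parIri <- paste0(fitIri, "/param/", sanitizeId(p$name))
    b$iri(fitIri, t("hasFittingParameters"), parIri)
    b$lit(parIri, t("parameterName"), p$name)
    b$lit(parIri, t("hasValue"), formatShortest(p$value), xsdDouble())
    b$lit(parIri, t("parameterUnit"), p$unit)
  }
  fitIri
}

#' @describeIn toGraph map a [PESScan] (which must pass [validateScan()]
#'   structurally) to its triple graph. The triple count is the affine
#'   function of (points, atoms, fittings) documented in the mapping
#'   table in the source; IRIs for coordinate, point, and value nodes are
#'   minted deterministically under the scan IRI.
#' @export
setMethod("toGraph", "PESScan", function(x, vocab = defaultVocabulary()) {
  t <- function(nm) termIri(vocab, nm)
  b <- triB()
  scanIri <- x@iri
  b$iri(scanIri, RDF_TYPE, t("PotentialEnergySurfaceScan"))
  for (sp in x@species) b$iri(scanIri, t("onSpecies"), sp@iri)
  for (fr in x@fragments) b$iri(scanIri, t("hasFragment"), fr@iri)

  coordIri <- paste0(scanIri, "/coordinate")
  b$iri(scanIri, t("hasScanCoordinate"), coordIri)
  b$iri(coordIri, RDF_TYPE, t(coordClassTerm(x@coordinate@kind)))
  for (a in x@coordinate@scanAtoms) b$iri(coordIri, t("hasScanAtom"), a)
  b$lit(coordIri, t("hasScanAtomOrder"),
        paste(x@coordinate@scanAtoms, collapse = ","))

  unitIri <- t(unitTermForLabel(x@coordinate@unit))
  for (p in x@points) {
    ptIri <- paste0(scanIri, "/point/", p@orderIndex)
    valIri <- paste0(ptIri, "/value")
    b$iri(scanIri, t("hasScanPoint"), ptIri)
    b$iri(ptIri, RDF_TYPE, t("ScanPoint"))
    b$iri(ptIri, t("hasScanCoordinateValue"), valIri)
    b$iri(valIri, RDF_TYPE, t("ScanCoordinateValue"))
    b$lit(valIri, t("hasValue"), formatShortest(p@value), xsdDouble())
    b$iri(valIri, t("hasUnit"), unitIri)
    b$lit(ptIri, t("hasInputAtomIDs"), paste(p@inputAtomIds, collapse = ","))
    b$lit(ptIri, t("hasProvenance"), p@provenance)
    calc <- p@calculation
    b$iri(ptIri, t("hasCalculation"), calc@iri)
    b$iri(calc@iri, RDF_TYPE, t("GaussianCalculation"))
    b$lit(calc@iri, t("hasSCFEnergy"), calc@scfText, xsdDouble())
    b$lit(calc@iri, t("hasGeometry"), geometryToText(calc@geometry))
    b$lit(calc@iri, t("hasProgram"), calc@program)
    b$lit(calc@iri, t("hasMethod"), calc@method)
    b$lit(calc@iri, t("hasBasisSet"), calc@basisSet)
    b$lit(calc@iri, t("hasCharge"), formatShortest(calc@charge), xsdDouble())
    b$lit(calc@iri, t("hasSpinMultiplicity"),
          as.character(as.integer(calc@spinMultiplicity)), xsdInteger())
    b$lit(calc@iri, t("hasJobKind"), calc@jobKind)
  }

  seen <- character(0)
  for (sp in c(x@species, x@fragments)) {
    if (sp@iri %in% seen) next
    seen <- c(seen, sp@iri)
    speciesTriples(b, sp, vocab)
  }
  for (f in x@fittings) fittingTriples(b, scanIri, f, vocab)
  b$graph()
})

litOf <- function(g, s, p, what, optional = FALSE) {
  df <- g@triples
  v <- df$o[df$s == s & df$p == p & df$lit]
  if (!length(v) && optional) return(NA_character_)
  one(v, what, s)
}

speciesFromGraph <- function(g, spIri, vocab) {
  t <- function(x) termIri(vocab, x)
  atomIris <- objectsOf(g, spIri, t("hasAtom"))
  if (!length(atomIris))
    pesStop("incomplete", "species <", spIri, "> has no atoms in graph")
  atoms <- do.call(rbind, lapply(atomIris, function(ai) {
    pos <- as.numeric(strsplit(litOf(g, ai, t("hasPosition"), "position"),
                               " ", fixed = TRUE)[[1]])
    data.frame(iri = ai,
               element = litOf(g, ai, t("hasElement"), "element"),
               index = as.integer(litOf(g, ai, t("hasAtomIndex"), "index")),
               x = pos[1], y = pos[2], z = pos[3],
               stringsAsFactors = FALSE)
  }))
  atoms <- atoms[order(atoms$index), , drop = FALSE]
  rownames(atoms) <- NULL
  SpeciesRef(iri = spIri,
             inchi = litOf(g, spIri, t("hasInChI"), "InChI"),
             label = litOf(g, spIri, t("label"), "label"),
             smiles = litOf(g, spIri, t("hasSMILES"), "SMILES",
                            optional = TRUE),
             atoms = atoms)
}

fittingFromGraph <- function(g, fitIri, vocab) {
  t <- function(x) termIri(vocab, x)
  parIris <- sort(objectsOf(g, fitIri, t("hasFittingParameters")))
  params <- do.call(rbind, lapply(parIris, function(pi)
    data.frame(name = litOf(g, pi, t("parameterName"), "parameter name"),
               value = as.numeric(litOf(g, pi, t("hasValue"),
                                        "parameter value")),
               unit = litOf(g, pi, t("parameterUnit"), "parameter unit"),
               stringsAsFactors = FALSE)))
  if (is.null(params))
    params <- data.frame(name = character(0), value = numeric(0),
                         unit = character(0))
  FittingRecord(
    methodName = litOf(g, fitIri, t("hasFittingMethod"), "fitting method"),
    methodSource = litOf(g, fitIri, t("hasFittingMethodSource"),
                         "fitting method source"),
    parameters = params)
}

#' Rebuild a PES scan from its triple graph
#'
#' Inverse of [toGraph()]: `fromGraph(toGraph(s), iri(s))` reproduces `s`
#' field for field (SCF energies compared as the exact printed decimals;
#' fitting parameters in canonical name order). Missing mandatory triples
#' raise an incompleteness error; a scan linked to more than one
#' coordinate node raises an ambiguity error (scans are one-dimensional).
#'
#' @param g a [TripleGraph]
#' @param scanIri IRI of the scan to extract
#' @param vocab a [VocabularyMap]
#' @return a [PESScan]
#' @export
fromGraph <- function(g, scanIri, vocab = defaultVocabulary()) {
  t <- function(x) termIri(vocab, x)
  if (!scanIri %in% subjectsWith(g, RDF_TYPE, t("PotentialEnergySurfaceScan")))
    pesStop("incomplete", "no PotentialEnergySurfaceScan <", scanIri,
            "> in graph")

  coordIri <- one(objectsOf(g, scanIri, t("hasScanCoordinate")),
                  "scan coordinate", scanIri)
  coordTypes <- objectsOf(g, coordIri, RDF_TYPE)
  kind <- c(distance = t("DistanceCoordinate"), angle = t("AngleCoordinate"),
            dihedral = t("DihedralAngleCoordinate"))
  kindName <- names(kind)[match(coordTypes, kind)]
  kindName <- kindName[!is.na(kindName)]
  if (!length(kindName))
    pesStop("incomplete", "coordinate node <", coordIri, "> has no kind")
  scanAtoms <- strsplit(litOf(g, coordIri, t("hasScanAtomOrder"),
                              "scan atom order"), ",", fixed = TRUE)[[1]]
  coordinate <- ScanCoordinate(kindName[1], scanAtoms)

  ptIris <- objectsOf(g, scanIri, t("hasScanPoint"))
  if (length(ptIris) < 2)
    pesStop("incomplete", "scan <", scanIri, "> has fewer than 2 points")
  points <- lapply(ptIris, function(pi) {
    valIri <- one(objectsOf(g, pi, t("hasScanCoordinateValue")),
                  "coordinate value node", pi)
    value <- as.numeric(litOf(g, valIri, t("hasValue"), "coordinate value"))
    unitIriVal <- one(objectsOf(g, valIri, t("hasUnit")), "unit", valIri)
    calcIri <- one(objectsOf(g, pi, t("hasCalculation")), "calculation", pi)
    scfText <- litOf(g, calcIri, t("hasSCFEnergy"), "SCF energy")
    calc <- CalculationRecord(
      iri = calcIri, scfEnergy = as.numeric(scfText), scfText = scfText,
      geometry = geometryFromText(litOf(g, calcIri, t("hasGeometry"),
                                        "geometry")),
      program = litOf(g, calcIri, t("hasProgram"), "program"),
      method = litOf(g, calcIri, t("hasMethod"), "method"),
      basisSet = litOf(g, calcIri, t("hasBasisSet"), "basis set"),
      charge = as.numeric(litOf(g, calcIri, t("hasCharge"), "charge")),
      spinMultiplicity = as.numeric(litOf(g, calcIri,
                                          t("hasSpinMultiplicity"),
                                          "spin multiplicity")),
      jobKind = litOf(g, calcIri, t("hasJobKind"), "job kind"))
    ScanPointRecord(
      value = value, unit = unitLabelForIri(vocab, unitIriVal),
      inputAtomIds = as.integer(strsplit(
        litOf(g, pi, t("hasInputAtomIDs"), "input atom ids"), ",",
        fixed = TRUE)[[1]]),
      calculation = calc,
      provenance = litOf(g, pi, t("hasProvenance"), "provenance"))
  })

  species <- lapply(sort(objectsOf(g, scanIri, t("onSpecies"))),
                    speciesFromGraph, g = g, vocab = vocab)
  if (!length(species))
    pesStop("incomplete", "scan <", scanIri, "> has no onSpecies link")
  fragments <- lapply(sort(objectsOf(g, scanIri, t("hasFragment"))),
                      speciesFromGraph, g = g, vocab = vocab)
  fittings <- lapply(sort(objectsOf(g, scanIri, t("hasFitting"))),
                     fittingFromGraph, g = g, vocab = vocab)

  PESScan(iri = scanIri, species = species, fragments = fragments,
          coordinate = coordinate, points = points, fittings = fittings)
}

#' Attach a fitting record to a scan in a graph
#'
#' Adds the fitting triples for `rec` under `scanIri`. The fitting node
#' IRI is minted from the record's content, so attaching an identical
#' record twice leaves the graph unchanged.
#'
#' @param g a [TripleGraph]
#' @param scanIri scan IRI (must exist in `g`)
#' @param rec a [FittingRecord]
#' @param vocab a [VocabularyMap]
#' @return the updated [TripleGraph]
#' @export
attachFitting <- function(g, scanIri, rec, vocab = defaultVocabulary()) {
  if (!scanIri %in% subjectsWith(g, RDF_TYPE,
                                 termIri(vocab, "PotentialEnergySurfaceScan")))
    pesStop("not_found", "no scan <", scanIri, "> in graph")
  b <- triB()
  fittingTriples(b, scanIri, rec, vocab)
  graphUnion(g, b$graph())
}
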