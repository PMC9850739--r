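## Vocabulary map: every class/property term used by the scan mapping,
## bound to absolute IRIs. Upstream term IRIs (species, calculation, unit
## vocabularies) are not standardized here; the defaults below are
## package-chosen and every one of them is overridable.

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

#' Default vocabulary for the scan graph
#'
#' Returns the package's default [VocabularyMap]: scan terms under the
#' `ps:` namespace, species surrogate terms under `os:`, calculation
#' surrogate terms under `oc:`, the value/unit pattern under `gc:`, and
#' unit individuals under `qu:`. Override any prefix or term IRI to align
#' with an external deployment.
#'
#' @param prefixes,terms named character vectors merged over the defaults
#' @return a [VocabularyMap]
#' @export
defaultVocabulary <- function(prefixes = character(0), terms = character(0)) {
  base <- "https://example.org/ontology/"
  pfx <- c(
    ps = paste0(base, "pes-scan#"),
    os = paste0(base, "species#"),
    oc = paste0(base, "compchem#"),
    gc = paste0(base, "core#"),
    qu = paste0(base, "unit#"),
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    xsd = XSD
  )
  ps <- function(x) paste0(pfx[["ps"]], x)
  os <- function(x) paste0(pfx[["os"]], x)
  oc <- function(x) paste0(pfx[["oc"]], x)
  gc <- function(x) paste0(pfx[["gc"]], x)
  qu <- function(x) paste0(pfx[["qu"]], x)
  tm <- c(
    # classes
    PotentialEnergySurfaceScan = ps("PotentialEnergySurfaceScan"),
    ScanCoordinate = ps("ScanCoordinate"),
    DistanceCoordinate = ps("DistanceCoordinate"),
    AngleCoordinate = ps("AngleCoordinate"),
    DihedralAngleCoordinate = ps("DihedralAngleCoordinate"),
    ScanPoint = ps("ScanPoint"),
    ScanCoordinateValue = ps("ScanCoordinateValue"),
    FittingRecord = ps("FittingRecord"),
    FittingParameter = ps("FittingParameter"),
    Species = os("Species"),
    Atom = os("Atom"),
    GaussianCalculation = oc("GaussianCalculation"),
    # scan properties
    onSpecies = ps("onSpecies"),
    hasFragment = ps("hasFragment"),
    hasScanCoordinate = ps("hasScanCoordinate"),
    hasScanAtom = ps("hasScanAtom"),
    hasScanAtomOrder = ps("hasScanAtomOrder"),
    hasScanPoint = ps("hasScanPoint"),
    hasScanCoordinateValue = ps("hasScanCoordinateValue"),
    hasCalculation = ps("hasCalculation"),
    hasInputAtomIDs = ps("hasInputAtomIDs"),
    hasProvenance = ps("hasProvenance"),
    hasFitting = ps("hasFitting"),
    hasFittingMethod = ps("hasFittingMethod"),
    hasFittingMethodSource = ps("hasFittingMethodSource"),
    hasFittingParameters = ps("hasFittingParameters"),
    parameterName = ps("parameterName"),
    parameterUnit = ps("parameterUnit"),
    # value + unit pattern
    hasValue = gc("hasValue"),
    hasUnit = gc("hasUnitOfMeasure"),
    # species surrogate
    hasInChI = os("hasInChI"),
    hasSMILES = os("hasSMILES"),
    hasAtom = os("hasAtom"),
    hasElement = os("hasElement"),
    hasAtomIndex = os("hasAtomIndex"),
    hasPosition = os("hasPosition"),
    label = "http://www.w3.org/2000/01/rdf-schema#label",
    # calculation surrogate
    hasSCFEnergy = oc("hasSCFEnergy"),
    hasGeometry = oc("hasGeometryXYZ"),
    hasProgram = oc("hasProgram"),
    hasMethod = oc("hasMethod"),
    hasBasisSet = oc("hasBasisSet"),
    hasCharge = oc("hasCharge"),
    hasSpinMultiplicity = oc("hasSpinMultiplicity"),
    hasJobKind = oc("hasJobKind"),
    # unit individuals
    unitAngstrom = qu("Angstrom"),
    unitDegree = qu("Degree"),
    unitHartree = qu("Hartree")
  )
  pfx[names(prefixes)] <- prefixes
  tm[names(terms)] <- terms
  new("VocabularyMap", prefixes = pfx, terms = tm)
}

termIri <- function(vocab, name) {
  if (!name %in% names(vocab@terms))
    pesStop("mapping", "vocabulary has no term named \"", name, "\"")
  unname(vocab@terms[[name]])
}

coordClassTerm <- function(kind)
  switch(kind, distance = "DistanceCoordinate", angle = "AngleCoordinate",
         dihedral = "DihedralAngleCoordinate")

unitTermForLabel <- function(label)
  switch(label, angstrom = "unitAngstrom", degree = "unitDegree",
         hartree = "unitHartree",
         pesStop("mapping", "no unit individual for label \"", label, "\""))

unitLabelForIri <- function(vocab, iriVal) {
  hits <- names(vocab@terms)[vocab@terms == iriVal]
  switch(hits[1], unitAngstrom = "angstrom", unitDegree = "degree",
         unitHartree = "hartree",
         pesStop("incomplete", "unknown unit IRI: ", iriVal))
}
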