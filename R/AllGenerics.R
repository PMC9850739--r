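#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the scan and fitting classes.
#' `iri()` returns the identifier of a node-backed object; `nPoints()` the
#' number of scan points; `coordinateValues()` the ordered scan-coordinate
#' grid; `scfEnergies()` the stored SCF energies (Hartree);
#' `scanPoints()`/`scanCoordinate()`/`fittingRecords()` the structural
#' slots of a [PESScan]; `energies()` the energy vector of an
#' [EnergyProfile]; `maxAbsResidual()` the maximum-residual diagnostic of
#' a fit.
#'
#' @param x object
#' @return the accessed component; see the class documentation.
#' @name accessors
#' @aliases iri nPoints coordinateValues scfEnergies scanPoints
#'   scanCoordinate fittingRecords energies maxAbsResidual
NULL

#' @rdname accessors
#' @export
setGeneric("iri", function(x) standardGeneric("iri"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("coordinateValues", function(x) standardGeneric("coordinateValues"))

#' @rdname accessors
#' @export
setGeneric("scfEnergies", function(x) standardGeneric("scfEnergies"))

#' @rdname accessors
#' @export
setGeneric("scanPoints", function(x) standardGeneric("scanPoints"))

#' @rdname accessors
#' @export
setGeneric("scanCoordinate", function(x) standardGeneric("scanCoordinate"))

#' @rdname accessors
#' @export
setGeneric("fittingRecords", function(x) standardGeneric("fittingRecords"))

#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @rdname accessors
#' @export
setGeneric("maxAbsResidual", function(x) standardGeneric("maxAbsResidual"))

#' Convert a fit result to a FittingRecord
#'
#' Packs the fitted parameters of an EVB calibration or a Morse fit into a
#' [FittingRecord] suitable for attaching to a scan graph. The numeric
#' values survive a graph round trip losslessly.
#'
#' @param x an [EVBFitResult] or [MorseFit]
#' @param methodSource free-text provenance (a citation or a tool name)
#' @return a [FittingRecord]
#' @export
setGeneric("asFittingRecord", function(x, methodSource = "evbscan")
  standardGeneric("asFittingRecord"))

#' Classical force-field energy of one geometry
#'
#' @param topology a [StateTopology]
#' @param geometry an N x 3 numeric matrix of Cartesian coordinates
#'   (Angstrom), or a data frame with columns `x`, `y`, `z`
#' @return total potential energy in kJ/mol
#' @export
setGeneric("ffEnergy", function(topology, geometry) standardGeneric("ffEnergy"))

#' Classical force-field energy profile along a scan
#'
#' Evaluates `ffEnergy` at every scan-point geometry and returns the
#' energies on the scan's coordinate grid.
#'
#' @param topology a [StateTopology]
#' @param scan a [PESScan]
#' @return an [EnergyProfile] (kJ/mol)
#' @export
setGeneric("ffProfile", function(topology, scan) standardGeneric("ffProfile"))

#' Map a scan to RDF triples
#'
#' @param x a [PESScan]
#' @param vocab a [VocabularyMap]; defaults to [defaultVocabulary()]
#' @return a [TripleGraph]
#' @export
setGeneric("toGraph", function(x, vocab = defaultVocabulary())
  standardGeneric("toGraph"))

#' Evaluate a coupling model on a coordinate grid
#'
#' @param model a [CouplingModel]
#' @param r numeric coordinate values
#' @return numeric H12 values (kJ/mol)
#' @export
setGeneric("couplingValues", function(model, r) standardGeneric("couplingValues"))
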