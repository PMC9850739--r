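## Central S4 classes. Constructors carry the class name (Bioconductor
## convention); accessors are in model.R and fitting.R.

setClassUnion("characterOrNULL", c("character", "NULL"))

# ---------------------------------------------------------------------------
# Species and atoms

#' Species reference with an atom table
#'
#' A light surrogate for an external species registry entry: a unique IRI,
#' the InChI (and optionally SMILES) identifier, a label, and the ordered
#' atom table of the reference geometry. Atom indices are 1-based and
#' contiguous; every atom carries its own IRI so scan coordinates can point
#' at atoms unambiguously.
#'
#' @slot iri unique identifier
#' @slot inchi InChI string (must start with `"InChI="`)
#' @slot smiles optional SMILES string (`NA_character_` when absent)
#' @slot label human-readable name
#' @slot atoms data frame with columns `iri`, `element`, `index`,
#'   `x`, `y`, `z` (Angstrom)
#' @export
setClass("SpeciesRef", representation(
  iri = "character", inchi = "character", smiles = "character",
  label = "character", atoms = "data.frame"
))

setValidity("SpeciesRef", function(object) {
  a <- object@atoms
  msgs <- character(0)
  if (!startsWith(object@inchi, "InChI="))
    msgs <- c(msgs, "inchi must begin with \"InChI=\"")
  if (nrow(a) == 0) msgs <- c(msgs, "atoms must be non-empty")
  need <- c("iri", "element", "index", "x", "y", "z")
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms must have columns", paste(need, collapse = ", ")))
  else {
    if (!identical(as.integer(a$index), seq_len(nrow(a))))
      msgs <- c(msgs, "atom indices must be contiguous 1..N in order")
    if (anyDuplicated(a$iri)) msgs <- c(msgs, "atom IRIs must be unique")
    if (!all(isElementSymbol(a$element)))
      msgs <- c(msgs, "unknown element symbol in atom table")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname SpeciesRef-class
#' @param iri,inchi,smiles,label,atoms see slots
#' @export
SpeciesRef <- function(iri, inchi, atoms, label = iri, smiles = NA_character_) {
  atoms$index <- as.integer(atoms$index)
  new("SpeciesRef", iri = iri, inchi = inchi, smiles = smiles,
      label = label, atoms = as.data.frame(atoms))
}

# ---------------------------------------------------------------------------
# Scan coordinate

#' Scan coordinate (distance, angle, or dihedral)
#'
#' The varied internal coordinate of a 1D PES scan, defined by the IRIs of
#' the species atoms that span it: 2 for a bond distance, 3 for a plane
#' angle, 4 for a dihedral. Distances are in Angstrom, angles in degrees.
#'
#' @slot kind one of `"distance"`, `"angle"`, `"dihedral"`
#' @slot scanAtoms ordered atom IRIs
#' @slot unit `"angstrom"` or `"degree"`
#' @export
setClass("ScanCoordinate", representation(
  kind = "character", scanAtoms = "character", unit = "character"
))

coordinateArity <- function(kind)
  switch(kind, distance = 2L, angle = 3L, dihedral = 4L,
         pesStop("config", "unknown coordinate kind: ", kind))

setValidity("ScanCoordinate", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("distance", "angle", "dihedral"))
    return("kind must be distance, angle, or dihedral")
  if (length(object@scanAtoms) != coordinateArity(object@kind))
    msgs <- c(msgs, sprintf("%s coordinate needs %d scan atoms",
                            object@kind, coordinateArity(object@kind)))
  expected <- if (object@kind == "distance") "angstrom" else "degree"
  if (!identical(object@unit, expected))
    msgs <- c(msgs, sprintf("unit for a %s coordinate must be %s",
                            object@kind, expected))
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScanCoordinate-class
#' @param kind,scanAtoms see slots
#' @export
ScanCoordinate <- function(kind, scanAtoms) {
  new("ScanCoordinate", kind = kind, scanAtoms = as.character(scanAtoms),
      unit = if (kind == "distance") "angstrom" else "degree")
}

# ---------------------------------------------------------------------------
# Calculation record

#' Per-point quantum calculation surrogate
#'
#' Holds what the fitting pipeline needs from one electronic-structure
#' calculation: the converged SCF energy (Hartree, kept both as a double
#' and exactly as printed in the source log), the Cartesian geometry
#' (Angstrom), and descriptive metadata.
#'
#' @slot iri identifier
#' @slot program program name/version text
#' @slot method functional / level of theory
#' @slot basisSet basis set label
#' @slot charge total charge (e)
#' @slot spinMultiplicity positive integer
#' @slot scfEnergy SCF energy in Hartree
#' @slot scfText the energy exactly as printed in the source log
#' @slot geometry data frame with columns `element`, `x`, `y`, `z`
#' @slot jobKind `"relaxed"`, `"rigid"`, or `"single_point"`
#' @export
setClass("CalculationRecord", representation(
  iri = "character", program = "character", method = "character",
  basisSet = "character", charge = "numeric", spinMultiplicity = "numeric",
  scfEnergy = "numeric", scfText = "character", geometry = "data.frame",
  jobKind = "character"
))

setValidity("CalculationRecord", function(object) {
  msgs <- character(0)
  if (object@spinMultiplicity < 1) msgs <- c(msgs, "spinMultiplicity must be >= 1")
  if (nrow(object@geometry) == 0) msgs <- c(msgs, "geometry must be non-empty")
  if (!object@jobKind %in% c("relaxed", "rigid", "single_point"))
    msgs <- c(msgs, "jobKind must be relaxed, rigid, or single_point")
  if (!is.finite(object@scfEnergy)) msgs <- c(msgs, "scfEnergy must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CalculationRecord-class
#' @param iri,program,method,basisSet,charge,spinMultiplicity,scfEnergy,scfText,geometry,jobKind see slots
#' @export
CalculationRecord <- function(iri, scfEnergy, geometry,
                              program = "unknown", method = "unknown",
                              basisSet = "unknown", charge = 0,
                              spinMultiplicity = 1,
                              scfText = formatShortest(scfEnergy),
                              jobKind = "single_point") {
  new("CalculationRecord", iri = iri, program = program, method = method,
      basisSet = basisSet, charge = charge,
      spinMultiplicity = spinMultiplicity, scfEnergy = scfEnergy,
      scfText = scfText, geometry = as.data.frame(geometry),
      jobKind = jobKind)
}

# ---------------------------------------------------------------------------
# Scan point

#' One point of a PES scan
#'
#' @slot orderIndex 0-based position after ascending sort by coordinate value
#' @slot value scan-coordinate value in the coordinate's unit
#' @slot unit unit label matching the scan coordinate
#' @slot inputAtomIds 1-based atom indices as used in the calculation input
#' @slot calculation the associated [CalculationRecord]
#' @slot provenance free-text source tag (file and step), not serialized
#'   semantics but carried through the graph for traceability
#' @export
setClass("ScanPointRecord", representation(
  orderIndex = "integer", value = "numeric", unit = "character",
  inputAtomIds = "integer", calculation = "CalculationRecord",
  provenance = "character"
))

#' @rdname ScanPointRecord-class
#' @param orderIndex,value,unit,inputAtomIds,calculation,provenance see slots
#' @export
ScanPointRecord <- function(value, unit, inputAtomIds, calculation,
                            orderIndex = 0L, provenance = "") {
  new("ScanPointRecord", orderIndex = as.integer(orderIndex), value = value,
      unit = unit, inputAtomIds = as.integer(inputAtomIds),
      calculation = calculation, provenance = provenance)
}

# ---------------------------------------------------------------------------
# Fitting record

#' Fitting-method record attached to a scan
#'
#' @slot methodName e.g. `"MorsePotential"` or `"EVB-2state-constant"`
#' @slot methodSource publication or tool reference
#' @slot parameters data frame with columns `name`, `value`, `unit`
#' @export
setClass("FittingRecord", representation(
  methodName = "character", methodSource = "character",
  parameters = "data.frame"
))

setValidity("FittingRecord", function(object) {
  p <- object@parameters
  if (!all(c("name", "value", "unit") %in% names(p)))
    return("parameters must have columns name, value, unit")
  if (anyDuplicated(p$name)) return("parameter names must be unique")
  TRUE
})

#' @rdname FittingRecord-class
#' @param methodName,methodSource,parameters see slots
#' @export
FittingRecord <- function(methodName, methodSource, parameters) {
  parameters <- as.data.frame(parameters)
  # canonical parameter order (by name) so a graph round trip is exact
  parameters <- parameters[order(parameters$name), , drop = FALSE]
  rownames(parameters) <- NULL
  new("FittingRecord", methodName = methodName, methodSource = methodSource,
      parameters = parameters)
}

# ---------------------------------------------------------------------------
# PES scan

#' A one-dimensional potential energy surface scan
#'
#' The central container: species (and optional fragments), one scan
#' coordinate, the ordered scan points with their calculation records, and
#' any fitting records. Points are kept sorted ascending by coordinate
#' value with distinct values; the original file order survives in each
#' point's `provenance`.
#'
#' @slot iri identifier
#' @slot species list of [SpeciesRef] (at least one)
#' @slot fragments list of [SpeciesRef] (possibly empty)
#' @slot coordinate the [ScanCoordinate]
#' @slot points list of [ScanPointRecord], sorted ascending
#' @slot fittings list of [FittingRecord]
#' @export
setClass("PESScan", representation(
  iri = "character", species = "list", fragments = "list",
  coordinate = "ScanCoordinate", points = "list", fittings = "list"
))

setValidity("PESScan", function(object) {
  msgs <- character(0)
  if (length(object@species) < 1) msgs <- c(msgs, "at least one species required")
  if (length(object@points) < 2) msgs <- c(msgs, "at least two scan points required")
  vals <- vapply(object@points, function(p) p@value, numeric(1))
  if (is.unsorted(vals, strictly = TRUE))
    msgs <- c(msgs, "points must be sorted ascending with distinct coordinate values")
  arity <- coordinateArity(object@coordinate@kind)
  nid <- vapply(object@points, function(p) length(p@inputAtomIds), integer(1))
  if (any(nid != arity))
    msgs <- c(msgs, "every point's inputAtomIds must match the coordinate arity")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PESScan-class
#' @param iri,species,fragments,coordinate,points,fittings see slots; points
#'   are re-sorted ascending by coordinate value and re-indexed at
#'   construction.
#' @export
PESScan <- function(iri, species, coordinate, points,
                    fragments = list(), fittings = list()) {
  if (is(species, "SpeciesRef")) species <- list(species)
  vals <- vapply(points, function(p) p@value, numeric(1))
  points <- points[order(vals)]
  for (k in seq_along(points)) points[[k]]@orderIndex <- k - 1L
  new("PESScan", iri = iri, species = species, fragments = fragments,
      coordinate = coordinate, points = points, fittings = fittings)
}

# ---------------------------------------------------------------------------
# Fitting-side value classes

#' Energy profile on a strictly increasing coordinate grid
#'
#' @slot coordinate strictly increasing scan-coordinate values
#' @slot energy energies in kJ/mol, same length
#' @slot unit coordinate unit label
#' @export
setClass("EnergyProfile", representation(
  coordinate = "numeric", energy = "numeric", unit = "character"
))

setValidity("EnergyProfile", function(object) {
  msgs <- character(0)
  if (length(object@coordinate) != length(object@energy))
    msgs <- c(msgs, "coordinate and energy must have equal length")
  if (length(object@coordinate) < 2) msgs <- c(msgs, "profile needs >= 2 points")
  if (!all(is.finite(object@coordinate)) || !all(is.finite(object@energy)))
    msgs <- c(msgs, "profile values must be finite")
  else if (is.unsorted(object@coordinate, strictly = TRUE))
    msgs <- c(msgs, "coordinate must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' @rdname EnergyProfile-class
#' @param coordinate,energy,unit see slots
#' @export
EnergyProfile <- function(coordinate, energy, unit = "angstrom") {
  new("EnergyProfile", coordinate = as.numeric(coordinate),
      energy = as.numeric(energy), unit = unit)
}

#' Aligned EVB input: two state profiles and a reference
#'
#' All three profiles must share an identical coordinate grid.
#'
#' @slot e1,e2 classical state profiles (kJ/mol)
#' @slot eref reference (quantum) profile (kJ/mol)
#' @export
setClass("EVBInput", representation(
  e1 = "EnergyProfile", e2 = "EnergyProfile", eref = "EnergyProfile"
))

setValidity("EVBInput", function(object) {
  g <- object@eref@coordinate
  if (!identical(object@e1@coordinate, g) || !identical(object@e2@coordinate, g))
    return("all three profiles must be on the identical coordinate grid")
  TRUE
})

#' @rdname EVBInput-class
#' @param e1,e2,eref see slots
#' @export
EVBInput <- function(e1, e2, eref) new("EVBInput", e1 = e1, e2 = e2, eref = eref)

#' EVB off-diagonal coupling model
#'
#' Constant coupling `H12(r) = A`, or a single Gaussian
#' `H12(r) = A * exp(-(r - r0)^2 / (2 w^2))`.
#'
#' @slot kind `"constant"` or `"gaussian"`
#' @slot A amplitude (kJ/mol)
#' @slot r0 Gaussian center (coordinate units; `NA` for constant)
#' @slot w Gaussian width (> 0, coordinate units; `NA` for constant)
#' @export
setClass("CouplingModel", representation(
  kind = "character", A = "numeric", r0 = "numeric", w = "numeric"
))

setValidity("CouplingModel", function(object) {
  if (!object@kind %in% c("constant", "gaussian"))
    return("kind must be constant or gaussian")
  if (object@kind == "gaussian" && (!is.finite(object@w) || object@w <= 0))
    return("gaussian coupling needs w > 0")
  TRUE
})

#' @rdname CouplingModel-class
#' @param kind,A,r0,w see slots
#' @export
CouplingModel <- function(kind, A, r0 = NA_real_, w = NA_real_) {
  new("CouplingModel", kind = kind, A = A, r0 = r0, w = w)
}

#' Result of an EVB coupling calibration
#'
#' @slot coupling fitted [CouplingModel]
#' @slot s1,s2 constant shifts applied to states 1 and 2 (kJ/mol)
#' @slot evb the EVB ground-state profile at the fitted parameters
#' @slot reference the reference profile used
#' @slot residuals `energies(evb) - energies(reference)` pointwise
#' @slot objective final sum of squared residuals
#' @slot converged optimizer convergence flag
#' @export
setClass("EVBFitResult", representation(
  coupling = "CouplingModel", s1 = "numeric", s2 = "numeric",
  evb = "EnergyProfile", reference = "EnergyProfile",
  residuals = "numeric", objective = "numeric", converged = "logical"
))

#' Result of a Morse-potential fit
#'
#' Model: `V(r) = De * (1 - exp(-a (r - re)))^2 + V0`.
#'
#' @slot De well depth (kJ/mol)
#' @slot re equilibrium distance (coordinate units)
#' @slot a width parameter (inverse coordinate units)
#' @slot V0 energy offset (kJ/mol)
#' @slot fitted fitted energies on the input grid
#' @slot residuals fitted minus observed
#' @slot converged optimizer convergence flag
#' @export
setClass("MorseFit", representation(
  De = "numeric", re = "numeric", a = "numeric", V0 = "numeric",
  fitted = "numeric", residuals = "numeric", converged = "logical"
))

# ---------------------------------------------------------------------------
# Force-field topology

#' Classical force-field topology of one chemical state
#'
#' Explicit (user-declared) topology: per-atom nonbonded parameters and
#' bonded terms over 1-based atom indices. Functional forms are documented
#' in [ffEnergy()].
#'
#' @slot label state name
#' @slot atoms data frame with columns `epsilon` (kJ/mol), `sigma`
#'   (Angstrom), `charge` (e); one row per atom
#' @slot bonds harmonic bonds: columns `i`, `j`, `k` (kJ/mol/A^2), `r0` (A)
#' @slot morse Morse bonds: columns `i`, `j`, `De` (kJ/mol), `a` (1/A), `re` (A)
#' @slot angles harmonic angles: columns `i`, `j`, `k3`, `ktheta`
#'   (kJ/mol/rad^2), `theta0` (degrees); `j` is the vertex
#' @slot torsions cosine torsions: columns `i`, `j`, `k3`, `l`, `Vn`
#'   (kJ/mol), `n` (integer), `gamma` (degrees)
#' @slot scale14 named numeric: factors for 1-4 `lj` and `coulomb` pairs
#' @export
setClass("StateTopology", representation(
  label = "character", atoms = "data.frame", bonds = "data.frame",
  morse = "data.frame", angles = "data.frame", torsions = "data.frame",
  scale14 = "numeric"
))

setValidity("StateTopology", function(object) {
  msgs <- character(0)
  a <- object@atoms
  if (nrow(a)) {
    if (any(a$epsilon < 0)) msgs <- c(msgs, "epsilon must be >= 0")
    if (any(a$sigma <= 0)) msgs <- c(msgs, "sigma must be > 0")
  }
  if (nrow(object@bonds) && any(object@bonds$k < 0))
    msgs <- c(msgs, "bond force constants must be >= 0")
  if (nrow(object@morse) && any(object@morse$De < 0))
    msgs <- c(msgs, "Morse De must be >= 0")
  chk <- function(df, cols) {
    if (!nrow(df)) return(TRUE)
    idx <- as.matrix(df[cols])
    all(idx >= 1) && !any(apply(idx, 1, anyDuplicated) > 0)
  }
  if (!chk(object@bonds, c("i", "j")) || !chk(object@morse, c("i", "j")) ||
      !chk(object@angles, c("i", "j", "k3")) ||
      !chk(object@torsions, c("i", "j", "k3", "l")))
    msgs <- c(msgs, "term atom indices must be 1-based and distinct within a term")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Knowledge-graph classes

#' A set of RDF triples
#'
#' Plain triple store: subjects and predicates are absolute IRIs; objects
#' are IRIs or typed literals. No blank nodes are used anywhere in the
#' mapping, which makes graph comparison a set comparison.
#'
#' @slot triples data frame with columns `s`, `p`, `o`, `lit` (logical:
#'   object is a literal), `dt` (datatype IRI or `NA` for plain literals
#'   and IRI objects)
#' @export
setClass("TripleGraph", representation(triples = "data.frame"))

#' Vocabulary map for the scan graph
#'
#' Binds every class and property term the mapping uses to an absolute
#' IRI, plus namespace prefixes for serialization. All upstream term IRIs
#' are configurable; [defaultVocabulary()] documents the defaults.
#'
#' @slot prefixes named character: prefix -> namespace IRI
#' @slot terms named character: term name -> absolute IRI
#' @export
setClass("VocabularyMap", representation(
  prefixes = "character", terms = "character"
))

setValidity("VocabularyMap", function(object) {
  if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
    return("terms must be uniquely named")
  if (anyDuplicated(object@terms))
    return("term IRIs must be distinct (bijective mapping)")
  TRUE
})
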