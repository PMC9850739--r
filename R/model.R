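## Accessors, show methods, and scan validation.

#' @rdname accessors
setMethod("iri", "PESScan", function(x) x@iri)
#' @rdname accessors
setMethod("iri", "SpeciesRef", function(x) x@iri)
#' @rdname accessors
setMethod("iri", "CalculationRecord", function(x) x@iri)

#' @rdname accessors
setMethod("nPoints", "PESScan", function(x) length(x@points))

#' @rdname accessors
setMethod("coordinateValues", "PESScan", function(x)
  vapply(x@points, function(p) p@value, numeric(1)))
#' @rdname accessors
setMethod("coordinateValues", "EnergyProfile", function(x) x@coordinate)

#' @rdname accessors
setMethod("scfEnergies", "PESScan", function(x)
  vapply(x@points, function(p) p@calculation@scfEnergy, numeric(1)))

#' @rdname accessors
setMethod("scanPoints", "PESScan", function(x) x@points)

#' @rdname accessors
setMethod("scanCoordinate", "PESScan", function(x) x@coordinate)

#' @rdname accessors
setMethod("fittingRecords", "PESScan", function(x) x@fittings)

#' @rdname accessors
setMethod("energies", "EnergyProfile", function(x) x@energy)

setMethod("show", "PESScan", function(object) {
  cat(sprintf("PESScan <%s>\n", object@iri))
  cat(sprintf("  coordinate: %s over %d atom(s) [%s]\n",
              object@coordinate@kind, length(object@coordinate@scanAtoms),
              object@coordinate@unit))
  v <- coordinateValues(object)
  cat(sprintf("  points: %d, range %.4g .. %.4g %s\n", length(v),
              min(v), max(v), object@coordinate@unit))
  cat(sprintf("  species: %s\n",
              paste(vapply(object@species, function(s) s@label, character(1)),
                    collapse = ", ")))
  if (length(object@fittings))
    cat(sprintf("  fittings: %s\n",
                paste(vapply(object@fittings, function(f) f@methodName,
                             character(1)), collapse = ", ")))
})

setMethod("show", "SpeciesRef", function(object) {
  cat(sprintf("SpeciesRef <%s> %s (%d atoms)\n  %s\n",
              object@iri, object@label, nrow(object@atoms), object@inchi))
})

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf("EnergyProfile: %d points, coordinate %.4g .. %.4g [%s], energy %.4g .. %.4g kJ/mol\n",
              length(object@coordinate), min(object@coordinate),
              max(object@coordinate), object@unit, min(object@energy),
              max(object@energy)))
})

setMethod("show", "CouplingModel", function(object) {
  if (object@kind == "constant")
    cat(sprintf("CouplingModel constant: A = %.6g kJ/mol\n", object@A))
  else
    cat(sprintf("CouplingModel gaussian: A = %.6g kJ/mol, r0 = %.6g, w = %.6g\n",
                object@A, object@r0, object@w))
})

## Resolve a scan's coordinate atoms to species-geometry indices, NA when
## an IRI does not resolve.
resolveScanAtoms <- function(scan) {
  allAtoms <- do.call(rbind, lapply(c(scan@species, scan@fragments),
                                    function(s) s@atoms))
  match(scan@coordinate@scanAtoms, allAtoms$iri)
}

#' Validate a PES scan against its own geometries
#'
#' Checks the structural invariants of a scan and recomputes every point's
#' coordinate value from the stored calculation geometry via
#' `inputAtomIds`, comparing against the recorded value. Violations are
#' collected, never thrown.
#'
#' @param scan a [PESScan]
#' @param tolDist tolerance for distance coordinates (Angstrom)
#' @param tolAngle tolerance for angle/dihedral coordinates (degrees)
#' @return data frame with columns `point` (1-based index into the sorted
#'   points, `NA` for scan-level problems) and `reason`; zero rows when
#'   the scan is self-consistent
#' @export
validateScan <- function(scan, tolDist = 1e-3, tolAngle = 0.1) {
  bad <- data.frame(point = integer(0), reason = character(0))
  note <- function(point, reason)
    rbind(bad, data.frame(point = point, reason = reason))

  vals <- coordinateValues(scan)
  if (any(diff(vals) <= 0))
    bad <- note(NA_integer_,
                "points not strictly ascending in coordinate value")
  kind <- scan@coordinate@kind
  arity <- coordinateArity(kind)
  if (length(scan@coordinate@scanAtoms) != arity)
    bad <- note(NA_integer_, "scan-coordinate arity mismatch")
  for (s in c(scan@species, scan@fragments)) {
    if (!startsWith(s@inchi, "InChI="))
      bad <- note(NA_integer_, sprintf("species %s: invalid InChI prefix", s@iri))
  }
  if (any(is.na(resolveScanAtoms(scan))))
    bad <- note(NA_integer_, "scan-coordinate atom IRI does not resolve to a species atom")

  tol <- if (kind == "distance") tolDist else tolAngle
  for (k in seq_along(scan@points)) {
    p <- scan@points[[k]]
    if (length(p@inputAtomIds) != arity) {
      bad <- note(k, "inputAtomIds arity mismatch")
      next
    }
    meas <- tryCatch(
      measureCoordinate(kind, p@calculation@geometry, p@inputAtomIds),
      error = function(e) NA_real_)
    if (is.na(meas)) {
      bad <- note(k, "atom index unresolvable in geometry")
    } else {
      dev <- abs(meas - p@value)
      if (kind == "dihedral") dev <- min(dev, abs(360 - dev))
      if (dev > tol)
        bad <- note(k, sprintf(
          "recorded coordinate %.6g differs from measured %.6g by %.3g",
          p@value, meas, dev))
    }
  }
  bad
}
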