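## Deterministic generators for every fixture the package needs: analytic
## two-state systems with known coupling, dialect-conformant pseudo-logs,
## and an ethanol-like worked-example scan. Every generator is a pure
## function of (spec, seed); seeds are explicit arguments and the global
## RNG state is restored afterwards.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Snap to the decimal the dialect prints, so log round trips are exact.
snap6 <- function(v) as.numeric(sprintf("%.6f", v))

stateCurve <- function(state, r) {
  switch(state$kind,
         harmonic = 0.5 * state$k * (r - state$r0)^2,
         morse = morseEnergy(r, state$De, state$a, state$re),
         pesStop("config", "unknown state generator kind: ", state$kind))
}

#' Canonical two-state study system
#'
#' The reference conditions used throughout the test surface: a 40-point
#' distance grid on 1.2-3.4 Angstrom, two harmonic diatomic-like states
#' with force constant 15 kJ/mol/A^2 and minima at 1.6 and 2.9 Angstrom
#' (soft states whose diabatic gaps stay commensurate with the coupling,
#' the strong-mixing regime EVB coupling calibration operates in), zero
#' shifts, and either a constant coupling of A = 25 kJ/mol or a gaussian
#' coupling A = 40 kJ/mol centered at r0 = 2.2 with width w = 0.3.
#'
#' @param coupling `"constant"` or `"gaussian"`
#' @param sigma zero-mean reference noise standard deviation (kJ/mol)
#' @param seed RNG seed for the noise
#' @return a two-state spec list for [makeTwoStateSystem()]
#' @export
canonicalTwoStateSpec <- function(coupling = c("constant", "gaussian"),
                                  sigma = 0, seed = 1) {
  coupling <- match.arg(coupling)
  list(
    grid = seq(1.2, 3.4, length.out = 40),
    state1 = list(kind = "harmonic", k = 15, r0 = 1.6),
    state2 = list(kind = "harmonic", k = 15, r0 = 2.9),
    coupling = if (coupling == "constant") CouplingModel("constant", A = 25)
               else CouplingModel("gaussian", A = 40, r0 = 2.2, w = 0.3),
    shifts = c(0, 0),
    sigma = sigma,
    seed = seed,
    unit = "angstrom"
  )
}

#' Forward-generate a two-state EVB system with known coupling
#'
#' Computes the two state profiles from the spec's analytic generators,
#' then the reference profile exactly as
#' `evbGround(E1 + s1, E2 + s2, H12(r))` plus seeded zero-mean gaussian
#' noise. The embedded ground truth is returned for recovery tests.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec list with `grid` (strictly increasing), `state1`/`state2`
#'   (`list(kind = "harmonic", k, r0)` or
#'   `list(kind = "morse", De, a, re)`), `coupling` ([CouplingModel]),
#'   `shifts` (numeric(2)), `sigma` (>= 0), `seed`, `unit`;
#'   see [canonicalTwoStateSpec()]
#' @return list with `input` (an [EVBInput]; state profiles unshifted)
#'   and `truth` (`coupling` and `shifts`)
#' @export
makeTwoStateSystem <- function(spec = canonicalTwoStateSpec()) {
  r <- spec$grid
  stopifnot(!is.unsorted(r, strictly = TRUE), spec$sigma >= 0)
  e1 <- stateCurve(spec$state1, r)
  e2 <- stateCurve(spec$state2, r)
  h <- couplingValues(spec$coupling, r)
  eref <- evbGround(e1 + spec$shifts[1], e2 + spec$shifts[2], h)
  if (spec$sigma > 0)
    eref <- eref + withSeed(spec$seed, stats::rnorm(length(r), 0, spec$sigma))
  unit <- spec$unit %||% "angstrom"
  list(input = EVBInput(e1 = EnergyProfile(r, e1, unit),
                        e2 = EnergyProfile(r, e2, unit),
                        eref = EnergyProfile(r, eref, unit)),
       truth = list(coupling = spec$coupling, shifts = spec$shifts))
}

## --- pseudo-log emission -------------------------------------------------

orientationBlockText <- function(geometry) {
  rule <- paste0(" ", strrep("-", 69))
  rows <- vapply(seq_len(nrow(geometry)), function(i) {
    z <- match(geometry$element[i], .ELEMENTS)
    sprintf(" %6d %10d %11d    %11.6f %11.6f %11.6f",
            i, z, 0L, geometry$x[i], geometry$y[i], geometry$z[i])
  }, character(1))
  c("                         Input orientation:",
    rule,
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    rule, rows, rule)
}

scanHeaderLine <- function(scan) {
  p1 <- scan@points[[1]]
  letter <- c(distance = "B", angle = "A", dihedral = "D")[[scan@coordinate@kind]]
  vals <- coordinateValues(scan)
  step <- if (length(vals) > 1) mean(diff(vals)) else 0
  sprintf(" %s %s S %d %.4f", letter,
          paste(p1@inputAtomIds, collapse = " "),
          length(vals) - 1L, step)
}

#' Emit a dialect-conformant pseudo-log for a scan ground truth
#'
#' Writes the scan's geometries and SCF energies (exactly as stored in
#' each point's `scfText`) into the documented log dialect, so that
#' [parseScanLog()] plus [assembleScan()] reproduce the truth. Relaxed
#' logs carry one "Optimization completed." marker per point preceded by
#' a seeded unconverged intermediate cycle; rigid logs are a bare
#' geometry/SCF sequence with the scan header; `"single_point"` returns
#' one log per point (no scan header).
#'
#' @param scan the ground-truth [PESScan]
#' @param type `"relaxed"`, `"rigid"`, or `"single_point"`
#' @param seed seed for the cosmetic intermediate-cycle energies
#' @return a single log text, or a character vector of per-point logs
#'   for `"single_point"`
#' @export
makeFixtureLog <- function(scan, type = c("relaxed", "rigid", "single_point"),
                           seed = 1) {
  type <- match.arg(type)
  calc1 <- scan@points[[1]]@calculation
  header <- c(
    " Entering Gaussian System (dialect-v1 emulation)",
    sprintf(" #p %s/%s scan",
            calc1@method, calc1@basisSet),
    if (type != "single_point") scanHeaderLine(scan),
    sprintf(" Charge = %d Multiplicity = %d",
            as.integer(calc1@charge), as.integer(calc1@spinMultiplicity)))
  scfLine <- function(text, method)
    sprintf(" SCF Done:  E(%s) =  %s     A.U. after   11 cycles",
            method, text)
  jitters <- withSeed(seed, stats::runif(nPoints(scan), 0.001, 0.01))

  pointBlock <- function(p, i) {
    calc <- p@calculation
    block <- character(0)
    if (type == "relaxed") {
      # one unconverged intermediate cycle, then the converged step
      inter <- sprintf("%.7f", calc@scfEnergy + jitters[i])
      block <- c(block, orientationBlockText(calc@geometry),
                 scfLine(inter, calc@method))
    }
    block <- c(block, orientationBlockText(calc@geometry),
               scfLine(calc@scfText, calc@method))
    if (type == "relaxed")
      block <- c(block, " Optimization completed.",
                 "    -- Stationary point found.")
    block
  }

  if (type == "single_point") {
    return(vapply(seq_along(scan@points), function(i)
      paste(c(header, pointBlock(scan@points[[i]], i),
              " Normal termination."), collapse = "\n"),
      character(1)))
  }
  body <- unlist(lapply(seq_along(scan@points), function(i)
    pointBlock(scan@points[[i]], i)))
  paste(c(header, body, " Normal termination."), collapse = "\n")
}

## --- ethanol-like worked example ----------------------------------------

#' Synthetic ethanol-like carbon-carbon bond scan
#'
#' A 9-atom ethanol-like species (C, C, O and six H) scanned along the
#' carbon-carbon distance: 12 relaxed-style points starting at exactly
#' 1.51 Angstrom and extending past 5 Angstrom. Geometries are built so
#' the recorded coordinate values equal [measureDistance()] on the
#' stored geometry exactly; energies follow a Morse-type curve
#' (De = 350 kJ/mol, re = 1.53, a = 1.9) on top of a constant electronic
#' baseline, stored in Hartree. The species is synthetic: it mimics the
#' shape of a real ethanol scan but is not quantum-chemistry data.
#'
#' @param kbBase namespace base for minted IRIs
#' @return a [PESScan]
#' @export
makeEthanolLikeScan <- function(kbBase = "https://example.org/kb/") {
  dvals <- c(1.51, 1.61, 1.71, 1.81, 1.91, 2.11, 2.31, 2.61, 3.01, 3.51,
             4.01, 5.01)
  ch <- 1.09; co <- 1.43; oh <- 0.96
  t1 <- c(-1 / 3, 2 * sqrt(2) / 3, 0)
  t2 <- c(-1 / 3, -sqrt(2) / 3, sqrt(2 / 3))
  t3 <- c(-1 / 3, -sqrt(2) / 3, -sqrt(2 / 3))
  baseGeom <- function(d) {
    c1 <- c(0, 0, 0)
    c2 <- c(d, 0, 0)
    geom <- rbind(
      c1, c2,
      c2 + co * c(1 / 3, 2 * sqrt(2) / 3, 0),              # O on C2
      c1 + ch * t1, c1 + ch * t2, c1 + ch * t3,            # CH3
      c2 + ch * c(1 / 3, -sqrt(2) / 3, sqrt(2 / 3)),       # 2 H on C2
      c2 + ch * c(1 / 3, -sqrt(2) / 3, -sqrt(2 / 3)),
      c2 + co * c(1 / 3, 2 * sqrt(2) / 3, 0) +
        oh * c(0.95, 0.25, 0)                              # H on O
    )
    geom <- apply(geom, 2, snap6)
    # keep the scanned C-C pair exact on the x axis
    geom[1, ] <- c(0, 0, 0)
    geom[2, ] <- c(d, 0, 0)
    data.frame(element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
               x = geom[, 1], y = geom[, 2], z = geom[, 3])
  }

  g0 <- baseGeom(dvals[1])
  atomIris <- paste0(kbBase, "species/ethanol_like/atom/", 1:9)
  species <- SpeciesRef(
    iri = paste0(kbBase, "species/ethanol_like"),
    inchi = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3",
    smiles = "CCO",
    label = "ethanol-like (synthetic)",
    atoms = data.frame(iri = atomIris, element = g0$element, index = 1:9,
                       x = g0$x, y = g0$y, z = g0$z,
                       stringsAsFactors = FALSE))
  coordinate <- ScanCoordinate("distance", atomIris[1:2])

  points <- lapply(seq_along(dvals), function(i) {
    d <- dvals[i]
    ekj <- morseEnergy(d, De = 350, a = 1.9, re = 1.53)
    scfText <- sprintf("%.7f", -155 + ekj / HARTREE_KJ_PER_MOL)
    calc <- CalculationRecord(
      iri = paste0(kbBase, "calculation/ethanol_like_", i),
      scfEnergy = as.numeric(scfText), scfText = scfText,
      geometry = baseGeom(d), program = "dialect-v1",
      method = "RB3LYP", basisSet = "cc-pVQZ", charge = 0,
      spinMultiplicity = 1, jobKind = "relaxed")
    ScanPointRecord(value = d, unit = "angstrom", inputAtomIds = c(1L, 2L),
                    calculation = calc,
                    provenance = paste0("synthetic:", i))
  })

  PESScan(iri = paste0(kbBase, "scan/ethanol_like_cc"),
          species = species, coordinate = coordinate, points = points)
}
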