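# Shared fixtures and independent oracles, built in code.

KB <- "https://example.org/kb/"

# Diatomic species with two atoms on the x axis; used wherever a minimal
# self-consistent scan is needed.
diatomicSpecies <- function(label = "dimer",
                            inchi = "InChI=1S/C2/c1-2") {
  SpeciesRef(
    iri = paste0(KB, "species/", label),
    inchi = inchi, label = label,
    atoms = data.frame(
      iri = paste0(KB, "species/", label, "/atom/", 1:2),
      element = c("C", "C"), index = 1:2,
      x = c(0, 1.5), y = c(0, 0), z = c(0, 0),
      stringsAsFactors = FALSE))
}

# Self-consistent diatomic scan: geometry distance equals the recorded
# coordinate value exactly; energies supplied in Hartree (stored with
# lossless lexical forms so graph round trips are exact).
makeDiatomicScan <- function(rvals, energiesHartree,
                             label = "dimer", jobKind = "relaxed",
                             inchi = "InChI=1S/C2/c1-2") {
  sp <- diatomicSpecies(label, inchi)
  points <- lapply(seq_along(rvals), function(i) {
    r <- rvals[i]
    scfText <- evbscan:::formatShortest(energiesHartree[i])
    calc <- CalculationRecord(
      iri = paste0(KB, "calculation/", label, "_", i),
      scfEnergy = as.numeric(scfText), scfText = scfText,
      geometry = data.frame(element = c("C", "C"),
                            x = c(0, r), y = c(0, 0), z = c(0, 0)),
      jobKind = jobKind)
    ScanPointRecord(value = r, unit = "angstrom", inputAtomIds = c(1L, 2L),
                    calculation = calc, provenance = paste0("fix:", i))
  })
  PESScan(iri = paste0(KB, "scan/", label),
          species = sp,
          coordinate = ScanCoordinate("distance", sp@atoms$iri),
          points = points)
}

identityAtomMap <- function(species)
  setNames(species@atoms$iri, as.character(seq_len(nrow(species@atoms))))

# Field-wise scan comparison used by round-trip tests (iri-independent
# variant compares the physics, not the minted identifiers).
expect_scan_physics_equal <- function(a, b) {
  expect_equal(coordinateValues(a), coordinateValues(b))
  expect_identical(
    vapply(scanPoints(a), function(p) p@calculation@scfText, character(1)),
    vapply(scanPoints(b), function(p) p@calculation@scfText, character(1)))
  for (k in seq_along(scanPoints(a))) {
    expect_equal(scanPoints(a)[[k]]@calculation@geometry,
                 scanPoints(b)[[k]]@calculation@geometry,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(scanPoints(a)[[k]]@inputAtomIds,
                     scanPoints(b)[[k]]@inputAtomIds)
  }
}

# Strict field-for-field comparison for graph round trips.
expect_scan_identical <- function(a, b) {
  expect_identical(iri(a), iri(b))
  expect_equal(a@coordinate, b@coordinate)
  expect_equal(length(a@points), length(b@points))
  for (k in seq_along(a@points)) expect_equal(a@points[[k]], b@points[[k]])
  expect_equal(lapply(a@species, function(s) s@iri),
               lapply(b@species, function(s) s@iri))
  for (k in seq_along(a@species))
    expect_equal(a@species[[k]], b@species[[k]], ignore_attr = TRUE)
  expect_equal(a@fittings, b@fittings, ignore_attr = TRUE)
}

# Random rigid motion: Householder-based random rotation + translation.
randomRigidMotion <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- rnorm(3, sd = 5)
  function(p) as.numeric(R %*% p + t0)
}

# Independent local-minima scan used as the oracle for state
# identification (deliberately written as a plain loop).
bruteStates <- function(e, kind) {
  n <- length(e)
  mins <- c()
  for (i in seq_len(n)) {
    left <- if (i == 1) TRUE else e[i] < e[i - 1]
    right <- if (i == n) TRUE else e[i] < e[i + 1]
    if (i == 1 && n > 1 && !(e[1] < e[2])) next
    if (i == n && n > 1 && !(e[n] < e[n - 1])) next
    if (left && right) mins <- c(mins, i)
  }
  if (length(mins) == 0) return(NULL)
  react <- mins[order(e[mins])][1]
  if (length(mins) == 1) {
    if (kind != "distance") return(NULL)
    if (react == n) return(NULL)
    return(c(react, n))
  }
  others <- mins[mins != react]
  c(react, others[order(e[others])][1])
}

# Smooth-ish random profile generator for the state-identification study.
randomProfile <- function(n = 21) {
  x <- seq(0, 1, length.out = n)
  e <- rep(0, n)
  for (k in 1:4) e <- e + rnorm(1, sd = 5) * sin(k * pi * x + runif(1, 0, pi))
  e + cumsum(rnorm(n, sd = 0.2))
}
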