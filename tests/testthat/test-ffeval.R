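# Classical force-field evaluation.

diatomicGeom <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)

test_that("single-term energies match their closed forms", {
  bond <- stateTopology("b", atoms = data.frame(epsilon = c(0, 0),
                                                sigma = c(1, 1),
                                                charge = c(0, 0)),
                        bonds = data.frame(i = 1, j = 2, k = 2000, r0 = 1.5))
  expect_equal(ffEnergy(bond, diatomicGeom(1.6)), 10)

  morse <- stateTopology("m", atoms = data.frame(epsilon = c(0, 0),
                                                 sigma = c(1, 1),
                                                 charge = c(0, 0)),
                         morse = data.frame(i = 1, j = 2, De = 350, a = 1.9,
                                            re = 1.53))
  expect_equal(ffEnergy(morse, diatomicGeom(1.53)), 0)

  lj <- stateTopology("lj", atoms = data.frame(epsilon = c(0.5, 0.5),
                                               sigma = c(3.4, 3.4),
                                               charge = c(0, 0)))
  expect_equal(ffEnergy(lj, diatomicGeom(3.4)), 0)
  # attractive well at 2^(1/6) sigma
  expect_equal(ffEnergy(lj, diatomicGeom(2^(1 / 6) * 3.4)), -0.5)
})

test_that("harmonic diatomic agrees with the closed form across a grid", {
  top <- stateTopology("b", atoms = data.frame(epsilon = c(0, 0),
                                               sigma = c(1, 1),
                                               charge = c(0, 0)),
                       bonds = data.frame(i = 1, j = 2, k = 837.3, r0 = 1.52))
  r <- seq(1.0, 3.0, length.out = 100)
  e <- vapply(r, function(ri) ffEnergy(top, diatomicGeom(ri)), numeric(1))
  expect_equal(e, 0.5 * 837.3 * (r - 1.52)^2, tolerance = 1e-10)
})

test_that("energies are invariant under rigid motions", {
  top <- stateTopology(
    "mix",
    atoms = data.frame(epsilon = c(0.3, 0.2, 0.4, 0.1),
                       sigma = c(3.2, 3.0, 3.4, 2.8),
                       charge = c(0.2, -0.1, -0.3, 0.2)),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), k = c(900, 800),
                       r0 = c(1.5, 1.4)),
    angles = data.frame(i = 1, j = 2, k3 = 3, ktheta = 300, theta0 = 110),
    torsions = data.frame(i = 1, j = 2, k3 = 3, l = 4, Vn = 6, n = 3,
                          gamma = 0))
  set.seed(23)
  geom <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.2, 0, 3.0, 1.4, 1.1),
                 4, 3, byrow = TRUE)
  e0 <- ffEnergy(top, geom)
  for (k in 1:10) {
    move <- randomRigidMotion()
    moved <- t(apply(geom, 1, move))
    expect_equal(ffEnergy(top, moved), e0, tolerance = 1e-8)
  }
})

test_that("bonded energy is linear in the force constants", {
  base <- stateTopology("b", atoms = data.frame(epsilon = c(0, 0, 0),
                                                sigma = c(1, 1, 1),
                                                charge = c(0, 0, 0)),
                        bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                           k = c(900, 700),
                                           r0 = c(1.4, 1.4)),
                        angles = data.frame(i = 1, j = 2, k3 = 3,
                                            ktheta = 250, theta0 = 100))
  doubled <- base
  doubled@bonds$k <- 2 * doubled@bonds$k
  doubled@angles$ktheta <- 2 * doubled@angles$ktheta
  geom <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.3, 1.1, 0.2), 3, 3, byrow = TRUE)
  expect_equal(ffEnergy(doubled, geom), 2 * ffEnergy(base, geom),
               tolerance = 1e-12)
})

test_that("empty topology yields a zero profile and errors are classed", {
  zero <- stateTopology("z", atoms = data.frame(epsilon = c(0, 0),
                                                sigma = c(1, 1),
                                                charge = c(0, 0)))
  scan <- makeDiatomicScan(c(1.4, 1.5, 1.6), c(-1, -1.1, -1.05))
  prof <- ffProfile(zero, scan)
  expect_equal(energies(prof), c(0, 0, 0))
  expect_equal(coordinateValues(prof), coordinateValues(scan))

  oob <- stateTopology("o", atoms = data.frame(epsilon = c(0, 0),
                                               sigma = c(1, 1),
                                               charge = c(0, 0)),
                       bonds = data.frame(i = 1, j = 5, k = 100, r0 = 1))
  expect_error(ffEnergy(oob, diatomicGeom(1.5)),
               class = "evbscan_topology_error")

  qq <- stateTopology("q", atoms = data.frame(epsilon = c(0, 0),
                                              sigma = c(1, 1),
                                              charge = c(0.1, -0.1)))
  expect_error(ffEnergy(qq, diatomicGeom(0)),
               class = "evbscan_geometry_error")
})

test_that("Morse-bond profile on a distance scan is lowest near re", {
  top <- stateTopology("m", atoms = data.frame(epsilon = c(0, 0),
                                               sigma = c(1, 1),
                                               charge = c(0, 0)),
                       morse = data.frame(i = 1, j = 2, De = 350, a = 1.9,
                                          re = 1.53))
  rvals <- seq(1.2, 4.0, by = 0.2)
  scan <- makeDiatomicScan(rvals, seq(-1, -2, length.out = length(rvals)))
  prof <- ffProfile(top, scan)
  expect_identical(which.min(energies(prof)),
                   which.min(abs(rvals - 1.53)))
})

test_that("exclusion policy removes 1-2/1-3 pairs and scales 1-4", {
  # chain of 4 atoms: only the 1-4 pair is nonbonded, scaled by 0.5
  chainAtoms <- data.frame(epsilon = rep(0, 4), sigma = rep(1, 4),
                           charge = c(0.3, 0, 0, -0.3))
  top <- stateTopology("c", atoms = chainAtoms,
                       bonds = data.frame(i = 1:3, j = 2:4, k = rep(0, 3),
                                          r0 = rep(1.5, 3)))
  geom <- matrix(c(0, 0, 0, 1.5, 0, 0, 3.0, 0, 0, 4.5, 0, 0),
                 4, 3, byrow = TRUE)
  expected <- 0.5 * 138.935458 * 0.3 * (-0.3) / 4.5
  expect_equal(ffEnergy(top, geom), expected, tolerance = 1e-12)

  noScale <- stateTopology("c", atoms = chainAtoms,
                           bonds = data.frame(i = 1:3, j = 2:4,
                                              k = rep(0, 3),
                                              r0 = rep(1.5, 3)),
                           scale14 = c(lj = 1, coulomb = 1))
  expect_equal(ffEnergy(noScale, geom), 2 * expected, tolerance = 1e-12)
})

test_that("topology YAML round trips through the documented schema", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "label: state1",
    "atoms:",
    "  - {element: C, epsilon: 0.276, sigma: 3.5, charge: -0.18}",
    "  - {element: C, epsilon: 0.276, sigma: 3.5, charge: -0.18}",
    "terms:",
    "  - {type: harmonic_bond, i: 1, j: 2, k: 2000, r0: 1.53}",
    "scale14: {lj: 0.5, coulomb: 0.5}"), path)
  top <- readTopology(path)
  expect_identical(top@label, "state1")
  expect_equal(top@bonds$k, 2000)
  expect_equal(ffEnergy(top, diatomicGeom(1.63)),
               0.5 * 2000 * 0.1^2, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("label: x", "atoms:",
               "  - {epsilon: 0, sigma: 1, charge: 0}",
               "terms:",
               "  - {type: harmonic_bond, i: 1, j: 2}"), bad)
  expect_error(readTopology(bad), class = "evbscan_config_error")
})
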