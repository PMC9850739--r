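# Domain model: unit conversion, internal-coordinate measurement, scan
# validation.

test_that("Hartree conversion is the pinned linear map", {
  expect_identical(hartreeToKJMol(0), 0)
  expect_identical(hartreeToKJMol(1), 2625.499639479826)
  expect_equal(hartreeToKJMol(-0.5), -1312.749819739913)
  expect_error(hartreeToKJMol(Inf), class = "evbscan_value_error")
  # linearity
  set.seed(11)
  a <- runif(50, -2, 2); b <- runif(50, -2, 2)
  expect_equal(hartreeToKJMol(a + b),
               hartreeToKJMol(a) + hartreeToKJMol(b),
               tolerance = 1e-9)
})

test_that("distance measurement matches elementary cases and the triangle inequality", {
  expect_equal(measureDistance(c(0, 0, 0), c(0, 0, 1.54)), 1.54)
  expect_identical(measureDistance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(measureDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(7)
  for (k in 1:50) {
    p <- matrix(rnorm(9, sd = 3), 3, 3)
    d12 <- measureDistance(p[1, ], p[2, ])
    d23 <- measureDistance(p[2, ], p[3, ])
    d13 <- measureDistance(p[1, ], p[3, ])
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_equal(d12, measureDistance(p[2, ], p[1, ]))
  }
})

test_that("plane angle covers orthogonal, collinear, and degenerate arms", {
  expect_equal(measureAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(measureAngle(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 0)
  expect_equal(measureAngle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_error(measureAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "evbscan_geometry_error")
})

test_that("dihedral obeys the pinned sign convention and range", {
  expect_equal(measureDihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                               c(-1, 0, 1)), 180)
  expect_equal(measureDihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                               c(1, 0, 1)), 0)
  # sign pinned by evaluating the atan2 cross-product formula by hand
  expect_equal(measureDihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                               c(0, 1, 1)), 90)
  expect_error(measureDihedral(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
                               c(0, 1, 1)),
               class = "evbscan_geometry_error")
  # the torsion is invariant under order reversal (it negates under
  # reflection, not reversal) and flips sign on mirroring
  set.seed(13)
  for (k in 1:50) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    d1 <- tryCatch(measureDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   error = function(e) NA)
    if (is.na(d1)) next
    expect_equal(measureDihedral(p[4, ], p[3, ], p[2, ], p[1, ]), d1,
                 tolerance = 1e-9)
    m <- p; m[, 3] <- -m[, 3]   # reflect through the xy plane
    dm <- measureDihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    dd <- abs(d1 + dm) %% 360
    expect_lt(min(dd, 360 - dd), 1e-9)
    expect_gt(d1, -180)
    expect_lte(d1, 180)
  }
})

test_that("all measurements are invariant under rigid motions", {
  set.seed(17)
  for (k in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    move <- randomRigidMotion()
    q <- t(apply(p, 1, move))
    expect_equal(measureDistance(p[1, ], p[2, ]),
                 measureDistance(q[1, ], q[2, ]), tolerance = 1e-9)
    a1 <- tryCatch(measureAngle(p[1, ], p[2, ], p[3, ]),
                   error = function(e) NA)
    if (!is.na(a1))
      expect_equal(a1, measureAngle(q[1, ], q[2, ], q[3, ]),
                   tolerance = 1e-9)
    d1 <- tryCatch(measureDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   error = function(e) NA)
    if (!is.na(d1))
      expect_equal(d1, measureDihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                   tolerance = 1e-9)
  }
})

test_that("validateScan passes a self-consistent scan and reports forced defects", {
  scan <- makeDiatomicScan(c(1.2, 1.5, 1.8), c(-1.01, -1.02, -1.0))
  expect_identical(nrow(validateScan(scan)), 0L)

  # perturb one recorded value by 0.1 A (tolerance 1e-3)
  bad <- scan
  bad@points[[2]]@value <- bad@points[[2]]@value + 0.1
  v <- validateScan(bad, tolDist = 1e-3)
  expect_identical(nrow(v), 1L)
  expect_identical(v$point, 2L)

  # duplicate coordinate values -> ordering violation (bypass constructor)
  dup <- scan
  dup@points[[2]]@value <- dup@points[[1]]@value
  dup@points[[2]]@calculation@geometry$x[2] <- dup@points[[1]]@value
  v2 <- validateScan(dup)
  expect_true(any(grepl("ascending", v2$reason)))

  # unresolvable atom index reported as a violation, not an exception
  oob <- scan
  oob@points[[1]]@inputAtomIds <- c(1L, 9L)
  v3 <- validateScan(oob)
  expect_true(any(grepl("unresolvable", v3$reason)))
})

test_that("class validity guards the core invariants", {
  expect_error(SpeciesRef(iri = "s", inchi = "not-an-inchi",
                          atoms = diatomicSpecies()@atoms),
               regexp = "InChI")
  expect_error(ScanCoordinate("distance", c("a", "b", "c")))
  expect_error(EnergyProfile(c(1, 2, 2.0), c(0, 0, 0)))
  expect_error(EnergyProfile(c(1, 2, 3), c(0, NA, 0)))
  sc <- makeDiatomicScan(c(1.4, 1.5), c(-1, -1.1))
  expect_error(PESScan(iri = "x", species = sc@species,
                       coordinate = sc@coordinate,
                       points = list(sc@points[[1]])),
               regexp = "two scan points")
})
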