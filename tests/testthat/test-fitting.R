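# EVB algebra, state identification, coupling calibration, Morse fitting.

test_that("state identification follows the bond-scan and double-well rules", {
  grid <- 1:5
  single <- EnergyProfile(grid, c(-5, -3, -1, -0.2, 0))
  expect_identical(unname(identifyStates(single, "distance")), c(1L, 5L))

  double <- EnergyProfile(grid, c(0, -4, 2, -3, 1))
  expect_identical(unname(identifyStates(double, "distance")), c(2L, 4L))
  expect_identical(unname(identifyStates(double, "angle")), c(2L, 4L))

  rising <- EnergyProfile(grid, c(0, 1, 2, 3, 4))
  expect_error(identifyStates(rising, "angle"),
               class = "evbscan_state_id_error")
  # distance rule has the maximum-distance fallback
  expect_identical(unname(identifyStates(rising, "distance")), c(1L, 5L))
})

test_that("state identification matches the brute-force oracle on random profiles", {
  set.seed(41)
  for (k in 1:300) {
    e <- randomProfile(15 + k %% 10)
    kind <- if (k %% 2) "distance" else "angle"
    oracle <- bruteStates(e, kind)
    got <- tryCatch(unname(identifyStates(EnergyProfile(seq_along(e), e),
                                          kind)),
                    error = function(err) NULL)
    expect_identical(got, oracle)
  }
})

test_that("state alignment pins the profile to the reference at the anchor", {
  grid <- c(1, 2)
  out <- alignState(EnergyProfile(grid, c(10, 12)), 1,
                    EnergyProfile(grid, c(0, 5)))
  expect_equal(out$shift, -10)
  expect_equal(energies(out$profile), c(0, 2))

  same <- alignState(EnergyProfile(grid, c(0, 7)), 1,
                     EnergyProfile(grid, c(0, 5)))
  expect_equal(same$shift, 0)

  # zero-of-energy convention at the maximum-distance point
  tail0 <- alignState(EnergyProfile(grid, c(3, 8)), 2,
                      EnergyProfile(grid, c(-2, 0)))
  expect_identical(energies(tail0$profile)[2], 0)
})

test_that("evbGround is the lower 2x2 eigenvalue, with its symmetries", {
  expect_equal(evbGround(0, 50, 0), 0)
  expect_equal(evbGround(10, 10, 3), 7)
  expect_equal(evbGround(0, 30, 20), -10)
  set.seed(43)
  for (k in 1:500) {
    e1 <- runif(1, -500, 500); e2 <- runif(1, -500, 500)
    h <- runif(1, -500, 500)
    lam <- min(eigen(matrix(c(e1, h, h, e2), 2, 2),
                     symmetric = TRUE)$values)
    g <- evbGround(e1, e2, h)
    expect_equal(g, lam, tolerance = 1e-10)
    expect_equal(g, evbGround(e2, e1, h))
    expect_equal(g, evbGround(e1, e2, -h))
    expect_lte(g, min(e1, e2) + 1e-12)
    expect_lte(evbGround(e1, e2, 2 * h), g + 1e-12)
  }
})

test_that("pointwise coupling inverts the ground-state relation", {
  expect_equal(pointwiseCoupling(9, 4, 0), 6)
  expect_equal(pointwiseCoupling(5, 2, 2), 0)
  expect_true(is.na(pointwiseCoupling(5, 7, 6)))
  set.seed(47)
  for (k in 1:500) {
    e1 <- runif(1, -200, 200); e2 <- runif(1, -200, 200)
    eref <- min(e1, e2) - runif(1, 0, 100)
    h <- pointwiseCoupling(e1, e2, eref)
    expect_false(is.na(h))
    expect_gte(h, 0)
    expect_equal(evbGround(e1, e2, h), eref, tolerance = 1e-9)
  }
})

test_that("constant coupling is recovered from a noiseless forward model", {
  sys <- makeTwoStateSystem(canonicalTwoStateSpec("constant"))
  fit <- calibrateCoupling(sys$input, "constant", fitShifts = TRUE)
  expect_true(fit@converged)
  expect_equal(fit@coupling@A, 25, tolerance = 1e-6 / 25)
  expect_lt(maxAbsResidual(fit), 1e-6)
  expect_equal(fit@residuals,
               energies(fit@evb) - energies(sys$input@eref))
})

test_that("gaussian coupling parameters are recovered to 1e-4 relative", {
  sys <- makeTwoStateSystem(canonicalTwoStateSpec("gaussian"))
  fit <- calibrateCoupling(sys$input, "gaussian", fitShifts = TRUE)
  expect_true(fit@converged)
  expect_equal(fit@coupling@A, 40, tolerance = 1e-4)
  expect_equal(fit@coupling@r0, 2.2, tolerance = 1e-4)
  expect_equal(fit@coupling@w, 0.3, tolerance = 1e-4)
})

test_that("identical states need no coupling", {
  r <- seq(1, 3, length.out = 20)
  e <- 30 * (r - 2)^2
  prof <- EnergyProfile(r, e)
  input <- EVBInput(prof, prof, prof)
  fit <- calibrateCoupling(input, "constant", shifts = c(0, 0))
  expect_equal(fit@coupling@A, 0, tolerance = 1e-8)
  expect_lt(maxAbsResidual(fit), 1e-8)
})

test_that("calibration is infeasible when the reference never dips below the states", {
  r <- seq(1, 2, length.out = 10)
  input <- EVBInput(EnergyProfile(r, rep(0, 10)),
                    EnergyProfile(r, rep(0, 10)),
                    EnergyProfile(r, rep(5, 10)))
  expect_error(calibrateCoupling(input, "constant", shifts = c(0, 0)),
               class = "evbscan_calibration_infeasible_error")
})

test_that("noisy constant-coupling recovery stays within 3 sigma / sqrt(n)", {
  bound <- 3 * 1 / sqrt(40)
  hits <- 0L
  for (seed in 1:25) {
    sys <- makeTwoStateSystem(canonicalTwoStateSpec("constant", sigma = 1,
                                                    seed = seed))
    fit <- calibrateCoupling(sys$input, "constant", shifts = c(0, 0))
    if (abs(fit@coupling@A - 25) <= bound) hits <- hits + 1L
  }
  expect_gte(hits, 23L)   # >= 95% of runs (full 100-seed study in acceptance)
})

test_that("Morse parameters are recovered from noiseless samples", {
  r <- seq(1.1, 5.0, length.out = 60)
  e <- 350 * (1 - exp(-1.9 * (r - 1.53)))^2
  fit <- fitMorse(EnergyProfile(r, e))
  expect_true(fit@converged)
  expect_equal(fit@De, 350, tolerance = 1e-6)
  expect_equal(fit@re, 1.53, tolerance = 1e-6)
  expect_equal(fit@a, 1.9, tolerance = 1e-6)
  expect_equal(fit@V0, 0, tolerance = 1e-4)
  # the model value at re is V0: residual at the minimum sample is bounded
  # by the global max residual
  expect_lte(abs(fit@residuals[which.min(e)]), maxAbsResidual(fit))
})

test_that("profiles without a well are rejected", {
  r <- seq(1, 2, length.out = 10)
  expect_error(fitMorse(EnergyProfile(r, rep(3, 10))),
               class = "evbscan_no_well_error")
  expect_error(fitMorse(EnergyProfile(r, seq(5, 1, length.out = 10))),
               class = "evbscan_no_well_error")
})

test_that("fit results convert to fitting records and survive the graph", {
  sys <- makeTwoStateSystem(canonicalTwoStateSpec("constant"))
  fit <- calibrateCoupling(sys$input, "constant", fitShifts = TRUE)
  rec <- asFittingRecord(fit, "unit test")
  expect_identical(rec@methodName, "EVB-2state-constant")
  expect_setequal(rec@parameters$name, c("A", "s1", "s2"))
  expect_identical(nrow(rec@parameters), 3L)

  r <- seq(1.1, 5.0, length.out = 60)
  mfit <- fitMorse(EnergyProfile(r, 350 * (1 - exp(-1.9 * (r - 1.53)))^2))
  mrec <- asFittingRecord(mfit, "unit test")
  expect_setequal(mrec@parameters$name, c("a", "De", "re", "V0"))

  scan <- makeDiatomicScan(c(1.4, 1.6), c(-1.0, -1.1))
  g <- attachFitting(toGraph(scan), iri(scan), mrec)
  back <- fromGraph(g, iri(scan))
  expect_identical(back@fittings[[1]]@parameters$value,
                   mrec@parameters$value)
})

test_that("gaussian record carries the coupling shape parameters", {
  sys <- makeTwoStateSystem(canonicalTwoStateSpec("gaussian"))
  fit <- calibrateCoupling(sys$input, "gaussian", fitShifts = TRUE)
  rec <- asFittingRecord(fit)
  expect_setequal(rec@parameters$name, c("A", "r0", "w", "s1", "s2"))
})
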