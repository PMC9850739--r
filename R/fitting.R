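## Numerical core of the force-field fitting workflow: state
## identification on the reference PES, state alignment, EVB ground-state
## energies, coupling calibration, and Morse-potential fitting. All
## energies here are kJ/mol.

#' @rdname accessors
setMethod("maxAbsResidual", "EVBFitResult", function(x) max(abs(x@residuals)))
#' @rdname accessors
setMethod("maxAbsResidual", "MorseFit", function(x) max(abs(x@residuals)))

setMethod("show", "EVBFitResult", function(object) {
  cat("EVB two-state coupling fit\n")
  show(object@coupling)
  cat(sprintf("  shifts: s1 = %.6g, s2 = %.6g kJ/mol\n", object@s1, object@s2))
  cat(sprintf("  max |residual| = %.6g kJ/mol over %d points; converged: %s\n",
              maxAbsResidual(object), length(object@residuals),
              object@converged))
})

setMethod("show", "MorseFit", function(object) {
  cat(sprintf(
    "Morse fit: De = %.6g kJ/mol, re = %.6g, a = %.6g, V0 = %.6g\n",
    object@De, object@re, object@a, object@V0))
  cat(sprintf("  max |residual| = %.6g kJ/mol; converged: %s\n",
              maxAbsResidual(object), object@converged))
})

## --- state identification ------------------------------------------------

localMinimaIdx <- function(e) {
  n <- length(e)
  idx <- integer(0)
  if (e[1] < e[2]) idx <- c(idx, 1L)
  if (n > 2)
    for (i in 2:(n - 1))
      if (e[i] < e[i - 1] && e[i] < e[i + 1]) idx <- c(idx, i)
  if (e[n] < e[n - 1]) idx <- c(idx, n)
  idx
}

#' Identify reactant and product states on a reference PES
#'
#' Chemical states are read off the reference profile: local minima are
#' candidate states; the lowest-energy minimum is the reactant. For a
#' distance (bond) scan with exactly one local minimum, the point at the
#' maximum scan distance (the last grid point) is taken as the product
#' state; otherwise the second-lowest local minimum is the product. A
#' profile with a single minimum on an angle or dihedral grid has no
#' product rule and raises a state-identification error.
#'
#' @param profile an [EnergyProfile] (length >= 3)
#' @param kind coordinate kind (`"distance"`, `"angle"`, `"dihedral"`)
#' @return named integer vector `c(reactant =, product =)` of 1-based
#'   grid indices
#' @export
identifyStates <- function(profile, kind = "distance") {
  e <- energies(profile)
  if (length(e) < 3)
    pesStop("state_id", "profile too short for state identification")
  mins <- localMinimaIdx(e)
  if (!length(mins))
    pesStop("state_id", "no local minimum on the reference profile")
  reactant <- mins[which.min(e[mins])]
  if (length(mins) == 1L) {
    if (kind != "distance")
      pesStop("state_id", "single-minimum profile on a ", kind,
              " scan: no product-state rule (supply anchors explicitly)")
    product <- length(e)
    if (product == reactant)
      pesStop("state_id", "single minimum at the maximum-distance point")
  } else {
    rest <- mins[mins != reactant]
    product <- rest[which.min(e[rest])]
  }
  c(reactant = reactant, product = product)
}

#' Shift a state profile to agree with the reference at an anchor
#'
#' The zero-of-energy convention: each classical state is shifted by a
#' constant so that it matches the reference energy at its own state
#' point (e.g. the maximum-distance point for the dissociated state of a
#' bond scan).
#'
#' @param e an [EnergyProfile] (the state energies)
#' @param anchorIndex 1-based grid index of the state point
#' @param eref the reference [EnergyProfile] on the same grid
#' @return list with `profile` (the shifted [EnergyProfile]) and
#'   `shift` (kJ/mol); `profile` matches `eref` exactly at the anchor
#' @export
alignState <- function(e, anchorIndex, eref) {
  if (anchorIndex < 1 || anchorIndex > length(e@energy))
    pesStop("value", "anchor index out of range")
  shift <- eref@energy[anchorIndex] - e@energy[anchorIndex]
  list(profile = EnergyProfile(e@coordinate, e@energy + shift, e@unit),
       shift = shift)
}

## --- EVB algebra ---------------------------------------------------------

#' EVB ground-state energy of a 2x2 Hamiltonian
#'
#' Lower eigenvalue of `[[e1, h12], [h12, e2]]`:
#' `(e1 + e2)/2 - sqrt((e1 - e2)^2 + 4 h12^2)/2`. Always at or below
#' `min(e1, e2)`. Vectorized.
#'
#' @param e1,e2 diagonal state energies (kJ/mol)
#' @param h12 off-diagonal coupling (kJ/mol)
#' @return ground-state energy (kJ/mol)
#' @export
evbGround <- function(e1, e2, h12) {
  0.5 * (e1 + e2) - 0.5 * sqrt((e1 - e2)^2 + 4 * h12^2)
}

#' Pointwise coupling that reproduces a reference energy
#'
#' Inverts the ground-eigenvalue relation: when
#' `eref <= min(e1, e2)`, `h12 = sqrt((e1 - eref)(e2 - eref))` satisfies
#' `evbGround(e1, e2, h12) == eref`. When the reference lies above the
#' lower diagonal the inversion has no real solution and `NA` is
#' returned (a value, not an error). Vectorized.
#'
#' @param e1,e2 state energies (kJ/mol)
#' @param eref reference energy (kJ/mol)
#' @return `h12 >= 0`, or `NA` where undefined
#' @export
pointwiseCoupling <- function(e1, e2, eref) {
  ok <- eref <= pmin(e1, e2)
  h <- rep(NA_real_, length(ok))
  h[ok] <- sqrt((e1[ok] - eref[ok]) * (e2[ok] - eref[ok]))
  h
}

## --- calibration ---------------------------------------------------------

couplingFromTheta <- function(kind, th) {
  if (kind == "constant") CouplingModel("constant", A = th[[1]])
  else CouplingModel("gaussian", A = th[[1]], r0 = th[[2]], w = th[[3]])
}

#' @describeIn couplingValues constant model returns `A` everywhere;
#'   gaussian returns `A exp(-(r - r0)^2 / (2 w^2))`.
#' @export
setMethod("couplingValues", "CouplingModel", function(model, r) {
  if (model@kind == "constant") rep(model@A, length(r))
  else model@A * exp(-(r - model@r0)^2 / (2 * model@w^2))
})

## Deterministic initialization from pointwise-coupling statistics.
initCoupling <- function(kind, r, h) {
  def <- which(!is.na(h) & h > 0)
  if (!length(def)) {
    if (all(is.na(h)))
      pesStop("calibration_infeasible",
              "pointwise coupling undefined at every grid point")
    def <- which(!is.na(h))
  }
  if (kind == "constant") return(stats::median(h[def]))
  pk <- def[which.max(h[def])]
  A0 <- h[pk]
  r00 <- r[pk]
  wsum <- sum(h[def])
  w0 <- sqrt(sum(h[def] * (r[def] - r00)^2) / wsum)
  if (!is.finite(w0) || w0 <= 0) w0 <- (max(r) - min(r)) / 10
  c(A0, r00, w0)
}

#' Calibrate the EVB coupling against a reference profile
#'
#' Minimizes the sum of squared deviations between the EVB ground-state
#' profile `evbGround(E1 + s1, E2 + s2, H12(r))` and the reference, over
#' the coupling parameters (and optionally the per-state shifts).
#'
#' States are identified on the reference with [identifyStates()] unless
#' `anchors` is given; each state is anchored ([alignState()]) at the
#' anchor index where its own energy is lower, which fixes the initial
#' shifts. Shift handling: `fitShifts = FALSE` keeps the anchored (or
#' supplied) shifts fixed; `fitShifts = TRUE` co-optimizes them starting
#' from the anchored values. Initialization of the coupling parameters is
#' deterministic, from [pointwiseCoupling()] statistics (median for the
#' constant model; peak height/location and width moment for the
#' gaussian). Optimization is deterministic Levenberg-Marquardt least
#' squares with a fixed iteration budget; non-convergence is reported in
#' the result, not thrown.
#'
#' @param input an [EVBInput]
#' @param kind `"constant"` or `"gaussian"` coupling
#' @param anchors optional integer(2): grid indices of the two state
#'   points (reactant, product)
#' @param shifts optional numeric(2): fixed shifts `c(s1, s2)` (kJ/mol),
#'   bypassing anchored alignment
#' @param fitShifts co-optimize `s1`, `s2`
#' @param coordKind coordinate kind passed to [identifyStates()]
#' @param control list: `maxit` (iteration budget, default 1000) and
#'   `ftol` (objective tolerance, default 1e-15)
#' @return an [EVBFitResult]
#' @export
calibrateCoupling <- function(input, kind = c("constant", "gaussian"),
                              anchors = NULL, shifts = NULL,
                              fitShifts = FALSE, coordKind = "distance",
                              control = list()) {
  kind <- match.arg(kind)
  maxit <- control$maxit %||% 1000L
  ftol <- control$ftol %||% 1e-15
  r <- input@eref@coordinate
  e1 <- input@e1@energy
  e2 <- input@e2@energy
  eref <- input@eref@energy

  if (is.null(shifts)) {
    if (is.null(anchors))
      anchors <- unname(identifyStates(input@eref, kind = coordKind))
    # state 1 is anchored where its own energy is lower of the two anchors
    a1 <- if (e1[anchors[1]] <= e1[anchors[2]]) anchors[1] else anchors[2]
    a2 <- if (a1 == anchors[1]) anchors[2] else anchors[1]
    s1 <- eref[a1] - e1[a1]
    s2 <- eref[a2] - e2[a2]
  } else {
    s1 <- shifts[1]; s2 <- shifts[2]
  }

  ## Deterministic multistart over shift initializations. Anchored shifts
  ## are the default start, but when the coupling itself carves the
  ## reference minimum (|H12| comparable to the diabatic gap) the anchored
  ## guess can be far off, so two scale-matching starts are tried as well;
  ## the best final objective wins (first-best tie break). With fixed
  ## shifts only the supplied pair is used.
  shiftStarts <- if (fitShifts) {
    unique(list(
      c(s1, s2),
      c(min(eref) - min(e1), min(eref) - min(e2)),
      c(stats::median(eref - e1), stats::median(eref - e2))))
  } else list(c(s1, s2))

  nCoup <- if (kind == "constant") 1L else 3L
  lower <- if (kind == "constant") 0 else c(0, min(r) - diff(range(r)),
                                            1e-8)
  upper <- if (kind == "constant") Inf else c(Inf, max(r) + diff(range(r)),
                                              Inf)
  if (fitShifts) {
    lower <- c(lower, -Inf, -Inf)
    upper <- c(upper, Inf, Inf)
  }

  resFn <- function(par) {
    cs1 <- if (fitShifts) par[nCoup + 1] else s1
    cs2 <- if (fitShifts) par[nCoup + 2] else s2
    h <- couplingValues(couplingFromTheta(kind, par[seq_len(nCoup)]), r)
    evbGround(e1 + cs1, e2 + cs2, h) - eref
  }

  ## Analytic Jacobian of the ground eigenvalue
  ## lambda = (a+b)/2 - s/2, s = sqrt((a-b)^2 + 4 h^2):
  ## d/da = (1 - (a-b)/s)/2, d/db = (1 + (a-b)/s)/2, d/dh = -2h/s.
  jacFn <- function(par) {
    cs1 <- if (fitShifts) par[nCoup + 1] else s1
    cs2 <- if (fitShifts) par[nCoup + 2] else s2
    a <- e1 + cs1; b <- e2 + cs2
    h <- couplingValues(couplingFromTheta(kind, par[seq_len(nCoup)]), r)
    s <- sqrt((a - b)^2 + 4 * h^2)
    s[s < 1e-300] <- 1e-300
    dldh <- -2 * h / s
    J <- if (kind == "constant") {
      g <- exp(0 * r)   # dh/dA = 1
      cbind(dldh * g)
    } else {
      A <- par[1]; r0 <- par[2]; w <- par[3]
      g <- exp(-(r - r0)^2 / (2 * w^2))
      cbind(dldh * g,
            dldh * A * g * (r - r0) / w^2,
            dldh * A * g * (r - r0)^2 / w^3)
    }
    if (fitShifts) {
      d <- (a - b) / s
      J <- cbind(J, 0.5 * (1 - d), 0.5 * (1 + d))
    }
    J
  }

  runLM <- function(par0) minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resFn, jac = jacFn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(1024L, maxit), ftol = ftol, ptol = 1e-15))

  fit <- NULL
  for (ss in shiftStarts) {
    h0 <- pointwiseCoupling(e1 + ss[1], e2 + ss[2], eref)
    th0 <- tryCatch(initCoupling(kind, r, h0), error = function(e) NULL)
    if (is.null(th0)) next
    par0 <- if (fitShifts) c(th0, ss) else th0
    cand <- runLM(par0)
    # polish restarts: re-running from the optimum resets the trust
    # region and walks down sloppy valleys (A vs shifts is one)
    for (k in 1:4) {
      again <- runLM(cand$par)
      if (again$deviance >= cand$deviance * (1 - 1e-12)) { cand <- again; break }
      cand <- again
    }
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  if (is.null(fit))
    pesStop("calibration_infeasible",
            "pointwise coupling undefined at every grid point")
  par <- unname(fit$par)
  coup <- couplingFromTheta(kind, par[seq_len(nCoup)])
  fs1 <- if (fitShifts) par[nCoup + 1] else s1
  fs2 <- if (fitShifts) par[nCoup + 2] else s2
  res <- resFn(par)
  evb <- EnergyProfile(r, eref + res, input@eref@unit)
  new("EVBFitResult", coupling = coup, s1 = fs1, s2 = fs2, evb = evb,
      reference = input@eref, residuals = res,
      objective = sum(res^2), converged = fit$info %in% 1:4)
}

## --- Morse fitting -------------------------------------------------------

morseEnergy <- function(r, De, a, re, V0 = 0)
  De * (1 - exp(-a * (r - re)))^2 + V0

#' Fit a Morse potential to an energy profile
#'
#' Least-squares fit of `V(r) = De (1 - exp(-a (r - re)))^2 + V0`.
#' Initialization is deterministic: `re` from the grid argmin, `De` from
#' the right-tail plateau minus the minimum, `a` from the finite-
#' difference curvature at the minimum (via `V''(re) = 2 De a^2`), `V0`
#' from the minimum energy. The profile must have an interior minimum
#' with a right tail above it; a monotone or flat profile raises a
#' no-well error.
#'
#' @param profile an [EnergyProfile] (kJ/mol)
#' @param control list: `maxit`, `ftol` as in [calibrateCoupling()]
#' @return a [MorseFit]
#' @export
fitMorse <- function(profile, control = list()) {
  r <- profile@coordinate
  e <- profile@energy
  imin <- which.min(e)
  if (imin == length(e) || e[length(e)] <= e[imin] ||
      max(e) - min(e) < .Machine$double.eps * 100)
    pesStop("no_well", "profile has no interior well with a rising tail")

  V0 <- e[imin]
  De0 <- max(e[length(e)] - V0, 1e-6)
  re0 <- r[imin]
  # curvature at the minimum from the nearest neighbours
  lo <- max(1L, imin - 1L); hi <- min(length(e), imin + 1L)
  if (hi - lo == 2L) {
    h1 <- r[imin] - r[lo]; h2 <- r[hi] - r[imin]
    k2 <- 2 * (h1 * e[hi] + h2 * e[lo] - (h1 + h2) * e[imin]) /
      (h1 * h2 * (h1 + h2))
  } else k2 <- NA_real_
  a0 <- if (is.finite(k2) && k2 > 0) sqrt(k2 / (2 * De0))
        else 2 / (r[length(r)] - re0)

  resFn <- function(p) morseEnergy(r, p[1], p[3], p[2], p[4]) - e
  fit <- minpack.lm::nls.lm(
    par = c(De0, re0, a0, V0),
    lower = c(1e-12, min(r), 1e-12, -Inf),
    fn = resFn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(1024L, control$maxit %||% 1000L),
      ftol = control$ftol %||% 1e-15, ptol = 1e-15))
  p <- unname(fit$par)
  res <- resFn(p)
  new("MorseFit", De = p[1], re = p[2], a = p[3], V0 = p[4],
      fitted = e + res, residuals = res, converged = fit$info %in% 1:4)
}

## --- fitting records -----------------------------------------------------

#' @describeIn asFittingRecord EVB result: method name
#'   `"EVB-2state-<kind>"`, parameters `A`, `s1`, `s2` for the constant
#'   model plus `r0`, `w` for the gaussian.
#' @export
setMethod("asFittingRecord", "EVBFitResult",
          function(x, methodSource = "evbscan") {
  cp <- x@coupling
  unitR <- x@reference@unit
  params <- data.frame(name = c("A", "s1", "s2"),
                       value = c(cp@A, x@s1, x@s2),
                       unit = rep("kJ/mol", 3), stringsAsFactors = FALSE)
  if (cp@kind == "gaussian")
    params <- rbind(params,
                    data.frame(name = c("r0", "w"), value = c(cp@r0, cp@w),
                               unit = rep(unitR, 2), stringsAsFactors = FALSE))
  FittingRecord(methodName = paste0("EVB-2state-", cp@kind),
                methodSource = methodSource, parameters = params)
})

#' @describeIn asFittingRecord Morse fit: method name
#'   `"MorsePotential"`, parameters `De`, `re`, `a`, `V0`.
#' @export
setMethod("asFittingRecord", "MorseFit",
          function(x, methodSource = "evbscan") {
  FittingRecord(
    methodName = "MorsePotential", methodSource = methodSource,
    parameters = data.frame(
      name = c("De", "re", "a", "V0"),
      value = c(x@De, x@re, x@a, x@V0),
      unit = c("kJ/mol", "angstrom", "1/angstrom", "kJ/mol"),
      stringsAsFactors = FALSE))
})

#' Build an EVB input from a scan and two state profiles
#'
#' Converts the scan's SCF energies from Hartree to kJ/mol (the one place
#' this conversion happens on the fitting path) and re-zeros the
#' reference at `zeroAt` (by default the maximum-distance point, the
#' customary zero of energy for bond scans). The state profiles must be
#' on the scan's coordinate grid.
#'
#' @param scan a [PESScan]
#' @param e1,e2 [EnergyProfile]s of the two classical states (kJ/mol)
#' @param zeroAt `"last"`, `"first"`, a grid index, or `NA` to keep
#'   absolute energies
#' @return an [EVBInput]
#' @export
evbInputFromScan <- function(scan, e1, e2, zeroAt = "last") {
  r <- coordinateValues(scan)
  eref <- hartreeToKJMol(scfEnergies(scan))
  iz <- if (identical(zeroAt, "last")) length(eref)
        else if (identical(zeroAt, "first")) 1L
        else if (is.numeric(zeroAt)) as.integer(zeroAt)
        else NA_integer_
  if (!is.na(iz)) eref <- eref - eref[iz]
  EVBInput(e1 = e1, e2 = e2,
           eref = EnergyProfile(r, eref, scan@coordinate@unit))
}
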