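---
title: "PES scans, semantic scan graphs, and EVB coupling calibration"
author: "evbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PES scans, semantic scan graphs, and EVB coupling calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evbscan)
```

# The problem

A one-dimensional potential energy surface (PES) scan samples the
electronic energy of a molecular system along one internal coordinate — a
bond distance, a plane angle, or a dihedral — with all other degrees of
freedom either re-optimized at each point (a *relaxed* scan) or held fixed
(a *rigid* scan). Such scans are the reference data for parametrizing
*reactive* force fields: classical force fields cannot describe bond
breaking, but the empirical valence bond (EVB) construction couples two
ordinary, non-reactive force fields — one per chemical state — into a
reactive surface whose quality is set by how well the coupling term is
calibrated against the quantum-mechanical scan.

`evbscan` covers this workflow end to end at desk scale:

1. **Parse** quantum-chemistry scan logs (a documented dialect modelled on
   Gaussian-style output) into scan objects with per-point geometries and
   SCF energies.
2. **Represent** scans semantically as RDF triples — scans linked to
   species (by atom IRIs and InChI) and to per-point calculation records —
   with Turtle serialization and the two canonical query patterns
   (scans-by-InChI, per-point energies).
3. **Evaluate** user-declared classical force-field topologies along the
   scan geometries.
4. **Calibrate** the EVB coupling (constant or Gaussian) so the EVB ground
   state reproduces the reference profile, or fit a Morse potential, and
   attach the resulting parameters back to the scan graph.

# The model

## EVB two-state Hamiltonian

Each chemical state contributes a classical energy profile $E_1(r)$,
$E_2(r)$ along the scan coordinate $r$. The EVB Hamiltonian at each point
is the symmetric $2\times 2$ matrix

$$H(r) = \begin{pmatrix} E_1(r) + s_1 & H_{12}(r) \\ H_{12}(r) & E_2(r) + s_2 \end{pmatrix},$$

whose lower eigenvalue

$$E_\mathrm{EVB}(r) = \tfrac12\!\left(E_1 + s_1 + E_2 + s_2\right)
  - \tfrac12\sqrt{(E_1 + s_1 - E_2 - s_2)^2 + 4 H_{12}^2}$$

is the reactive ground-state surface (`evbGround()`). The constant shifts
$s_1, s_2$ place each force field on the reference energy scale; the
coupling $H_{12}$ is what calibration determines. Two functional forms are
supported: a constant $H_{12}(r) = A$ and a single Gaussian
$H_{12}(r) = A\,e^{-(r-r_0)^2/2w^2}$. Both are standard EVB practice and
exercise the full calibration machinery; they are this package's own
choices, not an attribution to any external reference implementation.

Inverting the eigenvalue relation gives the *pointwise* coupling
(`pointwiseCoupling()`): whenever the reference lies at or below both
diagonal energies, $h = \sqrt{(E_1 - E_\mathrm{ref})(E_2 - E_\mathrm{ref})}$
reproduces the reference exactly at that point. Points where the reference
lies above the lower diagonal have no real solution and are marked
undefined (a value, not an error); the defined values seed the optimizer.

## State identification and the zero of energy

States are read off the reference profile (`identifyStates()`): local
minima are candidate states and the lowest is the reactant. For a distance
(bond) scan with exactly one local minimum, the maximum-distance grid point
is the product state — the dissociated asymptote of a bond-breaking scan.
Other coordinate kinds have no such fallback; a single-minimum angle or
dihedral profile requires explicit anchors. Boundary points count as local
minima when they are lower than their single neighbour; interior minima use
strict comparisons, so an exact plateau tie (possible only on synthetic
data) has no minimum at either tied point.

Each state is anchored to the reference at its own state point
(`alignState()`): the shift is chosen so state and reference agree exactly
there. This generalizes the customary zero-of-energy convention for bond
scans, where the dissociated state is zeroed at the maximum scanned
distance.

## Calibration

`calibrateCoupling()` minimizes
$\sum_i \left(E_\mathrm{EVB}(r_i) - E_\mathrm{ref}(r_i)\right)^2$ over the
coupling parameters, and optionally over $(s_1, s_2)$ (`fitShifts = TRUE`).
The numerical choices:

* **Optimizer**: Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
  with the analytic Jacobian of the ground eigenvalue
  ($\partial\lambda/\partial a = (1 - \Delta/s)/2$,
  $\partial\lambda/\partial h = -2h/s$ with $\Delta = a - b$,
  $s = \sqrt{\Delta^2 + 4h^2}$). The analytic Jacobian matters: the
  $(A, s_1, s_2)$ valley is sloppy, and finite-difference Jacobians stall
  around $10^{-6}$ relative parameter error where the analytic one reaches
  machine precision. Deterministic, no stochastic restarts; iteration
  budget 1024 per start, objective tolerance $10^{-15}$.
* **Initialization**: deterministic, from pointwise-coupling statistics —
  the median of defined values for the constant model; peak height,
  peak location, and a width moment for the Gaussian.
* **Shift multistart**: when shifts are co-fitted, three deterministic
  starts are tried (anchored shifts; well-depth matching
  $s_i = \min E_\mathrm{ref} - \min E_i$; median offset
  $s_i = \mathrm{median}(E_\mathrm{ref} - E_i)$) and the lowest final
  objective wins, with a first-best tie break. The extra starts guard the
  regime where the coupling itself carves the reference minimum (strong
  mixing, $|H_{12}|$ comparable to the diabatic gap), where anchoring at
  reference minima initializes far from the optimum and plain descent can
  stall in an $A = 0$ local minimum.
* Non-convergence within the budget is reported in the result
  (`converged = FALSE`), never thrown; a reference that never dips below
  the lower diagonal anywhere is a calibration-infeasibility error.

`fitMorse()` fits $V(r) = D_e\,(1 - e^{-a(r - r_e)})^2 + V_0$ by the same
Levenberg–Marquardt route, with deterministic initialization: $r_e$ from
the grid argmin, $D_e$ from the right-tail value minus the minimum, $a$
from the finite-difference curvature at the minimum via
$V''(r_e) = 2 D_e a^2$, and $V_0$ from the minimum. Profiles without an
interior well and a rising right tail are rejected (no-well error).

# Units and conventions

* Lengths in Ångström, angles in degrees, stored SCF energies in Hartree,
  everything on the fitting path in kJ/mol. The conversion constant is
  pinned bit-exactly in one place: `HARTREE_KJ_PER_MOL` =
  2625.499639479826.
* Atom indices are 1-based wherever they are user-visible (log files,
  `inputAtomIds`); 0-based only as the `orderIndex` provenance of sorted
  scan points.
* Dihedrals are signed, in $(-180, 180]$, IUPAC sign convention (clockwise
  positive viewed down the central bond). Under this convention the
  torsion is *invariant* under atom-order reversal and negates under
  reflection; the test suite pins the sign with the worked configuration
  `(1,0,0), (0,0,0), (0,0,1), (0,1,1)` $\to +90°$.
* Scan points are re-sorted ascending by coordinate value at assembly;
  duplicate values (within $10^{-6}$ coordinate units) collapse keeping
  the lowest SCF energy; the original file order survives in each point's
  provenance tag.

# The log dialect

The parser consumes a minimal, versioned dialect replicating the anchor
strings of Gaussian-style output: `Input orientation:` /
`Standard orientation:` geometry tables, `SCF Done:` energy lines,
`Optimization completed.` markers for relaxed steps, an optional
modredundant-style scan header (`B 1 2 S 10 0.2`), and an optional
`Charge = … Multiplicity = …` line. Real logs using these anchors parse
too, but only the documented dialect is guaranteed. Parsing rules that
matter:

* a relaxed step's energy is the last `SCF Done:` before its
  `Optimization completed.` marker, and its geometry the last orientation
  block before that energy, preferring `Input orientation:` (stable atom
  order) over `Standard orientation:`;
* trailing SCF work after the final marker becomes a step flagged
  `converged = FALSE` — retained for provenance, excluded from assembly;
* energies are stored exactly as printed (`scfText`) alongside the parsed
  double, so log and graph round trips are bit-exact;
* coordinate values are always recomputed from the geometry via the atom
  map; the scan header is a cross-check, not a source of values.

# The graph mapping

`toGraph()` emits a deterministic, blank-node-free triple set: the scan
node typed `PotentialEnergySurfaceScan` with `onSpecies`/`hasFragment`
links, one coordinate node typed by kind with one `hasScanAtom` triple per
atom (plus an ordered-atom literal, since RDF sets lose order), and per
point a `ScanPoint` with its value+unit node, `hasInputAtomIDs` literal,
and a calculation node carrying the SCF energy (lexical form = as
printed), geometry, method, and basis. The triple count is an affine
function of (points, atoms, fittings) documented in the mapping table in
`R/kg-mapping.R`, and the test suite pins it. Numeric literals use
shortest round-trip decimals. All term IRIs live in a configurable
`VocabularyMap`; the defaults are package-chosen surrogates, not asserted
upstream IRIs. Because every node IRI is minted deterministically,
`attachFitting()` is idempotent and graph isomorphism reduces to set
equality.

Queries: `findScansByInChI()` and `pointEnergies()` implement the two
canonical federated patterns directly; `sparqlSelect()` evaluates the
corresponding SPARQL SELECT templates (basic graph patterns only — no
`OPTIONAL`, `FILTER`, or property paths) and the tests cross-check the two
routes against each other. The Turtle writer emits a deterministic,
prefix-compacted serialization; an independent RDF parser (Python rdflib)
is used in the test suite as an external oracle for its validity.

# Force-field evaluation

`ffEnergy()` evaluates explicit, user-declared topologies — automatic atom
typing is out of scope, matching the user-defined-topology path of the
agent workflow. Functional forms: harmonic bond $\tfrac12 k (r - r_0)^2$,
Morse bond, harmonic angle $\tfrac12 k_\theta (\theta - \theta_0)^2$ (in
radians), OPLS-style cosine torsion $\tfrac{V_n}{2}(1 + \cos(n\phi -
\gamma))$, 12-6 Lennard-Jones with Lorentz–Berthelot combination, and
Coulomb with $f = 138.935458$ kJ mol⁻¹ Å e⁻². Exclusions: 1-2 and 1-3
pairs excluded, 1-4 pairs scaled 0.5 for both LJ and Coulomb
(configurable per topology). No cutoffs and no periodic boundary
conditions: these are gas-phase cluster scans. Whether a dimer case should
use intermolecular terms only is left to the topology author; the YAML
schema expresses either choice and no default is asserted.

# The synthetic study system

All recovery tests run on forward-generated data with known ground truth
(`makeTwoStateSystem()`): $E_\mathrm{ref}$ is computed *exactly* as
`evbGround(E1 + s1, E2 + s2, H12(r))` plus optional seeded Gaussian noise,
so any calibration error is attributable to the calibrator.

The canonical conditions (`canonicalTwoStateSpec()`): a 40-point distance
grid on 1.2–3.4 Å; two harmonic states with $k = 15$ kJ/mol/Å², minima at
1.6 and 2.9 Å; zero true shifts; constant coupling $A = 25$ kJ/mol or
Gaussian $(A, r_0, w) = (40, 2.2, 0.3)$; noise $\sigma = 1$ kJ/mol in the
robustness study. Two deliberate choices:

* **Stiffness.** $k = 15$ keeps the diabatic gap commensurate with $2A$
  across the whole grid, so the sensitivity
  $\partial E_\mathrm{EVB}/\partial A = 2H_{12}/\sqrt{\Delta^2 + 4H_{12}^2}$
  stays near unity at every point. That is the strong-mixing regime EVB
  coupling calibration operates in, and it is the regime in which the
  $\sigma/\sqrt{n}$ error scaling of the noise study holds: the
  least-squares error of $\hat A$ is $\sigma/\sqrt{\sum_i g_i^2}$, which
  only approaches $\sigma/\sqrt{n}$ when $g_i \approx 1$. With stiff
  states (large $k$) most grid points carry no information about $A$ and
  the same bound would be unattainable by any estimator.
* **Asymmetry.** The second well sits at 2.9 Å (not the grid-symmetric
  3.0) so the diabatic crossing is not the exact midpoint of the grid;
  at the midpoint the reference develops an exact two-point plateau tie
  and the strict local-minimum rule sees no interior minimum. Real scans
  do not produce exact ties; synthetic grids can.

The ethanol-like worked example (`makeEthanolLikeScan()`) is a 9-atom
C–C–O skeleton with tetrahedral hydrogens, scanned over 12 C–C distances
from exactly 1.51 Å past 5 Å, with energies following a Morse curve
($D_e = 350$ kJ/mol, $r_e = 1.53$ Å, $a = 1.9$ Å⁻¹) on a constant
electronic baseline. It is labelled synthetic throughout: it mimics the
*shape* of a real ethanol bond scan for testing the pipeline, and is not
quantum-chemistry data.

**What passing tests do and do not show.** The synthetic generator spans
the forward model exactly, so recovery tests demonstrate the calibrator's
correctness and precision, not its accuracy on real systems: real
reference profiles contain model error (the classical states cannot
reproduce DFT exactly for any coupling), optimizer-relevant noise
structure, and basis/method artifacts that no parameter of this generator
emulates. Residuals of several kJ/mol against real scans are expected and
are reported, not hidden, by the max-residual diagnostic.

# Problem sizes and runtime

The suite runs the eigensolver cross-check on $10^4$ random matrices, the
inversion identity on $10^4$ triples, the state-identification comparison
on 1000 random profiles, the noise study on 100 seeds, and the full
parser/graph round trips on the 12-point fixtures; the whole test suite
completes in well under a minute on one CPU, and
`scripts/acceptance.R` recomputes the same quantities from scratch in a
few seconds.

# Known limitations

* Two states only; no multi-state EVB, no environment-dependent
  couplings, no MD time stepping, and no uncertainty quantification of
  fitted parameters.
* One scan coordinate per scan (1D); multidimensional scans are out of
  scope.
* The SPARQL evaluator covers basic graph patterns only, sufficient for
  the two shipped templates.
* The Turtle reader accepts the subset the writer emits (plus bare
  numerals and `a`); it is not a general-purpose RDF parser.
* Topologies are always explicit; there is no automatic atom typing, and
  no force-field parameter libraries ship with the package.
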