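## Internal-coordinate measurements on Cartesian geometries (Angstrom in,
## Angstrom / degrees out) and the energy unit conversion.

#' Convert Hartree to kJ/mol
#'
#' Linear conversion by the molar Hartree [HARTREE_KJ_PER_MOL]. Log files
#' report SCF energies in Hartree; all fitting and residual reporting is
#' in kJ/mol.
#'
#' @param e energy in Hartree (vectorized)
#' @return energy in kJ/mol
#' @examples
#' hartreeToKJMol(1)        # 2625.4996...
#' hartreeToKJMol(-0.5)
#' @export
hartreeToKJMol <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)))
    pesStop("value", "hartreeToKJMol requires finite numeric input")
  e * HARTREE_KJ_PER_MOL
}

asPoint <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p)))
    pesStop("value", "a point must be 3 finite Cartesian coordinates")
  p
}

#' Distance between two points
#'
#' @param p1,p2 length-3 Cartesian coordinates (Angstrom)
#' @return Euclidean distance in Angstrom
#' @examples
#' measureDistance(c(0, 0, 0), c(0, 0, 1.54))  # 1.54
#' @export
measureDistance <- function(p1, p2) {
  sqrt(sum((asPoint(p1) - asPoint(p2))^2))
}

#' Plane angle at a vertex
#'
#' Angle p1-p2-p3 at vertex `p2`, in `[0, 180]` degrees.
#'
#' @param p1,p2,p3 length-3 Cartesian coordinates (Angstrom)
#' @return angle in degrees
#' @examples
#' measureAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
measureAngle <- function(p1, p2, p3) {
  v1 <- asPoint(p1) - asPoint(p2)
  v2 <- asPoint(p3) - asPoint(p2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    pesStop("geometry", "degenerate geometry: zero-length angle arm")
  cosang <- sum(v1 * v2) / (n1 * n2)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Signed dihedral (torsion) angle
#'
#' Torsion p1-p2-p3-p4 in `(-180, 180]` degrees with the IUPAC sign
#' convention: viewed down the p2 -> p3 axis, a clockwise rotation of the
#' far bond relative to the near bond is positive. Computed as
#' `atan2((n1 x n2) . b2hat, n1 . n2)` with `b1 = p2-p1`, `b2 = p3-p2`,
#' `b3 = p4-p3`, `n1 = b1 x b2`, `n2 = b2 x b3`; under this formula the
#' configuration `(1,0,0), (0,0,0), (0,0,1), (0,1,1)` measures +90.
#'
#' @param p1,p2,p3,p4 length-3 Cartesian coordinates (Angstrom)
#' @return signed torsion in degrees, `(-180, 180]`
#' @export
measureDihedral <- function(p1, p2, p3, p4) {
  p1 <- asPoint(p1); p2 <- asPoint(p2); p3 <- asPoint(p3); p4 <- asPoint(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    pesStop("geometry", "degenerate geometry: collinear atoms in dihedral")
  ang <- rad2deg(atan2(sum(cross(n1, n2) * (b2 / nb2)), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

## Measure the scan coordinate of `kind` on geometry rows `idx` (1-based).
measureCoordinate <- function(kind, geometry, idx) {
  pts <- lapply(idx, function(i) {
    if (i < 1 || i > nrow(geometry)) return(NULL)
    as.numeric(geometry[i, c("x", "y", "z")])
  })
  if (any(vapply(pts, is.null, logical(1))))
    pesStop("mapping", "atom index outside geometry: ",
            paste(idx, collapse = ","))
  switch(kind,
         distance = measureDistance(pts[[1]], pts[[2]]),
         angle = measureAngle(pts[[1]], pts[[2]], pts[[3]]),
         dihedral = measureDihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]))
}
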