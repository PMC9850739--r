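## Classical force-field energies for a declared chemical state, evaluated
## on gas-phase cluster geometries (no cutoffs, no periodicity).
##
## Functional forms (all energies kJ/mol, r in Angstrom, angles degrees):
##   harmonic bond    1/2 k (r - r0)^2
##   Morse bond       De (1 - exp(-a (r - re)))^2
##   harmonic angle   1/2 ktheta (theta - theta0)^2   (deviation in rad)
##   cosine torsion   Vn/2 (1 + cos(n phi - gamma))
##   Lennard-Jones    4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ],
##                    Lorentz-Berthelot combination
##   Coulomb          f q_i q_j / r, f = 138.935458 kJ mol^-1 A e^-1
## Exclusions: 1-2 and 1-3 pairs fully excluded; 1-4 pairs scaled (default
## 0.5 for both LJ and Coulomb), configurable per topology.

emptyTermFrame <- function(cols) {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Construct a state topology
#'
#' @param label state name
#' @param atoms data frame (one row per atom) with columns `epsilon`
#'   (kJ/mol), `sigma` (Angstrom), `charge` (e); extra columns (e.g.
#'   `element`) are carried along
#' @param bonds,morse,angles,torsions term tables, see
#'   [StateTopology-class]; `NULL` for none
#' @param scale14 named numeric with entries `lj` and `coulomb`
#' @return a [StateTopology]
#' @export
stateTopology <- function(label, atoms, bonds = NULL, morse = NULL,
                          angles = NULL, torsions = NULL,
                          scale14 = c(lj = 0.5, coulomb = 0.5)) {
  new("StateTopology", label = label, atoms = as.data.frame(atoms),
      bonds = if (is.null(bonds)) emptyTermFrame(c("i", "j", "k", "r0"))
              else as.data.frame(bonds),
      morse = if (is.null(morse)) emptyTermFrame(c("i", "j", "De", "a", "re"))
              else as.data.frame(morse),
      angles = if (is.null(angles))
                 emptyTermFrame(c("i", "j", "k3", "ktheta", "theta0"))
               else as.data.frame(angles),
      torsions = if (is.null(torsions))
                   emptyTermFrame(c("i", "j", "k3", "l", "Vn", "n", "gamma"))
                 else as.data.frame(torsions),
      scale14 = scale14)
}

#' Read a state topology from a YAML config
#'
#' Schema: top-level `label`, `atoms` (list of maps with `epsilon`,
#' `sigma`, `charge` and optionally `element`), `terms` (list of maps
#' with a `type` of `harmonic_bond`, `morse_bond`, `harmonic_angle`, or
#' `cosine_torsion` plus that term's parameters), and optional `scale14`
#' (map with `lj`, `coulomb`).
#'
#' @param path YAML file path
#' @return a [StateTopology]
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) pesStop("io", "topology file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$atoms)) pesStop("config", "topology needs an atoms block")
  atoms <- do.call(rbind, lapply(cfg$atoms, function(a)
    data.frame(element = a$element %||% "X",
               epsilon = a$epsilon %||% 0, sigma = a$sigma %||% 1,
               charge = a$charge %||% 0)))
  pick <- function(type, cols) {
    rows <- Filter(function(tm) identical(tm$type, type), cfg$terms %||% list())
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(tm) {
      miss <- setdiff(cols, names(tm))
      if (length(miss))
        pesStop("config", type, " term missing fields: ",
                paste(miss, collapse = ", "))
      as.data.frame(tm[cols])
    }))
  }
  sc <- c(lj = cfg$scale14$lj %||% 0.5, coulomb = cfg$scale14$coulomb %||% 0.5)
  stateTopology(
    label = cfg$label %||% "state",
    atoms = atoms,
    bonds = pick("harmonic_bond", c("i", "j", "k", "r0")),
    morse = pick("morse_bond", c("i", "j", "De", "a", "re")),
    angles = pick("harmonic_angle", c("i", "j", "k3", "ktheta", "theta0")),
    torsions = pick("cosine_torsion",
                    c("i", "j", "k3", "l", "Vn", "n", "gamma")),
    scale14 = sc)
}

asXYZ <- function(geometry) {
  if (is.matrix(geometry)) {
    if (ncol(geometry) != 3) pesStop("topology", "geometry must be N x 3")
    return(geometry)
  }
  if (is.data.frame(geometry) && all(c("x", "y", "z") %in% names(geometry)))
    return(as.matrix(geometry[, c("x", "y", "z")]))
  pesStop("topology", "geometry must be a matrix or data frame with x,y,z")
}

## Topological (bond-graph) distances up to 4, from the union of harmonic
## and Morse bond edges. Returns an N x N integer matrix (Inf beyond 4).
bondPathDepth <- function(top, n) {
  edges <- rbind(
    if (nrow(top@bonds)) top@bonds[, c("i", "j")] else NULL,
    if (nrow(top@morse)) setNames(top@morse[, c("i", "j")], c("i", "j"))
      else NULL)
  depth <- matrix(Inf, n, n)
  diag(depth) <- 0
  if (is.null(edges) || !nrow(edges)) return(depth)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier) && d < 4) {
      d <- d + 1
      frontier <- unique(unlist(adj[frontier]))
      frontier <- frontier[depth[s, frontier] > d]
      depth[s, frontier] <- d
    }
  }
  depth
}

#' @describeIn ffEnergy evaluate the topology on one geometry. Atom
#'   indices in terms are checked against the geometry size; a
#'   zero-distance nonbonded pair raises a singular-geometry error.
#' @export
setMethod("ffEnergy", "StateTopology", function(topology, geometry) {
  xyz <- asXYZ(geometry)
  n <- nrow(xyz)
  top <- topology
  maxIdx <- suppressWarnings(max(0, top@bonds$i, top@bonds$j, top@morse$i,
                                 top@morse$j, top@angles$i, top@angles$j,
                                 top@angles$k3, top@torsions$i,
                                 top@torsions$j, top@torsions$k3,
                                 top@torsions$l))
  if (maxIdx > n)
    pesStop("topology", "term references atom ", maxIdx,
            " but geometry has ", n, " atoms")
  if (nrow(top@atoms) && nrow(top@atoms) != n)
    pesStop("topology", "nonbonded table has ", nrow(top@atoms),
            " atoms but geometry has ", n)

  e <- 0
  dist <- function(i, j) measureDistance(xyz[i, ], xyz[j, ])
  for (r in seq_len(nrow(top@bonds))) {
    b <- top@bonds[r, ]
    e <- e + 0.5 * b$k * (dist(b$i, b$j) - b$r0)^2
  }
  for (r in seq_len(nrow(top@morse))) {
    m <- top@morse[r, ]
    e <- e + m$De * (1 - exp(-m$a * (dist(m$i, m$j) - m$re)))^2
  }
  for (r in seq_len(nrow(top@angles))) {
    a <- top@angles[r, ]
    th <- measureAngle(xyz[a$i, ], xyz[a$j, ], xyz[a$k3, ])
    e <- e + 0.5 * a$ktheta * deg2rad(th - a$theta0)^2
  }
  for (r in seq_len(nrow(top@torsions))) {
    tt <- top@torsions[r, ]
    phi <- measureDihedral(xyz[tt$i, ], xyz[tt$j, ], xyz[tt$k3, ], xyz[tt$l, ])
    e <- e + tt$Vn / 2 * (1 + cos(tt$n * deg2rad(phi) - deg2rad(tt$gamma)))
  }

  if (nrow(top@atoms)) {
    pars <- top@atoms
    anyNB <- any(pars$epsilon > 0) || any(pars$charge != 0)
    if (anyNB && n > 1) {
      depth <- bondPathDepth(top, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- depth[i, j]
        if (d <= 2) next
        scLJ <- if (d == 3) top@scale14[["lj"]] else 1
        scC <- if (d == 3) top@scale14[["coulomb"]] else 1
        r <- dist(i, j)
        if (r == 0)
          pesStop("geometry", "singular geometry: atoms ", i, " and ", j,
                  " coincide in a nonbonded pair")
        epsij <- sqrt(pars$epsilon[i] * pars$epsilon[j])
        sigij <- (pars$sigma[i] + pars$sigma[j]) / 2
        if (epsij > 0) {
          sr6 <- (sigij / r)^6
          e <- e + scLJ * 4 * epsij * (sr6^2 - sr6)
        }
        qq <- pars$charge[i] * pars$charge[j]
        if (qq != 0) e <- e + scC * COULOMB_KJ_ANG_E2 * qq / r
      }
    }
  }
  e
})

#' @describeIn ffProfile evaluate the topology at every scan-point
#'   geometry of the scan, in scan-point order.
#' @export
setMethod("ffProfile", signature("StateTopology", "PESScan"),
          function(topology, scan) {
  vals <- coordinateValues(scan)
  en <- vapply(scan@points, function(p)
    ffEnergy(topology, p@calculation@geometry), numeric(1))
  EnergyProfile(coordinate = vals, energy = en, unit = scan@coordinate@unit)
})
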