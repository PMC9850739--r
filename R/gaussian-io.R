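## Parser for quantum-chemistry scan logs in a documented text dialect
## modelled on Gaussian 09/16 output, and scan assembly from one or many
## logs.
##
## Dialect (version 1). A log is UTF-8 text with these anchor lines:
##
##   * scan header (optional, modredundant style), one line:
##       "B i j S n step"          bond scan, atoms i,j
##       "A i j k S n step"        angle scan
##       "D i j k l S n step"      dihedral scan
##   * geometry blocks introduced by a line containing
##     "Input orientation:" or "Standard orientation:", followed by a
##     dashed rule, two header lines, a dashed rule, one row per atom
##     ("center  atomic-number  atomic-type  X  Y  Z", coordinates in
##     Angstrom) and a terminating dashed rule;
##   * energy lines "SCF Done:  E(<method>) =  <value>  A.U. ...";
##   * for relaxed scans, one "Optimization completed." marker per
##     optimized scan step;
##   * optionally "Charge = <q> Multiplicity = <m>".
##
## Real Gaussian logs using these anchors parse as well, but only the
## dialect above is guaranteed.

splitLogLines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

## Parse one orientation block starting at line `at` (the anchor line).
## Returns list(geometry = data.frame, end = last line used).
parseOrientationBlock <- function(lines, at) {
  i <- at + 1L
  dash <- function(s) grepl("^\\s*-{10,}\\s*$", s)
  # skip: rule, header lines, rule
  while (i <= length(lines) && !dash(lines[i])) i <- i + 1L
  i <- i + 1L
  while (i <= length(lines) && !dash(lines[i])) i <- i + 1L
  i <- i + 1L
  rows <- list()
  while (i <= length(lines) && !dash(lines[i])) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(f) %in% c(5L, 6L) || anyNA(suppressWarnings(as.numeric(f))))
      pesStop("dialect", "malformed geometry row at line ", i)
    xyz <- as.numeric(f[(length(f) - 2L):length(f)])
    rows[[length(rows) + 1L]] <-
      data.frame(element = elementSymbol(as.integer(f[2])),
                 x = xyz[1], y = xyz[2], z = xyz[3])
    i <- i + 1L
  }
  if (!length(rows))
    pesStop("dialect", "empty geometry block at line ", at)
  list(geometry = do.call(rbind, rows), end = i)
}

scanLogIndex <- function(lines) {
  list(
    scf = grep("SCF Done:", lines),
    inputOri = grep("Input orientation:", lines, fixed = TRUE),
    stdOri = grep("Standard orientation:", lines, fixed = TRUE),
    opt = grep("Optimization completed", lines, fixed = TRUE)
  )
}

parseScfLine <- function(line, at) {
  m <- regmatches(line, regexec(
    "SCF Done:\\s*E\\(([^)]*)\\)\\s*=\\s*(-?[0-9]*\\.?[0-9]+(?:[DdEe][-+]?[0-9]+)?)",
    line))[[1]]
  if (length(m) != 3)
    pesStop("dialect", "malformed SCF line at line ", at)
  list(method = m[2], text = m[3],
       energy = as.numeric(sub("[Dd]", "e", m[3])))
}

#' Detect the scan type of a log
#'
#' A log is `relaxed` when it contains "Optimization completed." markers,
#' `rigid` when a scan header is declared without them, and
#' `single_point` otherwise.
#'
#' @param text log text (single string or character vector of lines)
#' @return one of `"relaxed"`, `"rigid"`, `"single_point"`
#' @export
detectScanType <- function(text) {
  lines <- splitLogLines(text)
  if (length(grep("Optimization completed", lines, fixed = TRUE)))
    return("relaxed")
  if (!is.null(extractScanSpec(lines))) return("rigid")
  "single_point"
}

#' Extract the declared scan specification from a log header
#'
#' Reads the modredundant-style scan declaration (`"B 1 2 S 10 0.2"` and
#' the `A`/`D` analogues). The declaration is treated as a cross-check;
#' coordinate values are always recomputed from geometries at assembly.
#'
#' @param text log text
#' @return `NULL` when no declaration is present, else a list with
#'   `atomIds` (1-based integers), `kind`, `nSteps`, `stepSize`
#' @export
extractScanSpec <- function(text) {
  lines <- splitLogLines(text)
  cand <- grep("^\\s*[BAD]\\s+\\d", lines)
  if (!length(cand)) return(NULL)
  line <- lines[cand[1]]
  m <- regmatches(line, regexec(
    "^\\s*([BAD])((?:\\s+\\d+)+)\\s+S\\s+(\\d+)\\s+(-?[0-9]*\\.?[0-9]+)\\s*$",
    line))[[1]]
  if (length(m) != 5)
    pesStop("dialect", "malformed scan declaration at line ", cand[1],
            ": ", trimws(line))
  ids <- as.integer(strsplit(trimws(m[3]), "\\s+")[[1]])
  kind <- c(B = "distance", A = "angle", D = "dihedral")[[m[2]]]
  if (length(ids) != coordinateArity(kind))
    pesStop("dialect", "scan declaration arity mismatch at line ", cand[1])
  list(atomIds = ids, kind = kind, nSteps = as.integer(m[4]),
       stepSize = as.numeric(m[5]))
}

#' Parse a scan log into raw steps
#'
#' For relaxed scans each "Optimization completed." marker yields one
#' step, taking the last SCF energy and the last geometry block before
#' the marker; trailing SCF work after the final marker becomes a step
#' flagged `converged = FALSE` rather than being dropped. For rigid and
#' single-point logs every SCF line yields one converged step. The
#' geometry assigned to an SCF line is the most recent "Input
#' orientation:" block before it, falling back to "Standard orientation:".
#'
#' @param text log text (single string or character vector of lines)
#' @param source label recorded in each step's provenance
#' @return a list of raw steps, each a list with `geometry` (data frame:
#'   `element`, `x`, `y`, `z`), `scfEnergy` (Hartree, numeric),
#'   `scfText` (the energy exactly as printed), `converged`, `line`, and
#'   `source`. Attributes: `type`, `method`, `charge`, `multiplicity`,
#'   `scanSpec`.
#' @export
parseScanLog <- function(text, source = "log") {
  lines <- splitLogLines(text)
  idx <- scanLogIndex(lines)
  if (!length(idx$scf))
    pesStop("empty_log", "no \"SCF Done:\" line found: not a scan log")

  geoms <- list()
  for (at in sort(c(idx$inputOri, idx$stdOri)))
    geoms[[as.character(at)]] <- parseOrientationBlock(lines, at)$geometry

  geomFor <- function(scfAt) {
    before <- function(cand) cand[cand < scfAt]
    pick <- before(idx$inputOri)
    if (!length(pick)) pick <- before(idx$stdOri)
    if (!length(pick))
      pesStop("dialect", "SCF energy at line ", scfAt,
              " has no preceding geometry block")
    geoms[[as.character(max(pick))]]
  }

  mkStep <- function(scfAt, converged) {
    e <- parseScfLine(lines[scfAt], scfAt)
    list(geometry = geomFor(scfAt), scfEnergy = e$energy, scfText = e$text,
         method = e$method, converged = converged, line = scfAt,
         source = source)
  }

  type <- detectScanType(lines)
  steps <- if (type == "relaxed") {
    prev <- 0L
    out <- list()
    for (m in idx$opt) {
      cand <- idx$scf[idx$scf > prev & idx$scf < m]
      if (!length(cand))
        pesStop("dialect", "optimization marker at line ", m,
                " has no SCF energy in its step")
      out[[length(out) + 1L]] <- mkStep(max(cand), TRUE)
      prev <- m
    }
    trailing <- idx$scf[idx$scf > prev]
    if (length(trailing))
      out[[length(out) + 1L]] <- mkStep(max(trailing), FALSE)
    out
  } else {
    lapply(idx$scf, mkStep, converged = TRUE)
  }

  qm <- regmatches(lines, regexec(
    "Charge\\s*=\\s*(-?\\d+)\\s+Multiplicity\\s*=\\s*(\\d+)", lines))
  qm <- Filter(function(x) length(x) == 3, qm)
  attr(steps, "type") <- type
  attr(steps, "method") <- if (length(steps)) steps[[1]]$method else "unknown"
  attr(steps, "charge") <- if (length(qm)) as.numeric(qm[[1]][2]) else 0
  attr(steps, "multiplicity") <- if (length(qm)) as.numeric(qm[[1]][3]) else 1
  attr(steps, "scanSpec") <- extractScanSpec(lines)
  steps
}

#' Assemble a PES scan from parsed logs
#'
#' Builds one [ScanPointRecord] per converged raw step, recomputing each
#' point's coordinate value from its geometry via the atom map. Points are
#' merged across logs, sorted ascending, and near-duplicates (coordinate
#' values closer than `dupTol`) collapsed keeping the lowest SCF energy.
#'
#' @param logs list of log texts or of [parseScanLog()] results
#' @param species a [SpeciesRef] (or list of them) the scan is on
#' @param coordinate the [ScanCoordinate]
#' @param atomMap named character vector mapping 1-based input atom
#'   indices (names) to species atom IRIs (values); must cover the
#'   coordinate's atoms
#' @param scanIri scan identifier; minted deterministically when omitted
#' @param fragments optional list of fragment [SpeciesRef]s
#' @param kbBase namespace base for minted IRIs
#' @param dupTol coordinate tolerance for duplicate collapsing
#' @return a [PESScan]
#' @export
assembleScan <- function(logs, species, coordinate, atomMap,
                         scanIri = NULL, fragments = list(),
                         kbBase = "https://example.org/kb/",
                         dupTol = 1e-6) {
  if (is(species, "SpeciesRef")) species <- list(species)
  if (!is.list(logs) || is(logs[[1]], "SpeciesRef"))
    pesStop("config", "logs must be a list of log texts or parsed logs")

  inputIds <- vapply(coordinate@scanAtoms, function(a) {
    hit <- names(atomMap)[atomMap == a]
    if (!length(hit)) NA_character_ else hit[1]
  }, character(1))
  if (anyNA(inputIds))
    pesStop("mapping", "atom map does not cover scan-coordinate atoms: ",
            paste(coordinate@scanAtoms[is.na(inputIds)], collapse = ", "))
  inputIds <- as.integer(inputIds)

  if (is.null(scanIri))
    scanIri <- paste0(kbBase, "scan/",
                      sanitizeId(paste0(species[[1]]@label, "_",
                                        coordinate@kind)))

  pts <- list()
  for (li in seq_along(logs)) {
    lg <- logs[[li]]
    if (is.character(lg)) lg <- parseScanLog(lg, source = paste0("log", li))
    jobKind <- attr(lg, "type") %||% "single_point"
    conv <- Filter(function(s) isTRUE(s$converged), lg)
    for (si in seq_along(conv)) {
      st <- conv[[si]]
      value <- measureCoordinate(coordinate@kind, st$geometry, inputIds)
      calc <- CalculationRecord(
        iri = paste0(kbBase, "calculation/",
                     sanitizeId(paste0(st$source, "_step", si))),
        scfEnergy = st$scfEnergy, scfText = st$scfText,
        geometry = st$geometry, program = "dialect-v1",
        method = st$method %||% (attr(lg, "method") %||% "unknown"),
        charge = attr(lg, "charge") %||% 0,
        spinMultiplicity = attr(lg, "multiplicity") %||% 1,
        jobKind = jobKind)
      pts[[length(pts) + 1L]] <- ScanPointRecord(
        value = value, unit = coordinate@unit, inputAtomIds = inputIds,
        calculation = calc,
        provenance = paste0(st$source, ":", st$line))
    }
  }
  if (!length(pts))
    pesStop("assembly", "no converged steps in any input log")

  vals <- vapply(pts, function(p) p@value, numeric(1))
  pts <- pts[order(vals)]
  vals <- sort(vals)
  keep <- list()
  for (p in pts) {
    if (length(keep) &&
        abs(p@value - keep[[length(keep)]]@value) < dupTol) {
      if (p@calculation@scfEnergy <
          keep[[length(keep)]]@calculation@scfEnergy)
        keep[[length(keep)]] <- p
    } else keep[[length(keep) + 1L]] <- p
  }

  PESScan(iri = scanIri, species = species, fragments = fragments,
          coordinate = coordinate, points = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
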