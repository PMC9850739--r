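## The two canonical (federated) query patterns over the scan graph, a
## minimal SPARQL SELECT evaluator on top, and the shipped query
## templates.

#' Find scans performed on a species, by InChI
#'
#' The first canonical pattern: locate species nodes whose InChI literal
#' matches exactly, then the scans that reference them through
#' `onSpecies`.
#'
#' @param g a [TripleGraph]
#' @param inchi InChI string (exact text match)
#' @param vocab a [VocabularyMap]
#' @return character vector of scan IRIs, sorted lexicographically
#'   (empty when no species matches)
#' @export
findScansByInChI <- function(g, inchi, vocab = defaultVocabulary()) {
  t <- function(x) termIri(vocab, x)
  speciesIris <- subjectsWith(g, t("hasInChI"), o = inchi, lit = TRUE)
  if (!length(speciesIris)) return(character(0))
  scans <- unique(unlist(lapply(speciesIris, function(sp)
    subjectsWith(g, t("onSpecies"), o = sp))))
  scans <- intersect(scans, subjectsWith(g, RDF_TYPE,
                                         t("PotentialEnergySurfaceScan")))
  sort(scans)
}

#' Coordinate values and SCF energies of a scan
#'
#' The second canonical pattern: for every scan point, retrieve the
#' coordinate value (with unit) and the SCF energy of the linked
#' calculation, ordered ascending by coordinate value.
#'
#' @param g a [TripleGraph]
#' @param scanIri scan IRI
#' @param vocab a [VocabularyMap]
#' @return data frame with columns `value` (numeric), `unit` (label),
#'   `scfEnergy` (Hartree, numeric), `scfText` (the stored literal)
#' @export
pointEnergies <- function(g, scanIri, vocab = defaultVocabulary()) {
  t <- function(x) termIri(vocab, x)
  ptIris <- objectsOf(g, scanIri, t("hasScanPoint"))
  if (!length(ptIris))
    pesStop("incomplete", "no scan points for <", scanIri, "> in graph")
  rows <- do.call(rbind, lapply(ptIris, function(pi) {
    valIri <- one(objectsOf(g, pi, t("hasScanCoordinateValue")),
                  "coordinate value node", pi)
    calcIri <- one(objectsOf(g, pi, t("hasCalculation")), "calculation", pi)
    scfText <- litOf(g, calcIri, t("hasSCFEnergy"), "SCF energy")
    unitIriVal <- one(objectsOf(g, valIri, t("hasUnit")), "unit", valIri)
    data.frame(value = as.numeric(litOf(g, valIri, t("hasValue"), "value")),
               unit = unitLabelForIri(vocab, unitIriVal),
               scfEnergy = as.numeric(scfText), scfText = scfText,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$value), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

## --- minimal SPARQL ------------------------------------------------------

sparqlTermToPattern <- function(tok, prefixes) {
  if (startsWith(tok, "?")) return(list(var = substring(tok, 2)))
  if (startsWith(tok, "<")) return(list(iri = gsub("^<|>$", "", tok)))
  if (startsWith(tok, "\"")) {
    lex <- sub("\\^\\^.*$", "", tok)
    return(list(lit = gsub("^\"|\"$", "", lex)))
  }
  if (tok == "a") return(list(iri = RDF_TYPE))
  m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:(.*)$", tok))[[1]]
  if (length(m) == 3 && m[2] %in% names(prefixes))
    return(list(iri = paste0(prefixes[[m[2]]], m[3])))
  pesStop("sparql", "cannot interpret query term: ", tok)
}

## Split a basic graph pattern on '.' separators, ignoring dots inside
## <IRIs> and "literals".
splitTriplePatterns <- function(body) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  out <- character(0)
  buf <- character(0)
  inIri <- FALSE; inStr <- FALSE
  for (ch in chars) {
    if (ch == "<" && !inStr) inIri <- TRUE
    if (ch == ">" && !inStr) inIri <- FALSE
    if (ch == "\"") inStr <- !inStr
    if (ch == "." && !inIri && !inStr) {
      out <- c(out, paste0(buf, collapse = ""))
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  out <- c(out, paste0(buf, collapse = ""))
  Filter(nzchar, trimws(out))
}

#' Evaluate a SPARQL SELECT over a graph
#'
#' Supports the fragment the shipped templates use: `PREFIX`
#' declarations, `SELECT` with explicit variables or `*`, and a `WHERE`
#' block that is a basic graph pattern (triple patterns joined by `.`;
#' terms are variables, IRIs, prefixed names, `a`, or plain string
#' literals). No `OPTIONAL`, `FILTER`, or property paths.
#'
#' @param g a [TripleGraph]
#' @param query SPARQL SELECT text
#' @return data frame, one column per selected variable, rows sorted
#'   lexicographically over all columns for determinism
#' @export
sparqlSelect <- function(g, query) {
  query <- gsub("[\r\n]", " ", query)
  pm <- regmatches(query, gregexpr("PREFIX\\s+([A-Za-z0-9_.-]*):\\s*<([^>]*)>",
                                   query))[[1]]
  prefixes <- character(0)
  for (d in pm) {
    mm <- regmatches(d, regexec("PREFIX\\s+([A-Za-z0-9_.-]*):\\s*<([^>]*)>",
                                d))[[1]]
    prefixes[[mm[2]]] <- mm[3]
  }
  sel <- regmatches(query, regexec(
    "SELECT\\s+((?:\\?[A-Za-z0-9_]+\\s*)+|\\*)\\s*WHERE", query))[[1]]
  if (length(sel) != 2) pesStop("sparql", "no SELECT ... WHERE clause found")
  body <- regmatches(query, regexec("WHERE\\s*\\{(.*)\\}", query))[[1]]
  if (length(body) != 2) pesStop("sparql", "no WHERE { ... } block found")
  if (grepl("OPTIONAL|FILTER|UNION|\\{", body[2]))
    pesStop("sparql", "only basic graph patterns are supported")

  pats <- splitTriplePatterns(body[2])
  df <- g@triples
  bindings <- data.frame(row.names = 1)   # one empty row: unit for joins
  for (pat in pats) {
    toks <- regmatches(pat, gregexpr(
      '"[^"]*"(\\^\\^\\S+)?|<[^>]*>|\\?[A-Za-z0-9_]+|\\S+', pat,
      perl = TRUE))[[1]]
    if (length(toks) != 3)
      pesStop("sparql", "triple pattern must have 3 terms: ", pat)
    terms <- lapply(toks, sparqlTermToPattern, prefixes = prefixes)
    cand <- df
    cols <- c(s = 1, p = 2, o = 3)
    sel3 <- character(0)
    for (pos in 1:3) {
      tm <- terms[[pos]]
      colName <- c("s", "p", "o")[pos]
      if (!is.null(tm$iri)) cand <- cand[cand[[colName]] == tm$iri &
                                           (colName != "o" | !cand$lit), ]
      else if (!is.null(tm$lit)) cand <- cand[cand$lit &
                                                cand[[colName]] == tm$lit, ]
      else sel3[tm$var] <- colName
    }
    part <- cand[, unname(sel3), drop = FALSE]
    names(part) <- names(sel3)
    part <- unique(part)
    common <- intersect(names(bindings), names(part))
    bindings <- if (length(common)) merge(bindings, part, by = common)
                else merge(bindings, part)
  }
  want <- if (trimws(sel[2]) == "*") names(bindings)
          else sub("^\\?", "", strsplit(trimws(sel[2]), "\\s+")[[1]])
  out <- unique(bindings[, want, drop = FALSE])
  if (nrow(out))
    out <- out[do.call(order, as.list(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sparqlPrefixBlock <- function(vocab = defaultVocabulary()) {
  paste(sprintf("PREFIX %s: <%s>", names(vocab@prefixes), vocab@prefixes),
        collapse = "\n")
}

#' Shipped SPARQL templates for the two canonical patterns
#'
#' `queryScansByInChI()` renders the species-to-scan federated lookup;
#' `queryPointEnergies()` renders the per-point coordinate-value /
#' SCF-energy retrieval. Both evaluate with [sparqlSelect()] and agree
#' with the direct implementations [findScansByInChI()] and
#' [pointEnergies()].
#'
#' @param inchi InChI string
#' @param vocab a [VocabularyMap]
#' @return SPARQL SELECT text
#' @export
queryScansByInChI <- function(inchi, vocab = defaultVocabulary()) {
  paste0(sparqlPrefixBlock(vocab), "\n",
         "SELECT ?scan WHERE {\n",
         "  ?species os:hasInChI \"", inchi, "\" .\n",
         "  ?scan ps:onSpecies ?species .\n",
         "  ?scan a ps:PotentialEnergySurfaceScan\n",
         "}\n")
}

#' @rdname queryScansByInChI
#' @param scanIri scan IRI
#' @export
queryPointEnergies <- function(scanIri, vocab = defaultVocabulary()) {
  paste0(sparqlPrefixBlock(vocab), "\n",
         "SELECT ?value ?energy WHERE {\n",
         "  <", scanIri, "> ps:hasScanPoint ?point .\n",
         "  ?point ps:hasScanCoordinateValue ?cv .\n",
         "  ?cv gc:hasValue ?value .\n",
         "  ?point ps:hasCalculation ?calc .\n",
         "  ?calc oc:hasSCFEnergy ?energy\n",
         "}\n")
}
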