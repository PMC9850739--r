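## Triple store primitives and Turtle serialization (scoped subset: IRIs,
## prefixed names, typed/plain string literals, ';' / ',' abbreviation,
## comments). The mapping never emits blank nodes, so two graphs are
## isomorphic iff their triple sets are equal.

tripleFrame <- function(s = character(0), p = character(0), o = character(0),
                        lit = logical(0), dt = character(0)) {
  data.frame(s = s, p = p, o = o, lit = lit, dt = dt,
             stringsAsFactors = FALSE)
}

#' Create an empty triple graph
#' @return a [TripleGraph] with zero triples
#' @export
emptyGraph <- function() new("TripleGraph", triples = tripleFrame())

#' Triples of a graph
#' @param g a [TripleGraph]
#' @return the underlying data frame (columns `s`, `p`, `o`, `lit`, `dt`)
#' @export
graphTriples <- function(g) g@triples

setMethod("show", "TripleGraph", function(object) {
  cat(sprintf("TripleGraph: %d triples, %d subjects\n",
              nrow(object@triples), length(unique(object@triples$s))))
})

canonTriples <- function(df) {
  df$dt[is.na(df$dt)] <- ""
  df <- df[order(df$s, df$p, df$o, df$lit, df$dt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Union of two graphs (set semantics, duplicates removed)
#' @param g1,g2 [TripleGraph]s
#' @return a [TripleGraph]
#' @export
graphUnion <- function(g1, g2) {
  df <- unique(rbind(g1@triples, g2@triples))
  rownames(df) <- NULL
  new("TripleGraph", triples = df)
}

#' Are two graphs isomorphic?
#'
#' The mapping mints deterministic IRIs and uses no blank nodes, so
#' isomorphism reduces to set equality of the canonicalized triples.
#'
#' @param g1,g2 [TripleGraph]s
#' @return logical
#' @export
graphsIsomorphic <- function(g1, g2)
  identical(canonTriples(unique(g1@triples)), canonTriples(unique(g2@triples)))

## --- lookups -------------------------------------------------------------

objectsOf <- function(g, s, p) {
  df <- g@triples
  df$o[df$s == s & df$p == p]
}

subjectsWith <- function(g, p, o = NULL, lit = NULL) {
  df <- g@triples
  keep <- df$p == p
  if (!is.null(o)) keep <- keep & df$o == o
  if (!is.null(lit)) keep <- keep & df$lit == lit
  unique(df$s[keep])
}

one <- function(x, what, subject) {
  if (length(x) == 0)
    pesStop("incomplete", "missing ", what, " for <", subject, ">")
  if (length(x) > 1)
    pesStop("ambiguous", "more than one ", what, " for <", subject, ">")
  x
}

## --- Turtle writer -------------------------------------------------------

escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescapeLiteral <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[k], "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        i <- i + 2L
      } else {
        buf <- c(buf, chars[i])
        i <- i + 1L
      }
    }
    out[k] <- paste0(buf, collapse = "")
  }
  out
}

compactIri <- function(iriVal, prefixes) {
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    if (startsWith(iriVal, ns)) {
      local <- substring(iriVal, nchar(ns) + 1L)
      if (grepl("^[A-Za-z][A-Za-z0-9_]*$", local))
        return(paste0(pfx, ":", local))
    }
  }
  paste0("<", iriVal, ">")
}

renderTerm <- function(o, lit, dt, prefixes) {
  if (!lit) return(compactIri(o, prefixes))
  base <- paste0("\"", escapeLiteral(o), "\"")
  if (!is.na(dt) && nzchar(dt))
    base <- paste0(base, "^^", compactIri(dt, prefixes))
  base
}

#' Serialize a graph to Turtle
#'
#' Deterministic output: prefixes sorted, subjects sorted, predicates and
#' objects sorted within subject, `;`-grouped. Numeric literals must
#' already carry shortest round-trip lexical forms (the mapping takes
#' care of this).
#'
#' @param g a [TripleGraph]
#' @param path output file; when `NULL` the Turtle text is returned
#' @param vocab [VocabularyMap] supplying namespace prefixes
#' @return `path` invisibly, or the Turtle text when `path` is `NULL`
#' @export
writeTurtle <- function(g, path = NULL, vocab = defaultVocabulary()) {
  pfx <- vocab@prefixes
  df <- canonTriples(unique(g@triples))
  out <- sprintf("@prefix %s: <%s> .", names(pfx)[order(names(pfx))],
                 pfx[order(names(pfx))])
  out <- c(out, "")
  for (s in unique(df$s)) {
    rows <- df[df$s == s, , drop = FALSE]
    lines <- vapply(seq_len(nrow(rows)), function(k) {
      dtv <- rows$dt[k]
      if (identical(dtv, "")) dtv <- NA_character_
      paste0("    ", compactIri(rows$p[k], pfx), " ",
             renderTerm(rows$o[k], rows$lit[k], dtv, pfx))
    }, character(1))
    out <- c(out,
             paste0("<", s, ">"),
             paste0(lines, c(rep(" ;", length(lines) - 1L), " .")),
             "")
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(path)
}

## --- Turtle reader -------------------------------------------------------

tokenizeTurtle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<-
      list(type = type, value = value)
  while (i <= n) {
    c0 <- chars[i]
    if (c0 %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (c0 == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (c0 == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) pesStop("turtle", "unterminated IRI")
      push("iri", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (c0 == "\"") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\" && j < n) { buf <- c(buf, chars[j], chars[j + 1L]); j <- j + 2L }
        else { buf <- c(buf, chars[j]); j <- j + 1L }
      }
      if (j > n) pesStop("turtle", "unterminated string literal")
      push("string", unescapeLiteral(paste0(buf, collapse = "")))
      i <- j + 1L; next
    }
    if (c0 == "^" && i < n && chars[i + 1L] == "^") {
      push("dcaret", "^^"); i <- i + 2L; next
    }
    if (c0 %in% c(";", ",", ".")) { push(c0, c0); i <- i + 1L; next }
    # bareword: @prefix keyword, prefixed name, 'a', or numeric literal
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",",
                                      "\"", "<", "#") &&
           !(chars[j] == "." && (j == n || chars[j + 1L] %in%
                                   c(" ", "\t", "\n", "\r"))))
      j <- j + 1L
    word <- paste0(chars[i:(j - 1L)], collapse = "")
    if (!nzchar(word)) pesStop("turtle", "tokenizer stall at position ", i)
    push("word", word)
    i <- j
  }
  toks
}

#' Read a Turtle file into a graph
#'
#' Accepts the subset [writeTurtle()] emits (plus bare numeric literals
#' and the `a` keyword). Prefixed names are expanded using the file's own
#' `@prefix` declarations.
#'
#' @param path file path, or use `text` for an in-memory string
#' @param text Turtle text (overrides `path`)
#' @return a [TripleGraph]
#' @export
readTurtle <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      pesStop("io", "cannot read Turtle file: ", path %||% "<missing>")
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  toks <- tokenizeTurtle(text)
  prefixes <- character(0)
  expand <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    w <- tok$value
    if (w == "a") return(RDF_TYPE)
    m <- regmatches(w, regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:(.*)$", w))[[1]]
    if (length(m) == 3) {
      pfx <- m[2]
      if (!pfx %in% names(prefixes))
        pesStop("turtle", "undeclared prefix: ", pfx)
      return(paste0(prefixes[[pfx]], m[3]))
    }
    pesStop("turtle", "cannot interpret term: ", w)
  }
  rows <- list()
  i <- 1L
  nt <- length(toks)
  readObject <- function(i) {
    tok <- toks[[i]]
    if (tok$type == "string") {
      dt <- NA_character_
      used <- 1L
      if (i + 1L <= nt && toks[[i + 1L]]$type == "dcaret") {
        dt <- expand(toks[[i + 2L]])
        used <- 3L
      }
      list(o = tok$value, lit = TRUE, dt = dt, used = used)
    } else if (tok$type == "iri" ||
               (tok$type == "word" && grepl(":", tok$value, fixed = TRUE))) {
      list(o = expand(tok), lit = FALSE, dt = NA_character_, used = 1L)
    } else if (tok$type == "word" &&
               grepl("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?$", tok$value)) {
      dt <- if (grepl("[.eE]", tok$value)) paste0(XSD, "double")
            else paste0(XSD, "integer")
      list(o = tok$value, lit = TRUE, dt = dt, used = 1L)
    } else pesStop("turtle", "unexpected object term: ", tok$value)
  }
  while (i <= nt) {
    tok <- toks[[i]]
    if (tok$type == "word" && tok$value %in% c("@prefix", "PREFIX")) {
      pfxTok <- toks[[i + 1L]]
      pfx <- sub(":$", "", pfxTok$value)
      iriTok <- toks[[i + 2L]]
      prefixes[[pfx]] <- iriTok$value
      i <- i + 3L
      if (i <= nt && toks[[i]]$type == ".") i <- i + 1L
      next
    }
    s <- expand(tok); i <- i + 1L
    repeat {
      p <- expand(toks[[i]]); i <- i + 1L
      repeat {
        obj <- readObject(i); i <- i + obj$used
        rows[[length(rows) + 1L]] <-
          data.frame(s = s, p = p, o = obj$o, lit = obj$lit, dt = obj$dt,
                     stringsAsFactors = FALSE)
        if (i <= nt && toks[[i]]$type == ",") { i <- i + 1L } else break
      }
      if (i <= nt && toks[[i]]$type == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= nt && toks[[i]]$type == ".") { i <- i + 1L; break }
      } else if (i <= nt && toks[[i]]$type == ".") {
        i <- i + 1L; break
      } else if (i > nt) break
      else if (toks[[i]]$type %in% c("word", "iri")) next
      else pesStop("turtle", "unexpected token in predicate position")
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else tripleFrame()
  new("TripleGraph", triples = unique(df))
}
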