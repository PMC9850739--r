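## Shortest round-trip decimal formatting: the fewest significant digits
## whose re-parse reproduces the double bit-for-bit. Used for every numeric
## literal written to Turtle so a write/read cycle is lossless.

formatShortest <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (!is.finite(v)) return(as.character(v))
    if (v == floor(v) && abs(v) < 1e15) {
      s <- sprintf("%.1f", v)   # keep a decimal point so xsd:double parses
      if (as.numeric(s) == v) return(s)
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

## 32-bit FNV-1a over a UTF-8 string; used only to mint short deterministic
## identifier suffixes (not for security).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # multiply mod 2^32 in two 16-bit halves to stay inside double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

sanitizeId <- function(s) {
  s <- gsub("[^A-Za-z0-9._-]+", "_", s)
  gsub("^_+|_+$", "", s)
}
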