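# N-Triples reader/writer. The line-oriented grammar also serves as the
# canonical serialization used for snapshots and determinism checks.

unescape_nt <- function(x) {
  if (!grepl("\\\\", x)) return(x)
  out <- character(0)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      nxt <- chars[i + 1L]
      esc <- switch(nxt,
        "t" = "\t", "b" = "\b", "n" = "\n", "r" = "\r", "f" = "\f",
        "\"" = "\"", "'" = "'", "\\" = "\\", NULL)
      if (!is.null(esc)) {
        out <- c(out, esc); i <- i + 2L; next
      }
      if (nxt == "u" && i + 5L <= n) {
        code <- paste(chars[(i + 2L):(i + 5L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 6L; next
      }
      if (nxt == "U" && i + 9L <= n) {
        code <- paste(chars[(i + 2L):(i + 9L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 10L; next
      }
      stop("invalid escape sequence \\", nxt)
    }
    out <- c(out, ch)
    i <- i + 1L
  }
  paste(out, collapse = "")
}

escape_nt <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

IRI_RE     <- "<([^<>\"{}|^`\\\\[:space:]]*)>"
BNODE_RE   <- "_:([A-Za-z0-9][A-Za-z0-9._-]*)"
LITERAL_RE <- "\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^<>[:space:]]*)>|@([A-Za-z]+(?:-[A-Za-z0-9]+)*))?"

NT_LINE_RE <- paste0(
  "^[[:space:]]*",
  "(?:", IRI_RE, "|", BNODE_RE, ")[[:space:]]+",
  IRI_RE, "[[:space:]]+",
  "(?:", IRI_RE, "|", BNODE_RE, "|", LITERAL_RE, ")",
  "[[:space:]]*\\.[[:space:]]*(?:#.*)?$"
)

parse_ntriples <- function(text, source = NULL) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  rows <- vector("list", length(lines))
  k <- 0L
  for (idx in seq_along(lines)) {
    line <- lines[[idx]]
    if (grepl("^[[:space:]]*$", line) || grepl("^[[:space:]]*#", line)) next
    m <- regmatches(line, regexec(NT_LINE_RE, line))[[1]]
    if (!length(m)) {
      stop(sprintf("N-Triples syntax error at line %d: %s", idx,
                   substr(trimws(line), 1, 80)), call. = FALSE)
    }
    # capture groups: 1 s-iri, 2 s-bnode, 3 p-iri, 4 o-iri, 5 o-bnode,
    #                 6 o-literal, 7 o-datatype, 8 o-lang
    s_kind <- if (nzchar(m[2])) "uri" else "blank"
    s <- if (nzchar(m[2])) unescape_nt(m[2]) else m[3]
    p <- unescape_nt(m[4])
    if (nzchar(m[5])) {
      o <- unescape_nt(m[5]); o_kind <- "uri"; o_dt <- NA; o_lang <- NA
    } else if (nzchar(m[6])) {
      o <- m[6]; o_kind <- "blank"; o_dt <- NA; o_lang <- NA
    } else {
      o <- unescape_nt(m[7]); o_kind <- "literal"
      o_dt <- if (nzchar(m[8])) unescape_nt(m[8]) else NA
      o_lang <- if (nzchar(m[9])) m[9] else NA
    }
    k <- k + 1L
    rows[[k]] <- triple_row(s, s_kind, p, o, o_kind,
                            as.character(o_dt), as.character(o_lang))
  }
  df <- if (k) do.call(rbind, rows[seq_len(k)]) else empty_triple_frame()
  triple_set(df, source = source, format = "ntriples")
}

format_term_nt <- function(val, kind, dt, lang, bnode_as_is = FALSE) {
  ifelse(kind == "uri", paste0("<", val, ">"),
  ifelse(kind == "blank",
         if (bnode_as_is) val else paste0("_:", gsub("[^A-Za-z0-9]", "", val)),
         paste0("\"", vapply(val, escape_nt, ""), "\"",
                ifelse(!is.na(lang), paste0("@", lang),
                ifelse(!is.na(dt), paste0("^^<", dt, ">"), "")))))
}

format_ntriples_rows <- function(df, bnode_as_is = FALSE) {
  if (!nrow(df)) return(character(0))
  s <- format_term_nt(df$s, df$s_kind, NA, NA, bnode_as_is)
  p <- paste0("<", df$p, ">")
  o <- format_term_nt(df$o, df$o_kind, df$o_dt, df$o_lang, bnode_as_is)
  paste(s, p, o, ".")
}

#' Serialize a triple set as N-Triples
#'
#' Output is canonical: triples sorted lexicographically with blank nodes
#' relabelled deterministically, so equal graphs serialize identically.
#'
#' @param ts a \code{triple_set}.
#' @return a single string (LF-separated lines).
#' @export
write_ntriples <- function(ts) {
  canonical_ntriples(ts)
}
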