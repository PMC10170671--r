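# Turtle reader/writer. Notation 3 documents are accepted through the same
# parser: the N3 constructs this tool consumes (prefixes, lists of
# statements, literals) form the Turtle-compatible subset of N3.

# --- relative IRI resolution (RFC 3986, merge subset) ------------------------

resolve_iri <- function(ref, base) {
  if (is.null(base) || !nzchar(ref %||% "")) {
    if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", ref)) return(ref)
    if (is.null(base)) return(ref)
  }
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", ref)) return(ref)
  if (startsWith(ref, "#")) return(paste0(sub("#.*$", "", base), ref))
  if (startsWith(ref, "//")) {
    scheme <- sub(":.*$", "", base)
    return(paste0(scheme, ":", ref))
  }
  root <- sub("^([A-Za-z][A-Za-z0-9+.-]*://[^/]*).*$", "\\1", base)
  if (startsWith(ref, "/")) return(paste0(root, ref))
  dir <- sub("[^/]*$", "", sub("[?#].*$", "", base))
  if (!nzchar(sub("^[A-Za-z][A-Za-z0-9+.-]*:", "", dir))) dir <- paste0(base, "/")
  out <- paste0(dir, ref)
  # collapse ./ and ../ segments
  while (grepl("/\\./", out)) out <- sub("/\\./", "/", out)
  while (grepl("/[^/]+/\\.\\./", out)) out <- sub("/[^/]+/\\.\\./", "/", out)
  out
}

# --- tokenizer ---------------------------------------------------------------

ttl_tokenize <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  peek_str <- function(len) substr(text, pos, min(n, pos + len - 1L))
  match_at <- function(re) {
    m <- regexpr(re, substr(text, pos, min(n, pos + 4095L)), perl = TRUE)
    if (m == 1L) substr(text, pos, pos + attr(m, "match.length") - 1L) else NULL
  }
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("[ \t\r\n]", ch)) { pos <- pos + 1L; next }
    if (ch == "#") {
      nl <- regexpr("\n", substr(text, pos, n), fixed = TRUE)
      if (nl < 0) break
      pos <- pos + nl
      next
    }
    if (ch == "<") {
      m <- match_at("^<[^<>\"{}|^`\\\\[:space:]]*>")
      if (is.null(m)) stop("bad IRI at offset ", pos, call. = FALSE)
      push("IRI", unescape_nt(substr(m, 2, nchar(m) - 1L)))
      pos <- pos + nchar(m)
      next
    }
    if (ch == "\"" || ch == "'") {
      q3 <- paste0(ch, ch, ch)
      if (peek_str(3L) == q3) {
        rest <- substr(text, pos + 3L, n)
        end <- regexpr(q3, rest, fixed = TRUE)
        if (end < 0) stop("unterminated long string", call. = FALSE)
        push("STRING", unescape_nt(substr(rest, 1L, end - 1L)))
        pos <- pos + 3L + end - 1L + 3L
        next
      }
      re <- if (ch == "\"") "^\"(?:[^\"\\\\\\n]|\\\\.)*\"" else "^'(?:[^'\\\\\\n]|\\\\.)*'"
      m <- match_at(re)
      if (is.null(m)) stop("unterminated string at offset ", pos, call. = FALSE)
      push("STRING", unescape_nt(substr(m, 2, nchar(m) - 1L)))
      pos <- pos + nchar(m)
      next
    }
    if (peek_str(2L) == "^^") { push("DTSEP", "^^"); pos <- pos + 2L; next }
    if (ch == "@") {
      m <- match_at("^@(prefix|base)\\b")
      if (!is.null(m)) { push("DIRECTIVE", substr(m, 2, nchar(m))); pos <- pos + nchar(m); next }
      m <- match_at("^@[A-Za-z]+(-[A-Za-z0-9]+)*")
      if (is.null(m)) stop("bad language tag at offset ", pos, call. = FALSE)
      push("LANGTAG", substr(m, 2, nchar(m)))
      pos <- pos + nchar(m)
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      # distinguish statement dot from a decimal's dot (handled by NUMBER re)
      push(ch, ch); pos <- pos + 1L; next
    }
    m <- match_at("^_:[A-Za-z0-9_][A-Za-z0-9._-]*")
    if (!is.null(m)) { push("BNODE", sub("^_:", "", m)); pos <- pos + nchar(m); next }
    m <- match_at("^[+-]?(\\d+\\.\\d*|\\.\\d+|\\d+)([eE][+-]?\\d+)?")
    if (!is.null(m)) {
      nxt <- substr(text, pos + nchar(m), pos + nchar(m))
      # "1." at statement end: the dot belongs to the statement
      if (endsWith(m, ".") && (nxt == "" || grepl("[ \t\r\n]", nxt))) {
        m <- substr(m, 1, nchar(m) - 1L)
      }
      push("NUMBER", m); pos <- pos + nchar(m); next
    }
    m <- match_at("^(true|false)(?![A-Za-z0-9_:])")
    if (!is.null(m)) { push("BOOLEAN", m); pos <- pos + nchar(m); next }
    m <- match_at("^(PREFIX|BASE)\\b")
    if (!is.null(m)) { push("DIRECTIVE", tolower(m)); pos <- pos + nchar(m); next }
    m <- match_at("^a(?![A-Za-z0-9_:-])")
    if (!is.null(m)) { push("A", "a"); pos <- pos + 1L; next }
    # prefixed name: PN_PREFIX? ':' PN_LOCAL?
    m <- match_at("^[A-Za-z0-9_\\-.À-￿]*:[A-Za-z0-9_\\-.%À-￿]*")
    if (!is.null(m)) {
      while (endsWith(m, ".")) m <- substr(m, 1, nchar(m) - 1L)  # trailing dot = statement end
      push("PNAME", m); pos <- pos + nchar(m); next
    }
    stop(sprintf("Turtle syntax error at offset %d near %s", pos,
                 substr(text, pos, pos + 24L)), call. = FALSE)
  }
  push("EOF", "")
  tokens
}

# --- parser ------------------------------------------------------------------

ttl_parser_env <- function(tokens, base) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env$prefixes <- list()
  env$base <- base
  env$rows <- list()
  env$nrow <- 0L
  env$bnode_counter <- 0L
  env
}

ttl_peek <- function(e) e$tokens[[e$i]]
ttl_next <- function(e) { t <- e$tokens[[e$i]]; e$i <- e$i + 1L; t }
ttl_expect <- function(e, type) {
  t <- ttl_next(e)
  if (t$type != type) {
    stop(sprintf("Turtle parse error: expected '%s' got '%s' (%s)",
                 type, t$type, t$value), call. = FALSE)
  }
  t
}

ttl_emit <- function(e, s, s_kind, p, o, o_kind, o_dt = NA_character_,
                     o_lang = NA_character_) {
  e$nrow <- e$nrow + 1L
  e$rows[[e$nrow]] <- triple_row(s, s_kind, p, o, o_kind, o_dt, o_lang)
}

ttl_fresh_bnode <- function(e) {
  e$bnode_counter <- e$bnode_counter + 1L
  paste0("genid", e$bnode_counter)
}

ttl_expand_pname <- function(e, pname) {
  parts <- regmatches(pname, regexec("^([^:]*):(.*)$", pname))[[1]]
  prefix <- parts[2]; local <- parts[3]
  ns <- e$prefixes[[prefix]]
  if (is.null(ns)) stop("undefined prefix '", prefix, ":'", call. = FALSE)
  paste0(ns, gsub("\\\\(.)", "\\1", local))
}

# returns list(value, kind, dt, lang)
ttl_parse_term <- function(e, as_subject = FALSE) {
  t <- ttl_next(e)
  switch(t$type,
    IRI = list(value = resolve_iri(t$value, e$base), kind = "uri",
               dt = NA_character_, lang = NA_character_),
    PNAME = list(value = ttl_expand_pname(e, t$value), kind = "uri",
                 dt = NA_character_, lang = NA_character_),
    A = list(value = RDF_TYPE, kind = "uri", dt = NA_character_, lang = NA_character_),
    BNODE = list(value = t$value, kind = "blank", dt = NA_character_, lang = NA_character_),
    STRING = {
      nxt <- ttl_peek(e)
      if (nxt$type == "LANGTAG") {
        ttl_next(e)
        list(value = t$value, kind = "literal", dt = NA_character_, lang = nxt$value)
      } else if (nxt$type == "DTSEP") {
        ttl_next(e)
        dt_tok <- ttl_next(e)
        dt <- switch(dt_tok$type,
          IRI = resolve_iri(dt_tok$value, e$base),
          PNAME = ttl_expand_pname(e, dt_tok$value),
          stop("expected datatype IRI after ^^", call. = FALSE))
        list(value = t$value, kind = "literal", dt = dt, lang = NA_character_)
      } else {
        list(value = t$value, kind = "literal", dt = NA_character_, lang = NA_character_)
      }
    },
    NUMBER = {
      dt <- if (grepl("[eE]", t$value)) paste0(XSD_NS, "double")
            else if (grepl("\\.", t$value)) paste0(XSD_NS, "decimal")
            else paste0(XSD_NS, "integer")
      list(value = t$value, kind = "literal", dt = dt, lang = NA_character_)
    },
    BOOLEAN = list(value = t$value, kind = "literal",
                   dt = paste0(XSD_NS, "boolean"), lang = NA_character_),
    "[" = {
      id <- ttl_fresh_bnode(e)
      if (ttl_peek(e)$type != "]") ttl_parse_po_list(e, id, "blank")
      ttl_expect(e, "]")
      list(value = id, kind = "blank", dt = NA_character_, lang = NA_character_)
    },
    "(" = {
      items <- list()
      while (ttl_peek(e)$type != ")") items[[length(items) + 1L]] <- ttl_parse_term(e)
      ttl_expect(e, ")")
      if (!length(items)) {
        list(value = paste0(RDF_NS, "nil"), kind = "uri",
             dt = NA_character_, lang = NA_character_)
      } else {
        ids <- vapply(items, function(x) ttl_fresh_bnode(e), "")
        for (k in seq_along(items)) {
          it <- items[[k]]
          ttl_emit(e, ids[k], "blank", paste0(RDF_NS, "first"),
                   it$value, it$kind, it$dt, it$lang)
          if (k < length(items)) {
            ttl_emit(e, ids[k], "blank", paste0(RDF_NS, "rest"), ids[k + 1L], "blank")
          } else {
            ttl_emit(e, ids[k], "blank", paste0(RDF_NS, "rest"),
                     paste0(RDF_NS, "nil"), "uri")
          }
        }
        list(value = ids[1L], kind = "blank", dt = NA_character_, lang = NA_character_)
      }
    },
    stop("Turtle parse error: unexpected token '", t$value, "'", call. = FALSE)
  )
}

ttl_parse_po_list <- function(e, s, s_kind) {
  repeat {
    pt <- ttl_parse_term(e)
    if (pt$kind != "uri") stop("predicate must be an IRI", call. = FALSE)
    repeat {
      ot <- ttl_parse_term(e)
      if (ot$kind == "literal") {
        ttl_emit(e, s, s_kind, pt$value, ot$value, "literal", ot$dt, ot$lang)
      } else {
        ttl_emit(e, s, s_kind, pt$value, ot$value, ot$kind)
      }
      if (ttl_peek(e)$type == ",") ttl_next(e) else break
    }
    if (ttl_peek(e)$type == ";") {
      ttl_next(e)
      while (ttl_peek(e)$type == ";") ttl_next(e)
      if (ttl_peek(e)$type %in% c(".", "]", "EOF")) break
    } else break
  }
}

parse_turtle <- function(text, source = NULL, base = NULL, format = "turtle") {
  text <- paste(text, collapse = "\n")
  e <- ttl_parser_env(ttl_tokenize(text), base %||% source)
  repeat {
    t <- ttl_peek(e)
    if (t$type == "EOF") break
    if (t$type == "DIRECTIVE") {
      ttl_next(e)
      if (t$value == "prefix") {
        pn <- ttl_expect(e, "PNAME")
        iri <- ttl_expect(e, "IRI")
        prefix <- sub(":$", "", pn$value)
        if (!grepl(":$", pn$value) && nzchar(pn$value)) {
          # tokenizer strips nothing; a prefix declaration is "p:"
          prefix <- sub(":.*$", "", pn$value)
        }
        e$prefixes[[prefix]] <- resolve_iri(iri$value, e$base)
      } else {
        iri <- ttl_expect(e, "IRI")
        e$base <- resolve_iri(iri$value, e$base)
      }
      if (ttl_peek(e)$type == ".") ttl_next(e)
      next
    }
    st <- ttl_parse_term(e, as_subject = TRUE)
    if (st$kind == "literal") stop("subject cannot be a literal", call. = FALSE)
    # a bare blank-node property list may end the statement immediately
    if (!(ttl_peek(e)$type == "." && st$kind == "blank")) {
      ttl_parse_po_list(e, st$value, st$kind)
    }
    ttl_expect(e, ".")
  }
  df <- if (e$nrow) do.call(rbind, e$rows[seq_len(e$nrow)]) else empty_triple_frame()
  triple_set(df, source = source, format = format)
}

# --- writer ------------------------------------------------------------------

DEFAULT_PREFIXES <- c(
  rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS,
  skos = "http://www.w3.org/2004/02/skos/core#",
  dqv = "http://www.w3.org/ns/dqv#",
  prov = "http://www.w3.org/ns/prov#",
  dcterms = "http://purl.org/dc/terms/"
)

ttl_abbrev <- function(iri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(iri, ns)) {
      local <- substr(iri, nchar(ns) + 1L, nchar(iri))
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && !endsWith(local, ".")) {
        return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

ttl_term <- function(val, kind, dt, lang, prefixes) {
  if (kind == "uri") return(ttl_abbrev(val, prefixes))
  if (kind == "blank") return(paste0("_:", gsub("[^A-Za-z0-9]", "", val)))
  out <- paste0("\"", escape_nt(val), "\"")
  if (!is.na(lang)) return(paste0(out, "@", lang))
  if (!is.na(dt)) return(paste0(out, "^^", ttl_abbrev(dt, prefixes)))
  out
}

#' Serialize a triple set as Turtle
#'
#' Deterministic output: subjects and predicates sorted, well-known
#' prefixes applied. Blank nodes are written with stable generated labels.
#'
#' @param ts a \code{triple_set}.
#' @param prefixes named character vector of prefix to namespace mappings;
#'   defaults cover rdf/rdfs/owl/xsd/skos/dqv/prov/dcterms.
#' @return single string of Turtle (LF line endings).
#' @export
write_turtle <- function(ts, prefixes = DEFAULT_PREFIXES) {
  df <- ts$triples
  used <- vapply(names(prefixes), function(p) {
    ns <- prefixes[[p]]
    any(startsWith(df$s, ns)) || any(startsWith(df$p, ns)) ||
      any(startsWith(df$o[df$o_kind == "uri"], ns)) ||
      any(startsWith(df$o_dt[!is.na(df$o_dt)], ns))
  }, TRUE)
  header <- sprintf("@prefix %s: <%s> .", names(prefixes)[used], prefixes[used])
  if (!nrow(df)) return(paste(c(header, ""), collapse = "\n"))
  skey <- paste(df$s_kind, df$s)
  out <- character(0)
  for (sk in sort(unique(skey))) {
    rows <- df[skey == sk, , drop = FALSE]
    subj <- ttl_term(rows$s[1], rows$s_kind[1], NA, NA, prefixes)
    rows <- rows[order(rows$p != RDF_TYPE, rows$p, rows$o), , drop = FALSE]
    body <- character(0)
    for (p in unique(rows$p)) {
      pr <- rows[rows$p == p, , drop = FALSE]
      pred <- if (p == RDF_TYPE) "a" else ttl_abbrev(p, prefixes)
      objs <- vapply(seq_len(nrow(pr)), function(i) {
        ttl_term(pr$o[i], pr$o_kind[i], pr$o_dt[i], pr$o_lang[i], prefixes)
      }, "")
      body <- c(body, paste0("    ", pred, " ", paste(objs, collapse = ", ")))
    }
    out <- c(out, paste0(subj, "\n", paste(body, collapse = " ;\n"), " ."))
  }
  paste(c(header, "", out, ""), collapse = "\n")
}
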