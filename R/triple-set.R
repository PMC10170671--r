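empty_triple_frame <- function() {
  data.frame(
    s = character(), s_kind = character(), p = character(),
    o = character(), o_kind = character(), o_dt = character(),
    o_lang = character(), stringsAsFactors = FALSE
  )
}

triple_row <- function(s, s_kind, p, o, o_kind, o_dt = NA_character_,
                       o_lang = NA_character_) {
  data.frame(s = s, s_kind = s_kind, p = p, o = o, o_kind = o_kind,
             o_dt = o_dt, o_lang = o_lang, stringsAsFactors = FALSE)
}

#' Construct a triple set
#'
#' A triple set is the parsed content of one RDF document: a deduplicated
#' table of triples with explicit node kinds, so a literal \code{"x"} is
#' never conflated with a URI node of the same lexical form.
#'
#' @param triples data.frame with columns \code{s}, \code{s_kind}
#'   (\code{"uri"} or \code{"blank"}), \code{p} (always a URI), \code{o},
#'   \code{o_kind} (\code{"uri"}, \code{"blank"} or \code{"literal"}),
#'   \code{o_dt} (datatype IRI or \code{NA}), \code{o_lang} (language tag
#'   or \code{NA}).
#' @param source optional file path or URI the triples were read from.
#' @param format one of \code{"turtle"}, \code{"rdfxml"},
#'   \code{"ntriples"}, \code{"n3"}, \code{"jsonld"}.
#' @return an object of class \code{triple_set}.
#' @export
triple_set <- function(triples = empty_triple_frame(), source = NULL,
                       format = "turtle") {
  stopifnot(is.data.frame(triples))
  if (!format %in% RDF_FORMATS) {
    stop("unknown RDF format label: ", format, call. = FALSE)
  }
  need <- c("s", "s_kind", "p", "o", "o_kind", "o_dt", "o_lang")
  missing_cols <- setdiff(need, names(triples))
  if (length(missing_cols)) {
    stop("triples frame lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  triples <- triples[, need, drop = FALSE]
  if (nrow(triples)) {
    bad <- !triples$s_kind %in% c("uri", "blank")
    if (any(bad)) stop("subject must be a URI or blank node")
    bad <- !triples$o_kind %in% c("uri", "blank", "literal")
    if (any(bad)) stop("object must be a URI, blank node or literal")
    # set semantics: collapse duplicate triples
    key <- triple_keys(triples)
    triples <- triples[!duplicated(key), , drop = FALSE]
    rownames(triples) <- NULL
  }
  structure(list(triples = triples, source = source, format = format),
            class = "triple_set")
}

triple_keys <- function(df) {
  paste(df$s_kind, df$s, df$p, df$o_kind, df$o,
        ifelse(is.na(df$o_dt), "", df$o_dt),
        ifelse(is.na(df$o_lang), "", df$o_lang), sep = "\r")
}

#' @export
print.triple_set <- function(x, ...) {
  cat(sprintf("<triple_set: %d triple(s), format=%s%s>\n",
              nrow(x$triples), x$format,
              if (!is.null(x$source)) paste0(", source=", x$source) else ""))
  invisible(x)
}

#' Number of triples in a triple set
#' @param ts a \code{triple_set}.
#' @return integer count of (distinct) triples.
#' @export
n_triples <- function(ts) nrow(ts$triples)

#' Test for a structured parse failure
#' @param x object returned by \code{\link{parse_content}} or
#'   \code{\link{fetch_and_parse}}.
#' @return TRUE when \code{x} is an \code{rdf_parse_failure}.
#' @export
is_parse_failure <- function(x) inherits(x, "rdf_parse_failure")

parse_failure <- function(message, format = NA_character_) {
  structure(list(message = as.character(message), format = format),
            class = "rdf_parse_failure")
}

#' @export
print.rdf_parse_failure <- function(x, ...) {
  cat(sprintf("<rdf parse failure [%s]: %s>\n", x$format, x$message))
  invisible(x)
}

#' Extract the unique-URI inventory of a triple set
#'
#' Every distinct URI appearing in subject, predicate or object position is
#' listed exactly once with its per-role occurrence counts. Blank nodes and
#' literals are never inventoried, and datatype IRIs of typed literals do
#' not count as graph nodes. The inventory size is the denominator used by
#' the URI-level quality metrics ("all unique URIs").
#'
#' @param ts a \code{triple_set}.
#' @return a \code{uri_inventory}: data.frame with columns \code{uri},
#'   \code{as_subject}, \code{as_predicate}, \code{as_object}, plus
#'   attribute \code{total_triples}.
#' @export
extract_unique_uris <- function(ts) {
  df <- ts$triples
  subj <- df$s[df$s_kind == "uri"]
  pred <- df$p
  obj  <- df$o[df$o_kind == "uri"]
  uris <- sort(unique(c(subj, pred, obj)))
  inv <- data.frame(
    uri = uris,
    as_subject = as.integer(table(factor(subj, levels = uris))),
    as_predicate = as.integer(table(factor(pred, levels = uris))),
    as_object = as.integer(table(factor(obj, levels = uris))),
    stringsAsFactors = FALSE
  )
  structure(inv, total_triples = nrow(df), class = c("uri_inventory", "data.frame"))
}

#' Count triples affected by a set of erroneous URIs
#'
#' A triple is affected when at least one member of \code{bad_uris} occurs
#' in any of its three positions; each triple is counted at most once even
#' if several bad URIs co-occur in it.
#'
#' @param ts a \code{triple_set}.
#' @param bad_uris character vector of URIs.
#' @return integer count of distinct affected triples.
#' @export
count_affected_triples <- function(ts, bad_uris) {
  if (!length(bad_uris)) return(0L)
  df <- ts$triples
  hit <- (df$s_kind == "uri" & df$s %in% bad_uris) |
    (df$p %in% bad_uris) |
    (df$o_kind == "uri" & df$o %in% bad_uris)
  sum(hit)
}

# --- graph equality up to blank-node bijection -------------------------------

bnode_signature_pass <- function(df, labels) {
  # one refinement round: hash each blank node's incident triples using
  # current labels for neighbouring blank nodes
  sig <- labels
  for (b in names(labels)) {
    rows_s <- df[df$s_kind == "blank" & df$s == b, , drop = FALSE]
    rows_o <- df[df$o_kind == "blank" & df$o == b, , drop = FALSE]
    enc <- function(kind, val) ifelse(kind == "blank", unname(labels[val]), paste0(kind, val))
    parts <- c(
      sort(paste0("S|", rows_s$p, "|", enc(rows_s$o_kind, rows_s$o),
                  "|", rows_s$o_dt, "|", rows_s$o_lang)),
      sort(paste0("O|", enc(rows_o$s_kind, rows_o$s), "|", rows_o$p))
    )
    sig[b] <- paste0(labels[b], "::", paste(parts, collapse = ";"))
  }
  # compress signatures to stable short labels
  uniq <- sort(unique(sig))
  stats::setNames(match(sig, uniq), names(sig))
}

canonical_ntriples <- function(ts) {
  df <- ts$triples
  bn <- unique(c(df$s[df$s_kind == "blank"], df$o[df$o_kind == "blank"]))
  if (length(bn)) {
    labels <- stats::setNames(rep(0L, length(bn)), bn)
    for (i in seq_len(max(3L, length(bn)))) {
      new_labels <- bnode_signature_pass(df, labels)
      if (identical(unname(new_labels), unname(labels))) break
      labels <- new_labels
    }
    # break remaining ties deterministically by signature then occurrence
    ord <- order(labels, names(labels))
    final <- stats::setNames(paste0("_:c", seq_along(bn)), names(labels)[ord])
    df$s <- ifelse(df$s_kind == "blank", unname(final[df$s]), df$s)
    df$o <- ifelse(df$o_kind == "blank", unname(final[df$o]), df$o)
  }
  lines <- format_ntriples_rows(df, bnode_as_is = TRUE)
  paste(sort(lines), collapse = "\n")
}

#' Test two triple sets for graph equality
#'
#' Equality is per RDF graph semantics: triple sets are equal when there is
#' a blank-node bijection making them identical. Ground (blank-node-free)
#' graphs compare by set equality of triples.
#'
#' @param a,b \code{triple_set} objects.
#' @return logical.
#' @export
ts_equal <- function(a, b) {
  if (n_triples(a) != n_triples(b)) return(FALSE)
  identical(canonical_ntriples(a), canonical_ntriples(b))
}

# subjects of a triple set (URIs only unless blanks requested)
ts_subjects <- function(ts, blanks = FALSE) {
  df <- ts$triples
  if (blanks) unique(df$s) else unique(df$s[df$s_kind == "uri"])
}

# all statements about one subject URI
ts_about <- function(ts, uri) {
  df <- ts$triples
  df[df$s_kind == "uri" & df$s == uri, , drop = FALSE]
}

# merge several triple sets (set union)
ts_union <- function(..., format = "turtle") {
  parts <- Filter(function(x) inherits(x, "triple_set"), list(...))
  df <- do.call(rbind, c(lapply(parts, `[[`, "triples"), list(empty_triple_frame())))
  triple_set(df, format = format)
}
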