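# RDF/XML reader built on xml2. XML well-formedness comes from libxml2;
# the RDF abstract-syntax mapping (node elements, property elements,
# rdf:about / rdf:ID / rdf:nodeID / rdf:resource, datatypes, xml:lang)
# is implemented here. rdf:ID values are validated as XML NCNames: an
# invalid non-colonized name is an RDF-level parse error even though the
# XML itself is well-formed.

XMLNS_XML <- "http://www.w3.org/XML/1998/namespace"

is_ncname <- function(x) {
  grepl("^[_\\p{L}][-._\\p{L}\\p{Nd}]*$", x, perl = TRUE)
}

rx_env <- function(doc, base) {
  e <- new.env(parent = emptyenv())
  e$rows <- list(); e$nrow <- 0L; e$base <- base; e$bn <- 0L
  ns <- tryCatch(as.character(xml2::xml_ns(doc)), error = function(err) character(0))
  ns_names <- tryCatch(names(xml2::xml_ns(doc)), error = function(err) character(0))
  names(ns) <- ns_names
  if (!XMLNS_XML %in% ns) ns <- c(ns, xml = XMLNS_XML)
  e$ns <- ns
  e
}

rx_emit <- function(e, s, s_kind, p, o, o_kind, o_dt = NA_character_,
                    o_lang = NA_character_) {
  e$nrow <- e$nrow + 1L
  e$rows[[e$nrow]] <- triple_row(s, s_kind, p, o, o_kind, o_dt, o_lang)
}

rx_fresh <- function(e) { e$bn <- e$bn + 1L; paste0("xgen", e$bn) }

# qualified attributes of a node, names resolved to "nsURI|local";
# unprefixed attributes keep a bare local name
rx_attrs <- function(e, node) {
  attrs <- xml2::xml_attrs(node, ns = e$ns)
  if (!length(attrs)) return(attrs)
  qualified <- vapply(names(attrs), function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% names(e$ns)) {
      paste0(e$ns[[parts[1]]], "|", parts[2])
    } else {
      nm
    }
  }, "")
  names(attrs) <- qualified
  attrs
}

rx_attr <- function(attrs, ns_uri, local) {
  v <- unname(attrs[match(paste0(ns_uri, "|", local), names(attrs))])
  if (!length(v) || is.na(v)) NULL else v
}

rx_expand_name <- function(e, node) {
  qn <- xml2::xml_name(node, ns = e$ns)
  parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2L && parts[1] %in% names(e$ns)) {
    return(paste0(e$ns[[parts[1]]], parts[2]))
  }
  stop("element '", qn, "' has no namespace", call. = FALSE)
}

RDFXML_SYNTAX_ATTRS <- c("about", "ID", "nodeID", "resource", "datatype",
                         "parseType", "RDF", "li")

rx_node_id <- function(e, attrs) {
  about <- rx_attr(attrs, RDF_NS, "about")
  id <- rx_attr(attrs, RDF_NS, "ID")
  node_id <- rx_attr(attrs, RDF_NS, "nodeID")
  if (!is.null(about)) return(list(value = resolve_iri(about, e$base), kind = "uri"))
  if (!is.null(id)) {
    if (!is_ncname(id)) {
      stop("rdf:ID value is not a valid NCName: '", id, "'", call. = FALSE)
    }
    return(list(value = resolve_iri(paste0("#", id), e$base), kind = "uri"))
  }
  if (!is.null(node_id)) return(list(value = node_id, kind = "blank"))
  list(value = rx_fresh(e), kind = "blank")
}

rx_process_node_element <- function(e, node) {
  attrs <- rx_attrs(e, node)
  subj <- rx_node_id(e, attrs)
  name <- rx_expand_name(e, node)
  if (name != paste0(RDF_NS, "Description")) {
    rx_emit(e, subj$value, subj$kind, RDF_TYPE, name, "uri")
  }
  # property attributes: namespaced, neither rdf syntax nor xml:
  for (an in names(attrs)) {
    if (!grepl("|", an, fixed = TRUE)) next
    parts <- strsplit(an, "|", fixed = TRUE)[[1]]
    if (parts[1] == XMLNS_XML) next
    if (parts[1] == RDF_NS && parts[2] %in% RDFXML_SYNTAX_ATTRS) next
    if (parts[1] == RDF_NS && parts[2] == "type") {
      rx_emit(e, subj$value, subj$kind, RDF_TYPE,
              resolve_iri(attrs[[an]], e$base), "uri")
      next
    }
    rx_emit(e, subj$value, subj$kind, paste0(parts[1], parts[2]),
            attrs[[an]], "literal")
  }
  for (child in xml2::xml_children(node)) {
    rx_process_property_element(e, subj, child)
  }
  subj
}

rx_process_property_element <- function(e, subj, node) {
  pred <- rx_expand_name(e, node)
  if (pred == paste0(RDF_NS, "li")) {
    stop("rdf:li containers are not supported", call. = FALSE)
  }
  attrs <- rx_attrs(e, node)
  rid <- rx_attr(attrs, RDF_NS, "ID")
  if (!is.null(rid) && !is_ncname(rid)) {
    stop("rdf:ID value is not a valid NCName: '", rid, "'", call. = FALSE)
  }
  resource <- rx_attr(attrs, RDF_NS, "resource")
  node_id <- rx_attr(attrs, RDF_NS, "nodeID")
  datatype <- rx_attr(attrs, RDF_NS, "datatype")
  parse_type <- rx_attr(attrs, RDF_NS, "parseType")
  lang <- rx_attr(attrs, XMLNS_XML, "lang")
  children <- xml2::xml_children(node)
  if (!is.null(resource)) {
    rx_emit(e, subj$value, subj$kind, pred, resolve_iri(resource, e$base), "uri")
  } else if (!is.null(node_id)) {
    rx_emit(e, subj$value, subj$kind, pred, node_id, "blank")
  } else if (identical(parse_type, "Resource")) {
    inner <- list(value = rx_fresh(e), kind = "blank")
    rx_emit(e, subj$value, subj$kind, pred, inner$value, "blank")
    for (child in children) rx_process_property_element(e, inner, child)
  } else if (identical(parse_type, "Literal")) {
    xml_text <- paste(vapply(children, as.character, ""), collapse = "")
    rx_emit(e, subj$value, subj$kind, pred, xml_text, "literal",
            paste0(RDF_NS, "XMLLiteral"))
  } else if (length(children)) {
    obj <- rx_process_node_element(e, children[[1]])
    rx_emit(e, subj$value, subj$kind, pred, obj$value, obj$kind)
  } else {
    rx_emit(e, subj$value, subj$kind, pred, xml2::xml_text(node), "literal",
            datatype %||% NA_character_, lang %||% NA_character_)
  }
}

parse_rdfxml <- function(text, source = NULL, base = NULL) {
  doc <- xml2::read_xml(paste(text, collapse = "\n"))
  root <- xml2::xml_root(doc)
  e <- rx_env(doc, base %||% source)
  root_attrs <- rx_attrs(e, root)
  xml_base <- rx_attr(root_attrs, XMLNS_XML, "base")
  if (!is.null(xml_base)) e$base <- xml_base
  root_name <- rx_expand_name(e, root)
  nodes <- if (root_name == paste0(RDF_NS, "RDF")) xml2::xml_children(root) else list(root)
  for (node in nodes) rx_process_node_element(e, node)
  df <- if (e$nrow) do.call(rbind, e$rows[seq_len(e$nrow)]) else empty_triple_frame()
  triple_set(df, source = source, format = "rdfxml")
}
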