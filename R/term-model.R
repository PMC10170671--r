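# Classification of defined URIs as classes or properties, plus
# deprecation detection. Evidence is the union of what the assessed
# resource itself says about a term and what the term's dereferenced
# (defining) document says; no RDFS/OWL entailment is applied.

CLASS_TYPES <- c(
  paste0(OWL_NS, "Class"),
  paste0(RDFS_NS, "Class")
)

PROPERTY_TYPES <- c(
  "rdf-property" = paste0(RDF_NS, "Property"),
  "object-property" = paste0(OWL_NS, "ObjectProperty"),
  "datatype-property" = paste0(OWL_NS, "DatatypeProperty"),
  "annotation-property" = paste0(OWL_NS, "AnnotationProperty"),
  "functional-property" = paste0(OWL_NS, "FunctionalProperty"),
  "transitive-property" = paste0(OWL_NS, "TransitiveProperty"),
  "symmetric-property" = paste0(OWL_NS, "SymmetricProperty"),
  "inverse-functional-property" = paste0(OWL_NS, "InverseFunctionalProperty")
)

#' Is a URI defined in its dereferenced graph?
#'
#' A URI counts as defined when it appears as the subject of at least one
#' triple in the graph obtained by resolving it. For hash URIs the full
#' URI (fragment included) is matched: the fragment identifier is the
#' term.
#'
#' @param uri the URI under test.
#' @param resolved the \code{triple_set} parsed from dereferencing it.
#' @return logical.
#' @export
is_defined <- function(uri, resolved) {
  df <- resolved$triples
  any(df$s_kind == "uri" & df$s == uri)
}

#' Classify a term as class and/or property and detect deprecation
#'
#' A URI is a class when typed \code{owl:Class} or \code{rdfs:Class}
#' without any property type; it is a property when typed
#' \code{rdf:Property} or any OWL property type. A URI typed both ways is
#' treated as a property (the class reading requires the absence of
#' property types) and flagged with a consistency warning.
#'
#' @param uri the term URI (must be defined in \code{resolved}).
#' @param local \code{triple_set} of the assessed resource (statements
#'   about the term in the resource itself).
#' @param resolved \code{triple_set} from dereferencing the term; the
#'   defining document is authoritative, local statements are the offline
#'   fallback.
#' @return a \code{term_classification}: list with \code{uri},
#'   \code{is_class}, \code{property_kinds}, \code{deprecated},
#'   \code{warnings}.
#' @export
classify_term <- function(uri, local = NULL, resolved = NULL) {
  about <- rbind(
    if (!is.null(local)) ts_about(local, uri) else empty_triple_frame(),
    if (!is.null(resolved)) ts_about(resolved, uri) else empty_triple_frame()
  )
  types <- unique(about$o[about$p == RDF_TYPE & about$o_kind == "uri"])
  kinds <- names(PROPERTY_TYPES)[PROPERTY_TYPES %in% types]
  has_class_type <- any(types %in% CLASS_TYPES)
  warnings <- character(0)
  if (has_class_type && length(kinds)) {
    warnings <- "typed as both class and property; treated as property"
  }
  structure(list(
    uri = uri,
    is_class = has_class_type && !length(kinds),
    property_kinds = kinds,
    deprecated = is_deprecated(uri, local, resolved),
    warnings = warnings
  ), class = "term_classification")
}

#' Is a term deprecated?
#'
#' TRUE iff an \code{owl:deprecated} statement about the URI exists in the
#' local or resolved graph whose object is a literal with case-folded
#' lexical form \code{"true"} or \code{"1"} (boolean-typed or plain).
#' Deprecation depends only on statements about the term, never on where
#' it is used.
#'
#' @inheritParams classify_term
#' @return logical.
#' @export
is_deprecated <- function(uri, local = NULL, resolved = NULL) {
  about <- rbind(
    if (!is.null(local)) ts_about(local, uri) else empty_triple_frame(),
    if (!is.null(resolved)) ts_about(resolved, uri) else empty_triple_frame()
  )
  dep <- about[about$p == OWL_DEPRECATED & about$o_kind == "literal", , drop = FALSE]
  any(tolower(dep$o) %in% c("true", "1"))
}

is_property_classification <- function(cls) length(cls$property_kinds) > 0L
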