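# Assessment reports: CSV summary/errors (counts are authoritative,
# percentages are re-derived at 1 decimal), an RDF quality-metadata graph
# aligned with DQV, and the FQM metric vocabulary itself.

DQV_NS  <- "http://www.w3.org/ns/dqv#"
SKOS_NS <- "http://www.w3.org/2004/02/skos/core#"
PROV_NS <- "http://www.w3.org/ns/prov#"
LDQD_NS <- "http://www.w3.org/2016/05/ldqd#"
FQM_DEFAULT_BASE <- "https://purl.org/fqm#"

FQM_METRICS <- list(
  non_resolvable = list(
    local = "nonResolvableURIs",
    label = "Non-resolvable URIs",
    category = "Resolvability",
    dimension = "availability",
    definition = paste(
      "Measure the proportion of unique non-resolvable URIs to all unique",
      "URIs in an RDF resource. A URI is non-resolvable if it returns an",
      "error code (e.g., http 404).")
  ),
  non_parsable = list(
    local = "nonParsableURIs",
    label = "Non-parsable URIs",
    category = "Parsability",
    dimension = "syntacticValidity",
    definition = paste(
      "Measure the proportion of unique non-parsable URIs to all unique",
      "URIs in an RDF resource. A URI is non-parsable if its media type is",
      "indicated as RDF content-type, but its content cannot be parsed as",
      "RDF triples.")
  ),
  undefined = list(
    local = "undefinedURIs",
    label = "Undefined URIs",
    category = "Consistency",
    dimension = "consistency",
    definition = paste(
      "Measure the proportion of unique, undefined URIs to all unique URIs",
      "in an RDF resource. A URI is considered as undefined if it does not",
      "exist within the parsed RDF triples resulting from resolving the",
      "URI.")
  ),
  misplaced = list(
    local = "misplacedClassesOrProperties",
    label = "Misplaced classes or properties",
    category = "Consistency",
    dimension = "consistency",
    definition = paste(
      "1) Measure the proportion of classes which are incorrectly used as",
      "a predicate to all unique classes; or 2) measure the proportion of",
      "properties which are incorrectly used as a class to all unique",
      "properties.")
  ),
  property_misuse = list(
    local = "misuseOfDatatypeOrObjectProperties",
    label = "Misuse of owl:DatatypeProperty or owl:ObjectProperty",
    category = "Consistency",
    dimension = "consistency",
    definition = paste(
      "Measure the proportion of misused owl:DatatypeProperty (or",
      "owl:ObjectProperty) properties to all properties.")
  ),
  deprecated_usage = list(
    local = "useOfDeprecatedClassesOrProperties",
    label = "Use of deprecated classes or properties",
    category = "Consistency",
    dimension = "consistency",
    definition = paste(
      "Measure the proportion of deprecated classes or properties to all",
      "unique classes or properties.")
  )
)

fmt_pct <- function(num, den) {
  if (den == 0) return("0.0")
  sprintf("%.1f", 100 * num / den)
}

csv_quote <- function(x) {
  needs <- grepl("[\",\n]", x)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
  x
}

write_csv_lines <- function(df, path) {
  cols <- lapply(df, function(x) csv_quote(as.character(x)))
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the CSV assessment report
#'
#' \code{summary.csv}: exactly six rows, one per metric, fixed column
#' order, counts plus percentages at 1 decimal. \code{errors.csv}: one row
#' per erroneous URI per metric with its error category and the number of
#' triples it affects. UTF-8, comma-separated, LF line endings.
#'
#' @param assessment an \code{rdf_assessment}.
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_csv_report <- function(assessment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(!is.null(assessment$metrics))
  rows <- lapply(METRIC_IDS, function(id) {
    m <- assessment$metrics[[id]]
    data.frame(
      metric_id = id,
      category = FQM_METRICS[[id]]$category,
      numerator = m$numerator,
      denominator = m$denominator,
      pct = fmt_pct(m$numerator, m$denominator),
      affected_triples = m$affected_triples,
      total_triples = m$total_triples,
      affected_pct = fmt_pct(m$affected_triples, m$total_triples),
      stringsAsFactors = FALSE
    )
  })
  summary_path <- file.path(out_dir, "summary.csv")
  write_csv_lines(do.call(rbind, rows), summary_path)

  err_rows <- list()
  for (id in METRIC_IDS) {
    m <- assessment$metrics[[id]]
    for (u in m$error_uris) {
      cat_detail <- if (id == "non_resolvable") {
        as.character(assessment$context$resolutions[[u]]$final_status)
      } else id
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        metric_id = id, error_uri = u, error_category = cat_detail,
        n_affected_triples = count_affected_triples(assessment$context$source, u),
        stringsAsFactors = FALSE
      )
    }
  }
  errors_path <- file.path(out_dir, "errors.csv")
  err_df <- if (length(err_rows)) do.call(rbind, err_rows) else
    data.frame(metric_id = character(), error_uri = character(),
               error_category = character(), n_affected_triples = integer())
  write_csv_lines(err_df, errors_path)
  invisible(c(summary_path, errors_path))
}

#' Emit the Foundational Quality Metrics vocabulary
#'
#' A graph declaring the six metrics as \code{dqv:Metric} instances, each
#' with a label, a definition, a category (Resolvability, Parsability or
#' Consistency) and one \code{dqv:inDimension} link to the corresponding
#' linked-data-quality dimension.
#'
#' @param base namespace the metric IRIs are minted under.
#' @return a \code{triple_set}.
#' @export
emit_fqm_vocabulary <- function(base = FQM_DEFAULT_BASE) {
  rows <- list()
  add <- function(s, p, o, kind, dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- triple_row(s, "uri", p, o, kind, dt)
  }
  categories <- unique(vapply(FQM_METRICS, `[[`, "", "category"))
  for (cat in categories) {
    cat_iri <- paste0(base, cat)
    add(cat_iri, RDF_TYPE, paste0(DQV_NS, "Category"), "uri")
    add(cat_iri, paste0(SKOS_NS, "prefLabel"), cat, "literal")
  }
  for (id in names(FQM_METRICS)) {
    meta <- FQM_METRICS[[id]]
    iri <- paste0(base, meta$local)
    add(iri, RDF_TYPE, paste0(DQV_NS, "Metric"), "uri")
    add(iri, paste0(SKOS_NS, "prefLabel"), meta$label, "literal")
    add(iri, paste0(SKOS_NS, "definition"), meta$definition, "literal")
    add(iri, paste0(base, "inCategory"), paste0(base, meta$category), "uri")
    add(iri, paste0(DQV_NS, "inDimension"), paste0(LDQD_NS, meta$dimension), "uri")
    add(iri, paste0(DQV_NS, "expectedDataType"), paste0(XSD_NS, "double"), "uri")
  }
  triple_set(do.call(rbind, rows), format = "turtle")
}

assessed_resource_iri <- function(source) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", source)) source
  else paste0("file://", source)
}

#' Build the RDF quality-metadata graph for an assessment
#'
#' One \code{dqv:QualityMeasurement} node per metric carrying the computed
#' proportion, linked to its FQM metric IRI and to the assessed resource;
#' the report node records \code{prov:generatedAtTime}.
#'
#' @param assessment an \code{rdf_assessment}.
#' @param base FQM namespace for metric IRIs.
#' @return a \code{triple_set}.
#' @export
build_quality_graph <- function(assessment, base = FQM_DEFAULT_BASE) {
  stopifnot(!is.null(assessment$metrics))
  resource <- assessed_resource_iri(assessment$source)
  report_iri <- "urn:rdfquality:report"
  rows <- list()
  add <- function(s, p, o, kind, dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- triple_row(s, "uri", p, o, kind, dt)
  }
  add(report_iri, RDF_TYPE, paste0(DQV_NS, "QualityMetadata"), "uri")
  add(report_iri, paste0(PROV_NS, "generatedAtTime"), assessment$timestamp,
      "literal", paste0(XSD_NS, "dateTime"))
  add(report_iri, paste0(DQV_NS, "computedOn"), resource, "uri")
  for (id in METRIC_IDS) {
    m <- assessment$metrics[[id]]
    node <- paste0("urn:rdfquality:measurement:", id)
    add(node, RDF_TYPE, paste0(DQV_NS, "QualityMeasurement"), "uri")
    add(node, paste0(DQV_NS, "isMeasurementOf"),
        paste0(base, FQM_METRICS[[id]]$local), "uri")
    add(node, paste0(DQV_NS, "computedOn"), resource, "uri")
    add(node, paste0(DQV_NS, "value"), sprintf("%.17g", m$proportion),
        "literal", paste0(XSD_NS, "double"))
    add(report_iri, paste0(DQV_NS, "hasQualityMeasurement"), node, "uri")
  }
  triple_set(do.call(rbind, rows), format = "turtle")
}

#' Write the complete report set for an assessment
#'
#' \code{summary.csv}, \code{errors.csv}, \code{report.ttl} (the DQV
#' quality graph) and \code{fqm.ttl} (the metric vocabulary).
#'
#' @inheritParams write_csv_report
#' @param base FQM namespace.
#' @return paths written, invisibly.
#' @export
write_reports <- function(assessment, out_dir, base = FQM_DEFAULT_BASE) {
  paths <- write_csv_report(assessment, out_dir)
  report_path <- file.path(out_dir, "report.ttl")
  ttl_prefixes <- c(DEFAULT_PREFIXES, fqm = base, ldqd = LDQD_NS)
  writeLines(write_turtle(build_quality_graph(assessment, base), ttl_prefixes),
             report_path, sep = "", useBytes = TRUE)
  vocab_path <- file.path(out_dir, "fqm.ttl")
  writeLines(write_turtle(emit_fqm_vocabulary(base), ttl_prefixes),
             vocab_path, sep = "", useBytes = TRUE)
  invisible(c(paths, report_path, vocab_path))
}
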