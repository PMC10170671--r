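# The six foundational quality metrics, computed over the unique-URI
# inventory, the resolution records, and the term classifications.
# Error sets follow the funnel: a URI failing resolvability is never
# tested for parsability, a non-parsable one never for definedness, and
# the term-usage metrics see only defined terms (misplacement and misuse
# only non-deprecated ones).

METRIC_IDS <- c("non_resolvable", "non_parsable", "undefined",
                "misplaced", "property_misuse", "deprecated_usage")

metric_result <- function(metric_id, error_uris, denominator, ctx,
                          detail = NULL, eligible = NA_integer_) {
  error_uris <- sort(unique(error_uris))
  numerator <- length(error_uris)
  total <- attr(ctx$inventory, "total_triples")
  affected <- count_affected_triples(ctx$source, error_uris)
  structure(list(
    metric_id = metric_id,
    error_uris = error_uris,
    numerator = numerator,
    denominator = as.integer(denominator),
    proportion = if (denominator > 0) numerator / denominator else 0,
    affected_triples = affected,
    total_triples = total,
    affected_proportion = if (total > 0) affected / total else 0,
    eligible = as.integer(eligible),
    detail = detail
  ), class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%-18s %d/%d (%.1f%%)  affected %d/%d (%.1f%%)\n",
              x$metric_id, x$numerator, x$denominator, 100 * x$proportion,
              x$affected_triples, x$total_triples,
              100 * x$affected_proportion))
  invisible(x)
}

#' Build the assessment context for a parsed resource
#'
#' Executes the dereferencing stages of the assessment: extracts the
#' unique-URI inventory, resolves every URI (one fetch per request
#' target), parses bodies served under an RDF content type, tests
#' definedness, and classifies defined terms.
#'
#' @param source_ts the assessed resource as a \code{triple_set}.
#' @param cfg a \code{\link{resolver_config}}.
#' @return an \code{assessment_context}.
#' @export
build_context <- function(source_ts, cfg = resolver_config()) {
  inventory <- extract_unique_uris(source_ts)
  uris <- inventory$uri
  resolutions <- lapply(uris, resolve_uri, cfg = cfg)
  names(resolutions) <- uris
  parsed <- list()
  for (u in uris) {
    rec <- resolutions[[u]]
    if (rec$resolvable && rec$rdf_content_type) {
      parsed[[u]] <- fetch_and_parse(rec, cfg)
    }
  }
  classifications <- list()
  for (u in names(parsed)) {
    if (!is_parse_failure(parsed[[u]]) && is_defined(u, parsed[[u]])) {
      classifications[[u]] <- classify_term(u, local = source_ts,
                                            resolved = parsed[[u]])
    }
  }
  structure(list(
    source = source_ts,
    inventory = inventory,
    resolutions = resolutions,
    parsed = parsed,
    classifications = classifications
  ), class = "assessment_context")
}

ctx_classes <- function(ctx) {
  keep <- vapply(ctx$classifications, function(c) c$is_class, TRUE)
  names(ctx$classifications)[keep]
}

ctx_properties <- function(ctx) {
  keep <- vapply(ctx$classifications, is_property_classification, TRUE)
  names(ctx$classifications)[keep]
}

ctx_deprecated <- function(ctx) {
  keep <- vapply(ctx$classifications, function(c) c$deprecated, TRUE)
  names(ctx$classifications)[keep]
}

#' Non-resolvable URIs metric
#'
#' Proportion of unique URIs returning a 4xx/5xx status (or failing at the
#' network level) to all unique URIs.
#'
#' @param ctx an \code{assessment_context}.
#' @return a \code{metric_result}.
#' @export
metric_non_resolvable <- function(ctx) {
  bad <- names(ctx$resolutions)[!vapply(ctx$resolutions, `[[`, TRUE, "resolvable")]
  detail <- vapply(ctx$resolutions[bad], function(r) as.character(r$final_status), "")
  metric_result("non_resolvable", bad, nrow(ctx$inventory), ctx,
                detail = detail, eligible = nrow(ctx$inventory))
}

#' Non-parsable URIs metric
#'
#' Proportion of URIs served under an RDF content type whose content
#' cannot be parsed into triples, to all unique URIs. The count of URIs
#' actually eligible (resolvable with RDF content type) is carried in
#' \code{eligible}.
#'
#' @inheritParams metric_non_resolvable
#' @return a \code{metric_result}.
#' @export
metric_non_parsable <- function(ctx) {
  eligible <- names(ctx$parsed)
  bad <- eligible[vapply(ctx$parsed, is_parse_failure, TRUE)]
  detail <- vapply(ctx$parsed[bad], `[[`, "", "message")
  metric_result("non_parsable", bad, nrow(ctx$inventory), ctx,
                detail = detail, eligible = length(eligible))
}

#' Undefined URIs metric
#'
#' Proportion of parsable URIs that never appear as the subject of a
#' triple in their own dereferenced graph, to all unique URIs. Undefined
#' URIs are findings that need investigation rather than certain errors;
#' the detail annotation says so.
#'
#' @inheritParams metric_non_resolvable
#' @return a \code{metric_result}.
#' @export
metric_undefined <- function(ctx) {
  parsable <- names(ctx$parsed)[!vapply(ctx$parsed, is_parse_failure, TRUE)]
  bad <- parsable[!vapply(parsable, function(u) is_defined(u, ctx$parsed[[u]]), TRUE)]
  detail <- stats::setNames(rep("not a subject in its resolved graph; needs investigation",
                                length(bad)), bad)
  metric_result("undefined", bad, nrow(ctx$inventory), ctx,
                detail = detail, eligible = length(parsable))
}

#' Misplaced classes or properties metric
#'
#' A class is misplaced when used as a predicate; a property is misplaced
#' when used as the object of an \code{rdf:type} triple. Only defined,
#' non-deprecated terms are examined. The pooled denominator is all
#' unique classes plus all unique properties; both sub-ratios are kept in
#' \code{detail}.
#'
#' @inheritParams metric_non_resolvable
#' @return a \code{metric_result}.
#' @export
metric_misplaced <- function(ctx) {
  classes <- ctx_classes(ctx)
  properties <- ctx_properties(ctx)
  deprecated <- ctx_deprecated(ctx)
  df <- ctx$source$triples
  preds <- unique(df$p)
  type_objects <- unique(df$o[df$p == RDF_TYPE & df$o_kind == "uri"])
  mis_classes <- intersect(setdiff(classes, deprecated), preds)
  mis_props <- intersect(setdiff(properties, deprecated), type_objects)
  detail <- list(
    misplaced_classes = mis_classes,
    misplaced_properties = mis_props,
    n_classes = length(classes),
    n_properties = length(properties)
  )
  metric_result("misplaced", c(mis_classes, mis_props),
                length(classes) + length(properties), ctx, detail = detail,
                eligible = length(setdiff(c(classes, properties), deprecated)))
}

#' Misuse of owl:DatatypeProperty or owl:ObjectProperty metric
#'
#' A datatype property used as predicate must be followed by a literal; an
#' object property by a URI (a blank node also names a resource and is not
#' misuse). Only defined, non-deprecated properties are examined; the
#' denominator is all unique properties.
#'
#' @inheritParams metric_non_resolvable
#' @return a \code{metric_result}.
#' @export
metric_property_misuse <- function(ctx) {
  properties <- ctx_properties(ctx)
  deprecated <- ctx_deprecated(ctx)
  df <- ctx$source$triples
  bad <- character(0)
  detail <- list()
  for (u in setdiff(properties, deprecated)) {
    kinds <- ctx$classifications[[u]]$property_kinds
    used <- df[df$p == u, , drop = FALSE]
    if (!nrow(used)) next
    offending <- empty_triple_frame()
    if ("datatype-property" %in% kinds) {
      offending <- rbind(offending, used[used$o_kind != "literal", , drop = FALSE])
    }
    if ("object-property" %in% kinds) {
      offending <- rbind(offending, used[used$o_kind == "literal", , drop = FALSE])
    }
    if (nrow(offending)) {
      bad <- c(bad, u)
      detail[[u]] <- offending
    }
  }
  metric_result("property_misuse", bad, length(properties), ctx,
                detail = detail, eligible = length(setdiff(properties, deprecated)))
}

#' Use of deprecated classes or properties metric
#'
#' Deprecated terms that are actually used in the assessed resource (any
#' position); a term deprecated in its defining ontology but unused is not
#' an error. Denominator: all unique classes plus properties.
#'
#' @inheritParams metric_non_resolvable
#' @return a \code{metric_result}.
#' @export
metric_deprecated_usage <- function(ctx) {
  classes <- ctx_classes(ctx)
  properties <- ctx_properties(ctx)
  deprecated <- ctx_deprecated(ctx)
  df <- ctx$source$triples
  used <- function(u) {
    any(df$s_kind == "uri" & df$s == u) || any(df$p == u) ||
      any(df$o_kind == "uri" & df$o == u)
  }
  # usage other than the deprecation statement itself: a resource that
  # *asserts* owl:deprecated about a term is describing it, not using it
  usage_df <- df[df$p != OWL_DEPRECATED, , drop = FALSE]
  used2 <- function(u) {
    any(usage_df$s_kind == "uri" & usage_df$s == u) | any(usage_df$p == u) |
      any(usage_df$o_kind == "uri" & usage_df$o == u)
  }
  bad <- deprecated[vapply(deprecated, used2, TRUE)]
  metric_result("deprecated_usage", bad, length(classes) + length(properties),
                ctx, detail = NULL, eligible = length(deprecated))
}

#' Run the full quality assessment
#'
#' Executes the six-step procedure: load and parse the resource, extract
#' unique URIs, dereference them, test parsability and definedness,
#' classify terms and check deprecation, analyze term usage, and time the
#' whole run. A source-level load failure does not raise: the returned
#' assessment records the resource's own resolvability/parsability as
#' FALSE and carries no metric rows.
#'
#' @param source file path or URI of the RDF resource.
#' @param cfg a \code{\link{resolver_config}}.
#' @param format optional explicit serialization label for the source.
#' @return an \code{rdf_assessment}: list with \code{source},
#'   \code{resource_resolvable}, \code{resource_parsable}, \code{metrics}
#'   (named list of six \code{metric_result}s), \code{inventory},
#'   \code{context}, \code{duration} (seconds), \code{timestamp}.
#' @export
run_assessment <- function(source, cfg = resolver_config(), format = NULL) {
  t0 <- Sys.time()
  timestamp <- if (!is.null(cfg$routing) && !is.null(cfg$routing$created)) {
    cfg$routing$created
  } else {
    format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  source_ts <- tryCatch(load_resource(source, format = format, cfg = cfg),
                        rdf_input_error = identity, rdf_parse_error = identity)
  if (inherits(source_ts, "condition")) {
    resolvable <- !inherits(source_ts, "rdf_input_error")
    return(structure(list(
      source = source, resource_resolvable = resolvable,
      resource_parsable = FALSE, metrics = NULL, inventory = NULL,
      context = NULL, failure = conditionMessage(source_ts),
      duration = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      timestamp = timestamp
    ), class = "rdf_assessment"))
  }
  ctx <- build_context(source_ts, cfg)
  metrics <- list(
    non_resolvable = metric_non_resolvable(ctx),
    non_parsable = metric_non_parsable(ctx),
    undefined = metric_undefined(ctx),
    misplaced = metric_misplaced(ctx),
    property_misuse = metric_property_misuse(ctx),
    deprecated_usage = metric_deprecated_usage(ctx)
  )
  structure(list(
    source = source,
    resource_resolvable = TRUE,
    resource_parsable = TRUE,
    metrics = metrics,
    inventory = ctx$inventory,
    context = ctx,
    failure = NULL,
    duration = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = timestamp
  ), class = "rdf_assessment")
}

#' @export
print.rdf_assessment <- function(x, ...) {
  cat("RDF resource quality assessment\n")
  cat("  source:", x$source, "\n")
  cat("  resource resolvable:", x$resource_resolvable,
      " parsable:", x$resource_parsable, "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  unique URIs: %d  triples: %d\n", nrow(x$inventory),
                attr(x$inventory, "total_triples")))
    for (m in x$metrics) print(m)
  } else {
    cat("  metrics skipped:", x$failure, "\n")
  }
  cat(sprintf("  time cost: %d:%05.2f\n", floor(x$duration / 60),
              x$duration %% 60))
  invisible(x)
}
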