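# Synthetic linked-data ecosystems with injected defects. The generator
# emits ontology documents (classes and properties, some deprecated), a
# subject resource using those terms correctly and incorrectly, and a
# routing table assigning each request target its HTTP behaviour. A
# ground-truth ledger of expected metric values is computed by
# construction and verified by an independent brute-force recount.
#
# Documents for foreign-host vocabulary URIs (e.g. the rdf: namespace) are
# synthetic stand-ins served from the routing table, not copies of the
# real documents.

FIXTURE_CREATED <- "2026-01-01T00:00:00Z"

#' Defect specification for a synthetic ecosystem
#'
#' Counts of injected defects. Funnel defects (non-resolvable,
#' non-parsable, undefined) and term-usage defects (misplacement, misuse,
#' deprecation) are assigned to disjoint terms, so the ledger is exact by
#' construction. Defaults state a moderately broken ecosystem: 50 terms,
#' 150 triples, 10 non-resolvable, 5 non-parsable, 4 undefined, 3 + 2
#' misplaced, 2 + 2 misused, 2 deprecated-in-use.
#'
#' @param n_terms number of ontology terms.
#' @param n_triples_target approximate size of the subject resource graph.
#' @param n_non_resolvable,n_non_parsable,n_undefined funnel defect counts.
#' @param status_mix named numeric weights over
#'   \code{404, 410, 500, 503, timeout} for non-resolvable terms.
#' @param n_misplaced_classes,n_misplaced_properties usage defect counts.
#' @param n_datatype_misuse,n_object_misuse property misuse counts.
#' @param n_deprecated_used deprecated terms that the subject graph uses.
#' @param seed integer driving all randomized choices.
#' @return a \code{defect_spec} list.
#' @export
defect_spec <- function(n_terms = 50, n_triples_target = 150,
                        n_non_resolvable = 10,
                        status_mix = c("404" = 0.5, "410" = 0.1, "500" = 0.15,
                                       "503" = 0.15, "timeout" = 0.1),
                        n_non_parsable = 5, n_undefined = 4,
                        n_misplaced_classes = 3, n_misplaced_properties = 2,
                        n_datatype_misuse = 2, n_object_misuse = 2,
                        n_deprecated_used = 2, seed = 1L) {
  spec <- list(n_terms = as.integer(n_terms),
               n_triples_target = as.integer(n_triples_target),
               n_non_resolvable = as.integer(n_non_resolvable),
               status_mix = status_mix,
               n_non_parsable = as.integer(n_non_parsable),
               n_undefined = as.integer(n_undefined),
               n_misplaced_classes = as.integer(n_misplaced_classes),
               n_misplaced_properties = as.integer(n_misplaced_properties),
               n_datatype_misuse = as.integer(n_datatype_misuse),
               n_object_misuse = as.integer(n_object_misuse),
               n_deprecated_used = as.integer(n_deprecated_used),
               seed = as.integer(seed))
  n_defects <- n_non_resolvable + n_non_parsable + n_undefined +
    n_misplaced_classes + n_misplaced_properties + n_datatype_misuse +
    n_object_misuse + n_deprecated_used
  if (n_defects > n_terms - 3L) {
    stop("infeasible defect spec: ", n_defects, " defects need at most ",
         n_terms - 3L, " (n_terms - 3 healthy carriers)", call. = FALSE)
  }
  counts <- unlist(spec[startsWith(names(spec), "n_")])
  if (any(counts < 0)) stop("defect counts must be non-negative", call. = FALSE)
  structure(spec, class = "defect_spec")
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

term_def_turtle <- function(uri, type_iri, deprecated = FALSE) {
  dep <- if (deprecated) {
    sprintf("<%s> <%s> \"true\"^^<%sboolean> .\n", uri, OWL_DEPRECATED, XSD_NS)
  } else ""
  sprintf("<%s> <%s> <%s> .\n%s", uri, RDF_TYPE, type_iri, dep)
}

term_def_rdfxml <- function(uri, type_iri, deprecated = FALSE) {
  dep <- if (deprecated) {
    sprintf("    <owl:deprecated rdf:datatype=\"%sboolean\">true</owl:deprecated>\n", XSD_NS)
  } else ""
  sprintf(paste0(
    "  <rdf:Description rdf:about=\"%s\">\n",
    "    <rdf:type rdf:resource=\"%s\"/>\n%s",
    "  </rdf:Description>\n"), uri, type_iri, dep)
}

rdfxml_doc <- function(body) {
  paste0("<?xml version=\"1.0\"?>\n",
         "<rdf:RDF xmlns:rdf=\"", RDF_NS, "\" xmlns:owl=\"", OWL_NS, "\"",
         " xmlns:rdfs=\"", RDFS_NS, "\">\n", body, "</rdf:RDF>\n")
}

# malformed RDF/XML: rdf:ID carrying an invalid non-colonized name, the
# classic cause of an RDF-level parse error in a well-formed XML document
malformed_rdfxml_doc <- function(uri) {
  rdfxml_doc(sprintf(paste0(
    "  <rdf:Description rdf:ID=\"1 invalid ncname\">\n",
    "    <rdfs:seeAlso rdf:resource=\"%s\"/>\n",
    "  </rdf:Description>\n"), uri))
}

route_entry <- function(status, content_type = NULL, body = NULL,
                        location = NULL, delay = NULL) {
  e <- list(status = status)
  if (!is.null(content_type)) e$content_type <- content_type
  if (!is.null(body)) e$body <- body
  if (!is.null(location)) e$location <- location
  if (!is.null(delay)) e$delay <- delay
  e
}

gt_entry <- function(error_uris, denominator, subject_df, total) {
  error_uris <- sort(unique(error_uris))
  affected <- sum(
    (subject_df$s_kind == "uri" & subject_df$s %in% error_uris) |
      (subject_df$p %in% error_uris) |
      (subject_df$o_kind == "uri" & subject_df$o %in% error_uris)
  )
  list(error_uris = error_uris, numerator = length(error_uris),
       denominator = as.integer(denominator), affected_triples = affected,
       total_triples = total)
}

#' Generate a synthetic linked-data ecosystem
#'
#' Deterministic under \code{spec$seed}. Produces ontology documents in
#' Turtle and RDF/XML, per-instance N-Triples documents, one subject
#' resource graph using every term (correctly, and incorrectly where the
#' spec injects a defect), a routing table assigning each request target
#' its HTTP behaviour, and the ground-truth ledger of expected metric
#' values (verified against an independent recount when
#' \code{verify = TRUE}).
#'
#' Hash-namespace and slash-namespace terms are both generated (roughly
#' 50/50 among healthy terms); defect-carrying terms get dedicated slash
#' routes so a defect never leaks onto sibling terms. A fraction of
#' healthy slash terms resolve through a 303 redirect.
#'
#' @param spec a \code{\link{defect_spec}}.
#' @param base_url base URL the local URIs are minted under.
#' @param timeout_delay seconds the server stalls on timeout-defect
#'   routes. Keep it between 1x and 2x the client timeout: the
#'   single-threaded server finishes the stall after the client aborts, so
#'   the residual (\code{timeout_delay - timeout}) delays the next queued
#'   request and must stay below the client timeout.
#' @param verify recount the ledger independently and stop on mismatch.
#' @return an \code{ecosystem}: list with \code{spec}, \code{base_url},
#'   \code{routing} (routes keyed by request target), \code{subject_url},
#'   \code{subject_ts}, \code{ground_truth}, \code{terms} (assignment
#'   table).
#' @export
generate_ecosystem <- function(spec = defect_spec(),
                               base_url = "http://127.0.0.1:8099",
                               timeout_delay = 0.75, verify = TRUE) {
  stopifnot(inherits(spec, "defect_spec"))
  with_local_seed(spec$seed, generate_ecosystem_impl(spec, base_url,
                                                     timeout_delay, verify))
}

generate_ecosystem_impl <- function(spec, base_url, timeout_delay, verify) {
  base_url <- sub("/$", "", base_url)
  n <- spec$n_terms
  roles <- rep("healthy", n)
  idx <- 1L
  take <- function(count, role) {
    if (count > 0L) roles[idx:(idx + count - 1L)] <<- role
    idx <<- idx + count
  }
  take(spec$n_non_resolvable, "non_resolvable")
  take(spec$n_non_parsable, "non_parsable")
  take(spec$n_undefined, "undefined")
  take(spec$n_misplaced_classes, "misplaced_class")
  take(spec$n_misplaced_properties, "misplaced_property")
  take(spec$n_datatype_misuse, "datatype_misuse")
  take(spec$n_object_misuse, "object_misuse")
  take(spec$n_deprecated_used, "deprecated")
  roles <- sample(roles)  # shuffle assignment across term indices

  # healthy terms rotate through kinds; first three are the carriers
  healthy_idx <- which(roles == "healthy")
  healthy_kind <- rep(c("object-property", "datatype-property", "class",
                        "class", "annotation-property"),
                      length.out = length(healthy_idx))

  n_groups <- max(2L, min(4L, n %/% 10L))
  term <- vector("list", n)
  h <- 0L
  for (i in seq_len(n)) {
    role <- roles[i]
    group <- ((i - 1L) %% n_groups) + 1L
    hashy <- role == "healthy" && stats::runif(1) < 0.5
    uri <- if (hashy) {
      sprintf("%s/onth%d#t%d", base_url, group, i)
    } else {
      sprintf("%s/ont%d/t%d", base_url, group, i)
    }
    kind <- switch(role,
      healthy = { h <- h + 1L; healthy_kind[h] },
      misplaced_class = "class",
      misplaced_property = "object-property",
      datatype_misuse = "datatype-property",
      object_misuse = "object-property",
      deprecated = if (i %% 2L == 0L) "class" else "object-property",
      "class")  # funnel defects: nominal kind, never observable
    term[[i]] <- list(i = i, uri = uri, role = role, kind = kind,
                      group = group, hashy = hashy)
  }
  terms <- do.call(rbind, lapply(term, function(t) {
    data.frame(uri = t$uri, role = t$role, kind = t$kind, group = t$group,
               hashy = t$hashy, stringsAsFactors = FALSE)
  }))

  carriers <- list(
    obj = term[[healthy_idx[which(healthy_kind == "object-property")[1]]]]$uri,
    dt = term[[healthy_idx[which(healthy_kind == "datatype-property")[1]]]]$uri,
    class = term[[healthy_idx[which(healthy_kind == "class")[1]]]]$uri
  )
  if (any(vapply(carriers, is.null, TRUE)) || anyNA(unlist(carriers))) {
    stop("infeasible spec: need healthy object/datatype/class carriers",
         call. = FALSE)
  }

  n_inst <- max(3L, n %/% 5L)
  instances <- sprintf("%s/data/s%d", base_url, seq_len(n_inst))
  inst <- function(k) instances[((k - 1L) %% n_inst) + 1L]

  type_iri_for <- function(kind) {
    switch(kind,
      "class" = paste0(OWL_NS, "Class"),
      "object-property" = paste0(OWL_NS, "ObjectProperty"),
      "datatype-property" = paste0(OWL_NS, "DatatypeProperty"),
      "annotation-property" = paste0(OWL_NS, "AnnotationProperty"))
  }

  # --- ontology documents: group g gathers its defined terms -----------------
  # RDF/XML for group 1, Turtle for the rest; undefined-defect terms are
  # omitted from their document (the document resolves but lacks them)
  doc_formats <- c("rdfxml", rep("turtle", n_groups - 1L))
  group_docs <- character(n_groups)
  for (g in seq_len(n_groups)) {
    members <- Filter(function(t) {
      t$group == g && !t$role %in% c("non_resolvable", "non_parsable", "undefined")
    }, term)
    defs <- vapply(members, function(t) {
      dep <- t$role == "deprecated"
      if (doc_formats[g] == "rdfxml") term_def_rdfxml(t$uri, type_iri_for(t$kind), dep)
      else term_def_turtle(t$uri, type_iri_for(t$kind), dep)
    }, "")
    group_docs[g] <- if (doc_formats[g] == "rdfxml") {
      rdfxml_doc(paste(defs, collapse = ""))
    } else {
      paste(defs, collapse = "")
    }
  }
  group_ct <- ifelse(doc_formats == "rdfxml", "application/rdf+xml", "text/turtle")

  routes <- list()
  statuses <- names(spec$status_mix)
  for (t in term) {
    target <- normalize_for_resolution(t$uri)
    g <- t$group
    if (t$role == "non_resolvable") {
      status <- sample(statuses, 1L, prob = spec$status_mix)
      routes[[target]] <- if (status == "timeout") {
        route_entry("timeout", delay = timeout_delay)
      } else {
        route_entry(as.integer(status), "text/plain", "error page")
      }
    } else if (t$role == "non_parsable") {
      routes[[target]] <- route_entry(200L, "application/rdf+xml",
                                      malformed_rdfxml_doc(t$uri))
    } else if (t$role == "undefined") {
      # the namespace document resolves and parses but omits the term
      routes[[target]] <- route_entry(200L, group_ct[g], group_docs[g])
    } else if (t$hashy) {
      routes[[target]] <- route_entry(200L, group_ct[g], group_docs[g])
    } else {
      # healthy slash term; some resolve via a 303 chain to a doc route
      if (stats::runif(1) < 0.1) {
        doc_target <- paste0(target, ".doc")
        routes[[target]] <- route_entry(303L, location = doc_target)
        routes[[doc_target]] <- route_entry(200L, group_ct[g], group_docs[g])
      } else {
        routes[[target]] <- route_entry(200L, group_ct[g], group_docs[g])
      }
    }
  }
  for (k in seq_len(n_inst)) {
    routes[[instances[k]]] <- route_entry(
      200L, "text/plain",
      sprintf("<%s> <%slabel> \"instance %d\" .\n", instances[k], RDFS_NS, k))
  }
  # synthetic stand-in for the rdf: namespace document defining rdf:type
  rdf_ns_target <- normalize_for_resolution(RDF_TYPE)
  routes[[rdf_ns_target]] <- route_entry(
    200L, "text/turtle", term_def_turtle(RDF_TYPE, paste0(RDF_NS, "Property")))

  # --- subject resource graph ------------------------------------------------
  rows <- list()
  emit <- function(s, p, o, o_kind, o_dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- triple_row(s, "uri", p, o, o_kind, o_dt)
  }
  k <- 0L
  for (t in term) {
    k <- k + 1L
    switch(t$role,
      healthy = switch(t$kind,
        "class" = emit(inst(k), RDF_TYPE, t$uri, "uri"),
        "object-property" = emit(inst(k), t$uri, inst(k + 1L), "uri"),
        "datatype-property" = emit(inst(k), t$uri, sprintf("value %d", t$i), "literal"),
        "annotation-property" = emit(inst(k), t$uri, sprintf("note %d", t$i), "literal")),
      non_resolvable = emit(inst(k), carriers$obj, t$uri, "uri"),
      non_parsable = emit(inst(k), carriers$obj, t$uri, "uri"),
      undefined = emit(inst(k), carriers$obj, t$uri, "uri"),
      misplaced_class = emit(inst(k), t$uri, inst(k + 1L), "uri"),
      misplaced_property = emit(inst(k), RDF_TYPE, t$uri, "uri"),
      datatype_misuse = emit(inst(k), t$uri, inst(k + 1L), "uri"),
      object_misuse = emit(inst(k), t$uri, sprintf("stray literal %d", t$i), "literal"),
      deprecated = if (t$kind == "class") {
        emit(inst(k), RDF_TYPE, t$uri, "uri")
      } else {
        emit(inst(k), t$uri, inst(k + 1L), "uri")
      })
  }
  # padding triples up to the target size, using healthy carriers only;
  # set semantics are respected (a duplicate proposal is skipped)
  seen <- new.env(parent = emptyenv())
  for (r in rows) assign(triple_keys(r), TRUE, envir = seen)
  pad <- 0L
  n_unique <- length(ls(seen))
  while (n_unique < spec$n_triples_target) {
    pad <- pad + 1L
    choice <- pad %% 3L
    cand <- if (choice == 0L) {
      triple_row(inst(pad), "uri", RDF_TYPE, carriers$class, "uri")
    } else if (choice == 1L) {
      triple_row(inst(pad), "uri", carriers$dt, sprintf("pad %d", pad), "literal")
    } else {
      triple_row(inst(pad), "uri", carriers$obj, inst(pad + 3L), "uri")
    }
    key <- triple_keys(cand)
    if (is.null(seen[[key]])) {
      assign(key, TRUE, envir = seen)
      rows[[length(rows) + 1L]] <- cand
      n_unique <- n_unique + 1L
    }
  }
  subject_df <- do.call(rbind, rows)
  subject_ts <- triple_set(subject_df, format = "turtle")
  subject_df <- subject_ts$triples  # after duplicate collapse
  subject_url <- paste0(base_url, "/resource")
  routes[[subject_url]] <- route_entry(200L, "text/turtle",
                                       write_turtle(subject_ts))
  subject_ts$source <- subject_url

  routing <- list(created = FIXTURE_CREATED, base = base_url, routes = routes)

  # --- ground-truth ledger by construction -----------------------------------
  total <- nrow(subject_df)
  uris_in_graph <- unique(c(subject_df$s[subject_df$s_kind == "uri"],
                            subject_df$p,
                            subject_df$o[subject_df$o_kind == "uri"]))
  n_uris <- length(uris_in_graph)
  role_uris <- function(role) terms$uri[terms$role == role]
  type_used <- RDF_TYPE %in% subject_df$p
  classes <- c(terms$uri[terms$kind == "class" &
                           !terms$role %in% c("non_resolvable", "non_parsable",
                                              "undefined")])
  properties <- c(terms$uri[terms$kind != "class" &
                              !terms$role %in% c("non_resolvable", "non_parsable",
                                                 "undefined")],
                  if (type_used) RDF_TYPE)
  n_cp <- length(classes) + length(properties)
  ground_truth <- list(
    non_resolvable = gt_entry(role_uris("non_resolvable"), n_uris, subject_df, total),
    non_parsable = gt_entry(role_uris("non_parsable"), n_uris, subject_df, total),
    undefined = gt_entry(role_uris("undefined"), n_uris, subject_df, total),
    misplaced = gt_entry(c(role_uris("misplaced_class"),
                           role_uris("misplaced_property")), n_cp, subject_df, total),
    property_misuse = gt_entry(c(role_uris("datatype_misuse"),
                                 role_uris("object_misuse")),
                               length(properties), subject_df, total),
    deprecated_usage = gt_entry(role_uris("deprecated"), n_cp, subject_df, total)
  )
  ground_truth$n_unique_uris <- n_uris
  ground_truth$n_classes <- length(classes)
  ground_truth$n_properties <- length(properties)

  eco <- structure(list(
    spec = spec, base_url = base_url, routing = routing,
    subject_url = subject_url, subject_ts = subject_ts,
    ground_truth = ground_truth, terms = terms
  ), class = "ecosystem")

  if (verify) {
    recount <- recount_ecosystem(eco)
    for (id in METRIC_IDS) {
      ok <- identical(recount[[id]]$error_uris, ground_truth[[id]]$error_uris) &&
        identical(recount[[id]]$denominator, ground_truth[[id]]$denominator) &&
        identical(recount[[id]]$affected_triples, ground_truth[[id]]$affected_triples)
      if (!ok) {
        stop("ecosystem generation self-check failed for metric ", id,
             call. = FALSE)
      }
    }
  }
  eco
}

#' @export
print.ecosystem <- function(x, ...) {
  cat(sprintf("<ecosystem: %d terms, %d triples, %d routes, base %s>\n",
              x$spec$n_terms, attr(extract_unique_uris(x$subject_ts), "total_triples"),
              length(x$routing$routes), x$base_url))
  invisible(x)
}

#' Independent brute-force recount of an ecosystem's expected metrics
#'
#' Recomputes every metric directly from the generated documents and
#' routing table with plain scans: manual redirect following, subject-set
#' membership for definedness, position scans for misplacement, misuse and
#' deprecated usage. Serves as the oracle that the assessment pipeline and
#' the generator's ledger are checked against.
#'
#' @param eco an \code{ecosystem}.
#' @return ledger in the same shape as \code{eco$ground_truth}.
#' @export
recount_ecosystem <- function(eco) {
  routes <- eco$routing$routes
  # re-parse the subject document from its routed body, not from eco$subject_ts
  sub_entry <- routes[[eco$subject_url]]
  sdf <- parse_content(sub_entry$body,
                       CONTENT_TYPE_FORMATS[[strip_media_params(sub_entry$content_type)]],
                       source = eco$subject_url)$triples
  total <- nrow(sdf)
  uris <- sort(unique(c(sdf$s[sdf$s_kind == "uri"], sdf$p,
                        sdf$o[sdf$o_kind == "uri"])))
  affected <- function(bad) {
    sum((sdf$s_kind == "uri" & sdf$s %in% bad) | (sdf$p %in% bad) |
          (sdf$o_kind == "uri" & sdf$o %in% bad))
  }
  lookup <- function(u) {
    cur <- sub("#.*$", "", u)
    hops <- 0L
    repeat {
      e <- routes[[cur]]
      if (is.null(e)) return(NULL)
      st <- e$status
      if (!identical(st, "timeout") && as.integer(st) %in% 301:399 &&
          !is.null(e$location)) {
        cur <- sub("#.*$", "", e$location)
        hops <- hops + 1L
        if (hops > 20L) return(NULL)
        next
      }
      return(e)
    }
  }
  resolvable <- logical(length(uris)); names(resolvable) <- uris
  rdf_ct <- logical(length(uris)); names(rdf_ct) <- uris
  parsed <- list()
  for (u in uris) {
    e <- lookup(u)
    ok <- !is.null(e) && !identical(e$status, "timeout") &&
      as.integer(e$status) >= 200L && as.integer(e$status) < 300L
    resolvable[u] <- ok
    if (!ok) next
    ct <- strip_media_params(e$content_type %||% "")
    rdf_ct[u] <- ct %in% names(CONTENT_TYPE_FORMATS)
    if (rdf_ct[u]) {
      parsed[[u]] <- parse_content(e$body, CONTENT_TYPE_FORMATS[[ct]], source = u)
    }
  }
  parse_ok <- vapply(names(parsed), function(u) !is_parse_failure(parsed[[u]]), TRUE)
  non_parsable <- names(parsed)[!parse_ok]
  defined <- character(0)
  undefined <- character(0)
  for (u in names(parsed)[parse_ok]) {
    pdf <- parsed[[u]]$triples
    if (any(pdf$s_kind == "uri" & pdf$s == u)) defined <- c(defined, u)
    else undefined <- c(undefined, u)
  }
  # classification by direct type scan over local + resolved statements
  classes <- character(0); props <- character(0)
  prop_kind <- list(); deprecated <- character(0)
  for (u in defined) {
    about <- rbind(sdf[sdf$s_kind == "uri" & sdf$s == u, , drop = FALSE],
                   parsed[[u]]$triples[parsed[[u]]$triples$s_kind == "uri" &
                                         parsed[[u]]$triples$s == u, , drop = FALSE])
    types <- about$o[about$p == RDF_TYPE & about$o_kind == "uri"]
    kinds <- names(PROPERTY_TYPES)[PROPERTY_TYPES %in% types]
    if (length(kinds)) { props <- c(props, u); prop_kind[[u]] <- kinds }
    else if (any(types %in% CLASS_TYPES)) classes <- c(classes, u)
    dep <- about[about$p == OWL_DEPRECATED & about$o_kind == "literal", , drop = FALSE]
    if (any(tolower(dep$o) %in% c("true", "1"))) deprecated <- c(deprecated, u)
  }
  live <- function(x) setdiff(x, deprecated)
  mis_cls <- intersect(live(classes), unique(sdf$p))
  mis_prp <- intersect(live(props),
                       unique(sdf$o[sdf$p == RDF_TYPE & sdf$o_kind == "uri"]))
  misuse <- character(0)
  for (u in live(props)) {
    used <- sdf[sdf$p == u, , drop = FALSE]
    if (!nrow(used)) next
    bad <- ("datatype-property" %in% prop_kind[[u]] && any(used$o_kind != "literal")) ||
      ("object-property" %in% prop_kind[[u]] && any(used$o_kind == "literal"))
    if (bad) misuse <- c(misuse, u)
  }
  nodep <- sdf[sdf$p != OWL_DEPRECATED, , drop = FALSE]
  dep_used <- deprecated[vapply(deprecated, function(u) {
    any(nodep$s_kind == "uri" & nodep$s == u) || any(nodep$p == u) ||
      any(nodep$o_kind == "uri" & nodep$o == u)
  }, TRUE)]
  n_cp <- length(classes) + length(props)
  mk <- function(bad, den) {
    bad <- sort(unique(bad))
    list(error_uris = bad, numerator = length(bad), denominator = as.integer(den),
         affected_triples = affected(bad), total_triples = total)
  }
  out <- list(
    non_resolvable = mk(uris[!resolvable], length(uris)),
    non_parsable = mk(non_parsable, length(uris)),
    undefined = mk(undefined, length(uris)),
    misplaced = mk(c(mis_cls, mis_prp), n_cp),
    property_misuse = mk(misuse, length(props)),
    deprecated_usage = mk(dep_used, n_cp)
  )
  out$n_unique_uris <- length(uris)
  out$n_classes <- length(classes)
  out$n_properties <- length(props)
  out
}

# --- Table-2-style worked-example ecosystem ----------------------------------

#' Ecosystem mirroring the published worked examples of each metric
#'
#' A fixed, seedless ecosystem reproducing, one per metric facet, the
#' classic defect patterns: a 404 property; a hash URI whose host document
#' is well-formed XML but invalid RDF/XML (bad NCName in rdf:ID); a
#' predicate whose namespace document omits it; a class used as a
#' predicate; a property used as the object of rdf:type; an object
#' property with a string object; a datatype property with a URI object;
#' and a deprecated class in use. All foreign-host documents are synthetic
#' stand-ins served from the routing table.
#'
#' @return an \code{ecosystem} whose \code{ground_truth} lists exactly one
#'   error URI per facet (expected_by_pattern attribute maps facets to
#'   URIs).
#' @export
mirror_table2_examples <- function() {
  sio <- "http://semanticscience.org/resource/"
  obo <- "http://purl.obolibrary.org/obo/"
  u <- list(
    similar_to = paste0(sio, "similarTo"),          # 404 -> non-resolvable
    sio_subj = paste0(sio, "SIO_001238"),
    obi = paste0(obo, "OBI_0000052"),
    me = "http://www.andrea-perego.name/foaf/#me",  # non-parsable host doc
    named_individual = paste0(OWL_NS, "NamedIndividual"),
    bfo = paste0(obo, "bfo"),
    theme = "http://purl.org/dc/terms/1.1/theme",   # undefined
    mculture = "http://m-culture.in.th/48081",
    image = "http://purl.org/dc/dcmitype/Image",    # misplaced class
    jpeg = "http://m-culture.in.th/media/big/201945.jpeg",
    cc = "https://creativecommons.org/licenses/by/4.0/",
    license = "http://purl.org/dc/terms/license",   # misplaced property
    oae = paste0(obo, "OAE_0001045"),
    see_also = paste0(RDFS_NS, "seeAlso"),          # object property, misused
    gender = "http://purl.org/ejp-rd/cde/example-rdf/gender1",
    sio300 = paste0(sio, "SIO_000300"),             # datatype property, misused
    snomed = "http://purl.bioontology.org/ontology/SNOMEDCT/703118005",
    thesaurus = "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#C50680",
    related = "http://www.w3.org/2004/02/skos/core#related",
    vsao = paste0(obo, "VSAO_0000002")              # deprecated class in use
  )
  rows <- rbind(
    triple_row(u$sio_subj, "uri", u$similar_to, u$obi, "uri"),
    triple_row(u$me, "uri", RDF_TYPE, u$named_individual, "uri"),
    triple_row(u$bfo, "uri", u$theme, "upper", "literal"),
    triple_row(u$mculture, "uri", u$image, u$jpeg, "uri"),
    triple_row(u$cc, "uri", RDF_TYPE, u$license, "uri"),
    triple_row(u$oae, "uri", u$see_also, "NCIt:C78345", "literal"),
    triple_row(u$gender, "uri", u$sio300, u$snomed, "uri"),
    triple_row(u$thesaurus, "uri", u$related, u$vsao, "uri")
  )
  subject_ts <- triple_set(rows, format = "turtle")
  base_url <- "http://fixtures.invalid/table2"
  subject_url <- paste0(base_url, "/resource")
  subject_ts$source <- subject_url

  typed <- function(uri, type_iri, deprecated = FALSE) {
    route_entry(200L, "text/turtle", term_def_turtle(uri, type_iri, deprecated))
  }
  plain <- function(uri) {
    route_entry(200L, "text/turtle",
                sprintf("<%s> <%slabel> \"stand-in definition\" .\n", uri, RDFS_NS))
  }
  routes <- list()
  set_route <- function(uri, entry) {
    routes[[normalize_for_resolution(uri)]] <<- entry
  }
  set_route(u$similar_to, route_entry(404L, "text/plain", "404 NOT Found"))
  set_route(u$me, route_entry(200L, "application/rdf+xml",
                              malformed_rdfxml_doc(u$me)))
  # the namespace document resolves and parses but never defines "theme"
  set_route(u$theme, route_entry(200L, "text/turtle", paste0(
    term_def_turtle("http://purl.org/dc/terms/1.1/title",
                    paste0(RDF_NS, "Property")),
    term_def_turtle("http://purl.org/dc/terms/1.1/creator",
                    paste0(RDF_NS, "Property")))))
  set_route(u$image, typed(u$image, paste0(OWL_NS, "Class")))
  set_route(u$license, typed(u$license, paste0(RDF_NS, "Property")))
  set_route(u$see_also, typed(u$see_also, paste0(OWL_NS, "ObjectProperty")))
  set_route(u$sio300, typed(u$sio300, paste0(OWL_NS, "DatatypeProperty")))
  set_route(u$vsao, typed(u$vsao, paste0(OWL_NS, "Class"), deprecated = TRUE))
  set_route(u$related, typed(u$related, paste0(RDF_NS, "Property")))
  set_route(u$named_individual, typed(u$named_individual, paste0(OWL_NS, "Class")))
  set_route(RDF_TYPE, typed(RDF_TYPE, paste0(RDF_NS, "Property")))
  for (nm in c("sio_subj", "obi", "bfo", "mculture", "cc", "oae", "gender",
               "snomed", "thesaurus")) {
    set_route(u[[nm]], plain(u[[nm]]))
  }
  set_route(u$jpeg, route_entry(200L, "image/jpeg", "not rdf"))
  routes[[subject_url]] <- route_entry(200L, "text/turtle",
                                       write_turtle(subject_ts))
  routing <- list(created = FIXTURE_CREATED, base = base_url, routes = routes)

  sdf <- subject_ts$triples
  total <- nrow(sdf)
  uris <- unique(c(sdf$s[sdf$s_kind == "uri"], sdf$p,
                   sdf$o[sdf$o_kind == "uri"]))
  # classes: Image, NamedIndividual, VSAO; properties: rdf:type, theme is
  # undefined, license/seeAlso/SIO_000300/related classified from stand-ins
  classes <- c(u$image, u$named_individual, u$vsao)
  properties <- c(RDF_TYPE, u$license, u$see_also, u$sio300, u$related)
  n_cp <- length(classes) + length(properties)
  ground_truth <- list(
    non_resolvable = gt_entry(u$similar_to, length(uris), sdf, total),
    non_parsable = gt_entry(u$me, length(uris), sdf, total),
    undefined = gt_entry(u$theme, length(uris), sdf, total),
    misplaced = gt_entry(c(u$image, u$license), n_cp, sdf, total),
    property_misuse = gt_entry(c(u$see_also, u$sio300), length(properties),
                               sdf, total),
    deprecated_usage = gt_entry(u$vsao, n_cp, sdf, total)
  )
  ground_truth$n_unique_uris <- length(uris)
  ground_truth$n_classes <- length(classes)
  ground_truth$n_properties <- length(properties)

  eco <- structure(list(
    spec = NULL, base_url = base_url, routing = routing,
    subject_url = subject_url, subject_ts = subject_ts,
    ground_truth = ground_truth,
    terms = NULL,
    expected_by_pattern = list(
      non_resolvable = u$similar_to, non_parsable = u$me,
      undefined = u$theme, misplaced_class = u$image,
      misplaced_property = u$license, object_misuse = u$see_also,
      datatype_misuse = u$sio300, deprecated_usage = u$vsao
    )
  ), class = "ecosystem")
  eco
}

#' Resolver configuration for an ecosystem
#'
#' Offline by default (routing-table resolution, zero network). With
#' \code{server} set (see \code{\link{serve_ecosystem}}), resolution goes
#' over live local HTTP: every request target is rewritten to the server's
#' \code{/fetch} endpoint, a short timeout is used so timeout-defect
#' routes trip quickly, and rate limiting is disabled.
#'
#' @param eco an \code{ecosystem}.
#' @param server optional server handle from \code{\link{serve_ecosystem}}.
#' @param timeout client timeout in seconds (default 0.5: above local
#'   round-trip latency, below the fixture stall delay).
#' @return a \code{\link{resolver_config}}.
#' @export
fixture_resolver_config <- function(eco, server = NULL, timeout = 0.5) {
  if (is.null(server)) {
    resolver_config(offline_snapshot = eco$routing, rate_limit = Inf)
  } else {
    base <- server$base_url
    resolver_config(
      timeout = timeout, rate_limit = Inf, retries = 1,
      url_rewrite = function(target) {
        paste0(base, "/fetch?uri=", utils::URLencode(target, reserved = TRUE))
      }
    )
  }
}
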