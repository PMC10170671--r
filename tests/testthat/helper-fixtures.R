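# Shared test helpers: tiny in-code graphs and routing tables.

RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
OWL <- "http://www.w3.org/2002/07/owl#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
XSD <- "http://www.w3.org/2001/XMLSchema#"

trip <- function(s, p, o, o_kind = "uri", o_dt = NA_character_,
                 o_lang = NA_character_, s_kind = "uri") {
  data.frame(s = s, s_kind = s_kind, p = p, o = o, o_kind = o_kind,
             o_dt = o_dt, o_lang = o_lang, stringsAsFactors = FALSE)
}

route200 <- function(body, content_type = "text/turtle") {
  list(status = 200L, content_type = content_type, body = body)
}

self_def <- function(uri) {
  route200(sprintf("<%s> <%slabel> \"stand-in\" .\n", uri, RDFS))
}

typed_def <- function(uri, type_iri, deprecated = FALSE) {
  dep <- if (deprecated) {
    sprintf("<%s> <%sdeprecated> \"true\"^^<%sboolean> .\n", uri, OWL, XSD)
  } else ""
  route200(sprintf("<%s> <%stype> <%s> .\n%s", uri, RDF, type_iri, dep))
}

# routing table where every URI of a triple set resolves to a defining
# document, except for explicit overrides
mini_routing <- function(ts, overrides = list()) {
  inv <- extract_unique_uris(ts)
  routes <- list()
  for (u in inv$uri) {
    routes[[sub("#.*$", "", u)]] <- self_def(u)
  }
  for (target in names(overrides)) {
    routes[[sub("#.*$", "", target)]] <- overrides[[target]]
  }
  list(created = "2026-01-01T00:00:00Z", base = "http://test.invalid",
       routes = routes)
}

offline_cfg <- function(routing) {
  resolver_config(offline_snapshot = routing, rate_limit = Inf)
}

# context for a triple set against a routing table
mini_context <- function(ts, overrides = list()) {
  build_context(ts, offline_cfg(mini_routing(ts, overrides)))
}

expect_ledger_equal <- function(assessment, gt, label = "") {
  for (id in names(assessment$metrics)) {
    m <- assessment$metrics[[id]]
    g <- gt[[id]]
    expect_identical(sort(m$error_uris), g$error_uris,
                     label = paste(label, id, "error_uris"))
    expect_identical(m$numerator, g$numerator,
                     label = paste(label, id, "numerator"))
    expect_identical(m$denominator, g$denominator,
                     label = paste(label, id, "denominator"))
    expect_identical(m$affected_triples, g$affected_triples,
                     label = paste(label, id, "affected_triples"))
    expect_identical(m$total_triples, g$total_triples,
                     label = paste(label, id, "total_triples"))
    expect_equal(m$proportion,
                 if (g$denominator > 0) g$numerator / g$denominator else 0,
                 label = paste(label, id, "proportion"))
  }
}

# deterministic randomized defect spec used by the acceptance suite
random_defect_spec <- function(seed, n_terms) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  budget <- n_terms - 4L
  draw <- function(max_share) {
    k <- sample.int(max(1L, min(budget, round(max_share * n_terms))), 1L) - 1L
    budget <<- budget - k
    k
  }
  defect_spec(
    n_terms = n_terms,
    n_triples_target = n_terms * 3L,
    n_non_resolvable = draw(0.2),
    n_non_parsable = draw(0.1),
    n_undefined = draw(0.1),
    n_misplaced_classes = draw(0.06),
    n_misplaced_properties = draw(0.06),
    n_datatype_misuse = draw(0.05),
    n_object_misuse = draw(0.05),
    n_deprecated_used = draw(0.05),
    seed = seed
  )
}
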