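# The six metrics over hand-built contexts and generated ecosystems.

# a small world with one defect per metric facet plus healthy terms
build_defect_world <- function() {
  ns <- "http://world.invalid/"
  u <- list(
    s1 = paste0(ns, "data/1"), s2 = paste0(ns, "data/2"),
    gone = paste0(ns, "gone"), garbled = paste0(ns, "garbled"),
    ghost = paste0(ns, "ghost"),
    cls = paste0(ns, "Cls"), mis_cls = paste0(ns, "MisCls"),
    mis_prop = paste0(ns, "misProp"),
    dt_bad = paste0(ns, "dtBad"), obj_bad = paste0(ns, "objBad"),
    dep_cls = paste0(ns, "DepCls"),
    obj_ok = paste0(ns, "objOk"), dt_ok = paste0(ns, "dtOk")
  )
  rows <- rbind(
    trip(u$s1, paste0(RDF, "type"), u$cls),             # correct class use
    trip(u$s1, u$obj_ok, u$s2),                          # correct object prop
    trip(u$s1, u$dt_ok, "fine", o_kind = "literal"),     # correct datatype prop
    trip(u$s1, u$obj_ok, u$gone),                        # non-resolvable object
    trip(u$s1, u$obj_ok, u$garbled),                     # non-parsable object
    trip(u$s1, u$obj_ok, u$ghost),                       # undefined object
    trip(u$s2, u$mis_cls, u$s1),                         # class as predicate
    trip(u$s2, paste0(RDF, "type"), u$mis_prop),         # property as type object
    trip(u$s2, u$dt_bad, u$s1),                          # datatype prop, URI object
    trip(u$s2, u$obj_bad, "stray", o_kind = "literal"),  # object prop, literal
    trip(u$s2, paste0(RDF, "type"), u$dep_cls)           # deprecated class in use
  )
  ts <- triple_set(rows)
  overrides <- list()
  overrides[[u$gone]] <- list(status = 410L, content_type = "text/plain", body = "gone")
  overrides[[u$garbled]] <- route200("not turtle (((", content_type = "text/turtle")
  overrides[[u$ghost]] <- route200(sprintf("<%sother> <%slabel> \"not the ghost\" .\n", ns, RDFS))
  overrides[[u$cls]] <- typed_def(u$cls, paste0(OWL, "Class"))
  overrides[[u$mis_cls]] <- typed_def(u$mis_cls, paste0(OWL, "Class"))
  overrides[[u$mis_prop]] <- typed_def(u$mis_prop, paste0(OWL, "ObjectProperty"))
  overrides[[u$dt_bad]] <- typed_def(u$dt_bad, paste0(OWL, "DatatypeProperty"))
  overrides[[u$obj_bad]] <- typed_def(u$obj_bad, paste0(OWL, "ObjectProperty"))
  overrides[[u$dep_cls]] <- typed_def(u$dep_cls, paste0(OWL, "Class"), deprecated = TRUE)
  overrides[[u$obj_ok]] <- typed_def(u$obj_ok, paste0(OWL, "ObjectProperty"))
  overrides[[u$dt_ok]] <- typed_def(u$dt_ok, paste0(OWL, "DatatypeProperty"))
  overrides[[paste0(RDF, "type")]] <- typed_def(paste0(RDF, "type"),
                                                paste0(RDF, "Property"))
  list(u = u, ts = ts, ctx = mini_context(ts, overrides))
}

test_that("each metric flags exactly its own defect in a mixed world", {
  w <- build_defect_world()
  ctx <- w$ctx
  u <- w$u
  expect_identical(metric_non_resolvable(ctx)$error_uris, u$gone)
  expect_identical(metric_non_parsable(ctx)$error_uris, u$garbled)
  expect_identical(metric_undefined(ctx)$error_uris, u$ghost)
  mis <- metric_misplaced(ctx)
  expect_setequal(mis$error_uris, c(u$mis_cls, u$mis_prop))
  expect_identical(mis$detail$misplaced_classes, u$mis_cls)
  expect_identical(mis$detail$misplaced_properties, u$mis_prop)
  misuse <- metric_property_misuse(ctx)
  expect_setequal(misuse$error_uris, c(u$dt_bad, u$obj_bad))
  expect_identical(metric_deprecated_usage(ctx)$error_uris, u$dep_cls)
})

test_that("denominators follow the metric definitions", {
  w <- build_defect_world()
  ctx <- w$ctx
  n_uris <- nrow(ctx$inventory)
  expect_identical(metric_non_resolvable(ctx)$denominator, n_uris)
  expect_identical(metric_non_parsable(ctx)$denominator, n_uris)
  expect_identical(metric_undefined(ctx)$denominator, n_uris)
  # classes: Cls, MisCls, DepCls; properties: rdf:type, misProp, dtBad,
  # objBad, objOk, dtOk
  expect_identical(metric_misplaced(ctx)$denominator, 9L)
  expect_identical(metric_property_misuse(ctx)$denominator, 6L)
  expect_identical(metric_deprecated_usage(ctx)$denominator, 9L)
})

test_that("funnel stages are disjoint and respect eligibility", {
  w <- build_defect_world()
  ctx <- w$ctx
  nr <- metric_non_resolvable(ctx)$error_uris
  np <- metric_non_parsable(ctx)$error_uris
  ud <- metric_undefined(ctx)$error_uris
  expect_length(intersect(nr, np), 0)
  expect_length(intersect(nr, ud), 0)
  expect_length(intersect(np, ud), 0)
  resolvable <- names(ctx$resolutions)[vapply(ctx$resolutions, `[[`, TRUE, "resolvable")]
  rdf_ct <- names(ctx$resolutions)[vapply(ctx$resolutions, `[[`, TRUE, "rdf_content_type")]
  parsable <- names(ctx$parsed)[!vapply(ctx$parsed, is_parse_failure, TRUE)]
  expect_true(all(ud %in% parsable))
  expect_true(all(parsable %in% rdf_ct))
  expect_true(all(rdf_ct %in% resolvable))
  expect_length(intersect(np, parsable), 0)
})

test_that("a blank-node object is a resource, not object-property misuse", {
  ns <- "http://world.invalid/"
  obj_p <- paste0(ns, "objP")
  ts <- triple_set(rbind(
    trip(paste0(ns, "s"), obj_p, "b1", o_kind = "blank"),
    trip(paste0(ns, "s"), paste0(RDF, "type"), paste0(ns, "C"))
  ))
  overrides <- list()
  overrides[[obj_p]] <- typed_def(obj_p, paste0(OWL, "ObjectProperty"))
  overrides[[paste0(ns, "C")]] <- typed_def(paste0(ns, "C"), paste0(OWL, "Class"))
  overrides[[paste0(RDF, "type")]] <- typed_def(paste0(RDF, "type"),
                                                paste0(RDF, "Property"))
  ctx <- mini_context(ts, overrides)
  expect_length(metric_property_misuse(ctx)$error_uris, 0)
  # but a datatype property with a blank-node object is misuse
  overrides[[obj_p]] <- typed_def(obj_p, paste0(OWL, "DatatypeProperty"))
  ctx2 <- mini_context(ts, overrides)
  expect_identical(metric_property_misuse(ctx2)$error_uris, obj_p)
})

test_that("deprecated terms are exempt from misplacement and misuse", {
  ns <- "http://world.invalid/"
  dep_p <- paste0(ns, "depProp")
  # a deprecated object property used with a literal object: only the
  # deprecated-usage metric fires (step 5 analyzes non-deprecated terms)
  ts <- triple_set(trip(paste0(ns, "s"), dep_p, "text", o_kind = "literal"))
  overrides <- list()
  overrides[[dep_p]] <- typed_def(dep_p, paste0(OWL, "ObjectProperty"),
                                  deprecated = TRUE)
  ctx <- mini_context(ts, overrides)
  expect_length(metric_property_misuse(ctx)$error_uris, 0)
  expect_length(metric_misplaced(ctx)$error_uris, 0)
  expect_identical(metric_deprecated_usage(ctx)$error_uris, dep_p)
})

test_that("a deprecated term defined but unused is not counted", {
  ns <- "http://world.invalid/"
  ts <- triple_set(trip(paste0(ns, "s"), paste0(RDF, "type"), paste0(ns, "C")))
  overrides <- list()
  # the class's defining doc also deprecates a sibling term, which the
  # subject graph never uses
  overrides[[paste0(ns, "C")]] <- route200(paste0(
    sprintf("<%sC> <%stype> <%sClass> .\n", ns, RDF, OWL),
    sprintf("<%sOld> <%stype> <%sClass> .\n", ns, RDF, OWL),
    sprintf("<%sOld> <%sdeprecated> \"true\"^^<%sboolean> .\n", ns, OWL, XSD)))
  overrides[[paste0(RDF, "type")]] <- typed_def(paste0(RDF, "type"),
                                                paste0(RDF, "Property"))
  ctx <- mini_context(ts, overrides)
  expect_length(metric_deprecated_usage(ctx)$error_uris, 0)
})

test_that("a perfect world yields six zero metrics", {
  eco <- generate_ecosystem(defect_spec(
    n_terms = 12, n_triples_target = 30, n_non_resolvable = 0,
    n_non_parsable = 0, n_undefined = 0, n_misplaced_classes = 0,
    n_misplaced_properties = 0, n_datatype_misuse = 0, n_object_misuse = 0,
    n_deprecated_used = 0, seed = 4))
  a <- run_assessment(eco$subject_url, offline_cfg(eco$routing))
  for (m in a$metrics) {
    expect_identical(m$numerator, 0L)
    expect_identical(m$affected_triples, 0L)
    expect_equal(m$proportion, 0)
  }
  expect_true(all(unlist(lapply(eco$ground_truth[1:6], `[[`, "numerator")) == 0))
})

test_that("proportions stay in [0,1] and numerators within denominators", {
  for (seed in c(5, 9)) {
    eco <- generate_ecosystem(defect_spec(seed = seed), verify = FALSE)
    a <- run_assessment(eco$subject_url, offline_cfg(eco$routing))
    for (m in a$metrics) {
      expect_gte(m$proportion, 0); expect_lte(m$proportion, 1)
      expect_lte(m$numerator, m$denominator)
      expect_lte(m$affected_triples, m$total_triples)
      expect_lte(m$denominator, nrow(a$inventory))
    }
  }
})

test_that("a resource shaped like a 137-URI data model gives 8/137 undefined", {
  ns <- "http://rim.test/"
  s <- paste0(ns, "model")
  p <- paste0(ns, "uses")
  ghosts <- sprintf("%sghost%d", ns, 1:8)
  objs <- sprintf("%so%d", ns, 1:127)
  ts <- triple_set(do.call(rbind, lapply(c(objs, ghosts), function(o) trip(s, p, o))))
  overrides <- stats::setNames(
    lapply(ghosts, function(g) route200(sprintf(
      "<%sother> <%slabel> \"elsewhere\" .\n", ns, RDFS))),
    ghosts)
  ctx <- mini_context(ts, overrides)
  expect_identical(nrow(ctx$inventory), 137L)
  m <- metric_undefined(ctx)
  expect_identical(m$numerator, 8L)
  expect_identical(m$denominator, 137L)
  expect_equal(round(100 * m$proportion, 1), 5.8)
})

test_that("source-level failures are reported, not raised", {
  a <- run_assessment("/nonexistent/source.ttl", resolver_config(rate_limit = Inf))
  expect_false(a$resource_resolvable)
  expect_false(a$resource_parsable)
  expect_null(a$metrics)

  bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines("not @ turtle (((", bad)
  b <- run_assessment(bad, resolver_config(rate_limit = Inf))
  expect_true(b$resource_resolvable)
  expect_false(b$resource_parsable)
  expect_null(b$metrics)
})
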