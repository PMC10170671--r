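# Dereferencing: normalization, content-type classification, offline
# resolution, body parsing, snapshots.

test_that("normalize_for_resolution strips fragments and case-folds authority", {
  expect_identical(normalize_for_resolution("http://xmlns.com/foaf/0.1/depicted_by"),
                   "http://xmlns.com/foaf/0.1/depicted_by")
  expect_identical(normalize_for_resolution("http://www.andrea-perego.name/foaf/#me"),
                   "http://www.andrea-perego.name/foaf/")
  expect_identical(normalize_for_resolution("HTTP://Example.ORG/Path#x"),
                   "http://example.org/Path")
  expect_error(normalize_for_resolution("relative/path"), "absolute")
  # two URIs differing only in fragment share a request target
  expect_identical(normalize_for_resolution("http://e.org/d#a"),
                   normalize_for_resolution("http://e.org/d#b"))
})

test_that("classify_content_type matches the six RDF media types exactly", {
  expect_true(classify_content_type("application/rdf+xml"))
  expect_true(classify_content_type("text/turtle; charset=utf-8"))
  expect_true(classify_content_type("TEXT/TURTLE"))
  expect_false(classify_content_type("text/html; charset=utf-8"))
  expect_false(classify_content_type(NULL))
  expect_false(classify_content_type(NA))
  # the map is data and overridable
  expect_false(classify_content_type("text/plain", map = c("text/turtle")))
  cfg <- resolver_config(strict_plain = FALSE, rate_limit = Inf)
  expect_false("text/plain" %in% cfg$content_type_map)
})

test_that("offline resolution classifies status codes and error categories", {
  routes <- list(
    "http://t.invalid/ok" = route200("<http://t.invalid/ok> <http://p> \"x\" .\n"),
    "http://t.invalid/gone" = list(status = 404L, content_type = "text/plain",
                                   body = "404 NOT Found"),
    "http://t.invalid/err" = list(status = 500L, content_type = "text/html",
                                  body = "oops"),
    "http://t.invalid/slow" = list(status = "timeout"),
    "http://t.invalid/hop" = list(status = 303L, location = "http://t.invalid/ok"),
    "http://t.invalid/loop" = list(status = 301L, location = "http://t.invalid/loop")
  )
  routing <- list(created = "2026-01-01T00:00:00Z", routes = routes)
  cfg <- offline_cfg(routing)
  ok <- resolve_uri("http://t.invalid/ok", cfg)
  expect_true(ok$resolvable)
  expect_true(ok$rdf_content_type)
  expect_identical(ok$final_status, 200L)

  gone <- resolve_uri("http://t.invalid/gone", cfg)
  expect_false(gone$resolvable)
  expect_identical(gone$final_status, 404L)
  expect_null(gone$body)

  expect_false(resolve_uri("http://t.invalid/err", cfg)$resolvable)

  slow <- resolve_uri("http://t.invalid/slow", cfg)
  expect_false(slow$resolvable)
  expect_identical(slow$final_status, "timeout")

  hop <- resolve_uri("http://t.invalid/hop", cfg)
  expect_true(hop$resolvable)
  expect_identical(length(hop$redirect_chain), 1L)

  loop <- resolve_uri("http://t.invalid/loop", cfg)
  expect_false(loop$resolvable)
  expect_identical(loop$final_status, "too-many-redirects")

  missing <- resolve_uri("http://t.invalid/absent", cfg)
  expect_false(missing$resolvable)
  expect_identical(missing$final_status, "connection-error")
})

test_that("one fetch per request target: fragment siblings share the record", {
  routing <- list(created = "x", routes = list(
    "http://t.invalid/doc" = route200("<http://t.invalid/doc#a> <http://p> \"1\" .\n")
  ))
  cfg <- offline_cfg(routing)
  a <- resolve_uri("http://t.invalid/doc#a", cfg)
  b <- resolve_uri("http://t.invalid/doc#b", cfg)
  expect_identical(a$request_target, b$request_target)
  expect_identical(a$body, b$body)
  expect_identical(a$uri, "http://t.invalid/doc#a")
  expect_identical(b$uri, "http://t.invalid/doc#b")
  # exactly one cache entry for the shared target
  expect_identical(sum(startsWith(ls(cfg$cache), "t:")), 1L)
})

test_that("fetch_and_parse honours preconditions and parses by content type", {
  routes <- list(
    "http://t.invalid/rx" = route200(paste0(
      "<?xml version=\"1.0\"?><rdf:RDF xmlns:rdf=\"", RDF, "\">",
      "<rdf:Description rdf:about=\"http://t.invalid/rx\"/></rdf:RDF>"),
      content_type = "application/rdf+xml"),
    "http://t.invalid/badrx" = route200(paste0(
      "<?xml version=\"1.0\"?><rdf:RDF xmlns:rdf=\"", RDF, "\">",
      "<rdf:Description rdf:ID=\"not ok\"/></rdf:RDF>"),
      content_type = "application/rdf+xml"),
    "http://t.invalid/prose" = route200("English prose served as plain text.",
                                        content_type = "text/plain"),
    "http://t.invalid/gone" = list(status = 404L)
  )
  cfg <- offline_cfg(list(created = "x", routes = routes))
  good <- fetch_and_parse(resolve_uri("http://t.invalid/rx", cfg), cfg)
  expect_s3_class(good, "triple_set")
  expect_true(is_parse_failure(
    fetch_and_parse(resolve_uri("http://t.invalid/badrx", cfg), cfg)))
  expect_true(is_parse_failure(
    fetch_and_parse(resolve_uri("http://t.invalid/prose", cfg), cfg)))
  expect_error(fetch_and_parse(resolve_uri("http://t.invalid/gone", cfg), cfg),
               "requires")
})

test_that("snapshots round-trip and replay identically", {
  eco <- generate_ecosystem(defect_spec(seed = 2, n_terms = 20,
    n_triples_target = 50, n_non_resolvable = 3, n_non_parsable = 2,
    n_undefined = 1, n_misplaced_classes = 1, n_misplaced_properties = 1,
    n_datatype_misuse = 1, n_object_misuse = 1, n_deprecated_used = 1),
    verify = FALSE)
  dir <- withr::local_tempdir()
  snapshot_write(eco$routing, dir)
  back <- snapshot_read(dir)
  expect_identical(back$created, eco$routing$created)
  expect_setequal(names(back$routes), names(eco$routing$routes))
  a1 <- run_assessment(eco$subject_url, offline_cfg(eco$routing))
  a2 <- run_assessment(eco$subject_url,
                       resolver_config(offline_snapshot = dir, rate_limit = Inf))
  for (id in names(a1$metrics)) {
    expect_identical(a1$metrics[[id]]$error_uris, a2$metrics[[id]]$error_uris)
  }
})

test_that("resolver_config validates its numeric invariants", {
  expect_error(resolver_config(timeout = 0))
  expect_error(resolver_config(max_redirects = -1))
  expect_error(resolver_config(retries = -1))
})
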