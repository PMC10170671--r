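# Parsing, the unique-URI inventory, and affected-triple counting.

test_that("well-formed documents parse in every serialization", {
  ttl <- paste0(
    "@prefix ex: <http://ex.org/> .\n",
    "ex:a ex:p ex:b .\nex:a ex:p \"x\" .\nex:b ex:q \"y\"@en .\n")
  ts <- parse_content(ttl, "turtle")
  expect_s3_class(ts, "triple_set")
  expect_identical(n_triples(ts), 3L)
  expect_identical(ts$format, "turtle")

  nt <- "<http://a> <http://b> <http://c> ."
  expect_identical(n_triples(parse_content(nt, "ntriples")), 1L)

  # the same graph in all five serializations is the same triple set
  rx <- paste0(
    "<?xml version=\"1.0\"?>\n",
    "<rdf:RDF xmlns:rdf=\"", RDF, "\" xmlns:ex=\"http://ex.org/\">\n",
    "<rdf:Description rdf:about=\"http://ex.org/a\">",
    "<ex:p rdf:resource=\"http://ex.org/b\"/><ex:p>x</ex:p>",
    "</rdf:Description>\n",
    "<rdf:Description rdf:about=\"http://ex.org/b\">",
    "<ex:q xml:lang=\"en\">y</ex:q></rdf:Description>\n</rdf:RDF>\n")
  jl <- paste0(
    '{"@context": {"ex": "http://ex.org/", "p": {"@id": "http://ex.org/p"}},',
    '"@graph": [',
    '{"@id": "ex:a", "http://ex.org/p": [{"@id": "ex:b"}, {"@value": "x"}]},',
    '{"@id": "ex:b", "http://ex.org/q": {"@value": "y", "@language": "en"}}]}')
  ts_rx <- parse_content(rx, "rdfxml")
  ts_jl <- parse_content(jl, "jsonld")
  ts_nt <- parse_content(write_ntriples(ts), "ntriples")
  ts_n3 <- parse_content(ttl, "n3")
  expect_true(ts_equal(ts, ts_rx))
  expect_true(ts_equal(ts, ts_jl))
  expect_true(ts_equal(ts, ts_nt))
  expect_true(ts_equal(ts, ts_n3))
})

test_that("malformed content yields a structured failure, not an error", {
  # invalid non-colonized name in rdf:ID: well-formed XML, invalid RDF/XML
  bad_xml <- paste0(
    "<?xml version=\"1.0\"?><rdf:RDF xmlns:rdf=\"", RDF, "\">",
    "<rdf:Description rdf:ID=\"1 invalid\"/></rdf:RDF>")
  res <- parse_content(bad_xml, "rdfxml")
  expect_true(is_parse_failure(res))
  expect_match(res$message, "NCName")

  # free text under the N-Triples grammar (text/plain) cannot parse
  expect_true(is_parse_failure(parse_content("This is English prose.", "ntriples")))
  expect_true(is_parse_failure(parse_content("also not turtle @@@", "turtle")))
  expect_true(is_parse_failure(parse_content("{not json", "jsonld")))

  # unknown format label is a configuration error and does throw
  expect_error(parse_content("x", "trig"), "unknown RDF format")
})

test_that("empty input behaves per serialization grammar", {
  # frozen against a reference parser: line-oriented and Turtle-family
  # grammars accept the empty document; XML and JSON require a document
  for (fmt in c("turtle", "ntriples", "n3")) {
    res <- parse_content("", fmt)
    expect_false(is_parse_failure(res), label = fmt)
    expect_identical(n_triples(res), 0L, label = fmt)
  }
  expect_true(is_parse_failure(parse_content("", "rdfxml")))
  expect_true(is_parse_failure(parse_content("", "jsonld")))
})

test_that("literals and URIs with the same lexical form stay distinct", {
  ts <- parse_content(paste0(
    "<http://ex.org/s> <http://ex.org/p> <http://ex.org/o> .\n",
    "<http://ex.org/s> <http://ex.org/p> \"http://ex.org/o\" .\n"), "ntriples")
  expect_identical(n_triples(ts), 2L)
  inv <- extract_unique_uris(ts)
  expect_identical(inv$as_object[inv$uri == "http://ex.org/o"], 1L)
})

test_that("unique-URI inventory counts roles and excludes non-URIs", {
  ts <- triple_set(rbind(
    trip("http://A", "http://p", "http://B"),
    trip("http://A", "http://p", "x", o_kind = "literal")
  ))
  inv <- extract_unique_uris(ts)
  expect_identical(nrow(inv), 3L)
  expect_identical(inv$as_subject[inv$uri == "http://A"], 2L)
  expect_identical(inv$as_predicate[inv$uri == "http://p"], 2L)
  expect_identical(inv$as_object[inv$uri == "http://B"], 1L)

  # one URI in both subject and object position: one entry, both counts
  ts2 <- triple_set(rbind(
    trip("http://A", "http://p", "http://B"),
    trip("http://B", "http://p", "http://A")
  ))
  inv2 <- extract_unique_uris(ts2)
  expect_identical(nrow(inv2), 3L)
  expect_true(all(inv2[inv2$uri == "http://A", c("as_subject", "as_object")] == 1L))

  # blank nodes and typed-literal datatype IRIs are never inventoried
  ts3 <- triple_set(rbind(
    trip("b", "http://p", "5", o_kind = "literal",
         o_dt = paste0(XSD, "integer"), s_kind = "blank")
  ))
  expect_identical(extract_unique_uris(ts3)$uri, "http://p")
})

test_that("a resource shaped like a 28-URI / 107-triple ontology gives 1/28 and 1/107", {
  s <- "http://dct.test/doc"
  p <- "http://dct.test/term"
  bad <- "http://dct.test/gone"
  objs <- sprintf("http://dct.test/o%d", 1:25)
  rows <- rbind(
    trip(s, p, bad),
    do.call(rbind, lapply(objs, function(o) trip(s, p, o))),
    do.call(rbind, lapply(1:81, function(k) trip(s, p, sprintf("lit %d", k),
                                                 o_kind = "literal")))
  )
  ts <- triple_set(rows)
  inv <- extract_unique_uris(ts)
  expect_identical(nrow(inv), 28L)
  expect_identical(attr(inv, "total_triples"), 107L)
  ctx <- mini_context(ts, overrides = stats::setNames(
    list(list(status = 404L, content_type = "text/plain", body = "gone")), bad))
  m <- metric_non_resolvable(ctx)
  expect_identical(m$numerator, 1L)
  expect_identical(m$denominator, 28L)
  expect_identical(m$affected_triples, 1L)
  expect_equal(round(100 * m$proportion, 1), 3.6)
  expect_equal(round(100 * m$affected_proportion, 1), 0.9)
})

test_that("count_affected_triples counts each triple at most once", {
  ts <- triple_set(rbind(
    trip("http://a", "http://bad1", "http://bad2"),
    trip("http://a", "http://p", "http://bad1"),
    trip("http://bad2", "http://p", "http://x"),
    trip("http://a", "http://p", "y", o_kind = "literal")
  ))
  expect_identical(count_affected_triples(ts, character(0)), 0L)
  expect_identical(count_affected_triples(ts, "http://bad1"), 2L)
  # co-occurring bad URIs: the shared triple counted once
  brute <- sum(apply(ts$triples, 1, function(r) {
    any(c(r[["s"]], r[["p"]], r[["o"]]) %in% c("http://bad1", "http://bad2"))
  }))
  expect_identical(count_affected_triples(ts, c("http://bad1", "http://bad2")),
                   brute)
})

test_that("inventory invariants hold over generated graphs", {
  for (seed in 1:5) {
    eco <- generate_ecosystem(defect_spec(seed = seed, n_terms = 20,
      n_triples_target = 60, n_non_resolvable = 3, n_non_parsable = 2,
      n_undefined = 2, n_misplaced_classes = 1, n_misplaced_properties = 1,
      n_datatype_misuse = 1, n_object_misuse = 1, n_deprecated_used = 1),
      verify = FALSE)
    ts <- eco$subject_ts
    inv <- extract_unique_uris(ts)
    expect_lte(nrow(inv), 3L * n_triples(ts))
    # order independence
    shuffled <- triple_set(ts$triples[sample(nrow(ts$triples)), ])
    inv2 <- extract_unique_uris(shuffled)
    expect_identical(inv[order(inv$uri), ], inv2[order(inv2$uri), ])
    # subadditivity of affected-triple counts
    uris <- inv$uri
    s1 <- uris[seq(1, length(uris), 2)]
    s2 <- uris[seq(2, length(uris), 2)]
    expect_lte(count_affected_triples(ts, union(s1, s2)),
               count_affected_triples(ts, s1) + count_affected_triples(ts, s2))
  }
})

test_that("load_resource reads files, infers formats, and reports failures", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines("<http://ex.org/a> <http://ex.org/p> <http://ex.org/b> .", path)
  ts <- load_resource(path)
  expect_identical(n_triples(ts), 1L)
  expect_identical(ts$format, "turtle")
  expect_true(attr(ts, "parsable"))

  bad <- withr::local_tempfile(fileext = ".rdf")
  writeLines("definitely not xml", bad)
  expect_error(load_resource(bad), class = "rdf_parse_error")
  expect_error(load_resource("/nonexistent/file.ttl"), class = "rdf_input_error")

  # no extension: try-parse cascade still finds the serialization
  anon <- withr::local_tempfile()
  writeLines("<http://ex.org/a> <http://ex.org/p> \"v\" .", anon)
  expect_identical(n_triples(load_resource(anon)), 1L)
})

test_that("duplicate triples collapse under set semantics", {
  ts <- triple_set(rbind(
    trip("http://a", "http://p", "http://b"),
    trip("http://a", "http://p", "http://b")
  ))
  expect_identical(n_triples(ts), 1L)
})
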