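---
title: "Foundational quality assessment of RDF resources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foundational quality assessment of RDF resources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rdfquality` treats an RDF resource — a dataset, schema, or ontology in
any of Turtle, RDF/XML, N-Triples, Notation 3, or JSON-LD — as a set of
triples whose non-literal nodes are URIs, and asks whether those URIs
uphold the minimal contract of linked data: they dereference, what they
return parses, it defines them, and the defined terms are used as
defined. Six metrics operationalize this, grouped as Resolvability (1),
Parsability (1), and Consistency (4). All six share one arithmetic
pattern: a metric is a ratio of unique erroneous URIs to a reference
population, accompanied by the count of *affected triples* (triples of
the assessed resource containing at least one erroneous URI, each triple
counted once per metric).

The assessment is a funnel. A URI that fails resolvability (4xx, 5xx, or
a network-level failure) is never tested for parsability; a URI not
served under an RDF media type is never parsed; only parsable URIs are
tested for definedness; only defined terms are classified; and only
non-deprecated terms are analyzed for misplacement and misuse. Error
sets of consecutive funnel stages are therefore disjoint by
construction, which the test suite asserts as an invariant.

Definedness is deliberately structural, not textual: a URI is defined
iff it occurs as the *subject* of at least one triple in the graph
obtained by dereferencing it. Working on parsed graphs avoids the
fragility of pattern matching over serialized text. For hash URIs the
full URI, fragment included, is the term being looked up; only the
request is sent to the fragment-stripped document URI.

Classification follows the asymmetric rule that a term is a class iff it
is typed `owl:Class` or `rdfs:Class` *without any property type*, and a
property iff typed `rdf:Property` or any of the OWL property types
(object, datatype, annotation, functional, transitive, symmetric,
inverse-functional). A term typed both ways is treated as a property and
carries a consistency warning. Evidence is the union of what the
assessed resource says about the term and what the term's dereferenced
document says; the defining document is authoritative, and no RDFS/OWL
entailment is applied (typing must be asserted, not inferred).

Deprecation is an assertion about a term — an `owl:deprecated` statement
whose object is a literal reading `true` or `1` after case folding —
never a property of its uses. `owl:DeprecatedClass`/`owl:DeprecatedProperty`
typing is not treated as deprecation (only the annotation property is
specified for this check); this is a deliberate narrow reading.

### Denominators

URI-level metrics (non-resolvable, non-parsable, undefined) divide by
*all unique URIs* of the resource. Term-level metrics divide by the
unique classes and/or properties: misplacement and deprecated usage use
classes + properties pooled, misuse uses properties. Because published
definitions can be read as pooled or split for misplacement, both
sub-ratios (misplaced classes / unique classes, misplaced properties /
unique properties) are carried in the metric's `detail`, and every
metric also reports the *eligible* population (e.g. how many URIs were
actually candidates for the parsability test) for transparency.

Blank nodes and literals are never inventoried — they are not URIs —
and datatype IRIs of typed literals are metadata of literals, not graph
nodes, so they do not count either. URIs occurring inside literal
values (string-typed URLs) are literals and excluded. Duplicate triples
collapse under set semantics before anything is counted.

## Resolution

Each unique URI is dereferenced once per run, keyed by its request
target (fragment stripped, scheme/authority case-folded), with a single
GET carrying an Accept header listing the RDF media types (rather than
HEAD-then-GET: the body is reused for the parsability test, halving
requests). Defaults: timeout 30 s, 1 retry, 10 redirects, 2 requests/s
rate limit against remote hosts. 3xx redirects are followed and are not
themselves errors — hash-namespace and persistent-URL indirection
require it. Network-level failures (timeout, DNS, connection) count as
non-resolvable with a distinct error category in `errors.csv`: an
outage and a 404 are both, from the consumer's perspective, a URI that
does not work today.

The media-type table maps exactly six types to serializations:
`text/turtle` and `application/x-turtle` (Turtle), `text/plain`
(N-Triples), `application/ld+json` (JSON-LD), `text/n3` (Notation 3),
`application/rdf+xml` (RDF/XML). Parameters are stripped and comparison
is case-insensitive. Two knobs exist because the table is imperfect in
practice: the published correspondence lists RDF/JSON under
`application/ld+json` (almost certainly a typo for
`application/rdf+json`); the map is implemented as printed but is
plain data, overridable via `content_type_map`. And `text/plain` is
honoured as N-Triples because the table says so, although prose served
as `text/plain` then inflates the non-parsable count; `strict_plain =
FALSE` demotes it.

Every resolution can be replayed: a routing table (status, content
type, body, redirect target per request target) can be saved as a plain
JSON snapshot and passed as `offline_snapshot`, in which case a run
makes zero network calls and is byte-reproducible. The snapshot records
its creation time, and a replayed run stamps its RDF report with that
stored time instead of the wall clock — this is why two replays of the
same snapshot produce byte-identical `summary.csv`, `errors.csv`, and
`report.ttl` without any special pleading in the tests. Wall-clock
duration is reported on the console, not in those files.

## The RDF layer

No RDF parsing library is available in the target environment, so the
package carries its own readers and writers: a line-oriented N-Triples
reader; a tokenizer/recursive-descent reader for Turtle (prefixes, base
resolution, literals with language tags and datatypes, numeric/boolean
shorthand, blank-node property lists, collections) which also serves
Notation 3 documents in the Turtle-compatible subset this tool
consumes; an RDF/XML reader on top of `xml2` (node and property
elements, `rdf:about`/`rdf:ID`/`rdf:nodeID`/`rdf:resource`,
`rdf:parseType` Resource/Literal, property attributes, `xml:lang`,
datatypes) that validates `rdf:ID` values as XML NCNames — a well-formed
XML document with an invalid non-colonized name in `rdf:ID` is an
RDF-level parse failure, a real-world failure mode the fixtures
reproduce; and a compact JSON-LD reader on top of `jsonlite`
(`@context` prefix/term definitions with `@id`/`@type` coercion,
`@graph`, `@value` objects, nested nodes). Graph equality is RDF graph
isomorphism: blank nodes are matched by iterative signature refinement,
and the canonical N-Triples writer relabels them deterministically.

Readers were cross-checked during development against an independent
reference parser on shared documents (including empty-input behaviour:
the Turtle family accepts the empty document, XML and JSON do not).
Known limits, acceptable for a quality-assessment tool and covered
honestly here rather than hidden: no TriG/N-Quads/named graphs, no
`rdf:li` containers or reification sugar in RDF/XML, no remote contexts
or framing in JSON-LD, and full N3 (rules, quantification) is out of
scope.

## The synthetic ecosystem (the stated world)

`generate_ecosystem(defect_spec(...))` builds a world in which the right
answer is known by construction: ontology documents defining classes
and properties (Turtle and RDF/XML; instance documents as N-Triples
under `text/plain`), one subject resource using every term, and a
routing table giving each request target its HTTP behaviour. The
default defect spec states a moderately broken 50-term, 150-triple
ecosystem: 10 non-resolvable URIs (status mix 50% 404, 10% 410, 15%
500, 15% 503, 10% timeout — client errors dominate in the wild, with a
minority of server errors and outages), 5 non-parsable, 4 undefined, 3
misplaced classes + 2 misplaced properties, 2 + 2 misused properties, 2
deprecated terms in use. Terms are hash- and slash-namespace roughly
50/50 among healthy terms (exercising fragment stripping); defect
carriers get dedicated slash routes so a defect never leaks onto
siblings; about 10% of healthy slash terms resolve through a 303
redirect. The "undefined" defect is realized the way it happens in
reality: the namespace document resolves and parses but simply omits
the term. Generation is deterministic under the seed, restores the
caller's RNG state, and is linear in the term count.

The ledger is not trusted blindly: at generation time (default
`verify = TRUE`) an independent brute-force recount — manual redirect
following, subject-membership scans, position scans over the subject
graph, re-parsed from the routed document bodies — must agree with the
constructed ground truth, or generation aborts. The same recount is the
oracle the acceptance suite compares the pipeline against.

Serving happens in a background R process (`callr`), because `httpuv`
callbacks cannot run while the assessing process blocks in `curl`.
Foreign-host URIs that the world must define (the `rdf:` namespace
stand-in document, for instance — a synthetic stand-in, not a copy of
the real document) are reached through the server's
`/fetch?uri=` endpoint via a URL-rewrite hook in the resolver
configuration. Timeout defects are simulated by a server stall longer
than the client timeout; because the server is single-threaded, the
stall must stay below twice the client timeout or its residue would
delay the *next* queued request past the deadline and flag a healthy
URI — hence the defaults of 0.5 s client timeout and 0.75 s stall, plus
one retry in live fixture runs.

What the generator does not emulate — so a green test does not
establish robustness against it: content negotiation that varies by
Accept header (each target has one fixed representation), chunked or
compressed transfer, TLS, very large documents, servers that lie about
content types in both directions, and the slow drift of the live web
(the reason published headline numbers for real resources are snapshots
of a date, not reproducible targets).

## Reports

`summary.csv` holds exactly six rows with raw counts as the
authoritative values and percentages re-derived at one decimal;
`errors.csv` one row per erroneous URI per metric with its error
category and per-URI affected-triple count. Undefined URIs are
annotated as needing investigation rather than condemned: a URI used
only as an object and absent from its document may be a data pointer,
not an error. The quality graph (`report.ttl`) expresses one
`dqv:QualityMeasurement` per metric with the computed proportion
(written with 17 significant digits so re-parsing recovers the double
exactly), linked to the assessed resource and to the metric's IRI in
the FQM vocabulary (`fqm.ttl`): six `dqv:Metric` instances under a
configurable base namespace (default `https://purl.org/fqm#`), each
with a label, a definition, a category (Resolvability, Parsability,
Consistency), and one `dqv:inDimension` link into the linked-data
quality dimensions vocabulary (availability, syntactic validity,
consistency). The exact IRIs of the upstream rendering are not fixed by
the published material, so labels and definitions are the contract and
the IRIs are configurable.

## Limitations

The misplacement check covers the two codified scenarios (class as
predicate, property as `rdf:type` object); other plausible misplacement
patterns are not claimed. Domain/range conformance checking is out of
scope — that is constraint-validation territory, a different tool
family. The denominator choices follow the published definitions
literally even where that means a numerator population (eligible URIs)
is smaller than the denominator (all unique URIs); the eligible counts
are reported so other ratios can be formed. Parser coverage is a
practical subset, not a conformance suite.
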