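# rdfquality

Automated foundational quality assessment of RDF resources.

## The problem

Linked data only works when its building blocks work: URIs that
dereference, content that parses, terms that are defined where they claim
to be, and ontology terms used the way their definitions say. In
practice, published RDF resources — biomedical ontologies, health data
models, metadata profiles — routinely violate these basics: a predicate
returns `404`, a namespace document is well-formed XML but invalid
RDF/XML, a term is spelled into the wrong namespace, a class is used as a
predicate, an `owl:ObjectProperty` points at a string, or a deprecated
class is still in use. Each of these silently breaks interoperability for
every downstream consumer.

`rdfquality` computes six objective, automatable, foundational quality
metrics over any RDF resource, in three categories:

| Category | Metric | What it measures |
|---|---|---|
| Resolvability | Non-resolvable URIs | unique URIs answering 4xx/5xx (or failing at the network level) / all unique URIs |
| Parsability | Non-parsable URIs | URIs served under an RDF media type whose content cannot be parsed into triples / all unique URIs |
| Consistency | Undefined URIs | parsable URIs that never occur as subject in their own dereferenced graph / all unique URIs |
| Consistency | Misplaced classes or properties | classes used as predicates; properties used as objects of `rdf:type` / all unique classes + properties |
| Consistency | Misuse of `owl:DatatypeProperty` / `owl:ObjectProperty` | datatype properties with resource objects; object properties with literal objects / all unique properties |
| Consistency | Use of deprecated classes or properties | terms asserted `owl:deprecated true` by their defining ontology and still used / all unique classes + properties |

For each metric the package reports the erroneous URIs, the ratio of
erroneous URIs *n/N*, and the number and share of *affected triples* —
triples of the assessed resource containing at least one erroneous URI.

The assessment procedure: (1) extract all unique URIs from the parsed
resource; (2) dereference each one with content negotiation and classify
the HTTP outcome; (3) parse bodies served under an RDF media type; (4)
test whether each parsable URI is defined (a subject) in its own resolved
graph; (5) classify defined terms as classes (`owl:Class` / `rdfs:Class`
without any property type) or properties (`rdf:Property` or any OWL
property type), read `owl:deprecated`, and analyze the usage of all
non-deprecated terms in the source graph; (6) write reports and record
the time cost.

Resources may be local files or URLs in Turtle, RDF/XML, N-Triples,
Notation 3, or JSON-LD. Reports come as CSV (`summary.csv`,
`errors.csv`) and as RDF quality metadata aligned with the W3C Data
Quality Vocabulary (DQV), with the six metrics themselves published as a
small vocabulary (`fqm.ttl`).

## Worked example

Every metric is testable without network access: the package generates
synthetic linked-data ecosystems — ontology documents, a subject resource
using their terms, and a routing table of HTTP behaviours with injected
defects — together with a ground-truth ledger.

```r
library(rdfquality)

eco <- generate_ecosystem(defect_spec(seed = 1))   # 50 terms, 150 triples
cfg <- resolver_config(offline_snapshot = eco$routing, rate_limit = Inf)
a   <- run_assessment(eco$subject_url, cfg)
print(a)
```

```
RDF resource quality assessment
  source: http://127.0.0.1:8099/resource 
  resource resolvable: TRUE  parsable: TRUE 
  unique URIs: 61  triples: 150
non_resolvable     10/61 (16.4%)  affected 10/150 (6.7%)
non_parsable       5/61 (8.2%)  affected 5/150 (3.3%)
undefined          4/61 (6.6%)  affected 4/150 (2.7%)
misplaced          5/32 (15.6%)  affected 5/150 (3.3%)
property_misuse    4/20 (20.0%)  affected 4/150 (2.7%)
deprecated_usage   2/32 (6.2%)  affected 2/150 (1.3%)
  time cost: 0:00.44
```

Reading the output: the subject resource uses 61 unique URIs in 150
triples. Ten URIs (16.4%) failed to dereference (the default defect spec
injects exactly 10: a mix of 404/410/500/503 and timeouts), and the ten
triples using them (6.7% of the resource) are affected. Five URIs
resolved under an RDF media type but did not parse, four resolved and
parsed but are not defined in their own documents, and so on — each
number equals the generator's ground-truth ledger
(`eco$ground_truth`). `write_reports(a, "out/")` writes `summary.csv`,
`errors.csv`, `report.ttl` (DQV quality measurements) and `fqm.ttl`.

The same ecosystem can be served over real local HTTP:

```r
srv <- serve_ecosystem(eco)
a   <- run_assessment(eco$subject_url, fixture_resolver_config(eco, server = srv))
stop_ecosystem_server(srv)
```

`mirror_table2_examples()` builds a fixed ecosystem with one classic
defect per metric facet (a 404 property, an invalid NCName in `rdf:ID`, a
term missing from its namespace document, a class used as predicate, a
property as `rdf:type` object, both misuse directions, and a deprecated
class in use).

## Command line

```sh
Rscript inst/cli/rdfquality assess my-ontology.ttl --out report/
Rscript inst/cli/rdfquality assess http://example.org/data --offline-snapshot snap/
Rscript inst/cli/rdfquality fixtures generate --seed 7 --n-terms 50 --out fixture/
Rscript inst/cli/rdfquality vocab emit --out fqm.ttl
```

Exit status 0 means the assessment completed (quality findings are
results, not failures); 1 is an operational failure (unreachable source);
2 a usage error.

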