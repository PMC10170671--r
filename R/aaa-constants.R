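# Shared constants; this file sorts first so top-level definitions in
# other files can use them.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
RDF_TYPE <- paste0(RDF_NS, "type")
OWL_DEPRECATED <- paste0(OWL_NS, "deprecated")

RDF_FORMATS <- c("turtle", "rdfxml", "ntriples", "n3", "jsonld")

`%||%` <- function(a, b) if (is.null(a)) b else a
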