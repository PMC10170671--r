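# Compact JSON-LD reader built on jsonlite. Supports the node-object
# subset this tool consumes: @context with prefix and term definitions
# (@id / @type coercion / @language), @id, @type, @graph, @value objects,
# nested node objects, arrays, and compact IRIs. Framing, @reverse,
# @container indexing and remote contexts are out of scope.

jl_env <- function(base) {
  e <- new.env(parent = emptyenv())
  e$rows <- list(); e$nrow <- 0L; e$bn <- 0L; e$base <- base
  e
}

jl_emit <- function(e, s, s_kind, p, o, o_kind, dt = NA_character_,
                    lang = NA_character_) {
  e$nrow <- e$nrow + 1L
  e$rows[[e$nrow]] <- triple_row(s, s_kind, p, o, o_kind, dt, lang)
}

jl_fresh <- function(e) { e$bn <- e$bn + 1L; paste0("jgen", e$bn) }

jl_ctx_parse <- function(ctx_raw, parent = list(terms = list(), base = NULL, vocab = NULL)) {
  ctx <- parent
  if (is.null(ctx_raw)) return(ctx)
  if (!is.list(ctx_raw)) stop("unsupported @context form", call. = FALSE)
  for (key in names(ctx_raw)) {
    val <- ctx_raw[[key]]
    if (key == "@base") { ctx$base <- val; next }
    if (key == "@vocab") { ctx$vocab <- val; next }
    if (is.character(val) && length(val) == 1L) {
      ctx$terms[[key]] <- list(id = val, type = NULL, language = NULL)
    } else if (is.list(val)) {
      ctx$terms[[key]] <- list(id = val[["@id"]] %||% key,
                               type = val[["@type"]],
                               language = val[["@language"]])
    }
  }
  ctx
}

jl_expand_iri <- function(e, ctx, x, vocab = FALSE) {
  if (startsWith(x, "_:")) return(list(value = sub("^_:", "", x), kind = "blank"))
  if (!is.null(ctx$terms[[x]])) {
    id <- ctx$terms[[x]]$id
    if (!identical(id, x)) return(jl_expand_iri(e, ctx, id, vocab))
  }
  m <- regmatches(x, regexec("^([^:/]+):(.*)$", x))[[1]]
  if (length(m) && !startsWith(m[3], "//")) {
    pre <- ctx$terms[[m[2]]]
    if (!is.null(pre)) {
      return(list(value = paste0(pre$id, m[3]), kind = "uri"))
    }
  }
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)) return(list(value = x, kind = "uri"))
  if (vocab && !is.null(ctx$vocab)) return(list(value = paste0(ctx$vocab, x), kind = "uri"))
  base <- ctx$base %||% e$base
  if (!is.null(base)) return(list(value = resolve_iri(x, base), kind = "uri"))
  list(value = x, kind = "uri")
}

jl_scalar_literal <- function(val) {
  if (is.logical(val)) {
    list(value = tolower(as.character(val)), dt = paste0(XSD_NS, "boolean"))
  } else if (is.numeric(val)) {
    if (val == as.integer(val) && !grepl("[.eE]", format(val))) {
      list(value = format(val, scientific = FALSE), dt = paste0(XSD_NS, "integer"))
    } else {
      list(value = format(val, scientific = TRUE), dt = paste0(XSD_NS, "double"))
    }
  } else {
    list(value = as.character(val), dt = NA_character_)
  }
}

jl_node <- function(e, ctx, obj) {
  if (!is.null(obj[["@context"]])) ctx <- jl_ctx_parse(obj[["@context"]], ctx)
  id_raw <- obj[["@id"]]
  subj <- if (is.null(id_raw)) list(value = jl_fresh(e), kind = "blank")
          else jl_expand_iri(e, ctx, id_raw)
  types <- obj[["@type"]]
  if (!is.null(types)) {
    if (is.character(types)) types <- as.list(types)
    for (tv in types) {
      t <- jl_expand_iri(e, ctx, tv, vocab = TRUE)
      jl_emit(e, subj$value, subj$kind, RDF_TYPE, t$value, t$kind)
    }
  }
  for (key in names(obj)) {
    if (startsWith(key, "@")) next
    pt <- jl_expand_iri(e, ctx, key, vocab = TRUE)
    term_def <- ctx$terms[[key]]
    vals <- obj[[key]]
    if (!is.list(vals) || !is.null(names(vals))) vals <- list(vals)
    for (v in vals) {
      jl_value(e, ctx, subj, pt$value, v, term_def)
    }
  }
  subj
}

jl_value <- function(e, ctx, subj, pred, v, term_def) {
  if (is.list(v) && is.null(names(v))) {
    for (item in v) jl_value(e, ctx, subj, pred, item, term_def)
    return(invisible())
  }
  if (is.list(v)) {
    if (!is.null(v[["@value"]])) {
      lit <- jl_scalar_literal(v[["@value"]])
      dt <- if (!is.null(v[["@type"]])) jl_expand_iri(e, ctx, v[["@type"]], TRUE)$value
            else lit$dt
      lang <- v[["@language"]] %||% NA_character_
      jl_emit(e, subj$value, subj$kind, pred, lit$value, "literal",
              dt %||% NA_character_, lang)
    } else if (!is.null(v[["@id"]]) && length(v) <= 1L) {
      o <- jl_expand_iri(e, ctx, v[["@id"]])
      jl_emit(e, subj$value, subj$kind, pred, o$value, o$kind)
    } else {
      o <- jl_node(e, ctx, v)
      jl_emit(e, subj$value, subj$kind, pred, o$value, o$kind)
    }
    return(invisible())
  }
  coerce_id <- !is.null(term_def) && identical(term_def$type, "@id")
  if (is.character(v) && coerce_id) {
    o <- jl_expand_iri(e, ctx, v)
    jl_emit(e, subj$value, subj$kind, pred, o$value, o$kind)
  } else {
    lit <- jl_scalar_literal(v)
    dt <- if (!is.null(term_def) && !is.null(term_def$type) &&
              !identical(term_def$type, "@id")) {
      jl_expand_iri(e, ctx, term_def$type, TRUE)$value
    } else lit$dt
    lang <- if (!is.null(term_def)) term_def$language %||% NA_character_ else NA_character_
    jl_emit(e, subj$value, subj$kind, pred, lit$value, "literal", dt, lang)
  }
}

parse_jsonld <- function(text, source = NULL, base = NULL) {
  data <- jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE)
  e <- jl_env(base %||% source)
  ctx <- jl_ctx_parse(if (is.list(data)) data[["@context"]] else NULL)
  nodes <- if (is.list(data) && !is.null(data[["@graph"]])) {
    data[["@graph"]]
  } else if (is.list(data) && is.null(names(data))) {
    data
  } else {
    list(data)
  }
  for (node in nodes) {
    if (!is.list(node)) stop("JSON-LD node object expected", call. = FALSE)
    local_node <- node
    local_node[["@context"]] <- node[["@context"]] %||% NULL
    ctx_local <- ctx
    jl_node(e, ctx_local, node)
  }
  df <- if (e$nrow) do.call(rbind, e$rows[seq_len(e$nrow)]) else empty_triple_frame()
  triple_set(df, source = source, format = "jsonld")
}
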