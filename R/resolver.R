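# URI dereferencing with content negotiation. Two interchangeable
# backends: live HTTP through curl, and an offline routing table (the
# same structure the fixture server serves), which makes runs
# bit-reproducible with zero network calls.

DEFAULT_ACCEPT <- paste(
  "text/turtle", "application/rdf+xml", "application/ld+json", "text/n3",
  "application/x-turtle", "text/plain;q=0.5", "*/*;q=0.1", sep = ", ")

ERROR_CATEGORIES <- c("timeout", "dns-failure", "connection-error",
                      "too-many-redirects")

#' Resolver configuration
#'
#' @param timeout request timeout in seconds (default 30).
#' @param max_redirects redirects followed before giving up (default 10);
#'   exceeding it records the error category \code{too-many-redirects}.
#' @param retries extra attempts after a network-level failure (default 1).
#' @param accept_header HTTP Accept header requesting RDF media types.
#' @param rate_limit maximum requests per second against remote hosts
#'   (default 2; use \code{Inf} for local fixture servers).
#' @param offline_snapshot a routing table (list keyed by request target)
#'   or a snapshot directory written by \code{\link{snapshot_write}}; when
#'   set, no network calls are made.
#' @param content_type_map character vector of media types treated as RDF
#'   content types; defaults to the six-entry serialization table.
#' @param url_rewrite optional function rewriting a request target to the
#'   URL actually fetched (used to direct foreign-host fixture URIs at a
#'   local server); records keep the original target.
#' @param strict_plain honour \code{text/plain} as an RDF content type
#'   (default TRUE, as the correspondence table prints it).
#' @return a \code{resolver_config} list with an attached per-run cache.
#' @export
resolver_config <- function(timeout = 30, max_redirects = 10, retries = 1,
                            accept_header = DEFAULT_ACCEPT, rate_limit = 2,
                            offline_snapshot = NULL,
                            content_type_map = names(rdf_content_types()),
                            url_rewrite = NULL, strict_plain = TRUE) {
  stopifnot(timeout > 0, max_redirects >= 0, retries >= 0)
  if (!strict_plain) {
    content_type_map <- setdiff(content_type_map, "text/plain")
  }
  routing <- offline_snapshot
  if (is.character(routing) && length(routing) == 1L) {
    routing <- snapshot_read(routing)
  }
  structure(list(
    timeout = timeout, max_redirects = max_redirects, retries = retries,
    accept_header = accept_header, rate_limit = rate_limit,
    routing = routing, content_type_map = tolower(content_type_map),
    url_rewrite = url_rewrite,
    cache = new.env(parent = emptyenv())
  ), class = "resolver_config")
}

#' Normalize a URI for dereferencing
#'
#' Strips the fragment (hash-namespace terms dereference to their host
#' document) and lower-cases the scheme and authority. Distinct URIs
#' sharing a request target share one HTTP fetch but keep separate
#' resolution records.
#'
#' @param uri an absolute URI.
#' @return the request target.
#' @export
normalize_for_resolution <- function(uri) {
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", uri)) {
    stop("not an absolute URI: ", uri, call. = FALSE)
  }
  target <- sub("#.*$", "", uri)
  m <- regmatches(target, regexec("^([A-Za-z][A-Za-z0-9+.-]*)(://)([^/?]*)(.*)$", target))[[1]]
  paste0(tolower(m[2]), m[3], tolower(m[4]), m[5])
}

#' Classify a media type as RDF content type
#'
#' TRUE iff the parameter-stripped, case-folded media type appears in the
#' configured map (by default the six types of the serialization table).
#'
#' @param content_type media type string, possibly with parameters, or
#'   \code{NULL}/\code{NA}.
#' @param map character vector of RDF media types.
#' @return logical.
#' @export
classify_content_type <- function(content_type,
                                  map = names(rdf_content_types())) {
  if (is.null(content_type) || is.na(content_type) || !nzchar(content_type)) {
    return(FALSE)
  }
  strip_media_params(content_type) %in% tolower(map)
}

resolution_record <- function(uri, target, status, content_type = NULL,
                              redirect_chain = character(0), body = NULL,
                              cfg = NULL) {
  is_error_cat <- is.character(status) && status %in% ERROR_CATEGORIES
  status_num <- if (is_error_cat) NA_integer_ else as.integer(status)
  resolvable <- !is_error_cat && status_num >= 200L && status_num < 300L
  ct <- if (!is.null(content_type) && !is.na(content_type)) {
    strip_media_params(content_type)
  } else NULL
  map <- if (is.null(cfg)) names(rdf_content_types()) else cfg$content_type_map
  structure(list(
    uri = uri,
    request_target = target,
    final_status = if (is_error_cat) status else status_num,
    content_type = ct,
    redirect_chain = redirect_chain,
    body = if (resolvable) body else NULL,
    resolvable = resolvable,
    rdf_content_type = resolvable && classify_content_type(ct, map)
  ), class = "resolution_record")
}

#' @export
print.resolution_record <- function(x, ...) {
  cat(sprintf("<resolution %s -> %s%s%s>\n", x$uri, x$final_status,
              if (!is.null(x$content_type)) paste0(" ", x$content_type) else "",
              if (length(x$redirect_chain)) paste0(" via ", length(x$redirect_chain), " redirect(s)") else ""))
  invisible(x)
}

# --- offline backend ---------------------------------------------------------

resolve_offline <- function(uri, target, cfg) {
  chain <- character(0)
  cur <- target
  repeat {
    entry <- cfg$routing$routes[[cur]]
    if (is.null(entry)) {
      return(resolution_record(uri, target, "connection-error",
                               redirect_chain = chain, cfg = cfg))
    }
    if (identical(entry$status, "timeout")) {
      return(resolution_record(uri, target, "timeout",
                               redirect_chain = chain, cfg = cfg))
    }
    status <- as.integer(entry$status)
    if (status >= 300L && status < 400L && !is.null(entry$location)) {
      if (length(chain) >= cfg$max_redirects) {
        return(resolution_record(uri, target, "too-many-redirects",
                                 redirect_chain = chain, cfg = cfg))
      }
      chain <- c(chain, entry$location)
      cur <- normalize_for_resolution(entry$location)
      next
    }
    return(resolution_record(uri, target, status, entry$content_type,
                             chain, entry$body, cfg = cfg))
  }
}

# --- live HTTP backend -------------------------------------------------------

curl_error_category <- function(message) {
  msg <- tolower(message)
  if (grepl("timed? ?out|timeout", msg)) return("timeout")
  if (grepl("resolve host|dns", msg)) return("dns-failure")
  "connection-error"
}

http_get_once <- function(url, cfg) {
  h <- curl::new_handle(
    followlocation = FALSE,
    timeout_ms = as.integer(cfg$timeout * 1000),
    connecttimeout_ms = as.integer(cfg$timeout * 1000),
    accept_encoding = "identity"
  )
  curl::handle_setheaders(h, Accept = cfg$accept_header)
  curl::curl_fetch_memory(url, handle = h)
}

rate_limit_wait <- function(cfg) {
  if (!is.finite(cfg$rate_limit)) return(invisible())
  last <- cfg$cache$.last_fetch
  gap <- 1 / cfg$rate_limit
  if (!is.null(last)) {
    wait <- gap - as.numeric(Sys.time()) + last
    if (wait > 0) Sys.sleep(wait)
  }
  cfg$cache$.last_fetch <- as.numeric(Sys.time())
  invisible()
}

resolve_live <- function(uri, target, cfg) {
  chain <- character(0)
  cur <- target
  repeat {
    fetch_url <- if (is.null(cfg$url_rewrite)) cur else cfg$url_rewrite(cur)
    attempt <- 0L
    res <- NULL
    repeat {
      rate_limit_wait(cfg)
      res <- tryCatch(http_get_once(fetch_url, cfg), error = identity)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      if (attempt > cfg$retries) {
        return(resolution_record(uri, target,
                                 curl_error_category(conditionMessage(res)),
                                 redirect_chain = chain, cfg = cfg))
      }
    }
    if (res$status_code >= 300L && res$status_code < 400L) {
      headers <- curl::parse_headers_list(res$headers)
      loc <- headers[["location"]]
      if (!is.null(loc)) {
        if (length(chain) >= cfg$max_redirects) {
          return(resolution_record(uri, target, "too-many-redirects",
                                   redirect_chain = chain, cfg = cfg))
        }
        loc <- resolve_iri(loc, cur)
        chain <- c(chain, loc)
        cur <- normalize_for_resolution(loc)
        next
      }
    }
    headers <- curl::parse_headers_list(res$headers)
    ct <- headers[["content-type"]]
    body <- tryCatch(rawToChar(res$content), error = function(e) "")
    return(resolution_record(uri, target, res$status_code, ct, chain, body,
                             cfg = cfg))
  }
}

#' Dereference one URI
#'
#' Follows redirects up to the configured maximum, sends an Accept header
#' requesting RDF media types, and never throws on network failure: an
#' exhausted fetch yields a record whose \code{final_status} is an error
#' category (\code{timeout}, \code{dns-failure}, \code{connection-error},
#' \code{too-many-redirects}), counted as non-resolvable. Results are
#' cached by request target, so each target is fetched once per run.
#'
#' @param uri absolute URI.
#' @param cfg a \code{\link{resolver_config}}.
#' @return a \code{resolution_record}.
#' @export
resolve_uri <- function(uri, cfg = resolver_config()) {
  target <- normalize_for_resolution(uri)
  key <- paste0("t:", target)
  cached <- cfg$cache[[key]]
  if (!is.null(cached)) {
    rec <- cached
    rec$uri <- uri
    return(rec)
  }
  rec <- if (!is.null(cfg$routing)) {
    resolve_offline(uri, target, cfg)
  } else {
    resolve_live(uri, target, cfg)
  }
  cfg$cache[[key]] <- rec
  rec
}

#' Parse the body of a resolved URI
#'
#' Requires a resolvable record with an RDF content type; the body is
#' parsed using the serialization implied by the content type (the
#' correspondence table reversed). Failure to parse is returned as a
#' structured \code{rdf_parse_failure}, feeding the non-parsable metric.
#'
#' @param record a \code{resolution_record}.
#' @param cfg a \code{\link{resolver_config}}.
#' @return a \code{triple_set} or an \code{rdf_parse_failure}.
#' @export
fetch_and_parse <- function(record, cfg = resolver_config()) {
  if (!record$resolvable || !record$rdf_content_type) {
    stop("fetch_and_parse requires a resolvable record with RDF content type",
         call. = FALSE)
  }
  fmt <- unname(CONTENT_TYPE_FORMATS[record$content_type])
  if (is.na(fmt)) fmt <- "turtle"
  parse_content(record$body %||% "", fmt, source = record$request_target)
}

# --- snapshots ---------------------------------------------------------------

#' Write a resolution routing table as an on-disk snapshot
#'
#' The snapshot is plain JSON (bodies included as strings) plus a creation
#' timestamp; loading it back with \code{\link{snapshot_read}} and passing
#' it as \code{offline_snapshot} replays a run with zero network calls.
#'
#' @param routing a routing table (as produced by
#'   \code{\link{generate_ecosystem}}, element \code{routing}).
#' @param dir directory to create.
#' @return \code{dir}, invisibly.
#' @export
snapshot_write <- function(routing, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(routing, file.path(dir, "snapshot.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a resolution snapshot
#' @param dir directory written by \code{\link{snapshot_write}}.
#' @return the routing table.
#' @export
snapshot_read <- function(dir) {
  path <- file.path(dir, "snapshot.json")
  if (!file.exists(path)) stop("no snapshot at ", dir, call. = FALSE)
  raw <- jsonlite::read_json(path)
  raw$routes <- lapply(raw$routes, function(e) {
    e$status <- if (identical(e$status, "timeout")) "timeout" else as.integer(e$status)
    e
  })
  raw
}
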