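# Local fixture HTTP endpoint honouring an ecosystem's routing table.
# The server runs in a background R process (callr) because the assessing
# process blocks in curl while requests arrive.

fixture_app <- function(routing) {
  routes <- routing$routes
  list(call = function(req) {
    path <- req$PATH_INFO %||% "/"
    if (identical(path, "/__health")) {
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "ok"))
    }
    target <- if (identical(path, "/fetch")) {
      q <- req$QUERY_STRING %||% ""
      utils::URLdecode(sub("^\\??uri=", "", q))
    } else {
      paste0("http://", req$HTTP_HOST %||% "127.0.0.1", path)
    }
    entry <- routes[[target]]
    if (is.null(entry)) {
      return(list(status = 404L, headers = list("Content-Type" = "text/plain"),
                  body = "no route"))
    }
    if (identical(entry$status, "timeout")) {
      Sys.sleep(entry$delay %||% 1.0)
      return(list(status = 200L, headers = list("Content-Type" = "text/plain"),
                  body = "slow response"))
    }
    status <- as.integer(entry$status)
    if (status >= 300L && status < 400L && !is.null(entry$location)) {
      return(list(status = status,
                  headers = list("Content-Type" = "text/plain",
                                 "Location" = entry$location),
                  body = ""))
    }
    list(status = status,
         headers = list("Content-Type" = entry$content_type %||% "text/plain"),
         body = entry$body %||% "")
  })
}

#' Run a fixture server in the current process (blocking)
#'
#' Serves a routing table on 127.0.0.1. Request targets are matched
#' directly by host + path, or explicitly via
#' \code{/fetch?uri=<percent-encoded-target>} for URIs minted under
#' foreign hosts.
#'
#' @param routing a routing table (\code{ecosystem$routing}).
#' @param port TCP port.
#' @return does not return; interrupt to stop.
#' @export
fixture_server_run <- function(routing, port) {
  httpuv::runServer("127.0.0.1", port, fixture_app(routing))
}

#' Serve an ecosystem over local HTTP
#'
#' Starts a background process serving the ecosystem's routing table and
#' waits until it responds.
#'
#' @param eco an \code{ecosystem}.
#' @param port TCP port; a random free port by default.
#' @return a \code{fixture_server} handle: \code{process},
#'   \code{base_url}, \code{port}. Stop it with
#'   \code{\link{stop_ecosystem_server}}.
#' @export
serve_ecosystem <- function(eco, port = NULL) {
  port <- port %||% httpuv::randomPort()
  px <- callr::r_bg(
    function(routing, port) rdfquality::fixture_server_run(routing, port),
    args = list(routing = eco$routing, port = port),
    supervise = TRUE
  )
  base_url <- sprintf("http://127.0.0.1:%d", port)
  deadline <- Sys.time() + 15
  repeat {
    if (!px$is_alive()) {
      stop("fixture server failed to start on port ", port, ": ",
           paste(px$read_all_error_lines(), collapse = "\n"), call. = FALSE)
    }
    ok <- tryCatch({
      h <- curl::new_handle(timeout = 1)
      res <- curl::curl_fetch_memory(paste0(base_url, "/__health"), handle = h)
      res$status_code == 200L
    }, error = function(e) FALSE)
    if (ok) break
    if (Sys.time() > deadline) {
      px$kill()
      stop("fixture server did not become healthy on port ", port, call. = FALSE)
    }
    Sys.sleep(0.05)
  }
  structure(list(process = px, base_url = base_url, port = port),
            class = "fixture_server")
}

#' Stop a fixture server
#' @param server handle from \code{\link{serve_ecosystem}}.
#' @return invisibly TRUE.
#' @export
stop_ecosystem_server <- function(server) {
  if (server$process$is_alive()) server$process$kill()
  invisible(TRUE)
}
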