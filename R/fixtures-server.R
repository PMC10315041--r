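# Ephemeral local HTTP server for fixture pages, so protocol-level
# metrics (redirects, status codes, A1.1) are exercised against a real
# HTTP transport. The server runs in a background R process.

#' Serve fixture pages over local HTTP while running a function
#'
#' Starts an ephemeral HTTP server (background R process) serving the
#' given pages, calls `fn(base_url)` and shuts the server down. Requests
#' to `redirect/<name>` answer 302 to `/<name>`; unknown paths answer 404
#' with an HTML body.
#'
#' @param pages Named character vector: path (without leading slash) to
#'   HTML content.
#' @param fn Function of one argument, the server's base URL
#'   (`http://127.0.0.1:<port>/`).
#' @return The value of `fn`.
#' @export
with_fixture_server <- function(pages, fn) {
  rlang::check_installed(c("callr", "httpuv"))
  dir <- tempfile("fixture-pages-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  for (nm in names(pages)) {
    writeLines(pages[[nm]], file.path(dir, nm), sep = "")
  }
  port <- httpuv::randomPort()
  px <- callr::r_bg(function(dir, port) {
    httpuv::runServer("127.0.0.1", port, list(
      call = function(req) {
        pi <- req$PATH_INFO
        if (is.null(pi)) pi <- "/"
        path <- sub("^/+", "", pi)
        if (grepl("^redirect/", path)) {
          target <- sub("^redirect/", "/", path)
          return(list(
            status = 302L,
            headers = list("Location" = target, "Content-Type" = "text/plain"),
            body = "redirecting"
          ))
        }
        f <- file.path(dir, path)
        if (nzchar(path) && file.exists(f)) {
          list(
            status = 200L,
            headers = list("Content-Type" = "text/html; charset=utf-8"),
            body = paste(readLines(f, warn = FALSE), collapse = "\n")
          )
        } else {
          list(
            status = 404L,
            headers = list("Content-Type" = "text/html; charset=utf-8"),
            body = "<html><body><h1>Not found</h1></body></html>"
          )
        }
      }
    ))
  }, args = list(dir = dir, port = port))
  on.exit(px$kill(), add = TRUE)
  base <- sprintf("http://127.0.0.1:%d/", port)
  up <- FALSE
  for (i in seq_len(200)) {
    up <- tryCatch({
      h <- curl::new_handle(timeout = 1)
      curl::curl_fetch_memory(paste0(base, "__ping__"), handle = h)
      TRUE
    }, error = function(e) FALSE)
    if (up) break
    if (!px$is_alive()) {
      abort("fixture server process died during startup",
        class = "faircheckr_fetch_error"
      )
    }
    Sys.sleep(0.05)
  }
  if (!up) abort("fixture server did not come up", class = "faircheckr_fetch_error")
  fn(base)
}
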