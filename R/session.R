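# Authenticated HTTP context shared by all retrieval functions.
#
# A session bundles a server configuration with the headers that encode the
# chosen authentication method, and a pluggable transport. A transport is a
# function(method, url, headers, body) returning list(status, body) where
# body is the raw response text; the default talks real HTTP through the curl
# package, and mock_transport() routes requests to an in-process synthetic
# store so the whole stack runs offline.

#' Describe a FHIR server and how to authenticate against it
#'
#' @param base_url Server base URL, e.g. `"http://localhost:8080/fhir"`.
#'   Trailing slashes are stripped (normalization is idempotent).
#' @param auth_method One of `"none"`, `"basic"`, `"token"`.
#' @param username,password Credentials for `basic` auth, and for the initial
#'   token exchange under `token` auth. Required (non-empty) unless
#'   `auth_method = "none"`. Prefer passing these from environment variables;
#'   they never belong in config files.
#' @param token A pre-issued bearer token; if supplied under `token` auth no
#'   initial exchange is performed.
#' @param token_endpoint,refresh_endpoint URLs of the token issue/refresh
#'   endpoints. Default to `<base_url>/auth/token` and `<base_url>/auth/refresh`.
#' @param token_refresh_interval Seconds after which a token is proactively
#'   refreshed (default 3600). Tokens are also refreshed reactively on a 401.
#' @param extra_headers Named character vector of additional request headers.
#' @param timeout Per-request timeout in seconds.
#' @param max_retries Retries on transport errors and 5xx responses.
#' @param retry_backoff_base Base of the exponential backoff, in seconds
#'   (first wait `retry_backoff_base`, then doubled each retry).
#' @param verify_tls Verify TLS certificates (default `TRUE`).
#'
#' @return A `fhir_server_config` object.
#' @seealso [create_session()], [read_server_config()]
#' @export
fhir_server_config <- function(base_url,
                               auth_method = c("none", "basic", "token"),
                               username = NULL,
                               password = NULL,
                               token = NULL,
                               token_endpoint = NULL,
                               refresh_endpoint = NULL,
                               token_refresh_interval = 3600,
                               extra_headers = character(0),
                               timeout = 60,
                               max_retries = 3,
                               retry_backoff_base = 1,
                               verify_tls = TRUE) {
  auth_method <- match.arg(auth_method)
  if (!is.character(base_url) || length(base_url) != 1 ||
      !grepl("^https?://[^[:space:]]+$", base_url)) {
    stop_config(sprintf("base_url is not a valid http(s) URL: %s",
                        paste(format(base_url), collapse = " ")))
  }
  base_url <- sub("/+$", "", base_url)
  if (auth_method == "basic" &&
      (!nzchar(username %||% "") || !nzchar(password %||% ""))) {
    stop_config("auth_method 'basic' requires non-empty username and password")
  }
  if (auth_method == "token" && !nzchar(token %||% "") &&
      (!nzchar(username %||% "") || !nzchar(password %||% ""))) {
    stop_config("auth_method 'token' requires a token, or credentials for the token exchange")
  }
  structure(
    list(
      base_url = base_url,
      auth_method = auth_method,
      username = username,
      password = password,
      token = token,
      token_endpoint = token_endpoint %||% paste0(base_url, "/auth/token"),
      refresh_endpoint = refresh_endpoint %||% paste0(base_url, "/auth/refresh"),
      token_refresh_interval = token_refresh_interval,
      extra_headers = extra_headers,
      timeout = timeout,
      max_retries = max_retries,
      retry_backoff_base = retry_backoff_base,
      verify_tls = verify_tls
    ),
    class = "fhir_server_config"
  )
}

#' Read a server configuration file
#'
#' Reads the non-secret half of a [fhir_server_config()] from a YAML file with
#' a `server:` section (`base_url`, `auth_method`, `timeout`, `max_retries`).
#' Credentials are taken from the environment variables `SKIFF_USER`,
#' `SKIFF_PASSWORD` and `SKIFF_TOKEN` — never from the file.
#'
#' @param path Path to the YAML config file.
#' @return A `fhir_server_config`.
#' @export
read_server_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_config("reading config files requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  srv <- cfg$server
  if (is.null(srv$base_url)) stop_config("config file lacks server.base_url")
  fhir_server_config(
    base_url = srv$base_url,
    auth_method = srv$auth_method %||% "none",
    username = Sys.getenv("SKIFF_USER", ""),
    password = Sys.getenv("SKIFF_PASSWORD", ""),
    token = Sys.getenv("SKIFF_TOKEN", ""),
    timeout = srv$timeout %||% 60,
    max_retries = srv$max_retries %||% 3
  )
}

basic_auth_header <- function(username, password) {
  paste("Basic", jsonlite::base64_enc(charToRaw(paste0(username, ":", password))))
}

#' Open an authenticated session against a FHIR server
#'
#' Builds the HTTP context every other retrieval function uses. For `none`
#' and `basic` auth this performs no network call; for `token` auth without a
#' pre-issued token it runs one token exchange against the configured token
#' endpoint.
#'
#' @param config A [fhir_server_config()].
#' @param transport Optional transport function (for in-process mock servers,
#'   see [mock_transport()]); defaults to real HTTP via the curl package.
#' @return A `fhir_session` (mutable environment: token state and request
#'   counters update in place).
#' @examples
#' store <- generate_cohort(cohort_config(n_patients = 3, seed = 1))
#' srv <- mock_fhir_server(store)
#' sess <- create_session(
#'   fhir_server_config("http://mock.local/fhir"),
#'   transport = mock_transport(srv)
#' )
#' bundle <- get_json(sess, "http://mock.local/fhir/Patient")
#' bundle$resourceType
#' @export
create_session <- function(config, transport = NULL) {
  stopifnot(inherits(config, "fhir_server_config"))
  sess <- new.env(parent = emptyenv())
  sess$config <- config
  sess$transport <- transport %||% curl_transport(config)
  sess$token <- config$token
  sess$token_issued_at <- if (nzchar(config$token %||% "")) Sys.time() else NULL
  sess$n_requests <- 0L
  sess$n_retries <- 0L
  class(sess) <- "fhir_session"
  if (config$auth_method == "token" && !nzchar(config$token %||% "")) {
    issue_token(sess)
  }
  sess
}

#' @export
print.fhir_session <- function(x, ...) {
  cat(sprintf("<fhir_session> %s (auth: %s, %d request%s)\n",
              x$config$base_url, x$config$auth_method, x$n_requests,
              if (x$n_requests == 1) "" else "s"))
  invisible(x)
}

session_headers <- function(sess) {
  h <- c(Accept = "application/fhir+json", sess$config$extra_headers)
  h <- switch(sess$config$auth_method,
    none = h,
    basic = c(h, Authorization = basic_auth_header(sess$config$username,
                                                   sess$config$password)),
    token = c(h, Authorization = paste("Bearer", sess$token))
  )
  h
}

# Exchange credentials for a fresh token at the token endpoint.
issue_token <- function(sess) {
  resp <- sess$transport(
    "POST", sess$config$token_endpoint,
    headers = c(Accept = "application/json"),
    body = json_string(list(username = sess$config$username,
                            password = sess$config$password))
  )
  if (resp$status != 200) {
    stop_auth(sprintf("token exchange rejected (status %d)", resp$status),
              status = resp$status)
  }
  tok <- json_parse(resp$body)
  sess$token <- tok$access_token
  sess$token_issued_at <- Sys.time()
  invisible(sess)
}

#' Refresh (or re-acquire) a session's bearer token
#'
#' No-op while the token is younger than `token_refresh_interval` (unless
#' `force = TRUE`). Otherwise tries the refresh endpoint with the current
#' token; if the server rejects the refresh, falls back to a full
#' re-authentication at the token endpoint. Only when both fail is an
#' authentication error raised.
#'
#' @param session A `fhir_session` with `auth_method = "token"`.
#' @param force Refresh even inside the validity window.
#' @return The session, invisibly (modified in place).
#' @export
refresh_token <- function(session, force = FALSE) {
  cfg <- session$config
  if (cfg$auth_method != "token") {
    stop_config("refresh_token() requires auth_method 'token'")
  }
  age <- as.numeric(difftime(Sys.time(), session$token_issued_at %||% Sys.time(),
                             units = "secs"))
  if (!force && !is.null(session$token_issued_at) &&
      age < cfg$token_refresh_interval) {
    return(invisible(session))
  }
  resp <- tryCatch(
    session$transport("POST", cfg$refresh_endpoint,
                      headers = c(Authorization = paste("Bearer", session$token)),
                      body = NULL),
    error = function(e) list(status = 599L, body = conditionMessage(e))
  )
  if (resp$status == 200) {
    tok <- json_parse(resp$body)
    session$token <- tok$access_token
    session$token_issued_at <- Sys.time()
    return(invisible(session))
  }
  # refresh rejected: full reauthentication
  tryCatch(issue_token(session), error = function(e) {
    stop_auth("token refresh and reauthentication both failed")
  })
  invisible(session)
}

#' Perform a GET request and parse the JSON body
#'
#' The HTTP workhorse behind all retrieval functions: retries transport
#' errors and 5xx responses up to `max_retries` times with exponential
#' backoff, proactively refreshes bearer tokens older than the configured
#' interval, and on a 401 refreshes once and replays the request. The body is
#' parsed without vector simplification, so JSON objects arrive as named
#' lists and arrays as unnamed lists.
#'
#' @param session A `fhir_session`.
#' @param url Absolute URL (pagination `next` links are passed verbatim; a
#'   host differing from the session's base URL triggers a warning, not an
#'   error, since FHIR servers commonly return absolute links).
#' @param params Optional parameter multimap appended to the URL.
#' @return The parsed JSON tree.
#' @export
get_json <- function(session, url, params = NULL) {
  cfg <- session$config
  if (!startsWith(url, cfg$base_url) &&
      !startsWith(url, sub("^(https?://[^/]+).*$", "\\1", cfg$base_url))) {
    warning(sprintf("following a link outside the session base URL: %s", url),
            call. = FALSE)
  }
  if (length(params)) {
    sep <- if (grepl("?", url, fixed = TRUE)) "&" else "?"
    url <- paste0(url, sep, encode_params(params))
  }
  if (cfg$auth_method == "token") refresh_token(session)

  refreshed <- FALSE
  attempt <- 0L
  repeat {
    session$n_requests <- session$n_requests + 1L
    resp <- tryCatch(
      session$transport("GET", url, headers = session_headers(session),
                        body = NULL),
      skiff_transport_error = function(e) list(status = 599L,
                                               body = conditionMessage(e))
    )
    if (resp$status == 401 && cfg$auth_method == "token" && !refreshed) {
      refresh_token(session, force = TRUE)
      refreshed <- TRUE
      next
    }
    if (resp$status >= 500 || resp$status == 599) {
      if (attempt < cfg$max_retries) {
        attempt <- attempt + 1L
        session$n_retries <- session$n_retries + 1L
        Sys.sleep(cfg$retry_backoff_base * 2^(attempt - 1L))
        next
      }
      stop_http(sprintf("request failed after %d retries (status %d): %s",
                        cfg$max_retries, resp$status,
                        substr(resp$body %||% "", 1, 200)),
                status = resp$status, body = resp$body)
    }
    if (resp$status >= 400) {
      stop_http(sprintf("HTTP %d for %s: %s", resp$status, url,
                        substr(resp$body %||% "", 1, 200)),
                status = resp$status, body = resp$body)
    }
    return(tryCatch(json_parse(resp$body),
                    error = function(e) {
                      stop_parse(sprintf("response body is not JSON: %s",
                                         conditionMessage(e)))
                    }))
  }
}

# Real-HTTP transport through the curl package. Not exercised by the test
# suite (which runs against the in-process mock) but used for live servers.
curl_transport <- function(config) {
  force(config)
  function(method, url, headers = character(0), body = NULL) {
    if (!requireNamespace("curl", quietly = TRUE)) {
      stop_config("live HTTP requires the 'curl' package; use mock_transport() offline")
    }
    h <- curl::new_handle(timeout = config$timeout,
                          ssl_verifypeer = as.integer(config$verify_tls))
    curl::handle_setheaders(h, .list = as.list(headers))
    if (identical(method, "POST")) {
      curl::handle_setopt(h, post = TRUE,
                          postfields = body %||% "",
                          copypostfields = body %||% "")
    }
    resp <- tryCatch(curl::curl_fetch_memory(url, handle = h),
                     error = function(e) stop_transport(conditionMessage(e)))
    list(status = resp$status_code, body = rawToChar(resp$content))
  }
}
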