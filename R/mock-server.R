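# In-process mock FHIR server.
#
# Serves a fhir_store through the same request/response contract the real
# HTTP transport uses (method, url, headers, body -> status, JSON text), so
# the whole client stack — auth, retries, pagination, _include, _history —
# exercises identical code paths offline. Responses are serialized to JSON
# text and re-parsed by the client, so value types match a network round
# trip exactly.

# Which search parameters the mock understands, per resource type:
# kind "token" matches CodeableConcept codings (or a plain string field),
# "date" supports ge/gt/le/lt/eq prefixes, "ref" matches Reference.reference.
MOCK_SEARCH_PARAMS <- list(
  Patient = list(
    `_id` = list(kind = "token", field = "id"),
    gender = list(kind = "token", field = "gender"),
    birthdate = list(kind = "date", field = "birthDate"),
    identifier = list(kind = "token", field = "identifier")
  ),
  Condition = list(
    `_id` = list(kind = "token", field = "id"),
    code = list(kind = "token", field = "code"),
    subject = list(kind = "ref", field = "subject"),
    patient = list(kind = "ref", field = "subject"),
    `onset-date` = list(kind = "date", field = "onsetDateTime")
  ),
  Observation = list(
    `_id` = list(kind = "token", field = "id"),
    code = list(kind = "token", field = "code"),
    subject = list(kind = "ref", field = "subject"),
    patient = list(kind = "ref", field = "subject"),
    date = list(kind = "date", field = "effectiveDateTime")
  ),
  DiagnosticReport = list(
    `_id` = list(kind = "token", field = "id"),
    code = list(kind = "token", field = "code"),
    subject = list(kind = "ref", field = "subject"),
    patient = list(kind = "ref", field = "subject"),
    date = list(kind = "date", field = "effectiveDateTime")
  ),
  ImagingStudy = list(
    `_id` = list(kind = "token", field = "id"),
    identifier = list(kind = "token", field = "identifier"),
    subject = list(kind = "ref", field = "subject"),
    patient = list(kind = "ref", field = "subject"),
    started = list(kind = "date", field = "started")
  )
)

#' Serve a synthetic store as an in-process FHIR server
#'
#' Implements the slice of the FHIR REST search API the client stack needs:
#' token (`code=C50`, `code=system|code`), date (`ge`/`gt`/`le`/`lt`
#' prefixes, half-open comparisons on calendar dates) and reference
#' parameters, `_count` paging with `next` links, `_include` of referenced
#' Patients, instance-level `_history`, plus a token-auth endpoint pair and
#' scriptable failure modes (flaky 5xx sequences, refresh rejection) for
#' testing retry logic.
#'
#' @param store A `fhir_store` from [generate_cohort()] or [read_store()].
#' @param base_url Base URL the server answers under.
#' @param auth `"none"`, `"basic"` or `"token"`.
#' @param username,password Expected credentials when `auth != "none"`.
#' @param default_count Page size applied when a query sends no `_count`.
#' @param lenient If `TRUE`, unsupported search parameters are ignored
#'   instead of rejected with HTTP 400.
#' @return A `mock_fhir_server` environment; pass it to [mock_transport()].
#' @export
mock_fhir_server <- function(store,
                             base_url = "http://mock.local/fhir",
                             auth = c("none", "basic", "token"),
                             username = "pirate", password = "arrr",
                             default_count = 100L,
                             lenient = FALSE) {
  srv <- new.env(parent = emptyenv())
  srv$store <- store
  srv$base_url <- sub("/+$", "", base_url)
  srv$auth <- match.arg(auth)
  srv$username <- username
  srv$password <- password
  srv$default_count <- default_count
  srv$lenient <- lenient
  srv$token_counter <- 0L
  srv$current_token <- NULL
  srv$reject_refresh <- FALSE
  srv$flaky <- integer(0)   # statuses to emit before succeeding
  srv$log <- list()
  class(srv) <- "mock_fhir_server"
  srv
}

#' @export
print.mock_fhir_server <- function(x, ...) {
  cat(sprintf("<mock_fhir_server> %s (auth: %s, %d requests logged)\n",
              x$base_url, x$auth, length(x$log)))
  invisible(x)
}

#' Script transient server failures
#'
#' The next `length(statuses)` resource requests answer with the given HTTP
#' statuses (e.g. `c(500, 503)`) before the server behaves again; used to
#' test retry/backoff.
#'
#' @param server A [mock_fhir_server()].
#' @param statuses Integer vector of HTTP statuses to emit.
#' @export
mock_set_flaky <- function(server, statuses) {
  server$flaky <- as.integer(statuses)
  invisible(server)
}

#' Retrieve the request log of a mock server
#'
#' @param server A [mock_fhir_server()].
#' @return A tibble with one row per request: `method`, `path`, `query`.
#' @export
mock_request_log <- function(server) {
  tibble::tibble(
    method = vapply(server$log, `[[`, character(1), "method"),
    path = vapply(server$log, `[[`, character(1), "path"),
    query = vapply(server$log, `[[`, character(1), "query")
  )
}

#' Use a mock server as a session transport
#'
#' @param server A [mock_fhir_server()].
#' @return A transport function suitable for [create_session()].
#' @export
mock_transport <- function(server) {
  force(server)
  function(method, url, headers = character(0), body = NULL) {
    mock_handle(server, method, url, headers, body)
  }
}

mock_response <- function(status, payload) {
  list(status = as.integer(status), body = as.character(json_string(payload)))
}

mock_outcome <- function(status, diagnostics) {
  mock_response(status, list(
    resourceType = "OperationOutcome",
    issue = list(list(severity = "error", code = "processing",
                      diagnostics = diagnostics))
  ))
}

mock_handle <- function(srv, method, url, headers = character(0), body = NULL) {
  if (!startsWith(url, srv$base_url)) {
    return(mock_outcome(404, sprintf("unknown host/path: %s", url)))
  }
  rest <- sub("^/", "", substr(url, nchar(srv$base_url) + 1, nchar(url)))
  parts <- split_url(rest)
  path <- parts$path
  params <- decode_query(parts$query)

  # auth endpoints (never flaky, never logged as resource traffic)
  if (identical(method, "POST") && path == "auth/token") {
    creds <- tryCatch(json_parse(body %||% "{}"), error = function(e) list())
    if (!identical(creds$username, srv$username) ||
        !identical(creds$password, srv$password)) {
      return(mock_outcome(401, "invalid credentials"))
    }
    srv$token_counter <- srv$token_counter + 1L
    srv$current_token <- sprintf("tok-%04d", srv$token_counter)
    return(mock_response(200, list(access_token = srv$current_token,
                                   expires_in = 3600)))
  }
  if (identical(method, "POST") && path == "auth/refresh") {
    bearer <- sub("^Bearer ", "", header_get(headers, "Authorization") %||% "")
    if (srv$reject_refresh || !identical(bearer, srv$current_token)) {
      return(mock_outcome(401, "refresh rejected"))
    }
    srv$token_counter <- srv$token_counter + 1L
    srv$current_token <- sprintf("tok-%04d", srv$token_counter)
    return(mock_response(200, list(access_token = srv$current_token,
                                   expires_in = 3600)))
  }

  # authentication check for resource traffic
  auth_header <- header_get(headers, "Authorization") %||% ""
  if (srv$auth == "basic" &&
      !identical(auth_header, basic_auth_header(srv$username, srv$password))) {
    return(mock_outcome(401, "basic authentication required"))
  }
  if (srv$auth == "token" &&
      !identical(sub("^Bearer ", "", auth_header), srv$current_token)) {
    return(mock_outcome(401, "valid bearer token required"))
  }

  srv$log <- c(srv$log, list(list(method = method, path = path,
                                  query = parts$query)))

  if (length(srv$flaky)) {
    status <- srv$flaky[[1]]
    srv$flaky <- srv$flaky[-1]
    if (status != 200) return(mock_outcome(status, "scripted failure"))
  }

  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(segs) == 1 && segs[[1]] %in% names(srv$store$resources) ||
      (length(segs) == 1 && segs[[1]] %in% names(MOCK_SEARCH_PARAMS))) {
    return(mock_search_response(srv, segs[[1]], params))
  }
  if (length(segs) == 2 && identical(segs[[2]], "_history")) {
    return(mock_type_history(srv, segs[[1]], params))
  }
  if (length(segs) == 3 && identical(segs[[3]], "_history")) {
    return(mock_instance_history(srv, segs[[1]], segs[[2]]))
  }
  if (length(segs) == 2) {
    res <- mock_find(srv$store, segs[[1]], segs[[2]])
    if (is.null(res)) return(mock_outcome(404, "resource not found"))
    return(mock_response(200, res))
  }
  mock_outcome(404, sprintf("no route for %s", path))
}

mock_find <- function(store, type, id) {
  for (res in store$resources[[type]]) if (identical(res$id, id)) return(res)
  NULL
}

# --- matching ------------------------------------------------------------

codings_of <- function(field_value) {
  # CodeableConcept, list of CodeableConcepts, or Identifier list
  if (is.null(field_value)) return(list())
  if (is_json_object(field_value)) field_value <- list(field_value)
  out <- list()
  for (item in field_value) {
    if (!is.null(item$coding)) out <- c(out, item$coding)
    else if (!is.null(item$code) || !is.null(item$value)) out <- c(out, list(item))
  }
  out
}

match_token <- function(resource, field, value) {
  fv <- resource[[field]]
  if (is.null(fv)) return(FALSE)
  has_system <- grepl("|", value, fixed = TRUE)
  if (has_system) {
    kv <- strsplit(value, "|", fixed = TRUE)[[1]]
    want_system <- kv[[1]]
    want_code <- if (length(kv) > 1) kv[[2]] else ""
  } else {
    want_system <- NULL
    want_code <- value
  }
  if (is.character(fv)) {
    # plain string field such as gender or id
    return(is.null(want_system) && identical(fv, want_code))
  }
  for (coding in codings_of(fv)) {
    code <- coding$code %||% coding$value
    system <- coding$system
    if (identical(code, want_code) &&
        (is.null(want_system) || identical(system, want_system))) {
      return(TRUE)
    }
  }
  FALSE
}

match_date <- function(resource, field, value) {
  fv <- resource[[field]]
  if (is.null(fv)) return(FALSE)
  prefix <- "eq"
  if (grepl("^(ge|gt|le|lt|eq|ne)", value)) {
    prefix <- substr(value, 1, 2)
    value <- substr(value, 3, nchar(value))
  }
  have <- as_date(fv)
  want <- as_date(value)
  switch(prefix,
         eq = have == want, ne = have != want,
         ge = have >= want, gt = have > want,
         le = have <= want, lt = have < want)
}

match_ref <- function(resource, field, value) {
  ref <- resource[[field]]$reference
  if (is.null(ref)) return(FALSE)
  identical(ref, value) || endsWith(ref, paste0("/", value))
}

mock_matches <- function(srv, type, params) {
  resources <- srv$store$resources[[type]] %||% list()
  defs <- MOCK_SEARCH_PARAMS[[type]] %||% list()
  control <- c("_count", "_page", "_include", "_total", "_sort", "_format")
  for (key in names(params)) {
    if (key %in% control) next  # handled by the caller
    def <- defs[[key]]
    if (is.null(def)) {
      if (srv$lenient) next
      stop_http(sprintf("unsupported search parameter '%s' for %s", key, type),
                status = 400L)
    }
    for (value in params[[key]]) {  # repeated params are ANDed
      matcher <- switch(def$kind, token = match_token, date = match_date,
                        ref = match_ref)
      keep <- vapply(resources, matcher, logical(1),
                     field = def$field, value = value)
      resources <- resources[keep]
    }
  }
  ids <- vapply(resources, function(r) r$id, character(1))
  resources[order(ids)]
}

resolve_includes <- function(srv, matches, include_values) {
  included <- list()
  seen <- character(0)
  for (iv in include_values) {
    segs <- strsplit(iv, ":", fixed = TRUE)[[1]]
    field <- if (length(segs) >= 2) segs[[2]] else iv
    for (res in matches) {
      ref <- res[[field]]$reference
      if (is.null(ref)) next
      if (ref %in% seen) next
      seen <- c(seen, ref)
      rsegs <- strsplit(ref, "/", fixed = TRUE)[[1]]
      target <- mock_find(srv$store, rsegs[[1]], rsegs[[2]])
      if (!is.null(target)) included <- c(included, list(target))
    }
  }
  included
}

bundle_entry <- function(srv, resource, mode) {
  list(
    fullUrl = paste0(srv$base_url, "/", resource$resourceType, "/", resource$id),
    resource = resource,
    search = list(mode = mode)
  )
}

mock_search_response <- function(srv, type, params) {
  matches <- tryCatch(mock_matches(srv, type, params),
                      skiff_http_error = function(e) e)
  if (inherits(matches, "skiff_http_error")) {
    return(mock_outcome(400, conditionMessage(matches)))
  }
  count <- as.integer(params[["_count"]][1] %||% srv$default_count)
  page <- as.integer(params[["_page"]][1] %||% 0L)
  total <- length(matches)
  from <- page * count + 1L
  to <- min(total, from + count - 1L)
  page_matches <- if (from <= to) matches[from:to] else list()

  entries <- lapply(page_matches, bundle_entry, srv = srv, mode = "match")
  if (!is.null(params[["_include"]])) {
    included <- resolve_includes(srv, page_matches, params[["_include"]])
    entries <- c(entries, lapply(included, bundle_entry, srv = srv,
                                 mode = "include"))
  }

  self_params <- params
  self_params[["_page"]] <- as.character(page)
  links <- list(list(relation = "self",
                     url = paste0(srv$base_url, "/", type, "?",
                                  encode_params(self_params))))
  if (to < total) {
    next_params <- params
    next_params[["_page"]] <- as.character(page + 1L)
    links <- c(links, list(list(
      relation = "next",
      url = paste0(srv$base_url, "/", type, "?", encode_params(next_params))
    )))
  }
  bundle <- list(resourceType = "Bundle", type = "searchset", total = total,
                 link = links)
  if (length(entries)) bundle$entry <- entries
  mock_response(200, bundle)
}

mock_versions <- function(store, type, id) {
  key <- paste0(type, "/", id)
  versions <- store$versions[[key]]
  if (is.null(versions)) {
    res <- mock_find(store, type, id)
    if (is.null(res)) return(NULL)
    versions <- list(res)
  }
  rev(versions)  # newest first
}

mock_instance_history <- function(srv, type, id) {
  versions <- mock_versions(srv$store, type, id)
  if (is.null(versions)) return(mock_outcome(404, "resource not found"))
  entries <- lapply(versions, function(res) {
    list(fullUrl = paste0(srv$base_url, "/", type, "/", id), resource = res)
  })
  mock_response(200, list(resourceType = "Bundle", type = "history",
                          total = length(entries), link = list(), entry = entries))
}

mock_type_history <- function(srv, type, params) {
  entries <- list()
  for (res in srv$store$resources[[type]] %||% list()) {
    for (v in mock_versions(srv$store, type, res$id)) {
      entries <- c(entries, list(list(
        fullUrl = paste0(srv$base_url, "/", type, "/", res$id), resource = v
      )))
    }
  }
  mock_response(200, list(resourceType = "Bundle", type = "history",
                          total = length(entries), link = list(), entry = entries))
}

#' Run one search against a store without a server round trip
#'
#' Direct, paged access to the mock search engine: the same matching,
#' `_include` and paging logic [mock_fhir_server()] serves over the
#' transport, exposed for tests and store exploration.
#'
#' @param store A `fhir_store`.
#' @param query A [fhir_search_query()].
#' @param page_token Zero-based page number.
#' @return The Bundle as a parsed JSON tree.
#' @export
mock_search <- function(store, query, page_token = 0L) {
  srv <- mock_fhir_server(store)
  params <- query$request_params
  params[["_count"]] <- as.character(query$page_size)
  params[["_page"]] <- as.character(page_token)
  resp <- mock_search_response(srv, query$resource_type, params)
  if (resp$status != 200) stop_http("mock search failed", status = resp$status,
                                    body = resp$body)
  json_parse(resp$body)
}
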