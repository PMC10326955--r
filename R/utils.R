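# Shared internal helpers: condition constructors, URL plumbing, JSON-tree
# predicates. All JSON is handled as nested R lists (jsonlite,
# simplifyVector = FALSE) so that objects are named lists and arrays are
# unnamed lists, mirroring the JSON data model exactly.

skiff_error <- function(class, message, ...) {
  structure(
    class = c(class, "skiff_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_config <- function(message, ...) stop(skiff_error("skiff_config_error", message, ...))
stop_auth <- function(message, ...) stop(skiff_error("skiff_auth_error", message, ...))
stop_http <- function(message, status = NA_integer_, body = NULL, ...) {
  stop(skiff_error("skiff_http_error", message, status = status, body = body, ...))
}
stop_parse <- function(message, ...) stop(skiff_error("skiff_parse_error", message, ...))
stop_domain <- function(message, ...) stop(skiff_error("skiff_domain_error", message, ...))
stop_key <- function(message, ...) stop(skiff_error("skiff_key_error", message, ...))
stop_notfound <- function(message, ...) stop(skiff_error("skiff_notfound_error", message, ...))
stop_transport <- function(message, ...) stop(skiff_error("skiff_transport_error", message, ...))

is_json_object <- function(x) is.list(x) && !is.null(names(x))
is_json_array <- function(x) is.list(x) && is.null(names(x))

json_parse <- function(txt) jsonlite::fromJSON(txt, simplifyVector = FALSE)
json_string <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Percent-encode one query component (RFC 3986 unreserved characters kept).
url_encode <- function(x) URLencode(as.character(x), reserved = TRUE)

# Serialize a parameter multimap (named list; each element a character vector,
# repeated keys allowed) into a query string with stable order.
encode_params <- function(params) {
  if (length(params) == 0) return("")
  pieces <- character(0)
  for (i in seq_along(params)) {
    key <- names(params)[[i]]
    for (v in params[[i]]) {
      pieces <- c(pieces, paste0(url_encode(key), "=", url_encode(v)))
    }
  }
  paste(pieces, collapse = "&")
}

# Parse a query string back into a multimap (list of character vectors).
decode_query <- function(query) {
  out <- list()
  if (is.null(query) || !nzchar(query)) return(out)
  for (pair in strsplit(query, "&", fixed = TRUE)[[1]]) {
    kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
    key <- URLdecode(kv[[1]])
    val <- if (length(kv) > 1) URLdecode(paste(kv[-1], collapse = "=")) else ""
    out[[key]] <- c(out[[key]], val)
  }
  out
}

split_url <- function(url) {
  q <- regexpr("?", url, fixed = TRUE)
  if (q == -1) list(path = url, query = "") else {
    list(path = substr(url, 1, q - 1), query = substr(url, q + 1, nchar(url)))
  }
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards, so generators are deterministic without
# clobbering user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

as_date <- function(x) as.Date(substr(as.character(x), 1, 10))

# Safe lookup in a named character vector or list of headers.
header_get <- function(headers, name) {
  if (name %in% names(headers)) headers[[name]] else NULL
}

compact <- function(x) x[!vapply(x, is.null, logical(1))]
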