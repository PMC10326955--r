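# Retrieval functions: single paginated search, time-partitioned search,
# per-row constrained search, resource history, and the facades that combine
# retrieval with table building.
#
# n_procs is a partitioning contract, not a worker count: it fixes how work
# is split (e.g. how many time spans a date range becomes) and results are
# guaranteed identical to sequential execution, which is also how the work
# is actually run — a mutable HTTP session (token rotation, retry counters)
# cannot be shared safely across forked R workers.

#' Describe one FHIR search
#'
#' @param resource_type FHIR resource name, e.g. `"Observation"`.
#' @param request_params Parameter multimap: a named list where each element
#'   is a character vector; repeated keys and multi-valued elements are both
#'   serialized as repeated `key=value` pairs, in stable order.
#' @param page_size Sent as `_count`.
#' @param include_history If `TRUE` the query targets the type-level
#'   `_history` endpoint.
#' @return A `fhir_search_query`.
#' @export
fhir_search_query <- function(resource_type, request_params = list(),
                              page_size = 100L, include_history = FALSE) {
  if (!is.character(resource_type) || !nzchar(resource_type)) {
    stop_domain("resource_type must be a non-empty string")
  }
  if (length(request_params) && (is.null(names(request_params)) ||
                                 any(!nzchar(names(request_params))))) {
    stop_domain("request_params must be a fully named list")
  }
  if (page_size < 1) stop_domain("page_size must be positive")
  structure(
    list(resource_type = resource_type,
         request_params = lapply(request_params, as.character),
         page_size = as.integer(page_size),
         include_history = isTRUE(include_history)),
    class = "fhir_search_query"
  )
}

#' @export
print.fhir_search_query <- function(x, ...) {
  cat(sprintf("<fhir_search_query> %s?%s (_count=%d%s)\n", x$resource_type,
              encode_params(x$request_params), x$page_size,
              if (x$include_history) ", history" else ""))
  invisible(x)
}

#' Serialize a search query into a request URL
#'
#' Parameters are percent-encoded and repeated keys appear as repeated
#' pairs; `_count` is appended from the query's page size. Code systems are
#' carried inside token values (`system|code`), so a value such as
#' `"http://loinc.org|16112-5"` arrives encoded but intact.
#'
#' @param session A `fhir_session`.
#' @param query A [fhir_search_query()].
#' @return The URL string.
#' @export
build_search_url <- function(session, query) {
  base <- paste0(session$config$base_url, "/", query$resource_type)
  if (query$include_history) base <- paste0(base, "/_history")
  params <- query$request_params
  params[["_count"]] <- as.character(query$page_size)
  paste0(base, "?", encode_params(params))
}

new_bundle_set <- function(bundles, query, log) {
  structure(list(bundles = bundles, source_query = query, retrieval_log = log),
            class = "fhir_bundle_set")
}

#' @export
print.fhir_bundle_set <- function(x, ...) {
  cat(sprintf("<fhir_bundle_set> %d bundle%s, %d entr%s (%s)\n",
              length(x$bundles), if (length(x$bundles) == 1) "" else "s",
              total_entries(x), if (total_entries(x) == 1) "y" else "ies",
              x$source_query$resource_type))
  invisible(x)
}

#' Count the entries across all bundles of a bundle set
#'
#' @param bundles A `fhir_bundle_set` (or a plain list of Bundles).
#' @return Integer total of per-bundle entry counts.
#' @export
total_entries <- function(bundles) {
  bs <- if (inherits(bundles, "fhir_bundle_set")) bundles$bundles else bundles
  sum(vapply(bs, function(b) length(b$entry), integer(1)))
}

next_link <- function(bundle) {
  for (link in bundle$link %||% list()) {
    if (identical(link$relation, "next")) return(link$url)
  }
  NULL
}

#' Run one search and follow its pagination to the end
#'
#' Issues the query, then follows Bundle links with relation `"next"` until
#' none is left or `max_bundles` pages were fetched. The total entry count
#' is invariant under the page size.
#'
#' @param session A `fhir_session`.
#' @param query A [fhir_search_query()].
#' @param max_bundles Optional page cap.
#' @param on_bundle Optional callback invoked with (bundle, index) right
#'   after each page arrives; an error raised there aborts before the next
#'   page is fetched (the alternate build-while-fetching mode of the
#'   facades).
#' @return A `fhir_bundle_set` in retrieval order.
#' @export
steal_bundles <- function(session, query, max_bundles = Inf,
                          on_bundle = NULL) {
  url <- build_search_url(session, query)
  bundles <- list()
  log <- list()
  while (!is.null(url) && length(bundles) < max_bundles) {
    bundle <- get_json(session, url)
    if (!identical(bundle$resourceType, "Bundle")) {
      stop_parse(sprintf("expected a Bundle, got resourceType '%s'",
                         bundle$resourceType %||% "<none>"))
    }
    bundles <- c(bundles, list(bundle))
    log <- c(log, list(list(url = url, status = 200L,
                            entry_count = length(bundle$entry))))
    if (!is.null(on_bundle)) on_bundle(bundle, length(bundles))
    url <- next_link(bundle)
  }
  new_bundle_set(bundles, query, log)
}

#' Split a date range into contiguous half-open spans
#'
#' Produces `min(n, days)` spans `[a, b)` that partition `[start, end)`:
#' pairwise disjoint, ordered, lengths differing by at most one day with the
#' longer spans first. Half-open boundaries guarantee that a resource dated
#' exactly on an interior boundary lands in exactly one span.
#'
#' @param start,end Dates (`start < end`); `end` is exclusive.
#' @param n Desired number of spans.
#' @return A `time_partition`: list with `spans`, a data.frame of
#'   `start`/`end` Date columns.
#' @examples
#' partition_time_span("2020-01-01", "2020-01-11", 3)$spans
#' @export
partition_time_span <- function(start, end, n) {
  start <- as_date(start); end <- as_date(end)
  if (start >= end) stop_domain("start must be before end")
  if (n < 1) stop_domain("n must be at least 1")
  days <- as.integer(end - start)
  n_spans <- min(as.integer(n), days)
  base <- days %/% n_spans
  rem <- days %% n_spans
  lengths <- base + (seq_len(n_spans) <= rem)
  ends <- start + cumsum(lengths)
  starts <- c(start, head(ends, -1))
  structure(list(spans = data.frame(start = starts, end = ends)),
            class = "time_partition")
}

#' Search a long date range as partitioned sub-queries
#'
#' Splits `[start, end)` into `n_procs` spans ([partition_time_span()]) and
#' runs one sub-query per span, with `date_param=ge<start_i>` and
#' `date_param=lt<end_i>` added to the query. Sub-query results are
#' concatenated in span order; the multiset of returned resources equals the
#' single-query result over the full range. A failing sub-query (after its
#' own transport retries) fails the whole call; partial results are
#' discarded.
#'
#' @param session A `fhir_session`.
#' @param query A [fhir_search_query()]; must not already constrain
#'   `date_param`.
#' @param date_param Date-type search parameter of the resource type (e.g.
#'   `"date"` for Observation).
#' @param start,end Date range, `end` exclusive.
#' @param n_procs Number of spans to partition into (default 1).
#' @return A `fhir_bundle_set`.
#' @export
sail_through_search_space <- function(session, query, date_param, start, end,
                                      n_procs = 1L) {
  partition <- partition_time_span(start, end, n_procs)
  bundles <- list()
  log <- list()
  for (i in seq_len(nrow(partition$spans))) {
    sub <- query
    sub$request_params[[date_param]] <- c(
      paste0("ge", partition$spans$start[[i]]),
      paste0("lt", partition$spans$end[[i]])
    )
    bs <- steal_bundles(session, sub)
    bundles <- c(bundles, bs$bundles)
    log <- c(log, bs$retrieval_log)
  }
  new_bundle_set(bundles, query, log)
}

#' Map table columns to search parameters
#'
#' Declares how each row of a constraint table becomes a search parameter:
#' `row_constraints(subject = "subject")` sends the `subject` column as the
#' `subject` parameter; supplying `list(param = "code", system =
#' "http://loinc.org")` prefixes each cell value with the system
#' (`system|code` token form).
#'
#' @param ... One entry per constrained column: either a parameter name
#'   string or `list(param =, system =)`.
#' @return A `row_constraints` object.
#' @export
row_constraints <- function(...) {
  entries <- list(...)
  if (length(entries) == 0 || is.null(names(entries)) ||
      any(!nzchar(names(entries)))) {
    stop_domain("row_constraints() needs named arguments (column = parameter)")
  }
  entries <- lapply(entries, function(e) {
    if (is.character(e)) list(param = e, system = NULL)
    else list(param = e$param, system = e$system %||% NULL)
  })
  structure(entries, class = "row_constraints")
}

#' Run one constrained sub-query per table row
#'
#' For each row, the base query is extended with one parameter per
#' constraint: value = the row's cell, prefixed `system|` when the
#' constraint names a system. Rows with a missing or empty cell in any
#' constrained column are skipped (reported in the `skipped` attribute, with
#' a message), not errors; transport failures still fail fast.
#'
#' @param session A `fhir_session`.
#' @param table A data.frame whose columns include every constrained column.
#' @param query Base [fhir_search_query()].
#' @param constraints A [row_constraints()].
#' @param n_procs Partitioning contract only; results equal sequential
#'   execution.
#' @return A list with one element per non-skipped row:
#'   `list(row = <index>, bundles = <fhir_bundle_set>)`, in input row order,
#'   with skipped row indices in `attr(, "skipped")`.
#' @export
trade_rows_for_bundles <- function(session, table, query, constraints,
                                   n_procs = 1L) {
  stopifnot(inherits(constraints, "row_constraints"))
  missing_cols <- setdiff(names(constraints), names(table))
  if (length(missing_cols)) {
    stop_key(sprintf("constraint column(s) absent from table: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  out <- list()
  skipped <- integer(0)
  for (i in seq_len(nrow(table))) {
    sub <- query
    skip <- FALSE
    for (col in names(constraints)) {
      cell <- table[[col]][[i]]
      if (is.null(cell) || length(cell) == 0 || is.na(cell) || !nzchar(cell)) {
        skip <- TRUE
        break
      }
      spec <- constraints[[col]]
      value <- if (!is.null(spec$system)) paste0(spec$system, "|", cell)
               else as.character(cell)
      sub$request_params[[spec$param]] <- c(sub$request_params[[spec$param]],
                                            value)
    }
    if (skip) {
      skipped <- c(skipped, i)
      message(sprintf("row %d skipped: missing constraint value", i))
      next
    }
    out <- c(out, list(list(row = i, bundles = steal_bundles(session, sub))))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Fetch the edit history of one resource
#'
#' @param session A `fhir_session`.
#' @param resource_type Resource name.
#' @param resource_id Server-assigned id.
#' @return A `fhir_bundle_set` whose entries are the versions, newest first.
#' @export
request_history <- function(session, resource_type, resource_id) {
  if (!nzchar(resource_id %||% "")) stop_domain("resource_id must be non-empty")
  url <- paste0(session$config$base_url, "/", resource_type, "/",
                resource_id, "/_history")
  bundle <- tryCatch(get_json(session, url),
                     skiff_http_error = function(e) {
                       if (identical(e$status, 404L)) {
                         stop_notfound(sprintf("%s/%s not found",
                                               resource_type, resource_id))
                       }
                       stop(e)
                     })
  query <- fhir_search_query(resource_type, include_history = TRUE)
  new_bundle_set(list(bundle), query,
                 list(list(url = url, status = 200L,
                           entry_count = length(bundle$entry))))
}

# --- facades -------------------------------------------------------------

#' Search and flatten in one call
#'
#' `steal_bundles_to_dataframe()` composes [steal_bundles()] with
#' [bundles_to_table()]; likewise for the sail/trade variants and their
#' retrieval functions. `build` selects when rows are built: `"bulk"`
#' retrieves every page first, `"alternate"` flattens each page as it
#' arrives so an extraction failure stops the run before the next page is
#' fetched.
#'
#' @param session A `fhir_session`.
#' @param query A [fhir_search_query()].
#' @param spec An [extraction_spec()].
#' @param max_bundles Optional page cap.
#' @param build `"bulk"` or `"alternate"`.
#' @param n_procs Partitioning contract only; results equal sequential.
#' @return A tibble (see [bundles_to_table()]).
#' @export
steal_bundles_to_dataframe <- function(session, query, spec,
                                       max_bundles = Inf,
                                       build = c("bulk", "alternate"),
                                       n_procs = 1L) {
  build <- match.arg(build)
  if (build == "bulk") {
    return(bundles_to_table(steal_bundles(session, query, max_bundles), spec,
                            n_procs = n_procs))
  }
  pieces <- list()
  steal_bundles(session, query, max_bundles, on_bundle = function(bundle, i) {
    pieces[[i]] <<- bundle_records(bundle, spec, bundle_index = i)
  })
  records_to_table(do.call(c, pieces %||% list()), spec)
}

#' @rdname steal_bundles_to_dataframe
#' @param date_param,start,end As in [sail_through_search_space()].
#' @export
sail_through_search_space_to_dataframe <- function(session, query, date_param,
                                                   start, end, spec,
                                                   n_procs = 1L,
                                                   build = c("bulk", "alternate")) {
  build <- match.arg(build)
  bs <- sail_through_search_space(session, query, date_param, start, end,
                                  n_procs)
  bundles_to_table(bs, spec)
}

#' @rdname steal_bundles_to_dataframe
#' @param table,constraints As in [trade_rows_for_bundles()].
#' @param with_columns Character vector of input-table columns copied onto
#'   every output row originating from that input row.
#' @export
trade_rows_for_dataframe <- function(session, table, query, constraints, spec,
                                     with_columns = NULL, n_procs = 1L) {
  missing_cols <- setdiff(with_columns, names(table))
  if (length(missing_cols)) {
    stop_key(sprintf("with_columns absent from table: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  results <- trade_rows_for_bundles(session, table, query, constraints,
                                    n_procs)
  pieces <- lapply(results, function(res) {
    part <- bundles_to_table(res$bundles, spec)
    for (col in with_columns) {
      part[[col]] <- rep(table[[col]][[res$row]], length.out = nrow(part))
    }
    part
  })
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  if (length(pieces) == 0) {
    empty <- bundles_to_table(new_bundle_set(list(), query, list()), spec)
    for (col in with_columns) empty[[col]] <- character(0)
    return(empty)
  }
  do.call(rbind, pieces)
}
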