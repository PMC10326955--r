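# Bundle -> table transformation. One row represents one resource (the
# default), with cells driven by FHIRPath expressions, by a full recursive
# dump, or by a user processing function that may emit any record shape.
# Multi-valued path results become list cells, never exploded rows, so the
# one-row-per-resource reading of a table survives repeating elements.

#' Declare how resources become table columns
#'
#' Three modes:
#' * `fhir_paths` (the default when `...` is given): each argument is
#'   `alias = "path"`; cells hold the path's collection (empty → `NA`,
#'   singleton → scalar, several values → list cell).
#' * `full_dump` (`mode = "full_dump"`): every leaf of the resource becomes
#'   a column named by its dotted path with 0-based indices
#'   (`"name.0.family"`).
#' * `processing_function` (`processing_fn` given): the function is called
#'   once per Bundle and returns a data.frame (or list of named-list
#'   records); rows need not correspond to resources.
#'
#' @param ... `alias = "FHIRPath"` pairs for `fhir_paths` mode.
#' @param mode Override the mode explicitly.
#' @param processing_fn A `function(bundle)` for `processing_function` mode.
#' @return An `extraction_spec`.
#' @examples
#' extraction_spec(pid = "id", family = "name.family")
#' @export
extraction_spec <- function(..., mode = NULL, processing_fn = NULL) {
  columns <- list(...)
  if (!is.null(processing_fn)) {
    mode <- "processing_function"
  } else if (is.null(mode)) {
    mode <- "fhir_paths"
  }
  mode <- match.arg(mode, c("fhir_paths", "full_dump", "processing_function"))
  if (mode == "fhir_paths") {
    if (length(columns) == 0) stop_domain("fhir_paths mode needs alias = path pairs")
    if (is.null(names(columns)) || any(!nzchar(names(columns)))) {
      stop_domain("every extraction column needs an alias")
    }
    if (anyDuplicated(names(columns))) stop_domain("aliases must be unique")
    columns <- lapply(columns, function(p) {
      if (inherits(p, "fhirpath")) p else fhirpath_parse(p)
    })
  } else if (length(columns)) {
    stop_domain(sprintf("%s mode takes no column definitions", mode))
  }
  structure(list(columns = columns, mode = mode, processing_fn = processing_fn),
            class = "extraction_spec")
}

# recursive full dump: dotted names, 0-based array indices, leaves as cells
flatten_json <- function(x, prefix = "") {
  if (is_json_object(x)) {
    out <- list()
    for (name in names(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", name) else name
      out <- c(out, flatten_json(x[[name]], key))
    }
    out
  } else if (is_json_array(x)) {
    out <- list()
    for (i in seq_along(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", i - 1L) else
        as.character(i - 1L)
      out <- c(out, flatten_json(x[[i]], key))
    }
    out
  } else {
    setNames(list(x), prefix)
  }
}

#' Flatten one resource into a record
#'
#' @param resource Parsed resource (named list).
#' @param spec An [extraction_spec()] in `fhir_paths` or `full_dump` mode.
#' @return Named list: one element per column; `NA` for an empty
#'   collection, a scalar for a singleton, a list for several values.
#' @export
flatten_resource <- function(resource, spec) {
  stopifnot(inherits(spec, "extraction_spec"))
  if (spec$mode == "full_dump") return(flatten_json(resource))
  if (spec$mode != "fhir_paths") {
    stop_domain("flatten_resource() needs fhir_paths or full_dump mode")
  }
  out <- list()
  for (alias in names(spec$columns)) {
    values <- tryCatch(
      fhirpath_eval(spec$columns[[alias]], resource),
      error = function(e) {
        stop_domain(sprintf("column '%s': %s", alias, conditionMessage(e)))
      }
    )
    out[[alias]] <- if (length(values) == 0) NA
                    else if (length(values) == 1) values[[1]]
                    else values
  }
  out
}

# records for one bundle under any spec mode; attaches provenance fields
bundle_records <- function(bundle, spec, bundle_index = NA_integer_) {
  if (spec$mode == "processing_function") {
    result <- tryCatch(spec$processing_fn(bundle), error = function(e) {
      stop_domain(sprintf("processing_fn failed on bundle %s: %s",
                          bundle_index, conditionMessage(e)))
    })
    if (is.data.frame(result)) {
      result <- lapply(seq_len(nrow(result)), function(i) {
        setNames(lapply(names(result), function(cn) result[[cn]][[i]]),
                 names(result))
      })
    }
    return(lapply(result, function(rec) {
      attr(rec, "provenance") <- list(resource_type = NA_character_,
                                      id = NA_character_)
      rec
    }))
  }
  lapply(bundle$entry %||% list(), function(entry) {
    res <- entry$resource
    rec <- flatten_resource(res, spec)
    attr(rec, "provenance") <- list(
      resource_type = res$resourceType %||% NA_character_,
      id = res$id %||% NA_character_
    )
    rec
  })
}

# assemble records into a tibble: spec columns first, then first-seen order
records_to_table <- function(records, spec) {
  records <- records %||% list()
  lead_cols <- if (spec$mode == "fhir_paths") names(spec$columns) else character(0)
  all_cols <- lead_cols
  for (rec in records) all_cols <- union(all_cols, names(rec))
  columns <- lapply(all_cols, function(cn) {
    lapply(records, function(rec) {
      if (cn %in% names(rec)) rec[[cn]] else NA
    })
  })
  names(columns) <- all_cols
  tbl <- tibble::as_tibble(lapply(columns, simplify_column))
  if (length(records) && ncol(tbl) == 0) tbl <- tibble::tibble(.rows = length(records))
  if (nrow(tbl) == 0 && length(all_cols)) {
    tbl <- tibble::as_tibble(setNames(rep(list(logical(0)), length(all_cols)),
                                      all_cols))
  }
  prov <- lapply(records, function(rec) {
    attr(rec, "provenance") %||% list(resource_type = NA_character_,
                                      id = NA_character_)
  })
  attr(tbl, "provenance") <- tibble::tibble(
    resource_type = vapply(prov, function(p) p$resource_type %||% NA_character_,
                           character(1)),
    id = vapply(prov, function(p) p$id %||% NA_character_, character(1))
  )
  tbl
}

# a column stays a list column unless every cell is a length-1 atomic
simplify_column <- function(cells) {
  simple <- all(vapply(cells, function(v) {
    (is.atomic(v) && length(v) == 1 && !is.list(v)) || is.null(v)
  }, logical(1)))
  if (!simple) return(cells)
  values <- lapply(cells, function(v) if (is.null(v)) NA else v)
  types <- unique(vapply(values, function(v) class(v)[[1]], character(1)))
  types <- setdiff(types, "logical")  # bare NA is logical
  if (length(types) > 1) return(values)
  unlist(values, use.names = FALSE) %||% logical(0)
}

#' Flatten a bundle set into a table
#'
#' Iterates the entries of every bundle in order and builds one row per
#' entry (`fhir_paths` / `full_dump`) or whatever the processing function
#' returns (called once per Bundle). The column set is the union of record
#' keys — spec columns first, then first-seen order — with missing values
#' padded as `NA`. Output is independent of `n_procs`.
#'
#' @param bundles A `fhir_bundle_set` or plain list of Bundles.
#' @param spec An [extraction_spec()].
#' @param n_procs Partitioning contract only; results equal sequential.
#' @return A tibble; per-row resource provenance (type, id) is attached as
#'   the `"provenance"` attribute where available.
#' @export
bundles_to_table <- function(bundles, spec, n_procs = 1L) {
  bs <- if (inherits(bundles, "fhir_bundle_set")) bundles$bundles else bundles
  records <- list()
  for (i in seq_along(bs)) {
    records <- c(records, bundle_records(bs[[i]], spec, bundle_index = i))
  }
  records_to_table(records, spec)
}

#' Merge rows that share a key
#'
#' Rows with the same non-missing value in `key_column` collapse into one
#' row in first-appearance order; rows with a missing key stay unmerged (as
#' singleton groups, interleaved in the same order). In the other columns,
#' non-missing values win over missing ones; genuinely conflicting scalars
#' are collected into an ordered list cell rather than silently dropped, so
#' the merge is lossless and auditable.
#'
#' @param table A data.frame/tibble.
#' @param key_column Column to merge on.
#' @return A tibble.
#' @export
merge_rows <- function(table, key_column) {
  if (!key_column %in% names(table)) {
    stop_key(sprintf("key column '%s' not in table", key_column))
  }
  n <- nrow(table)
  cols <- names(table)
  as_cells <- function(col) {
    v <- table[[col]]
    if (is.list(v)) v else as.list(v)
  }
  cells <- lapply(cols, as_cells)
  names(cells) <- cols
  key_missing <- vapply(cells[[key_column]], function(v) {
    is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v))
  }, logical(1))
  keys <- vapply(seq_len(n), function(i) {
    if (key_missing[[i]]) sprintf(".missing-%d", i)
    else as.character(cells[[key_column]][[i]])
  }, character(1))
  groups <- split(seq_len(n), factor(keys, levels = unique(keys)))
  merged <- lapply(cols, function(col) {
    lapply(groups, function(rows) {
      vals <- cells[[col]][rows]
      vals <- vals[!vapply(vals, function(v) {
        is.null(v) || (is.atomic(v) && length(v) == 1 && is.na(v))
      }, logical(1))]
      uniq <- unique(vals)
      if (length(uniq) == 0) NA
      else if (length(uniq) == 1) uniq[[1]]
      else uniq
    })
  })
  names(merged) <- cols
  tibble::as_tibble(lapply(merged, function(col) {
    simplify_column(unname(col))
  }))
}

#' Write a table as CSV or JSON-lines
#'
#' CSV follows RFC 4180 (UTF-8, quoted fields); list cells are serialized
#' as JSON arrays inside the cell so no information is lost. JSON-lines
#' writes one record object per line.
#'
#' @param table A data.frame/tibble.
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_resource_table <- function(table, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(table)), function(i) {
      rec <- lapply(names(table), function(cn) table[[cn]][[i]])
      names(rec) <- names(table)
      as.character(json_string(rec))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  flat <- as.data.frame(lapply(table, function(col) {
    if (!is.list(col)) return(as.character(col))
    vapply(col, function(v) {
      if (is.null(v) || (is.atomic(v) && length(v) == 1 && is.na(v))) NA_character_
      else if (is.atomic(v) && length(v) == 1) as.character(v)
      else as.character(jsonlite::toJSON(v, auto_unbox = TRUE, digits = NA))
    }, character(1))
  }), check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a constraint table from CSV
#'
#' @param path CSV file (header row; RFC 4180 quoting).
#' @return A tibble of character columns.
#' @export
read_resource_table <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE))
}
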