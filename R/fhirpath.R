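# FHIRPath subset: parser and evaluator.
#
# The subset covers what attribute extraction needs: dotted member access
# with FHIRPath collection semantics (navigating into an array maps over its
# elements and flattens one level), 0-based index selectors `[n]`,
# `where(<member> = '<literal>')`, `exists()`, `empty()`, `first()`,
# `count()`, `replace('a','b')`, `join('sep')`, and an optional leading
# resource-type qualifier (`Patient.id`) that yields empty on other types.
# Everything outside this grammar is rejected at parse time with a position,
# so the boundary of the dialect is explicit.

#' Parse a FHIRPath expression (subset)
#'
#' @param expr Expression string, e.g. `"identifier.where(system =
#'   'urn:x').value"`.
#' @return A `fhirpath` object (list of segments plus the source text).
#'   `format()` renders the canonical form; parsing the canonical form is a
#'   fixpoint.
#' @examples
#' p <- fhirpath_parse("name.given")
#' fhirpath_eval(p, list(resourceType = "Patient",
#'                       name = list(list(given = list("Anna", "B")))))
#' @export
fhirpath_parse <- function(expr) {
  if (!is.character(expr) || length(expr) != 1 || !nzchar(expr)) {
    stop_parse("empty FHIRPath expression")
  }
  segments <- list()
  pos <- 1L
  n <- nchar(expr)
  expect_segment <- TRUE
  while (pos <= n) {
    rest <- substr(expr, pos, n)
    if (!expect_segment) {
      if (!startsWith(rest, ".")) {
        stop_parse(sprintf("expected '.' at position %d in '%s'", pos, expr))
      }
      pos <- pos + 1L
      expect_segment <- TRUE
      next
    }
    m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest)
    if (m == -1) {
      stop_parse(sprintf("expected a name at position %d in '%s'", pos, expr))
    }
    name <- regmatches(rest, m)
    pos <- pos + attr(m, "match.length")
    rest <- substr(expr, pos, n)
    if (startsWith(rest, "(")) {
      parsed <- parse_function(name, expr, pos)
      segments <- c(segments, list(parsed$segment))
      pos <- parsed$pos
    } else {
      segments <- c(segments, list(list(kind = "member", name = name)))
      # optional index selectors
      repeat {
        rest <- substr(expr, pos, n)
        im <- regexpr("^\\[([0-9]+)\\]", rest)
        if (im == -1) break
        idx <- as.integer(gsub("\\[|\\]", "", regmatches(rest, im)))
        segments <- c(segments, list(list(kind = "index", index = idx)))
        pos <- pos + attr(im, "match.length")
      }
    }
    expect_segment <- FALSE
  }
  if (expect_segment) {
    stop_parse(sprintf("empty segment at position %d in '%s'", pos, expr))
  }
  structure(list(segments = segments, source_text = expr), class = "fhirpath")
}

# parse name(...) at `pos` (pos points at the '('); returns segment + new pos
parse_function <- function(name, expr, pos) {
  n <- nchar(expr)
  close <- find_close_paren(expr, pos)
  if (is.na(close)) {
    stop_parse(sprintf("unbalanced '(' at position %d in '%s'", pos, expr))
  }
  args_text <- substr(expr, pos + 1L, close - 1L)
  segment <- switch(
    name,
    exists = , empty = , first = , count = {
      if (nzchar(trimws(args_text))) {
        stop_parse(sprintf("%s() takes no arguments (position %d)", name, pos))
      }
      list(kind = name)
    },
    where = {
      wm <- regexec("^\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*'((?:[^'\\\\]|\\\\.)*)'\\s*$",
                    args_text)
      groups <- regmatches(args_text, wm)[[1]]
      if (length(groups) == 0) {
        stop_parse(sprintf(
          "where() supports only <member> = '<literal>' (position %d)", pos))
      }
      list(kind = "where", member = groups[[2]],
           literal = gsub("\\\\(.)", "\\1", groups[[3]]))
    },
    replace = {
      am <- regexec("^\\s*'((?:[^'\\\\]|\\\\.)*)'\\s*,\\s*'((?:[^'\\\\]|\\\\.)*)'\\s*$",
                    args_text)
      groups <- regmatches(args_text, am)[[1]]
      if (length(groups) == 0) {
        stop_parse(sprintf("replace() needs two string literals (position %d)", pos))
      }
      list(kind = "replace", from = gsub("\\\\(.)", "\\1", groups[[2]]),
           to = gsub("\\\\(.)", "\\1", groups[[3]]))
    },
    join = {
      am <- regexec("^\\s*'((?:[^'\\\\]|\\\\.)*)'\\s*$", args_text)
      groups <- regmatches(args_text, am)[[1]]
      if (length(groups) == 0) {
        stop_parse(sprintf("join() needs one string literal (position %d)", pos))
      }
      list(kind = "join", sep = gsub("\\\\(.)", "\\1", groups[[2]]))
    },
    stop_parse(sprintf("unsupported function '%s' at position %d in '%s'",
                       name, pos, expr))
  )
  list(segment = segment, pos = close + 1L)
}

find_close_paren <- function(expr, open_pos) {
  depth <- 0L
  in_string <- FALSE
  for (i in open_pos:nchar(expr)) {
    ch <- substr(expr, i, i)
    if (in_string) {
      if (ch == "'") in_string <- FALSE
      next
    }
    if (ch == "'") in_string <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  NA_integer_
}

#' @export
format.fhirpath <- function(x, ...) {
  out <- character(0)
  for (seg in x$segments) {
    piece <- switch(seg$kind,
      member = seg$name,
      index = sprintf("[%d]", seg$index),
      exists = "exists()", empty = "empty()", first = "first()",
      count = "count()",
      where = sprintf("where(%s = '%s')", seg$member, seg$literal),
      replace = sprintf("replace('%s','%s')", seg$from, seg$to),
      join = sprintf("join('%s')", seg$sep)
    )
    sep <- if (length(out) == 0 || seg$kind == "index") "" else "."
    out <- c(out, sep, piece)
  }
  paste(out, collapse = "")
}

#' @export
print.fhirpath <- function(x, ...) {
  cat("<fhirpath>", format(x), "\n")
  invisible(x)
}

# navigate one member name from a collection, flattening arrays one level
fp_member <- function(collection, name) {
  out <- list()
  for (item in collection) {
    if (!is_json_object(item)) next
    value <- item[[name]]
    if (is.null(value)) next
    if (is_json_array(value)) out <- c(out, value)
    else out <- c(out, list(value))
  }
  out
}

#' Evaluate a FHIRPath expression on a resource
#'
#' Evaluation is pure and always yields a flat ordered list (the FHIRPath
#' collection). Missing members yield the empty collection, which propagates
#' through navigation; `exists()`, `empty()` and `count()` then yield
#' `FALSE`/`TRUE`/`0` rather than empty. A leading resource-type qualifier
#' (capitalized first segment, e.g. `Patient.birthDate`) yields empty when
#' the resource's `resourceType` differs, which is how mixed `_include`
#' Bundles route attributes per type.
#'
#' @param path A `fhirpath` from [fhirpath_parse()], or an expression string.
#' @param resource A resource as a parsed JSON tree (named list).
#' @return Unnamed list of values (scalars or subtrees).
#' @export
fhirpath_eval <- function(path, resource) {
  if (is.character(path)) path <- fhirpath_parse(path)
  stopifnot(inherits(path, "fhirpath"))
  if (!is_json_object(resource)) {
    stop_domain("fhirpath_eval() needs a resource (a named JSON object)")
  }
  segments <- path$segments
  # leading resource-type qualifier: capitalized member matching no field is
  # routing, a capitalized member that IS a field (rare) still navigates
  if (length(segments) && segments[[1]]$kind == "member" &&
      grepl("^[A-Z]", segments[[1]]$name) &&
      is.null(resource[[segments[[1]]$name]])) {
    if (!identical(resource$resourceType, segments[[1]]$name)) return(list())
    segments <- segments[-1]
  }
  collection <- list(resource)
  for (seg in segments) {
    collection <- switch(seg$kind,
      member = fp_member(collection, seg$name),
      index = {
        if (seg$index < length(collection)) collection[seg$index + 1L]
        else list()
      },
      first = if (length(collection)) collection[1] else list(),
      exists = list(length(collection) > 0),
      empty = list(length(collection) == 0),
      count = list(length(collection)),
      where = {
        keep <- vapply(collection, function(item) {
          vals <- list(item)
          for (m in strsplit(seg$member, ".", fixed = TRUE)[[1]]) {
            vals <- fp_member(vals, m)
          }
          any(vapply(vals, function(v) {
            is.character(v) && identical(v, seg$literal) ||
              is.numeric(v) && !is.na(suppressWarnings(as.numeric(seg$literal))) &&
                isTRUE(v == as.numeric(seg$literal))
          }, logical(1)))
        }, logical(1))
        collection[keep]
      },
      replace = lapply(collection, function(v) {
        if (!is.character(v)) {
          stop_domain(sprintf("replace() applied to a non-string in '%s'",
                              path$source_text))
        }
        gsub(seg$from, seg$to, v, fixed = TRUE)
      }),
      join = {
        if (!all(vapply(collection, is.character, logical(1)))) {
          stop_domain(sprintf("join() applied to non-strings in '%s'",
                              path$source_text))
        }
        if (length(collection) == 0) list()
        else list(paste(unlist(collection), collapse = seg$sep))
      }
    )
  }
  collection
}
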