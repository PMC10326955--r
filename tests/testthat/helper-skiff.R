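# Shared fixtures: mock-backed sessions, hand-built stores with exact dates,
# random JSON resources, and the path-enumeration oracle the FHIRPath engine
# is checked against.

# A session wired to an in-process mock server over `store`.
mock_session <- function(store, auth = "none",
                         base_url = "http://mock.local/fhir", ...) {
  srv <- mock_fhir_server(store, base_url = base_url, auth = auth)
  args <- list(base_url = base_url, auth_method = auth,
               retry_backoff_base = 0, ...)
  if (auth != "none") {
    args$username <- "pirate"
    args$password <- "arrr"
  }
  sess <- create_session(do.call(fhir_server_config, args),
                         transport = mock_transport(srv))
  list(session = sess, server = srv)
}

# Store with one Patient and one Observation per date (ids obs-0001, ...).
obs_store <- function(dates) {
  store <- skiff:::new_store()
  skiff:::store_add(store, list(resourceType = "Patient", id = "pat-001",
                                gender = "female", birthDate = "1970-01-01"))
  for (i in seq_along(dates)) {
    skiff:::store_add(store, list(
      resourceType = "Observation", id = sprintf("obs-%04d", i),
      status = "final",
      code = list(coding = list(list(system = "http://loinc.org",
                                     code = "0000-0"))),
      subject = list(reference = "Patient/pat-001"),
      effectiveDateTime = as.character(dates[[i]])
    ))
  }
  store
}

# Store with n bare Patients.
patient_store <- function(n) {
  store <- skiff:::new_store()
  for (i in seq_len(n)) {
    skiff:::store_add(store, list(resourceType = "Patient",
                                  id = sprintf("pat-%04d", i),
                                  gender = if (i %% 2) "female" else "male"))
  }
  store
}

# All resource ids retrieved by a bundle set.
bundle_ids <- function(bundle_set) {
  unlist(lapply(bundle_set$bundles, function(b) {
    vapply(b$entry %||% list(), function(e) e$resource$id, character(1))
  })) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) as.Date(substr(as.character(x), 1, 10))

# --- random JSON resources and the independent FHIRPath oracle -----------

FIELD_NAMES <- c("alpha", "beta", "gamma", "delta", "value", "name", "item")

random_json <- function(depth = 3) {
  roll <- runif(1)
  if (depth == 0 || roll < 0.35) {
    # scalar leaf
    switch(sample(3, 1),
           paste0("s", sample(100, 1)),
           sample(1000, 1),
           sample(c(TRUE, FALSE), 1))
  } else if (roll < 0.6) {
    # array of objects or of scalars (never array-of-array, as in FHIR)
    if (runif(1) < 0.3) {
      unname(lapply(seq_len(sample(3, 1)),
                    function(i) paste0("v", sample(100, 1))))
    } else {
      unname(lapply(seq_len(sample(3, 1)), function(i) {
        random_object(depth - 1)
      }))
    }
  } else {
    random_object(depth - 1)
  }
}

random_object <- function(depth) {
  fields <- sample(FIELD_NAMES, sample(2:4, 1))
  setNames(lapply(fields, function(f) random_json(depth)), fields)
}

random_resource <- function() {
  res <- random_object(3)
  res$resourceType <- "Synthetic"
  res$id <- paste0("syn-", sample(10000, 1))
  res
}

# Enumerate every scalar leaf of a tree as (dot path without indices, value),
# in document order. This is the oracle's whole machinery: a navigation-only
# FHIRPath over trees without nested arrays selects exactly the leaves whose
# index-stripped path equals the expression, in document order.
enumerate_leaves <- function(node, path = character(0)) {
  if (is.list(node) && !is.null(names(node))) {
    out <- list()
    for (nm in names(node)) {
      out <- c(out, enumerate_leaves(node[[nm]], c(path, nm)))
    }
    out
  } else if (is.list(node)) {
    out <- list()
    for (el in node) out <- c(out, enumerate_leaves(el, path))
    out
  } else {
    list(list(path = paste(path, collapse = "."), value = node))
  }
}

# Oracle: values of all scalar leaves reachable by a member-only path.
oracle_navigate <- function(resource, path) {
  leaves <- enumerate_leaves(resource)
  hits <- Filter(function(l) identical(l$path, path), leaves)
  lapply(hits, function(l) l$value)
}

# Member-only paths whose every occurrence in the tree is a scalar leaf
# (field names can repeat at different depths, so a path may reach both a
# scalar and a subtree; the enumeration oracle is only defined for the pure
# scalar case).
leaf_paths <- function(resource) {
  paths <- unique(vapply(enumerate_leaves(resource), function(l) l$path,
                         character(1)))
  Filter(function(p) !any(startsWith(paths, paste0(p, "."))), paths)
}
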