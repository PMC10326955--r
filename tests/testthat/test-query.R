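# Search URL serialization, pagination, time partitioning, per-row
# constrained queries, history, and the facade functions.

test_that("search URLs serialize params in stable order with _count", {
  ctx <- mock_session(patient_store(1))
  url <- build_search_url(ctx$session,
                          fhir_search_query("Condition", list(code = "C50")))
  expect_equal(url, "http://mock.local/fhir/Condition?code=C50&_count=100")

  url <- build_search_url(ctx$session, fhir_search_query("Patient"))
  expect_equal(url, "http://mock.local/fhir/Patient?_count=100")

  url <- build_search_url(ctx$session, fhir_search_query(
    "Observation", list(date = c("ge2020-01-01", "lt2020-02-01"))))
  expect_equal(url, paste0("http://mock.local/fhir/Observation?",
                           "date=ge2020-01-01&date=lt2020-02-01&_count=100"))

  # token values with a system arrive as an encoded system|code pair
  url <- build_search_url(ctx$session, fhir_search_query(
    "Observation", list(code = "http://loinc.org|16112-5")))
  expect_match(url, "code=http%3A%2F%2Floinc.org%7C16112-5", fixed = TRUE)

  expect_error(fhir_search_query(""), class = "skiff_domain_error")
  expect_error(fhir_search_query("Patient", list("x")),
               class = "skiff_domain_error")
})

test_that("pagination is followed to the end and the entry total is invariant", {
  ctx <- mock_session(patient_store(5))
  bs <- steal_bundles(ctx$session, fhir_search_query("Patient", page_size = 2))
  expect_length(bs$bundles, 3)   # ceil(5 / 2)
  expect_equal(total_entries(bs), 5)

  for (k in c(1, 3, 5, 100)) {
    bs_k <- steal_bundles(ctx$session,
                          fhir_search_query("Patient", page_size = k))
    expect_equal(total_entries(bs_k), 5)
    expect_equal(sort(bundle_ids(bs_k)), sort(bundle_ids(bs)))
  }

  # empty result: one bundle, zero entries
  none <- steal_bundles(ctx$session, fhir_search_query(
    "Patient", list(gender = "other")))
  expect_length(none$bundles, 1)
  expect_equal(total_entries(none), 0)

  # truncation contract
  capped <- steal_bundles(ctx$session,
                          fhir_search_query("Patient", page_size = 2),
                          max_bundles = 1)
  expect_equal(total_entries(capped), 2)
})

test_that("time spans partition the range half-open, longer spans first", {
  p <- partition_time_span("2020-01-01", "2020-01-11", 5)
  expect_equal(nrow(p$spans), 5)
  expect_true(all(as.integer(p$spans$end - p$spans$start) == 2))

  p <- partition_time_span("2020-01-01", "2020-01-11", 3)
  expect_equal(as.integer(p$spans$end - p$spans$start), c(4, 3, 3))

  # n capped at the day count
  p <- partition_time_span("2020-01-01", "2020-01-03", 10)
  expect_equal(nrow(p$spans), 2)

  # disjoint cover of [start, end)
  p <- partition_time_span("2020-03-07", "2020-11-19", 7)
  expect_equal(p$spans$start[[1]], as.Date("2020-03-07"))
  expect_equal(p$spans$end[[nrow(p$spans)]], as.Date("2020-11-19"))
  expect_equal(p$spans$start[-1], p$spans$end[-nrow(p$spans)])

  expect_error(partition_time_span("2020-01-02", "2020-01-01", 2),
               class = "skiff_domain_error")
})

test_that("partitioned search equals the single-range query, boundaries once", {
  dates <- as.Date("2020-01-01") + c(0, 30, 92, 92, 184, 273, 364)
  ctx <- mock_session(obs_store(dates))
  single <- steal_bundles(ctx$session, fhir_search_query(
    "Observation", list(date = c("ge2020-01-01", "lt2021-01-01"))))
  for (n_procs in c(1, 2, 4)) {
    sailed <- sail_through_search_space(
      ctx$session, fhir_search_query("Observation"), "date",
      "2020-01-01", "2021-01-01", n_procs = n_procs)
    expect_equal(sort(bundle_ids(sailed)), sort(bundle_ids(single)))
  }
  # resources dated exactly on interior boundaries appear exactly once:
  # with n = 4 over 2020 (366 days) the spans break at days 92 and 184
  sailed <- sail_through_search_space(
    ctx$session, fhir_search_query("Observation"), "date",
    "2020-01-01", "2021-01-01", n_procs = 4)
  ids <- bundle_ids(sailed)
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(ids, length(dates))
})

test_that("per-row queries constrain on cell values and skip missing cells", {
  store <- generate_cohort(cohort_config(n_patients = 8, seed = 11))
  ctx <- mock_session(store)
  refs <- vapply(store$resources$Patient[1:3],
                 function(p) paste0("Patient/", p$id), character(1))
  table <- tibble::tibble(subject = c(refs[1:2], NA, refs[3]))
  results <- suppressMessages(trade_rows_for_bundles(
    ctx$session, table, fhir_search_query("ImagingStudy"),
    row_constraints(subject = "subject")))
  expect_length(results, 3)
  expect_equal(attr(results, "skipped"), 3L)
  expect_equal(vapply(results, `[[`, integer(1), "row"), c(1L, 2L, 4L))
  # each row's bundles hold only that patient's studies
  for (res in results) {
    refs_seen <- unlist(lapply(res$bundles$bundles, function(b) {
      vapply(b$entry %||% list(),
             function(e) e$resource$subject$reference, character(1))
    }))
    expect_true(all(refs_seen == table$subject[[res$row]]))
  }

  # row-union equivalence against sequential single queries
  sequential <- unlist(lapply(table$subject[c(1, 2, 4)], function(ref) {
    bundle_ids(steal_bundles(ctx$session, fhir_search_query(
      "ImagingStudy", list(subject = ref))))
  }))
  traded <- unlist(lapply(results, function(r) bundle_ids(r$bundles)))
  expect_equal(sort(traded), sort(sequential))

  expect_length(suppressMessages(trade_rows_for_bundles(
    ctx$session, table[0, , drop = FALSE], fhir_search_query("ImagingStudy"),
    row_constraints(subject = "subject"))), 0)
  expect_error(trade_rows_for_bundles(
    ctx$session, table, fhir_search_query("ImagingStudy"),
    row_constraints(nope = "subject")), class = "skiff_key_error")
})

test_that("system-qualified constraints serialize as system|code", {
  ctx <- mock_session(generate_cohort(cohort_config(n_patients = 4, seed = 3)))
  table <- tibble::tibble(loinc = "16112-5")
  suppressMessages(trade_rows_for_bundles(
    ctx$session, table, fhir_search_query("Observation"),
    row_constraints(loinc = list(param = "code",
                                 system = "http://loinc.org"))))
  log <- mock_request_log(ctx$server)
  expect_match(log$query[nrow(log)], "code=http%3A%2F%2Floinc.org%7C16112-5",
               fixed = TRUE)
})

test_that("resource histories arrive newest first", {
  store <- generate_cohort(cohort_config(n_patients = 4, seed = 5))
  ctx <- mock_session(store)
  pid <- store$resources$Patient[[1]]$id

  hist <- request_history(ctx$session, "Patient", pid)
  expect_equal(total_entries(hist), 3)   # planted 3-version history
  versions <- hist$bundles[[1]]$entry
  expect_equal(versions[[1]]$resource$gender,
               store$resources$Patient[[1]]$gender)  # newest first

  # unversioned resource: single current version
  pid2 <- store$resources$Patient[[2]]$id
  expect_equal(total_entries(request_history(ctx$session, "Patient", pid2)), 1)

  expect_error(request_history(ctx$session, "Patient", "no-such-id"),
               class = "skiff_notfound_error")
})

test_that("facades compose retrieval with table building", {
  ctx <- mock_session(patient_store(5))
  tbl <- steal_bundles_to_dataframe(ctx$session,
                                    fhir_search_query("Patient"),
                                    extraction_spec(id = "id"))
  expect_equal(nrow(tbl), 5)
  expect_equal(names(tbl), "id")

  # with_columns propagates source-row values onto every output row
  store <- generate_cohort(cohort_config(n_patients = 6, seed = 2))
  ctx2 <- mock_session(store)
  refs <- vapply(store$resources$Patient[1:2],
                 function(p) paste0("Patient/", p$id), character(1))
  table <- tibble::tibble(subject = refs, icd_code = c("C50", "C78.0"))
  out <- trade_rows_for_dataframe(
    ctx2$session, table, fhir_search_query("ImagingStudy"),
    row_constraints(subject = "subject"),
    extraction_spec(id = "id", patient = "subject.reference"),
    with_columns = "icd_code")
  expect_true("icd_code" %in% names(out))
  for (i in seq_len(nrow(out))) {
    expect_equal(out$icd_code[[i]],
                 table$icd_code[[match(out$patient[[i]], table$subject)]])
  }
})

test_that("alternate build mode stops before fetching the next page", {
  ctx <- mock_session(patient_store(6))
  boom <- function(bundle) stop("schema violation")
  spec <- extraction_spec(processing_fn = function(bundle) {
    if (length(ctx$server$log) >= 2) boom(bundle)
    list(list(id = "x"))
  })
  expect_error(
    steal_bundles_to_dataframe(ctx$session,
                               fhir_search_query("Patient", page_size = 2),
                               spec, build = "alternate"),
    class = "skiff_domain_error")
  # 3 pages exist; the failure on page 2 must prevent the page-3 request
  expect_equal(nrow(mock_request_log(ctx$server)), 2)
})
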