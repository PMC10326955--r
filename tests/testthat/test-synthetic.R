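# Generator determinism and integrity, mock search semantics, store
# persistence, and the end-to-end example pipeline.

store_digest <- function(store) {
  digest_part <- function(x) {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  list(resources = digest_part(store$resources),
       versions = digest_part(store$versions),
       dicom = lapply(store$dicom, function(series) lapply(series, identity)))
}

test_that("identical config and seed give a byte-identical store", {
  a <- generate_cohort(cohort_config(n_patients = 10, seed = 31))
  b <- generate_cohort(cohort_config(n_patients = 10, seed = 31))
  expect_identical(store_digest(a), store_digest(b))
  c <- generate_cohort(cohort_config(n_patients = 10, seed = 32))
  expect_false(identical(store_digest(a)$resources, store_digest(c)$resources))
  # generation leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_cohort(cohort_config(n_patients = 5)))
  expect_identical(runif(3), before)
})

test_that("prevalence drives condition counts; referential integrity holds", {
  cfg <- cohort_config(
    n_patients = 10, seed = 7,
    condition_codes = list(
      list(system = "http://hl7.org/fhir/sid/icd-10", code = "C50",
           prevalence = 1.0),
      list(system = "http://hl7.org/fhir/sid/icd-10", code = "C78.0",
           prevalence = 0.4)
    ))
  store <- generate_cohort(cfg)
  codes <- vapply(store$resources$Condition,
                  function(c) c$code$coding[[1]]$code, character(1))
  expect_equal(sum(codes == "C50"), 10)  # prevalence 1.0 -> every patient
  expect_true(validate_store(store))
  # both-code carriers by direct store enumeration are reproducible
  subj <- vapply(store$resources$Condition,
                 function(c) c$subject$reference, character(1))
  both <- intersect(subj[codes == "C50"], subj[codes == "C78.0"])
  store2 <- generate_cohort(cfg)
  codes2 <- vapply(store2$resources$Condition,
                   function(c) c$code$coding[[1]]$code, character(1))
  subj2 <- vapply(store2$resources$Condition,
                  function(c) c$subject$reference, character(1))
  expect_equal(both, intersect(subj2[codes2 == "C50"],
                               subj2[codes2 == "C78.0"]))
  expect_error(cohort_config(positive_doc_fraction = 1.2),
               class = "skiff_domain_error")
})

test_that("mock search filters tokens, honors half-open dates and _include", {
  store <- generate_cohort(cohort_config(n_patients = 15, seed = 37))
  ctx <- mock_session(store)

  # token with and without system
  codes <- vapply(store$resources$Condition,
                  function(c) c$code$coding[[1]]$code, character(1))
  n_c50 <- sum(codes == "C50")
  for (value in c("C50", "http://hl7.org/fhir/sid/icd-10|C50")) {
    bs <- steal_bundles(ctx$session, fhir_search_query(
      "Condition", list(code = value)))
    expect_equal(total_entries(bs), n_c50)
  }
  # wrong system matches nothing
  expect_equal(total_entries(steal_bundles(ctx$session, fhir_search_query(
    "Condition", list(code = "http://snomed.info/sct|C50")))), 0)

  # half-open date window selects exactly one calendar day
  day <- store$resources$Observation[[1]]$effectiveDateTime
  bs <- steal_bundles(ctx$session, fhir_search_query(
    "Observation", list(date = c(paste0("ge", day), paste0("lt", as_date(day) + 1)))))
  dates <- unlist(lapply(bs$bundles, function(b) {
    vapply(b$entry %||% list(),
           function(e) e$resource$effectiveDateTime, character(1))
  }))
  expect_true(all(dates == day))
  n_that_day <- sum(vapply(store$resources$Observation,
                           function(o) o$effectiveDateTime == day, logical(1)))
  expect_equal(length(dates), n_that_day)

  # _include pulls each referenced patient exactly once
  bs <- steal_bundles(ctx$session, fhir_search_query(
    "ImagingStudy", list(`_include` = "ImagingStudy:subject")))
  modes <- unlist(lapply(bs$bundles, function(b) {
    vapply(b$entry, function(e) e$search$mode, character(1))
  }))
  n_studies <- length(store$resources$ImagingStudy)
  distinct_refs <- unique(vapply(store$resources$ImagingStudy,
                                 function(s) s$subject$reference, character(1)))
  expect_equal(sum(modes == "match"), n_studies)
  expect_equal(sum(modes == "include"), length(distinct_refs))

  # unsupported parameters: 400 strict, ignored lenient
  expect_error(steal_bundles(ctx$session, fhir_search_query(
    "Patient", list(`value-quantity` = "5"))), class = "skiff_http_error")
  lenient <- mock_fhir_server(store, lenient = TRUE)
  sess <- create_session(fhir_server_config("http://mock.local/fhir",
                                            retry_backoff_base = 0),
                         transport = mock_transport(lenient))
  expect_equal(total_entries(steal_bundles(sess, fhir_search_query(
    "Patient", list(`value-quantity` = "5")))), 15)
})

test_that("mock paging is invariant in _count", {
  store <- generate_cohort(cohort_config(n_patients = 12, seed = 41))
  ctx <- mock_session(store)
  reference <- sort(bundle_ids(steal_bundles(
    ctx$session, fhir_search_query("Observation", page_size = 1000))))
  for (k in c(1, 2, 10, 100)) {
    ids <- sort(bundle_ids(steal_bundles(
      ctx$session, fhir_search_query("Observation", page_size = k))))
    expect_equal(ids, reference)
  }
})

test_that("stores round-trip through the on-disk ndjson + dicom layout", {
  store <- generate_cohort(cohort_config(n_patients = 5, seed = 43))
  dir <- withr::local_tempdir()
  write_store(store, dir)
  back <- read_store(dir)
  expect_setequal(names(back$resources), names(store$resources))
  for (type in names(store$resources)) {
    expect_identical(
      jsonlite::toJSON(back$resources[[type]], auto_unbox = TRUE, digits = NA),
      jsonlite::toJSON(store$resources[[type]], auto_unbox = TRUE, digits = NA),
      label = type)
  }
  expect_identical(back$dicom, store$dicom)
})

test_that("the example pipeline matches exhaustive store enumeration", {
  store <- generate_cohort(cohort_config(n_patients = 30, seed = 47))
  ctx <- mock_session(store)
  cohort <- example_results_pipeline(ctx$session)

  codes <- vapply(store$resources$Condition,
                  function(c) c$code$coding[[1]]$code, character(1))
  subj <- vapply(store$resources$Condition,
                 function(c) c$subject$reference, character(1))
  expected <- sort(sub("Patient/", "",
                       intersect(subj[codes == "C50"],
                                 subj[codes == "C78.0"])))
  expect_equal(cohort$patient_id, expected)

  # marker cells obey the ±30-day window exactly, per store enumeration
  for (i in seq_len(nrow(cohort))) {
    anchor <- as_date(cohort$metastasis_date[[i]])
    ref <- paste0("Patient/", cohort$patient_id[[i]])
    er <- Filter(function(o) {
      o$subject$reference == ref &&
        o$code$coding[[1]]$code == "16112-5"
    }, store$resources$Observation)
    in_window <- Filter(function(o) {
      abs(as.integer(as_date(o$effectiveDateTime) - anchor)) <= 30
    }, er)
    if (length(in_window) == 0) {
      expect_true(is.na(cohort$er_status[[i]]))
    } else {
      expect_false(is.na(cohort$er_status[[i]]))
    }
  }
})

test_that("the pipeline is deterministic down to the CSV bytes", {
  run_once <- function() {
    store <- generate_cohort(cohort_config(n_patients = 25, seed = 53))
    ctx <- mock_session(store)
    cohort <- example_results_pipeline(ctx$session)
    path <- tempfile(fileext = ".csv")
    write_resource_table(cohort, path)
    on.exit(unlink(path))
    unname(tools::md5sum(path))
  }
  expect_equal(run_once(), run_once())
})
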