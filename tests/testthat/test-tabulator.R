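# Resource flattening, bundle-set tabulation, merge-on-key consolidation,
# and the table writers.

PATIENT1 <- list(resourceType = "Patient", id = "p1",
                 name = list(list(family = "Smith",
                                  given = list("Anna", "B"))))

test_that("flatten_resource follows the empty/scalar/list cell rule", {
  rec <- flatten_resource(PATIENT1, extraction_spec(pid = "id",
                                                    fam = "name.family"))
  expect_equal(rec, list(pid = "p1", fam = "Smith"))

  rec <- flatten_resource(PATIENT1, extraction_spec(given = "name.given"))
  expect_equal(rec$given, list("Anna", "B"))

  rec <- flatten_resource(PATIENT1, extraction_spec(x = "name.nothing"))
  expect_true(is.na(rec$x))

  dump <- flatten_resource(PATIENT1, extraction_spec(mode = "full_dump"))
  expect_true(all(c("id", "name.0.family", "name.0.given.0",
                    "name.0.given.1") %in% names(dump)))
  expect_equal(dump[["name.0.family"]], "Smith")
})

test_that("row conservation: rows out equal entries in, across page sizes", {
  store <- generate_cohort(cohort_config(n_patients = 9, seed = 4))
  ctx <- mock_session(store)
  n_obs <- length(store$resources$Observation)
  for (k in c(2, 7, 100)) {
    bs <- steal_bundles(ctx$session,
                        fhir_search_query("Observation", page_size = k))
    tbl <- bundles_to_table(bs, extraction_spec(id = "id",
                                                date = "effectiveDateTime"))
    expect_equal(nrow(tbl), n_obs)
    dump <- bundles_to_table(bs, extraction_spec(mode = "full_dump"))
    expect_equal(nrow(dump), n_obs)
  }
  # empty input keeps the spec's columns
  empty <- bundles_to_table(list(), extraction_spec(id = "id"))
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), "id")
})

test_that("full_dump projected onto aliases reproduces fhir_paths mode", {
  store <- generate_cohort(cohort_config(n_patients = 6, seed = 9))
  ctx <- mock_session(store)
  bs <- steal_bundles(ctx$session, fhir_search_query("Condition"))
  paths <- c(id = "id", code = "code.coding.code",
             patient = "subject.reference", onset = "onsetDateTime")
  via_paths <- bundles_to_table(bs, do.call(extraction_spec, as.list(paths)))
  dump <- bundles_to_table(bs, extraction_spec(mode = "full_dump"))
  dump_cols <- c(id = "id", code = "code.coding.0.code",
                 patient = "subject.reference", onset = "onsetDateTime")
  for (alias in names(paths)) {
    expect_equal(dump[[dump_cols[[alias]]]], via_paths[[alias]],
                 label = alias)
  }
})

test_that("processing functions build component columns, one row per resource", {
  store <- generate_cohort(cohort_config(n_patients = 12, seed = 21))
  ctx <- mock_session(store)
  bs <- steal_bundles(ctx$session, fhir_search_query(
    "Observation", list(code = "http://loinc.org|85354-9")))
  n_panels <- total_entries(bs)
  expect_gt(n_panels, 0)

  blood_panel_info <- function(bundle) {
    lapply(bundle$entry, function(entry) {
      res <- entry$resource
      rec <- list(id = res$id)
      for (comp in res$component) {
        display <- comp$code$coding[[1]]$display
        rec[[display]] <- comp$valueQuantity$value
        rec[[paste(display, "unit")]] <- comp$valueQuantity$unit
      }
      rec
    })
  }
  tbl <- bundles_to_table(bs, extraction_spec(processing_fn = blood_panel_info))
  expect_equal(nrow(tbl), n_panels)
  expect_true(all(c("Systolic blood pressure", "Systolic blood pressure unit",
                    "Diastolic blood pressure",
                    "Diastolic blood pressure unit") %in% names(tbl)))
  expect_true(all(tbl[["Systolic blood pressure unit"]] == "mmHg"))
  expect_true(is.numeric(tbl[["Diastolic blood pressure"]]))

  # processing failures are wrapped with the bundle index
  bad <- extraction_spec(processing_fn = function(b) stop("nope"))
  expect_error(bundles_to_table(bs, bad), "bundle 1")
})

test_that("merge_rows combines _include'd patients onto their studies", {
  store <- generate_cohort(cohort_config(n_patients = 10, seed = 6))
  ctx <- mock_session(store)
  bs <- steal_bundles(ctx$session, fhir_search_query(
    "ImagingStudy", list(`_include` = "ImagingStudy:subject")))
  spec <- extraction_spec(
    study_id = "ImagingStudy.id",
    patient_id = "ImagingStudy.subject.reference.replace('Patient/','')",
    gender = "Patient.gender",
    pat_id = "Patient.id"
  )
  tbl <- bundles_to_table(bs, spec)
  tbl$patient_id[is.na(tbl$patient_id)] <- tbl$pat_id[is.na(tbl$patient_id)]
  merged <- merge_rows(tbl[, c("study_id", "patient_id", "gender")],
                       "patient_id")
  n_studies <- length(store$resources$ImagingStudy)
  patients_with_studies <- unique(vapply(
    store$resources$ImagingStudy,
    function(s) sub("Patient/", "", s$subject$reference), character(1)))
  expect_equal(nrow(merged), length(patients_with_studies))
  # every merged row now carries the patient's gender
  expect_false(any(is.na(unlist(merged$gender))))
  # and the study ids survive (possibly as list cells)
  expect_equal(length(unlist(merged$study_id)), n_studies)
})

test_that("merge_rows keeps distinct keys, collects conflicts, leaves NA keys", {
  tbl <- tibble::tibble(k = c("a", "b", NA, "a", NA),
                        x = c("1", NA, "3", "2", "5"),
                        y = c("same", "y2", "y3", "same", NA))
  merged <- merge_rows(tbl, "k")
  # 2 distinct keys + 2 missing-key rows
  expect_equal(nrow(merged), 4)
  row_a <- merged[match("a", merged$k), ]
  expect_equal(sort(unlist(row_a$x)), c("1", "2"))   # conflict -> list cell
  expect_equal(unlist(row_a$y), "same")              # agreeing values collapse
  # all-distinct keys: no-op
  distinct <- tibble::tibble(k = c("a", "b"), v = c("1", "2"))
  expect_equal(as.data.frame(merge_rows(distinct, "k")),
               as.data.frame(distinct))
  expect_error(merge_rows(distinct, "zz"), class = "skiff_key_error")
})

test_that("CSV and JSON-lines writers round-trip, list cells as JSON arrays", {
  tbl <- tibble::tibble(id = c("a", "b"),
                        vals = list(list("x", "y"), "z"),
                        n = c(1L, 2L))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_resource_table(tbl, csv)
  back <- read_resource_table(csv)
  expect_equal(back$id, tbl$id)
  expect_equal(jsonlite::fromJSON(back$vals[[1]]), c("x", "y"))
  expect_equal(back$vals[[2]], "z")

  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  write_resource_table(tbl, jsonl, format = "jsonl")
  lines <- readLines(jsonl)
  expect_length(lines, 2)
  expect_equal(jsonlite::fromJSON(lines[[1]])$vals, c("x", "y"))
})
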