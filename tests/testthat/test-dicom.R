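# Part-10 codec round-trips, on-disk layout, and the download ledger.

test_that("encoded instances round-trip through the decoder", {
  bytes <- dicom_encode("1.2.3.4", "1.2.3", "1.2.3.1", patient_id = "pat-001",
                        instance_number = 7L,
                        pixel_data = as.raw(seq_len(64) - 1))
  parsed <- dicom_decode(bytes)
  expect_equal(skiff:::dicom_tag(parsed, "sop_instance_uid"), "1.2.3.4")
  expect_equal(skiff:::dicom_tag(parsed, "study_uid"), "1.2.3")
  expect_equal(skiff:::dicom_tag(parsed, "series_uid"), "1.2.3.1")
  expect_equal(skiff:::dicom_tag(parsed, "patient_id"), "pat-001")
  expect_equal(skiff:::dicom_tag(parsed, "rows"), 8L)
  expect_equal(skiff:::dicom_tag(parsed, "instance_number"), "7")
  expect_equal(skiff:::dicom_tag(parsed, "pixel_data"),
               as.raw(seq_len(64) - 1))
  expect_error(dicom_decode(as.raw(1:10)), class = "skiff_domain_error")
})

test_that("written files parse as valid DICOM under an independent reader", {
  # pydicom (from the same tool stack) is the independent oracle here
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(dicom_encode("1.2.840.99.1", "1.2.840.99", "1.2.840.99.2",
                        patient_id = "pat-042"), path)
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.SOPInstanceUID, ds.StudyInstanceUID, ds.PatientID,",
    "      ds.Rows, len(ds.PixelData))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(tail(out, 1), "1.2.840.99.1 1.2.840.99 pat-042 8 64")
})

test_that("series resolution honors explicit series and flags unknowns", {
  store <- generate_cohort(cohort_config(n_patients = 6, seed = 23))
  client <- dicomweb_store_client(store)
  study_uid <- names(store$dicom)[[1]]
  all_series <- names(store$dicom[[study_uid]])

  expect_equal(resolve_series(client, study_uid), all_series)
  expect_equal(resolve_series(client, study_uid, all_series[[1]]),
               all_series[[1]])
  expect_error(resolve_series(client, study_uid, "9.9.9"),
               class = "skiff_notfound_error")
  expect_error(resolve_series(client, "9.9.9.9"),
               class = "skiff_notfound_error")
  expect_error(resolve_series(client, "not a uid"),
               class = "skiff_domain_error")
})

test_that("store_series lays out folders, cleans up on failure, idempotent", {
  store <- generate_cohort(cohort_config(n_patients = 6, seed = 23))
  study_uid <- names(store$dicom)[[1]]
  series_uid <- names(store$dicom[[study_uid]])[[1]]
  instances <- store$dicom[[study_uid]][[series_uid]]
  out <- withr::local_tempdir()

  folder <- store_series(instances, out, study_uid, series_uid)
  expect_equal(folder, file.path(out, study_uid, series_uid))
  expect_length(list.files(folder), length(instances))

  flat <- store_series(instances, out, study_uid, series_uid,
                       hierarchical = FALSE, naming = "sequential")
  expect_equal(flat, file.path(out, paste0(study_uid, "_", series_uid)))
  expect_equal(list.files(flat),
               sprintf("%06d.dcm", seq_along(instances)))

  # idempotence: identical final state on re-run
  before <- tools::md5sum(list.files(folder, full.names = TRUE))
  store_series(instances, out, study_uid, series_uid)
  expect_equal(unname(tools::md5sum(list.files(folder, full.names = TRUE))),
               unname(before))

  # zero instances: corrupt, nothing written
  expect_error(store_series(list(), out, study_uid, "9.8.7"),
               class = "skiff_corrupt_error")
  expect_false(dir.exists(file.path(out, study_uid, "9.8.7")))

  # invalid payloads: folder removed, no partial series left
  expect_error(store_series(list(as.raw(1:4)), out, study_uid, "9.8.6"))
  expect_false(dir.exists(file.path(out, study_uid, "9.8.6")))
})

test_that("the ledger partitions resolved series and matches the disk", {
  store <- generate_cohort(cohort_config(n_patients = 8, seed = 29))
  uids <- names(store$dicom)
  # fault one series of the second study with a transport error
  faulted_series <- names(store$dicom[[uids[[2]]]])[[1]]
  client <- dicomweb_store_client(store, faults = setNames(
    "transport", paste0(uids[[2]], "/", faulted_series)))
  table <- tibble::tibble(study_uid = c(uids[[1]], uids[[2]], "9.9.9.9"))
  out <- withr::local_tempdir()

  ledger <- download_data_from_dataframe(client, table, "study_uid",
                                         output_dir = out)
  resolved <- length(store$dicom[[uids[[1]]]]) + length(store$dicom[[uids[[2]]]])
  # bogus study resolves to nothing and fails as a unit
  expect_equal(nrow(ledger$successes) + nrow(ledger$failures), resolved + 1)
  expect_equal(nrow(ledger$failures), 2)
  expect_setequal(ledger$failures$error_category, c("transport", "not_found"))

  # files on disk equal the summed instance counts
  on_disk <- length(list.files(out, pattern = "\\.dcm$", recursive = TRUE))
  expect_equal(on_disk, sum(ledger$successes$instance_count))

  # re-running yields an identical ledger
  ledger2 <- download_data_from_dataframe(client, table, "study_uid",
                                          output_dir = out)
  expect_equal(ledger2$successes, ledger$successes)
  expect_equal(ledger2$failures, ledger$failures)

  # empty input: empty ledger
  empty <- download_data_from_dataframe(
    client, table[0, , drop = FALSE], "study_uid",
    output_dir = withr::local_tempdir())
  expect_equal(nrow(empty$successes), 0)
  expect_equal(nrow(empty$failures), 0)

  # explicit series column restricts the download
  one <- download_data_from_dataframe(
    client,
    tibble::tibble(study_uid = uids[[1]],
                   series_uid = names(store$dicom[[uids[[1]]]])[[1]]),
    "study_uid", series_col = "series_uid",
    output_dir = withr::local_tempdir())
  expect_equal(nrow(one$successes), 1)
})
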