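# End-to-end demonstration pipeline: metastatic-breast-cancer-style cohort
# assembly over a synthetic store. Mirrors the canonical workflow —
# intersect two ICD-10-coded Conditions, attach demographics and survival
# dates, pull LOINC-coded marker Observations and thorax ImagingStudies
# restricted to a ±30-day window around the metastasis diagnosis, and merge
# everything into one row per patient.

#' Assemble the example cohort table
#'
#' Runs the full client stack against a session (normally one backed by
#' [mock_transport()] over a store from [generate_cohort()]):
#'
#' 1. Conditions with ICD-10 `C50` (breast cancer) and `C78.0` (pulmonary
#'    metastases) are retrieved; the cohort is the patients carrying both,
#'    with the metastasis onset date as the anchor.
#' 2. Demographics (gender, birth date, death date) are fetched per patient
#'    with a per-row constrained query.
#' 3. The four marker Observations (LOINC `16112-5` estrogen receptor,
#'    `16113-3` progesterone receptor, `48676-1` HER-2, `21908-9` TNM
#'    stage) are fetched per patient and kept only when dated at most
#'    `window_days` days before or after the metastasis diagnosis; with
#'    several eligible values the one closest to the anchor wins (ties to
#'    the earlier date).
#' 4. ImagingStudies are fetched per patient under the same window; the
#'    matching study UIDs are recorded (the download step is separate, see
#'    [download_data_from_dataframe()]).
#' 5. `survival_days` is the day count from metastasis diagnosis to death
#'    for deceased patients (`event = 1`), otherwise to `study_end`
#'    (`event = 0`).
#'
#' Rows are one per cohort patient, ordered by patient id; patients without
#' eligible markers or imaging keep their row with those cells missing.
#'
#' @param session A `fhir_session`.
#' @param window_days Eligibility window half-width in days (default 30).
#' @param study_end Censoring date for patients alive at the end of the
#'   observation period.
#' @param page_size Page size used for the underlying queries.
#' @return A tibble with one row per cohort patient.
#' @export
example_results_pipeline <- function(session, window_days = 30L,
                                     study_end = "2021-01-01",
                                     page_size = 50L) {
  icd <- ICD10_SYSTEM
  # 1. the two Conditions, patients carrying both
  cond_spec <- extraction_spec(patient = "subject.reference",
                               onset = "onsetDateTime")
  c50 <- steal_bundles_to_dataframe(
    session, fhir_search_query("Condition", list(code = paste0(icd, "|C50")),
                               page_size = page_size), cond_spec)
  c78 <- steal_bundles_to_dataframe(
    session, fhir_search_query("Condition",
                               list(code = paste0(icd, "|C78.0")),
                               page_size = page_size), cond_spec)
  cohort_refs <- sort(intersect(unique(c50$patient), unique(c78$patient)))
  if (length(cohort_refs) == 0) {
    return(tibble::tibble(patient_id = character(0)))
  }
  anchor <- setNames(c78$onset[match(cohort_refs, c78$patient)], cohort_refs)
  cohort <- tibble::tibble(
    patient_id = sub("^Patient/", "", cohort_refs),
    metastasis_date = unname(anchor)
  )

  # 2. demographics
  demo <- trade_rows_for_dataframe(
    session, cohort,
    fhir_search_query("Patient", page_size = page_size),
    row_constraints(patient_id = "_id"),
    extraction_spec(patient_id = "id", gender = "gender",
                    birth_date = "birthDate",
                    deceased = "deceasedDateTime")
  )
  cohort <- merge_rows(rbind_fill(cohort, demo), "patient_id")

  # 3. marker Observations inside the window
  markers <- c(er_status = "16112-5", pr_status = "16113-3",
               her2_status = "48676-1", tnm_stage = "21908-9")
  obs_spec <- extraction_spec(
    patient = "subject.reference", date = "effectiveDateTime",
    coded = "valueCodeableConcept.coding.code", text = "valueString"
  )
  for (col in names(markers)) {
    rows <- trade_rows_for_bundles(
      session, tibble::tibble(subject = paste0("Patient/", cohort$patient_id)),
      fhir_search_query("Observation",
                        list(code = paste0(LOINC_SYSTEM, "|", markers[[col]])),
                        page_size = page_size),
      row_constraints(subject = "subject")
    )
    values <- rep(NA_character_, nrow(cohort))
    for (res in rows) {
      i <- res$row
      tbl <- bundles_to_table(res$bundles, obs_spec)
      if (nrow(tbl) == 0) next
      offset <- abs(as.integer(as_date(tbl$date) -
                                 as_date(cohort$metastasis_date[[i]])))
      eligible <- which(offset <= window_days)
      if (length(eligible) == 0) next
      pick <- eligible[order(offset[eligible], tbl$date[eligible])][1]
      values[[i]] <- as.character(tbl$coded[[pick]] %|NA|% tbl$text[[pick]])
    }
    cohort[[col]] <- values
  }

  # 4. imaging inside the window
  img_rows <- trade_rows_for_bundles(
    session, tibble::tibble(subject = paste0("Patient/", cohort$patient_id)),
    fhir_search_query("ImagingStudy", page_size = page_size),
    row_constraints(subject = "subject")
  )
  img_spec <- extraction_spec(uid = "identifier.value", date = "started",
                              description = "description")
  study_uids <- rep(NA_character_, nrow(cohort))
  n_studies <- integer(nrow(cohort))
  for (res in img_rows) {
    i <- res$row
    tbl <- bundles_to_table(res$bundles, img_spec)
    if (nrow(tbl) == 0) next
    offset <- abs(as.integer(as_date(tbl$date) -
                               as_date(cohort$metastasis_date[[i]])))
    eligible <- which(offset <= window_days &
                        grepl("Thorax", tbl$description))
    n_studies[[i]] <- length(eligible)
    if (length(eligible)) {
      uids <- sub("^urn:oid:", "", unlist(tbl$uid[eligible]))
      study_uids[[i]] <- paste(sort(uids), collapse = ";")
    }
  }
  cohort$thorax_study_uids <- study_uids
  cohort$n_thorax_studies <- n_studies

  # 5. survival columns
  death <- as_date(ifelse(is.na(cohort$deceased), NA, cohort$deceased))
  end <- pmin(death, as_date(study_end), na.rm = TRUE)
  cohort$event <- as.integer(!is.na(death))
  cohort$survival_days <- as.integer(end - as_date(cohort$metastasis_date))
  cohort[order(cohort$patient_id), , drop = FALSE]
}

# first non-missing of two scalars
`%|NA|%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}

# rbind tables with different column sets, padding with NA
rbind_fill <- function(...) {
  tables <- list(...)
  cols <- Reduce(union, lapply(tables, names))
  pieces <- lapply(tables, function(tbl) {
    for (cn in setdiff(cols, names(tbl))) tbl[[cn]] <- NA
    tbl[cols]
  })
  do.call(rbind, pieces)
}
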