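# Deterministic synthetic FHIR resource store.
#
# The generator emulates the structure of a hospital FHIR server at desk
# scale: Patients with demographics and vital status, ICD-10-coded
# Conditions, LOINC-coded marker Observations anchored around a metastasis
# diagnosis date, component-bearing blood-pressure panels, free-text
# DiagnosticReports with planted positive/negative sentences, and
# ImagingStudies backed by a DICOM instance store. The same (config, seed)
# always yields the same store.

ICD10_SYSTEM <- "http://hl7.org/fhir/sid/icd-10"
LOINC_SYSTEM <- "http://loinc.org"
DCM_SYSTEM <- "http://dicom.nema.org/resources/ontology/DCM"
UID_ROOT <- "1.2.826.0.1.3680043.10.1437"

POSITIVE_SENTENCE <- "There is new evidence of sarcoma in the imaged region."
EXCLUSION_SENTENCE <- "Findings are consistent with the known osteosarcoma."
NEGATIVE_SENTENCES <- c(
  "No suspicious lesion is identified.",
  "The lung parenchyma is clear.",
  "No pleural effusion is seen.",
  "Unchanged appearance compared to the prior exam."
)

#' Configure a synthetic cohort
#'
#' Describes the synthetic store that [generate_cohort()] builds. The
#' defaults reproduce a metastatic-breast-cancer-style cohort: ICD-10 `C50`
#' (breast cancer) and `C78.0` (pulmonary metastases) Conditions, and the
#' four LOINC-coded marker Observations — estrogen receptor `16112-5`,
#' progesterone receptor `16113-3`, HER-2 `48676-1` and TNM stage `21908-9` —
#' dated near each metastasis diagnosis so that a ±30-day eligibility window
#' separates usable from unusable markers.
#'
#' @param n_patients Number of Patients.
#' @param seed Integer seed; identical (config, seed) gives a byte-identical
#'   store.
#' @param condition_codes List of `list(system, code, prevalence)` entries;
#'   each patient carries the code with the given probability.
#' @param observation_codes List of `list(system, code, display, kind)`
#'   entries generated per metastasis patient; `kind` is
#'   `"positive_negative"` (valueCodeableConcept POS/NEG) or `"tnm"`
#'   (valueString like `"T2 N1 M0"`).
#' @param date_range Character vector `c(start, end)`; all clinical dates
#'   fall in the half-open interval `[start, end)`.
#' @param studies_per_patient,docs_per_patient Either a fixed integer or
#'   `list(dist = "poisson", lambda = x)`.
#' @param positive_doc_fraction Fraction of documents carrying the planted
#'   positive sentence; half as many again carry the exclusion sentence.
#' @param bp_panel_fraction Fraction of patients with a blood-pressure panel
#'   Observation (systolic/diastolic components).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 50,
                          seed = 1L,
                          condition_codes = list(
                            list(system = ICD10_SYSTEM, code = "C50",
                                 display = "Malignant neoplasm of breast",
                                 prevalence = 0.5),
                            list(system = ICD10_SYSTEM, code = "C78.0",
                                 display = "Secondary malignant neoplasm of lung",
                                 prevalence = 0.4)
                          ),
                          observation_codes = list(
                            list(system = LOINC_SYSTEM, code = "16112-5",
                                 display = "Estrogen receptor Ag [Presence]",
                                 kind = "positive_negative"),
                            list(system = LOINC_SYSTEM, code = "16113-3",
                                 display = "Progesterone receptor Ag [Presence]",
                                 kind = "positive_negative"),
                            list(system = LOINC_SYSTEM, code = "48676-1",
                                 display = "HER2 [Interpretation]",
                                 kind = "positive_negative"),
                            list(system = LOINC_SYSTEM, code = "21908-9",
                                 display = "Stage group.clinical Cancer",
                                 kind = "tnm")
                          ),
                          date_range = c("2020-01-01", "2021-01-01"),
                          studies_per_patient = list(dist = "poisson", lambda = 1),
                          docs_per_patient = list(dist = "poisson", lambda = 1.5),
                          positive_doc_fraction = 0.3,
                          bp_panel_fraction = 0.6) {
  for (cc in condition_codes) {
    if (cc$prevalence < 0 || cc$prevalence > 1) {
      stop_domain(sprintf("prevalence for %s outside [0, 1]", cc$code))
    }
  }
  if (positive_doc_fraction < 0 || positive_doc_fraction > 1) {
    stop_domain("positive_doc_fraction outside [0, 1]")
  }
  structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         condition_codes = condition_codes,
         observation_codes = observation_codes,
         date_range = date_range,
         studies_per_patient = studies_per_patient,
         docs_per_patient = docs_per_patient,
         positive_doc_fraction = positive_doc_fraction,
         bp_panel_fraction = bp_panel_fraction),
    class = "cohort_config"
  )
}

draw_count <- function(spec, n) {
  if (is.numeric(spec)) rep(as.integer(spec), n)
  else if (identical(spec$dist, "poisson")) rpois(n, spec$lambda)
  else stop_domain("unknown count distribution spec")
}

random_dates <- function(n, start, end) {
  # half-open [start, end)
  days <- as.integer(as_date(end) - as_date(start))
  as.character(as_date(start) + sample.int(days, n, replace = TRUE) - 1L)
}

new_store <- function() {
  store <- new.env(parent = emptyenv())
  store$resources <- list()
  store$versions <- list()
  store$dicom <- list()
  class(store) <- "fhir_store"
  store
}

store_add <- function(store, resource) {
  type <- resource$resourceType
  store$resources[[type]] <- c(store$resources[[type]], list(resource))
  invisible(resource)
}

#' @export
print.fhir_store <- function(x, ...) {
  counts <- vapply(x$resources, length, integer(1))
  cat("<fhir_store>\n")
  for (type in names(counts)) cat(sprintf("  %s: %d\n", type, counts[[type]]))
  cat(sprintf("  DICOM studies: %d\n", length(x$dicom)))
  invisible(x)
}

#' Generate a deterministic synthetic FHIR resource store
#'
#' Builds the in-memory store that [mock_fhir_server()] serves. See
#' [cohort_config()] for what is generated. All randomness is drawn from a
#' private RNG stream seeded with `config$seed`, so repeated calls are
#' byte-identical and the caller's RNG state is untouched.
#'
#' @param config A [cohort_config()].
#' @return A `fhir_store` environment with fields `resources` (per-type
#'   lists of JSON-style trees), `versions` (edit histories keyed
#'   `"Type/id"`), and `dicom` (study UID → series UID → raw part-10
#'   instances).
#' @examples
#' store <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' length(store$resources$Patient)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, build_store(config))
}

build_store <- function(config) {
  store <- new_store()
  n <- config$n_patients
  d0 <- config$date_range[[1]]
  d1 <- config$date_range[[2]]
  pat_ids <- sprintf("pat-%03d", seq_len(n))

  # --- Patients -----------------------------------------------------------
  genders <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4))
  birth <- as.character(as_date("1930-01-01") +
                          sample.int(22000, n, replace = TRUE))
  deceased <- runif(n) < 0.25
  death_dates <- random_dates(n, d0, d1)
  for (i in seq_len(n)) {
    pat <- list(
      resourceType = "Patient",
      id = pat_ids[[i]],
      identifier = list(list(system = "urn:skiff:mrn",
                             value = sprintf("MRN-%05d", i))),
      name = list(list(family = sprintf("Family%03d", i),
                       given = list(sprintf("Given%03d", i)))),
      gender = genders[[i]],
      birthDate = birth[[i]]
    )
    if (deceased[[i]]) {
      pat$deceasedDateTime <- paste0(death_dates[[i]], "T00:00:00+00:00")
    }
    store_add(store, pat)
  }

  # --- Conditions ---------------------------------------------------------
  con_n <- 0L
  onset_by_patient <- list()  # patient id -> metastasis onset date
  for (cc in config$condition_codes) {
    carriers <- which(runif(n) < cc$prevalence)
    onsets <- random_dates(length(carriers), d0, d1)
    for (j in seq_along(carriers)) {
      con_n <- con_n + 1L
      i <- carriers[[j]]
      store_add(store, list(
        resourceType = "Condition",
        id = sprintf("con-%04d", con_n),
        code = list(coding = list(list(system = cc$system, code = cc$code,
                                       display = cc$display %||% cc$code))),
        subject = list(reference = paste0("Patient/", pat_ids[[i]])),
        onsetDateTime = onsets[[j]]
      ))
      if (identical(cc$code, "C78.0")) {
        onset_by_patient[[pat_ids[[i]]]] <- onsets[[j]]
      }
    }
  }

  # --- Marker Observations (anchored at metastasis onset ± 45 days) -------
  obs_n <- 0L
  for (pid in names(onset_by_patient)) {
    anchor <- as_date(onset_by_patient[[pid]])
    for (oc in config$observation_codes) {
      obs_n <- obs_n + 1L
      offset <- sample(-45:45, 1)
      obs <- list(
        resourceType = "Observation",
        id = sprintf("obs-%04d", obs_n),
        status = "final",
        code = list(coding = list(list(system = oc$system, code = oc$code,
                                       display = oc$display))),
        subject = list(reference = paste0("Patient/", pid)),
        effectiveDateTime = as.character(anchor + offset)
      )
      if (identical(oc$kind, "tnm")) {
        obs$valueString <- paste0("T", sample(1:4, 1), " N", sample(0:3, 1),
                                  " M", sample(0:1, 1))
      } else {
        pos <- runif(1) < 0.5
        obs$valueCodeableConcept <- list(coding = list(list(
          system = "http://terminology.hl7.org/CodeSystem/v2-0078",
          code = if (pos) "POS" else "NEG",
          display = if (pos) "Positive" else "Negative"
        )))
      }
      store_add(store, obs)
    }
  }

  # --- Blood-pressure panels (component-bearing Observations) -------------
  bp_patients <- which(runif(n) < config$bp_panel_fraction)
  bp_dates <- random_dates(length(bp_patients), d0, d1)
  for (j in seq_along(bp_patients)) {
    obs_n <- obs_n + 1L
    i <- bp_patients[[j]]
    sys_v <- round(runif(1, 95, 180))
    dia_v <- round(runif(1, 55, 110))
    store_add(store, list(
      resourceType = "Observation",
      id = sprintf("obs-%04d", obs_n),
      status = "final",
      code = list(coding = list(list(system = LOINC_SYSTEM, code = "85354-9",
                                     display = "Blood pressure panel"))),
      subject = list(reference = paste0("Patient/", pat_ids[[i]])),
      effectiveDateTime = bp_dates[[j]],
      component = list(
        list(code = list(coding = list(list(system = LOINC_SYSTEM,
                                            code = "8480-6",
                                            display = "Systolic blood pressure"))),
             valueQuantity = list(value = sys_v, unit = "mmHg")),
        list(code = list(coding = list(list(system = LOINC_SYSTEM,
                                            code = "8462-4",
                                            display = "Diastolic blood pressure"))),
             valueQuantity = list(value = dia_v, unit = "mmHg"))
      )
    ))
  }

  # --- DiagnosticReports with planted text --------------------------------
  rep_n <- 0L
  doc_counts <- draw_count(config$docs_per_patient, n)
  for (i in seq_len(n)) {
    if (doc_counts[[i]] == 0) next
    dates <- random_dates(doc_counts[[i]], d0, d1)
    for (k in seq_len(doc_counts[[i]])) {
      rep_n <- rep_n + 1L
      u <- runif(1)
      planted <- if (u < config$positive_doc_fraction) "positive"
                 else if (u < 1.5 * config$positive_doc_fraction) "exclusion"
                 else "negative"
      body <- c(
        sample(NEGATIVE_SENTENCES, 2),
        switch(planted, positive = POSITIVE_SENTENCE,
               exclusion = EXCLUSION_SENTENCE, negative = NULL),
        sample(NEGATIVE_SENTENCES, 1)
      )
      text <- paste0(
        "Report requested by Dr. Smith on ", dates[[k]],
        ". Technique: routine acquisition. Findings: ",
        paste(body, collapse = " "),
        " Impression: see above."
      )
      store_add(store, list(
        resourceType = "DiagnosticReport",
        id = sprintf("rep-%04d", rep_n),
        status = "final",
        code = list(coding = list(list(system = LOINC_SYSTEM, code = "18748-4",
                                       display = "Diagnostic imaging study"))),
        subject = list(reference = paste0("Patient/", pat_ids[[i]])),
        effectiveDateTime = dates[[k]],
        conclusion = text,
        presentedForm = list(list(
          contentType = "text/plain",
          data = jsonlite::base64_enc(charToRaw(text))
        )),
        # generator-side truth, prefixed so it never collides with FHIR fields
        `_planted` = planted
      ))
    }
  }

  # --- ImagingStudies + DICOM instance store ------------------------------
  img_n <- 0L
  study_counts <- draw_count(config$studies_per_patient, n)
  # metastasis patients get one guaranteed thorax CT near the diagnosis
  for (i in seq_len(n)) {
    pid <- pat_ids[[i]]
    extra <- if (!is.null(onset_by_patient[[pid]])) 1L else 0L
    k_studies <- study_counts[[i]] + extra
    if (k_studies == 0) next
    for (s in seq_len(k_studies)) {
      img_n <- img_n + 1L
      anchored <- extra == 1L && s == 1L
      date <- if (anchored) {
        as.character(as_date(onset_by_patient[[pid]]) + sample(-40:40, 1))
      } else {
        random_dates(1, d0, d1)
      }
      add_imaging_study(store, img_n, pid, date,
                        description = if (anchored) "CT Thorax"
                                      else sample(c("CT Abdomen", "CT Thorax",
                                                    "MR Head"), 1))
    }
  }

  # --- Planted edit histories ---------------------------------------------
  if (n >= 1) {
    p1 <- store$resources$Patient[[1]]
    v1 <- p1; v1$gender <- "unknown"
    v2 <- p1; v2$name[[1]]$family <- paste0(p1$name[[1]]$family, "-maiden")
    store$versions[[paste0("Patient/", p1$id)]] <- list(v1, v2, p1)
  }
  if (con_n >= 1) {
    c1 <- store$resources$Condition[[1]]
    v1 <- c1; v1$code$coding[[1]]$display <- "(preliminary)"
    store$versions[[paste0("Condition/", c1$id)]] <- list(v1, c1)
  }

  store$config <- config
  store
}

add_imaging_study <- function(store, img_n, pid, date, description) {
  study_uid <- sprintf("%s.2.%d", UID_ROOT, img_n)
  n_series <- sample(1:3, 1)
  series <- list()
  dicom_series <- list()
  total_instances <- 0L
  modality <- if (grepl("^MR", description)) "MR" else "CT"
  for (se in seq_len(n_series)) {
    series_uid <- sprintf("%s.3.%d.%d", UID_ROOT, img_n, se)
    n_inst <- sample(2:4, 1)
    total_instances <- total_instances + n_inst
    instances <- lapply(seq_len(n_inst), function(k) {
      dicom_encode(
        sop_instance_uid = sprintf("%s.4.%d.%d.%d", UID_ROOT, img_n, se, k),
        study_uid = study_uid, series_uid = series_uid,
        patient_id = pid, patient_name = pid,
        modality = modality, instance_number = k,
        pixel_data = as.raw(sample.int(256, 64, replace = TRUE) - 1L)
      )
    })
    dicom_series[[series_uid]] <- instances
    series <- c(series, list(list(
      uid = series_uid, number = se,
      modality = list(system = DCM_SYSTEM, code = modality),
      numberOfInstances = n_inst
    )))
  }
  store$dicom[[study_uid]] <- dicom_series
  store_add(store, list(
    resourceType = "ImagingStudy",
    id = sprintf("img-%04d", img_n),
    identifier = list(list(system = "urn:dicom:uid",
                           value = paste0("urn:oid:", study_uid))),
    status = "available",
    subject = list(reference = paste0("Patient/", pid)),
    started = date,
    description = description,
    modality = list(list(system = DCM_SYSTEM, code = modality)),
    numberOfSeries = length(series),
    numberOfInstances = total_instances,
    series = series
  ))
}

#' Check referential integrity of a synthetic store
#'
#' Verifies that every Condition/Observation/DiagnosticReport/ImagingStudy
#' references an existing Patient and that every ImagingStudy's DICOM study
#' UID is present in the instance store.
#'
#' @param store A `fhir_store`.
#' @return `TRUE` invisibly; stops with a domain error on the first
#'   violation.
#' @export
validate_store <- function(store) {
  pat_ids <- vapply(store$resources$Patient, function(p) p$id, character(1))
  refs <- paste0("Patient/", pat_ids)
  for (type in c("Condition", "Observation", "DiagnosticReport", "ImagingStudy")) {
    for (res in store$resources[[type]]) {
      if (!(res$subject$reference %in% refs)) {
        stop_domain(sprintf("%s/%s references missing %s",
                            type, res$id, res$subject$reference))
      }
    }
  }
  for (res in store$resources$ImagingStudy) {
    uid <- sub("^urn:oid:", "", res$identifier[[1]]$value)
    if (is.null(store$dicom[[uid]])) {
      stop_domain(sprintf("ImagingStudy/%s has no DICOM study %s", res$id, uid))
    }
  }
  invisible(TRUE)
}

#' Write a store to disk as newline-delimited JSON
#'
#' One `<Type>.ndjson` file per resource type (one resource per line) plus a
#' `dicom/` tree of part-10 files; the layout [read_store()] loads back.
#'
#' @param store A `fhir_store`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (type in names(store$resources)) {
    lines <- vapply(store$resources[[type]],
                    function(r) as.character(json_string(r)), character(1))
    writeLines(lines, file.path(dir, paste0(type, ".ndjson")))
  }
  for (study_uid in names(store$dicom)) {
    for (series_uid in names(store$dicom[[study_uid]])) {
      sdir <- file.path(dir, "dicom", study_uid, series_uid)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      instances <- store$dicom[[study_uid]][[series_uid]]
      for (k in seq_along(instances)) {
        writeBin(instances[[k]],
                 file.path(sdir, sprintf("%06d.dcm", k)))
      }
    }
  }
  invisible(dir)
}

#' Load a store written by [write_store()]
#'
#' @param dir Directory holding `<Type>.ndjson` files and optionally a
#'   `dicom/` tree.
#' @return A `fhir_store`.
#' @export
read_store <- function(dir) {
  store <- new_store()
  for (f in sort(list.files(dir, pattern = "\\.ndjson$", full.names = TRUE))) {
    type <- sub("\\.ndjson$", "", basename(f))
    store$resources[[type]] <- lapply(readLines(f), json_parse)
  }
  ddir <- file.path(dir, "dicom")
  if (dir.exists(ddir)) {
    for (study_uid in list.dirs(ddir, recursive = FALSE, full.names = FALSE)) {
      sdir <- file.path(ddir, study_uid)
      for (series_uid in list.dirs(sdir, recursive = FALSE, full.names = FALSE)) {
        files <- sort(list.files(file.path(sdir, series_uid), full.names = TRUE))
        store$dicom[[study_uid]][[series_uid]] <- lapply(files, function(p) {
          readBin(p, "raw", file.size(p))
        })
      }
    }
  }
  store
}
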