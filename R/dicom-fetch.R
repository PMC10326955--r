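# Bulk retrieval of DICOM series referenced by ImagingStudy resources.
#
# The client object exposes the two DICOMweb verbs the downloader needs —
# QIDO-RS series listing and WADO-RS instance retrieval — as plain R
# functions. dicomweb_store_client() binds them to the synthetic instance
# store (with scriptable per-series faults); the same interface can wrap a
# real endpoint.

#' DICOMweb client over a synthetic store
#'
#' @param store A `fhir_store` whose `dicom` field maps study UID → series
#'   UID → list of raw part-10 instances.
#' @param faults Named character vector scripting failures: names are
#'   `"<study_uid>"` or `"<study_uid>/<series_uid>"`, values the failure
#'   kind (`"transport"` or `"not_found"`).
#' @return A `dicomweb_client`: list of functions `query_series(study_uid)`
#'   and `retrieve_instances(study_uid, series_uid)`.
#' @export
dicomweb_store_client <- function(store, faults = character(0)) {
  force(store); force(faults)
  fault_for <- function(key) {
    if (key %in% names(faults)) faults[[key]] else NULL
  }
  check_fault <- function(study_uid, series_uid = NULL) {
    key <- if (is.null(series_uid)) study_uid
           else paste0(study_uid, "/", series_uid)
    kind <- fault_for(key)
    if (identical(kind, "transport")) {
      stop_transport(sprintf("scripted transport failure for %s", key))
    }
    if (identical(kind, "not_found")) {
      stop_notfound(sprintf("scripted not_found for %s", key))
    }
  }
  structure(list(
    query_series = function(study_uid) {
      check_fault(study_uid)
      series <- store$dicom[[study_uid]]
      if (is.null(series)) {
        stop_notfound(sprintf("study %s not found", study_uid))
      }
      names(series)
    },
    retrieve_instances = function(study_uid, series_uid) {
      check_fault(study_uid)
      check_fault(study_uid, series_uid)
      series <- store$dicom[[study_uid]]
      if (is.null(series)) {
        stop_notfound(sprintf("study %s not found", study_uid))
      }
      instances <- series[[series_uid]]
      if (is.null(instances)) {
        stop_notfound(sprintf("series %s not found in study %s",
                              series_uid, study_uid))
      }
      instances
    }
  ), class = "dicomweb_client")
}

valid_uid <- function(uid) {
  is.character(uid) && length(uid) == 1 && !is.na(uid) &&
    grepl("^[0-9]+(\\.[0-9]+)+$", uid)
}

#' Resolve which series a download request covers
#'
#' With an explicit series UID the request resolves to that series alone
#' (existence verified); without one, to the endpoint's full series listing
#' for the study.
#'
#' @param client A `dicomweb_client`.
#' @param study_uid Study UID (dot-separated numeric components).
#' @param series_uid Optional series UID.
#' @return Character vector of series UIDs.
#' @export
resolve_series <- function(client, study_uid, series_uid = NULL) {
  if (!valid_uid(study_uid)) {
    stop_domain(sprintf("not a DICOM UID: %s", format(study_uid)))
  }
  listing <- client$query_series(study_uid)
  if (is.null(series_uid)) return(listing)
  if (!series_uid %in% listing) {
    stop_notfound(sprintf("series %s not in study %s", series_uid, study_uid))
  }
  series_uid
}

#' Write one series to disk as part-10 files
#'
#' `hierarchical = TRUE` nests `<out>/<study_uid>/<series_uid>/`;
#' `FALSE` uses a flat `<out>/<study_uid>_<series_uid>/` folder. Files are
#' named by SOP instance UID (`naming = "uid"`) or `000001.dcm`-style
#' (`"sequential"`). Writing is idempotent — a re-run overwrites to the
#' identical final state — and a failure removes the partial folder so no
#' half-written series survives.
#'
#' @param instances List of raw part-10 streams.
#' @param output_dir Destination root.
#' @param study_uid,series_uid UIDs naming the folder.
#' @param hierarchical Nested or flat layout.
#' @param naming `"uid"` or `"sequential"`.
#' @return The created folder path (relative to `output_dir`'s parent as
#'   given).
#' @export
store_series <- function(instances, output_dir, study_uid, series_uid,
                         hierarchical = TRUE,
                         naming = c("uid", "sequential")) {
  naming <- match.arg(naming)
  if (length(instances) == 0) {
    stop(skiff_error("skiff_corrupt_error", sprintf(
      "series %s resolved to zero instances", series_uid)))
  }
  folder <- if (hierarchical) {
    file.path(output_dir, study_uid, series_uid)
  } else {
    file.path(output_dir, paste0(study_uid, "_", series_uid))
  }
  if (dir.exists(folder)) unlink(folder, recursive = TRUE)
  ok <- dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  if (!ok && !dir.exists(folder)) {
    stop(skiff_error("skiff_write_error",
                     sprintf("cannot create folder %s", folder)))
  }
  tryCatch({
    for (k in seq_along(instances)) {
      parsed <- dicom_decode(instances[[k]])
      name <- switch(naming,
        uid = paste0(dicom_tag(parsed, "sop_instance_uid"), ".dcm"),
        sequential = sprintf("%06d.dcm", k)
      )
      writeBin(instances[[k]], file.path(folder, name))
    }
  }, error = function(e) {
    unlink(folder, recursive = TRUE)
    if (inherits(e, "skiff_error")) stop(e)
    stop(skiff_error("skiff_write_error", conditionMessage(e)))
  })
  folder
}

#' Download every study/series listed in a table
#'
#' For each row: resolve the request to series ([resolve_series()]),
#' retrieve the instances, and write them ([store_series()]). Per-series
#' failures never abort the run — the point of a bulk download is to finish
#' and report — so the result is a pair of tables: `successes`
#' (`study_uid`, `series_uid`, `folder`, `instance_count`) and `failures`
#' (`study_uid`, `series_uid`, `error_category`, `message`), in input order
#' expanded by series. Every resolved (study, series) pair lands in exactly
#' one of the two.
#'
#' @param client A `dicomweb_client`.
#' @param table Table holding the identifiers.
#' @param study_col Column with StudyInstanceUIDs.
#' @param series_col Optional column with SeriesInstanceUIDs (`NA` cells
#'   mean "whole study").
#' @param output_dir Destination root.
#' @param hierarchical,naming Passed to [store_series()].
#' @param write_ledgers If `TRUE`, writes `successes.csv` / `failures.csv`
#'   next to `output_dir`.
#' @return A `download_ledger`: list of tibbles `successes` and `failures`.
#' @export
download_data_from_dataframe <- function(client, table, study_col,
                                         series_col = NULL, output_dir,
                                         hierarchical = TRUE,
                                         naming = c("uid", "sequential"),
                                         write_ledgers = FALSE) {
  naming <- match.arg(naming)
  if (!study_col %in% names(table)) {
    stop_config(sprintf("study column '%s' not in table", study_col))
  }
  if (!is.null(series_col) && !series_col %in% names(table)) {
    stop_config(sprintf("series column '%s' not in table", series_col))
  }
  successes <- list()
  failures <- list()
  fail <- function(study, series, category, message) {
    failures[[length(failures) + 1L]] <<- tibble::tibble(
      study_uid = study, series_uid = series %||% NA_character_,
      error_category = category, message = message
    )
  }
  error_category <- function(e) {
    if (inherits(e, "skiff_notfound_error")) "not_found"
    else if (inherits(e, "skiff_transport_error")) "transport"
    else if (inherits(e, "skiff_corrupt_error")) "corrupt"
    else "write"
  }
  for (i in seq_len(nrow(table))) {
    study <- as.character(table[[study_col]][[i]])
    series_req <- if (!is.null(series_col)) {
      v <- table[[series_col]][[i]]
      if (is.null(v) || is.na(v) || !nzchar(v)) NULL else as.character(v)
    } else NULL
    series_list <- tryCatch(
      resolve_series(client, study, series_req),
      error = function(e) e
    )
    if (inherits(series_list, "error")) {
      fail(study, series_req, error_category(series_list),
           conditionMessage(series_list))
      next
    }
    for (series in series_list) {
      result <- tryCatch({
        instances <- client$retrieve_instances(study, series)
        folder <- store_series(instances, output_dir, study, series,
                               hierarchical = hierarchical, naming = naming)
        tibble::tibble(study_uid = study, series_uid = series,
                       folder = folder,
                       instance_count = length(instances))
      }, error = function(e) e)
      if (inherits(result, "error")) {
        fail(study, series, error_category(result), conditionMessage(result))
      } else {
        successes[[length(successes) + 1L]] <- result
      }
    }
  }
  empty_success <- tibble::tibble(study_uid = character(0),
                                  series_uid = character(0),
                                  folder = character(0),
                                  instance_count = integer(0))
  empty_failure <- tibble::tibble(study_uid = character(0),
                                  series_uid = character(0),
                                  error_category = character(0),
                                  message = character(0))
  ledger <- structure(list(
    successes = if (length(successes)) do.call(rbind, successes) else empty_success,
    failures = if (length(failures)) do.call(rbind, failures) else empty_failure
  ), class = "download_ledger")
  if (write_ledgers) {
    base <- dirname(output_dir)
    write.csv(ledger$successes, file.path(base, "successes.csv"),
              row.names = FALSE)
    write.csv(ledger$failures, file.path(base, "failures.csv"),
              row.names = FALSE)
  }
  ledger
}

#' @export
print.download_ledger <- function(x, ...) {
  cat(sprintf("<download_ledger> %d succeeded, %d failed\n",
              nrow(x$successes), nrow(x$failures)))
  invisible(x)
}
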