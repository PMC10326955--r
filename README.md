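# skiff

Clinical-research cohorts live on FHIR (Fast Healthcare Interoperability
Resources) servers as deeply nested JSON resources — Patients, Conditions,
Observations, DiagnosticReports, ImagingStudies — while the statistics that
answer research questions want flat tables. skiff is an R toolkit that
bridges the two: it runs authenticated, paginated searches against a FHIR
REST endpoint, flattens the returned Bundles into one-row-per-resource
tables driven by FHIRPath expressions, triages free-text reports with
regular expressions, and bulk-downloads the DICOM series behind
ImagingStudy resources from a DICOMweb endpoint. It is aimed at
researchers and data scientists assembling study cohorts from hospital
EHR/FHIR infrastructure.

Everything is testable offline: the package ships a deterministic
synthetic cohort generator and an in-process mock FHIR/DICOMweb server
with realistic search semantics (token `system|code` parameters, `ge`/`lt`
date prefixes, reference parameters, `_count` paging with `next` links,
`_include`, `_history`).

## The model

A search is a pair (resource type, parameter multimap) serialized to the
FHIR REST form `base/{Type}?key=value&...&_count=n`; the server answers
with Bundle pages chained by `next` links. Three retrieval strategies
cover cohort work:

- **single query** (`steal_bundles`) — one search, pagination followed to
  the end;
- **time-partitioned query** (`sail_through_search_space`) — a date range
  `[start, end)` split into half-open spans `[a_i, b_i)` whose lengths
  differ by at most one day, one sub-query per span
  (`date=ge a_i&date=lt b_i`); half-open boundaries guarantee each
  resource is returned exactly once;
- **per-row constrained query** (`trade_rows_for_bundles`) — one sub-query
  per row of a constraint table, each cell becoming a search parameter
  value (optionally prefixed `system|`).

Flattening evaluates a documented FHIRPath subset (member navigation with
collection semantics, `[n]` indexing, `where(field = 'literal')`,
`exists()`, `empty()`, `first()`, `count()`, `replace()`, `join()`)
against each resource; empty collections become `NA`, singletons scalars,
multi-valued results list cells. `merge_rows` consolidates rows sharing a
key (e.g. `_include`d Patients onto their ImagingStudies), collecting
genuine conflicts into list cells rather than dropping them.

Document triage segments text into sentences (rule-based, deterministic,
with an abbreviation exception list), then keeps sentences matching a main
regular expression and not matching an optional exclusion expression —
search `sarcoma` while excluding `osteosarcoma`.

## Worked example

```r
library(skiff)

store   <- generate_cohort(cohort_config(n_patients = 30, seed = 47))
server  <- mock_fhir_server(store)
session <- create_session(fhir_server_config("http://mock.local/fhir"),
                          transport = mock_transport(server))

# estrogen-receptor Observations (LOINC 16112-5), flattened by FHIRPath
obs <- steal_bundles_to_dataframe(
  session,
  fhir_search_query("Observation", list(code = "http://loinc.org|16112-5")),
  extraction_spec(id = "id", patient = "subject.reference",
                  date = "effectiveDateTime",
                  result = "valueCodeableConcept.coding.code"))
head(obs, 3)
#> # A tibble: 3 × 4
#>   id       patient         date       result
#>   <chr>    <chr>           <chr>      <chr>
#> 1 obs-0001 Patient/pat-002 2020-02-01 POS
#> 2 obs-0005 Patient/pat-007 2020-11-21 NEG
#> 3 obs-0009 Patient/pat-009 2020-11-30 POS
```

The end-to-end pipeline intersects patients carrying both ICD-10 `C50`
(breast cancer) and `C78.0` (pulmonary metastases), attaches demographics,
keeps the four LOINC marker Observations dated within ±30 days of the
metastasis diagnosis, records thorax CT studies under the same window, and
derives survival columns (days from diagnosis to death, or to the study
end with `event = 0`):

```r
cohort <- example_results_pipeline(session)
cohort[, c("patient_id", "metastasis_date", "er_status", "tnm_stage",
           "event", "survival_days")]
#> # A tibble: 1 × 6
#>   patient_id metastasis_date er_status tnm_stage event survival_days
#>   <chr>      <chr>           <chr>     <chr>     <int>         <int>
#> 1 pat-009    2020-11-19      POS       T4 N1 M1      0            43
```

With this seed exactly one of the 30 synthetic patients carries both
diagnoses; their ER marker (positive) and TNM stage fell inside the
window, and the patient was alive at the study end 43 days after the
diagnosis.

Document triage on one report:

```r
cfg <- miner_config("sarcoma", exclusion_pattern = "osteosarcoma",
                    header_keyword = "Findings")
mine_text("Technique: CT. Findings: New evidence of sarcoma. Known osteosarcoma unchanged.",
          cfg)
#> $matched
#> [1] TRUE
#> $matching_sentences
#> [1] "Findings: New evidence of sarcoma."
#> $match_count
#> [1] 1
#> $excluded_count
#> [1] 1
```

The header before `Findings` was discarded, the sarcoma sentence matched,
and the osteosarcoma sentence was excluded and counted.

A command-line wrapper for the query/mine/download/fixtures workflows is
installed under `inst/cli/skiff.R`.

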