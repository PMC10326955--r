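---
title: "Cohort extraction from FHIR servers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort extraction from FHIR servers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiff)
```

## The problem

Hospital FHIR servers expose clinical data as nested JSON resources behind
a REST search API. Building a study cohort means running many searches
(diagnoses, lab values, imaging metadata, documents), walking paginated
Bundle responses, and reshaping arbitrarily nested resources into the flat
tables statistical work expects. skiff packages that workflow: an
authenticated session layer, three retrieval strategies, a FHIRPath-driven
tabulator, a regular-expression document miner, and a DICOMweb bulk
downloader — all runnable offline against a deterministic synthetic store.

## Session layer

A `fhir_server_config()` fixes the server base URL, the authentication
method (`none`, `basic`, or bearer `token`), timeouts, and the retry
policy. Defaults: timeout 60 s, `max_retries = 3`, exponential backoff
with base 1 s (1, 2, 4 s), TLS verification on. These are deliberately
conservative client-side defaults for shared hospital infrastructure; all
are per-config tunable.

Token lifecycle. Two complementary triggers refresh a bearer token:
proactively once its age exceeds `token_refresh_interval` (default 3600 s),
and reactively when a request answers 401 — covering both client-side and
server-side expiry without assuming either. A rejected refresh falls back
to a full re-authentication at the token endpoint; only when both fail
does the session raise an authentication error. The token endpoint
contract (POST `auth/token` with credentials, POST `auth/refresh` with the
current bearer) is the one the bundled mock server implements; real
deployments vary, which is why both endpoints are configurable.

Transports are pluggable functions `(method, url, headers, body) →
(status, body text)`. The mock transport serializes responses to JSON text
and the client re-parses them, so offline tests exercise byte-identical
code paths to live HTTP (which goes through the curl package).

## Retrieval strategies

`steal_bundles()` runs one search and follows `next` links until
exhaustion; the total entry count is invariant under the page size
(`_count`), which the test suite checks for page sizes 1–100 over stores
of 0–250 resources.

`sail_through_search_space()` splits a date range into `n_procs` spans.
Spans are half-open `[a, b)` with `date=ge a` and `date=lt b`: a resource
dated exactly on an interior boundary belongs to exactly one span, so the
union over spans equals the single-range query with neither duplicates nor
gaps. Span lengths differ by at most one day with remainder days assigned
to the earliest spans — a deterministic rule independent of how the
remainder happens to divide.

`trade_rows_for_bundles()` issues one sub-query per row of a constraint
table; `row_constraints()` maps columns to parameter names, optionally
prefixing values with a code system (`system|code`). Rows with missing
constraint cells are skipped and reported rather than raised: a bulk
cohort run should not die on one incomplete row, while transport errors
still fail fast because they indicate a broken run, not broken data.

**Concurrency as a contract.** `n_procs` fixes how work is partitioned
(e.g. the number of date spans) and the package guarantees results
identical to sequential execution. Execution itself is sequential: a
mutable session (rotating tokens, retry counters) and the in-process mock
(request log, scripted fault sequences) cannot be shared safely across
forked R workers, and the guarantee that matters scientifically — same
output for any `n_procs` — is exactly what the tests pin down. A parallel
worker model could be substituted behind the same interface without
changing any result.

The facades (`steal_bundles_to_dataframe()` and relatives) compose
retrieval with tabulation. The `alternate` build mode flattens each page
as it arrives, so an extraction error aborts before the next page is
fetched — useful when a schema mismatch should stop a long run early; the
default `bulk` mode retrieves everything first.

## FHIRPath subset

The tabulator needs attribute access, not a full expression language, so
the parser accepts exactly: member navigation, `[n]` indexing (0-based,
applied to the collection), `where(member = 'literal')`, `exists()`,
`empty()`, `first()`, `count()`, `replace('a','b')`, `join('sep')`, and a
leading resource-type qualifier (`Patient.birthDate`) that yields empty on
other types — which is how mixed `_include` Bundles route attributes to
the right rows before merging. Anything else is a parse error with a
position, making the dialect boundary explicit rather than silently
approximate. `where` compares only against string literals; date and
quantity comparisons are out of scope, as are aggregates and `resolve()`.

Evaluation follows FHIRPath collection semantics: every expression yields
a flat ordered list; navigating into an array maps over elements and
flattens one level; missing members yield the empty collection, which
propagates (with `exists`/`empty`/`count` then yielding
`FALSE`/`TRUE`/`0`). The engine is checked against an independently
written oracle that enumerates every scalar leaf with its index-free dot
path: for trees without nested arrays (FHIR JSON has none), a
navigation-only path selects exactly the leaves at that path in document
order. The comparison is restricted to paths that are purely scalar-valued,
since the enumeration oracle is undefined when a name reaches both a
scalar and a subtree; the acceptance run checks ~40k path evaluations
over 1000 random resources.

## Tabulation

One row represents one resource. Multi-valued path results become list
cells, never exploded rows — exploding would silently change row counts
and break the one-row-per-resource reading. Cells are `NA` (empty
collection), scalar (singleton), or an ordered list. `full_dump` mode
flattens every leaf with dot-and-index names (`name.0.family`, 0-based to
match the path indexer); the naming convention for deeply nested lists is
this package's own. Processing-function mode calls a user function once
per Bundle and accepts any record shape (e.g. one column per
blood-pressure component display name plus unit columns).

`merge_rows()` collapses rows sharing a key in first-appearance order;
missing-key rows stay as singleton groups interleaved in the same order.
Non-missing values win over missing; conflicting non-missing scalars are
collected into an ordered list cell — lossless and auditable, where
first-wins would hide real discrepancies. Column order is spec order, then
first-seen order, so CSV output is deterministic.

## Document mining

The pipeline is decode → optional header strip → sentence split →
per-sentence regex. `strip_header()` keeps the keyword itself, so the
operation is idempotent. The sentence splitter is rule-based: a boundary
is terminal punctuation followed by whitespace and an upper-case letter or
digit, unless the preceding token is on the abbreviation list (defaults
include `Dr`, `Prof`, `Fig`, `e.g`); decimals never split because no
whitespace follows the period. A statistical segmenter would be more
accurate on edge cases but adds a heavyweight model dependency and
nondeterminism; the splitter is pluggable (`split_fn`) for users who want
one. Matching is case-insensitive by default because clinical text casing
is inconsistent. The exclusion mechanism is a second regular expression
that removes sentences from the match set and counts them — not sentiment
analysis, which would require a validated language model.

## DICOM retrieval

The downloader resolves each (study, optional series) request through
QIDO-RS-style series listing, retrieves instances WADO-RS-style, and
writes DICOM part-10 files (hierarchical `study/series/` folders by
default, reducing files per directory on large pulls). Per-series failures
are recorded and the run continues — the two-table ledger
(successes/failures) is the point of a bulk download — and a failed write
removes the partial folder so no half-written series can pass a
file-count check. Every resolved pair lands in exactly one table, and the
file count on disk equals the summed `instance_count`, both checked.

The part-10 codec (explicit VR little endian, single-frame 8-bit
grayscale) is written in-package and kept deliberately minimal: it exists
to generate and validate synthetic instances. One test validates written
files with pydicom as an independent reader.

## Synthetic store and mock server

`generate_cohort()` emulates the structure of a metastatic-breast-cancer
cohort at desk scale: ICD-10 `C50` at prevalence 0.5 and `C78.0` at 0.4
(so with the default 50 patients a both-codes cohort of ~10 exists);
the four LOINC markers (`16112-5`, `16113-3`, `48676-1`, `21908-9`) dated
uniformly within ±45 days of the metastasis onset, so a ±30-day
eligibility window genuinely separates usable from unusable markers;
blood-pressure panel Observations with systolic/diastolic components
(60 % of patients); Poisson document and study counts (λ = 1.5 and 1);
30 % of documents carrying a planted positive sentence and half as many
again a planted exclusion sentence, making miner precision and recall
exactly computable; and one guaranteed thorax CT per metastasis patient
dated within ±40 days of onset. Every study is backed by 1–3 series of
2–4 minimal DICOM instances. These values are fixed study conditions, not
tuning knobs; prevalences and rates were chosen once as plausible for the
emulated scenario. All randomness comes from a private RNG stream seeded
by `config$seed`, so identical configs are byte-identical and the
caller's RNG is untouched.

What the store does **not** emulate: clinically realistic value
distributions, coding errors and missingness patterns of real EHRs,
FHIR profile constraints, terminology-server semantics, or server-side
patient-record linkage. Passing tests therefore demonstrate client-stack
correctness — retrieval fidelity, flattening fidelity, accounting — not
robustness to dirty real-world data.

The mock server implements token (`code`, `code=system|code`), date
(`ge`/`gt`/`le`/`lt` on calendar dates), and reference parameters,
`_count`/`next` paging (deterministic id order), `_include` of referenced
Patients (deduplicated per page), instance-level `_history` (newest
first), HTTP 400 on unsupported parameters (a lenient mode ignores them
instead, mirroring real servers' leniency), plus scripted failure
sequences and refresh rejection for retry testing.

## The example pipeline

`example_results_pipeline()` chains the modules: intersect `C50` and
`C78.0` carriers; per-patient demographics; the four markers kept only
within ±30 days of the metastasis onset (the window is enforced
client-side after per-patient queries — the per-row constraint mapping
carries cell values, not per-row date windows; with several eligible
values the one nearest the anchor wins, ties to the earlier date);
thorax studies under the same window; survival days to death or to the
study end (default 2021-01-01) with an event flag. Output is ordered by
patient id and byte-deterministic: the same seed yields the identical
CSV.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small stores — 5–60
patients, 250-resource paging checks, 50 randomized date-partition
fixtures, 1000 random resources for the path oracle — sizes at which
every expected value can be recomputed by exhaustive enumeration of the
store, which is what the tests do. Dates are compared at calendar-day
precision (FHIR date search semantics); ties in marker selection break
toward the earlier date; table cells simplify to atomic columns only when
every cell is a length-1 atomic, otherwise the column stays a list column
to avoid lossy coercion.

## Known limitations

- Write operations, GraphQL, and the bulk-data `$export` API are out of
  scope, as are OAuth2/SMART-on-FHIR flows and credential storage.
- The FHIRPath dialect is the documented subset; expressions outside it
  are rejected, not approximated.
- Combining per-row constraints with time partitioning in one call is
  deliberately unimplemented; the composition is ambiguous (which spans
  per row?) and either function can be applied in sequence.
- The mock server indexes only the search parameters the package's
  workflows need; it is a test double, not a FHIR server implementation.
- DIMSE transfer (C-MOVE/C-GET), image conversion, and de-identification
  are out of scope for the downloader.
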