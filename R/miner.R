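# Regex triage of clinical free text: header stripping, deterministic
# rule-based sentence segmentation, and main/exclusion pattern matching.
# The segmenter is rule-based on purpose — a statistical sentence model
# would add a heavyweight dependency and nondeterminism for no benefit at
# triage precision; its engine is pluggable for users who want one.

DEFAULT_ABBREVIATIONS <- c(
  "Dr", "Prof", "Mr", "Mrs", "Ms", "St", "Fig", "No", "vs", "ca", "approx",
  "e.g", "i.e", "z.B", "bzw", "inkl", "cf", "al"
)

#' Configure the document miner
#'
#' @param main_pattern Regular expression that makes a sentence a match.
#' @param exclusion_pattern Optional regular expression; sentences matching
#'   it are dropped from the matches and counted separately (e.g. search
#'   `"sarcoma"` but exclude `"osteosarcoma"`).
#' @param header_keyword Optional keyword (e.g. `"Findings"`); everything
#'   before its first occurrence is removed before segmentation.
#' @param case_insensitive Match case-insensitively (default `TRUE`;
#'   clinical text casing is inconsistent).
#' @param text_column Column holding the document text in
#'   [nlp_on_dataframe()].
#' @param decode_fn Optional `function(cell) -> character` applied before
#'   anything else (e.g. base64 decoding of `presentedForm` payloads).
#' @param abbreviations Tokens after which a period never ends a sentence.
#' @param split_fn Optional replacement sentence segmenter,
#'   `function(text) -> character vector`.
#' @return A `miner_config`.
#' @export
miner_config <- function(main_pattern,
                         exclusion_pattern = NULL,
                         header_keyword = NULL,
                         case_insensitive = TRUE,
                         text_column = "text",
                         decode_fn = NULL,
                         abbreviations = DEFAULT_ABBREVIATIONS,
                         split_fn = NULL) {
  tryCatch(regexpr(main_pattern, ""), error = function(e) {
    stop_domain(sprintf("main_pattern does not compile: %s", conditionMessage(e)))
  })
  if (!is.null(exclusion_pattern)) {
    tryCatch(regexpr(exclusion_pattern, ""), error = function(e) {
      stop_domain(sprintf("exclusion_pattern does not compile: %s",
                          conditionMessage(e)))
    })
  }
  structure(
    list(main_pattern = main_pattern, exclusion_pattern = exclusion_pattern,
         header_keyword = header_keyword,
         case_insensitive = isTRUE(case_insensitive),
         text_column = text_column, decode_fn = decode_fn,
         abbreviations = abbreviations, split_fn = split_fn),
    class = "miner_config"
  )
}

#' Remove everything before a structural keyword
#'
#' Clinical documents often carry boilerplate headers; the relevant part
#' starts at a known keyword. Returns the substring starting at the first
#' occurrence of `keyword` (inclusive), so the operation is idempotent. If
#' the keyword is absent the text is returned unchanged with attribute
#' `header_found = FALSE`.
#'
#' @param text Document text.
#' @param keyword Non-empty keyword, matched literally.
#' @return The (possibly) trimmed text, with a logical `header_found`
#'   attribute.
#' @export
strip_header <- function(text, keyword) {
  if (!nzchar(keyword %||% "")) stop_domain("keyword must be non-empty")
  at <- regexpr(keyword, text, fixed = TRUE)
  if (at == -1) return(structure(text, header_found = FALSE))
  structure(substr(text, at, nchar(text)), header_found = TRUE)
}

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: a boundary is terminal
#' punctuation (`.!?`) followed by whitespace and an upper-case letter or
#' digit, unless the token before the period is a known abbreviation.
#' Decimal numbers never split (no whitespace after the period). The
#' concatenation of the sentences reproduces the input up to boundary
#' whitespace.
#'
#' @param text Character scalar.
#' @param abbreviations Abbreviation exception list.
#' @return Character vector of sentences (empty for empty input).
#' @examples
#' split_sentences("No mass. Dr. Smith saw a 3.5 cm lesion.")
#' @export
split_sentences <- function(text, abbreviations = DEFAULT_ABBREVIATIONS) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  candidates <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (candidates[[1]] == -1) return(trimws(text))
  lengths <- attr(candidates, "match.length")
  cut_points <- integer(0)
  for (k in seq_along(candidates)) {
    end <- candidates[[k]] + lengths[[k]] - 1L
    before <- substr(text, 1, candidates[[k]] - 1L)
    token <- sub("^.*?([A-Za-z](?:[A-Za-z.])*)$", "\\1", before)
    if (tolower(token) %in% tolower(abbreviations)) next
    cut_points <- c(cut_points, end)
  }
  if (length(cut_points) == 0) return(trimws(text))
  starts <- c(1L, cut_points + 1L)
  ends <- c(cut_points, nchar(text))
  sentences <- trimws(substring(text, starts, ends))
  sentences[nzchar(sentences)]
}

#' Triage one document
#'
#' Pipeline: optional `decode_fn`, optional [strip_header()],
#' [split_sentences()], then per-sentence matching of the main pattern;
#' sentences that also match the exclusion pattern are dropped from the
#' matches and tallied in `excluded_count`.
#'
#' @param text Document text (or whatever `decode_fn` accepts).
#' @param config A [miner_config()].
#' @return A `doc_report`: list with `matched`, `matching_sentences`,
#'   `match_count`, `excluded_count`, `header_found`.
#' @examples
#' cfg <- miner_config("sarcoma", exclusion_pattern = "osteosarcoma")
#' mine_text("Evidence of sarcoma. Known osteosarcoma.", cfg)
#' @export
mine_text <- function(text, config) {
  stopifnot(inherits(config, "miner_config"))
  if (!is.null(config$decode_fn)) {
    text <- tryCatch(config$decode_fn(text), error = function(e) {
      stop_domain(sprintf("decode_fn failed: %s", conditionMessage(e)))
    })
  }
  header_found <- NA
  if (!is.null(config$header_keyword) && !is.null(text) && !is.na(text)) {
    text <- strip_header(text, config$header_keyword)
    header_found <- attr(text, "header_found")
  }
  splitter <- config$split_fn %||%
    function(t) split_sentences(t, config$abbreviations)
  sentences <- splitter(text)
  hit <- grepl(config$main_pattern, sentences,
               ignore.case = config$case_insensitive, perl = TRUE)
  excluded_count <- 0L
  if (!is.null(config$exclusion_pattern)) {
    excl <- grepl(config$exclusion_pattern, sentences,
                  ignore.case = config$case_insensitive, perl = TRUE)
    excluded_count <- sum(hit & excl)
    hit <- hit & !excl
  }
  matching <- sentences[hit]
  structure(
    list(matched = length(matching) > 0,
         matching_sentences = as.character(matching),
         match_count = length(matching),
         excluded_count = as.integer(excluded_count),
         header_found = header_found),
    class = "doc_report"
  )
}

#' Triage every document of a table
#'
#' Applies [mine_text()] to `config$text_column` of each row and appends
#' the report columns `matched`, `matching_sentences` (list column),
#' `match_count` and `excluded_count`. Rows with a missing text cell get
#' `matched = NA`. Output is identical for any `n_procs`.
#'
#' @param table A data.frame/tibble.
#' @param config A [miner_config()].
#' @param n_procs Partitioning contract only; results equal sequential.
#' @return The input table with the report columns appended.
#' @export
nlp_on_dataframe <- function(table, config, n_procs = 1L) {
  stopifnot(inherits(config, "miner_config"))
  if (!config$text_column %in% names(table)) {
    stop_key(sprintf("text column '%s' not in table", config$text_column))
  }
  texts <- table[[config$text_column]]
  reports <- lapply(seq_len(nrow(table)), function(i) {
    cell <- if (is.list(texts)) texts[[i]] else texts[[i]]
    if (is.null(cell) || (is.atomic(cell) && length(cell) == 1 && is.na(cell))) {
      return(list(matched = NA, matching_sentences = character(0),
                  match_count = NA_integer_, excluded_count = NA_integer_))
    }
    mine_text(cell, config)
  })
  out <- tibble::as_tibble(table)
  out$matched <- vapply(reports, function(r) r$matched, logical(1))
  out$matching_sentences <- lapply(reports, function(r) r$matching_sentences)
  out$match_count <- vapply(reports, function(r) as.integer(r$match_count),
                            integer(1))
  out$excluded_count <- vapply(reports,
                               function(r) as.integer(r$excluded_count),
                               integer(1))
  out
}
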