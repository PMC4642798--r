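# Corpus IO: reading/writing tweet tables and the topical keyword filter.

CORPUS_COLUMNS <- c(
  "tweet_id", "handle", "timestamp", "text",
  "follower_count", "following_count", "statuses_count", "is_retweet"
)

TIMESTAMP_FORMAT <- "%Y-%m-%dT%H:%M:%SZ"

#' Construct a tweet corpus tibble
#'
#' A corpus is an ordinary tibble with one row per tweet and a fixed schema:
#' `tweet_id` (unique character id), `handle` (posting account, no leading
#' "@"), `timestamp` (POSIXct, UTC), `text`, the three account-size counts
#' recorded at the time the tweet was posted (`follower_count`,
#' `following_count`, `statuses_count`), and the logical `is_retweet`.
#' `tweet_corpus()` coerces and validates; all pipeline functions accept any
#' tibble with these columns.
#'
#' @param x A data frame with (at least) the corpus columns.
#' @return A validated tibble with the corpus columns first, input order
#'   preserved.
#' @export
#' @examples
#' tweet_corpus(tibble::tibble(
#'   tweet_id = "t1", handle = "vaper99",
#'   timestamp = as.POSIXct("2012-06-01 10:00:00", tz = "UTC"),
#'   text = "loving my new ecig", follower_count = 10L,
#'   following_count = 20L, statuses_count = 100L, is_retweet = FALSE
#' ))
tweet_corpus <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(CORPUS_COLUMNS, names(x))
  if (length(missing) > 0) {
    abort(paste0("corpus is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- x |>
    mutate(
      tweet_id = as.character(.data$tweet_id),
      handle = sub("^@", "", as.character(.data$handle)),
      timestamp = lubridate::with_tz(.data$timestamp, "UTC"),
      text = as.character(.data$text),
      follower_count = as.integer(.data$follower_count),
      following_count = as.integer(.data$following_count),
      statuses_count = as.integer(.data$statuses_count),
      is_retweet = as.logical(.data$is_retweet)
    ) |>
    relocate(all_of(CORPUS_COLUMNS))
  validate_corpus(x)
  x
}

validate_corpus <- function(x) {
  if (anyDuplicated(x$tweet_id) > 0) {
    abort("corpus invariant violated: tweet_id values must be unique")
  }
  counts <- c(x$follower_count, x$following_count, x$statuses_count)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("corpus invariant violated: account counts must be non-negative")
  }
  if (anyNA(x$timestamp)) {
    abort("corpus invariant violated: timestamps must parse")
  }
  invisible(x)
}

#' Read a tweet corpus from CSV or JSONL
#'
#' Rows whose timestamp does not parse (ISO 8601, UTC) are skipped, counted,
#' and reported with their line numbers via a warning and the
#' `"skipped_rows"` attribute of the result. A missing required column is a
#' fatal error naming the column.
#'
#' @param path File path.
#' @param format `"csv"` (comma-separated, quoted, UTF-8, header row) or
#'   `"jsonl"` (one JSON object per line).
#' @return A corpus tibble in file order, with attribute `skipped_rows`
#'   (integer line numbers of skipped records).
#' @export
read_tweets <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE),
    jsonl = read_jsonl_raw(path)
  )
  missing <- setdiff(CORPUS_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("input is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ts <- as.POSIXct(strptime(raw$timestamp, TIMESTAMP_FORMAT, tz = "UTC"))
  counts <- suppressWarnings(cbind(
    as.integer(raw$follower_count),
    as.integer(raw$following_count),
    as.integer(raw$statuses_count)
  ))
  bad <- is.na(ts) | rowSums(is.na(counts)) > 0 | is.na(raw$tweet_id) |
    is.na(raw$text)
  # line numbers are 1-based data lines; +1 accounts for the CSV header
  skipped <- which(bad) + if (format == "csv") 1L else 0L
  if (length(skipped) > 0) {
    warn(paste0("skipped ", length(skipped), " malformed record(s) at line(s): ",
                paste(skipped, collapse = ", ")))
  }
  out <- tibble(
    tweet_id = raw$tweet_id[!bad],
    handle = raw$handle[!bad],
    timestamp = ts[!bad],
    text = raw$text[!bad],
    follower_count = counts[!bad, 1],
    following_count = counts[!bad, 2],
    statuses_count = counts[!bad, 3],
    is_retweet = tolower(as.character(raw$is_retweet[!bad])) %in%
      c("true", "t", "1")
  )
  out <- tweet_corpus(out)
  attr(out, "skipped_rows") <- skipped
  out
}

read_jsonl_raw <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(as_tibble(sapply(CORPUS_COLUMNS, function(x) character(0),
                            simplify = FALSE)))
  }
  rows <- map(lines, function(l) {
    rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(rec)) return(NULL)
    as_tibble(map(rec, function(v) as.character(v %||% NA_character_)))
  })
  ok <- !map_lgl(rows, is.null)
  out <- list_rbind(rows[ok])
  # re-insert placeholder rows for unparseable lines so line numbers line up
  if (any(!ok)) {
    full <- out[rep(NA_integer_, length(lines)), ]
    full[which(ok), ] <- out
    out <- full
  }
  out
}

#' Write a tweet corpus to CSV or JSONL
#'
#' Timestamps are serialized as ISO 8601 UTC (`YYYY-MM-DDTHH:MM:SSZ`), so a
#' written corpus re-read with [read_tweets()] is equal field-for-field.
#'
#' @param corpus A corpus tibble.
#' @inheritParams read_tweets
#' @return `path`, invisibly.
#' @export
write_tweets <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  corpus <- tweet_corpus(corpus)
  flat <- corpus |>
    mutate(
      timestamp = format(.data$timestamp, TIMESTAMP_FORMAT, tz = "UTC"),
      is_retweet = ifelse(.data$is_retweet, "true", "false")
    ) |>
    select(all_of(CORPUS_COLUMNS))
  if (format == "csv") {
    readr::write_csv(flat, path, quote = "all", progress = FALSE)
  } else {
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(flat) > 0) {
      json <- vapply(seq_len(nrow(flat)), function(i) {
        as.character(jsonlite::toJSON(as.list(flat[i, ]), auto_unbox = TRUE))
      }, character(1))
      writeLines(json, con)
    }
  }
  invisible(path)
}

#' Keyword syntax for topical filtering
#'
#' The inclusion/exclusion term lists that define "tweets about
#' e-cigarettes". Terms are casefolded. Single tokens match on word
#' boundaries; multiword phrases match as substrings.
#'
#' @param include Non-empty character vector of inclusion terms.
#' @param exclude Character vector of exclusion terms (other tobacco or drug
#'   topics, e.g. "marijuana", "hookah").
#' @return A `keyword_syntax` object.
#' @export
keyword_syntax <- function(include, exclude = character(0)) {
  include <- unique(str_to_lower(trimws(include)))
  exclude <- unique(str_to_lower(trimws(exclude)))
  if (length(include) == 0) abort("include terms must be non-empty")
  overlap <- intersect(include, exclude)
  if (length(overlap) > 0) {
    abort(paste0("include and exclude terms overlap: ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(include = include, exclude = exclude),
            class = "keyword_syntax")
}

#' @export
print.keyword_syntax <- function(x, ...) {
  cat("<keyword_syntax> ", length(x$include), " include / ",
      length(x$exclude), " exclude terms\n", sep = "")
  invisible(x)
}

#' Read a keyword syntax from a YAML config file
#'
#' The file has `include:` and `exclude:` list sections.
#'
#' @param path YAML file path.
#' @return A [keyword_syntax()] object.
#' @export
read_keyword_syntax <- function(path) {
  cfg <- yaml::read_yaml(path)
  keyword_syntax(unlist(cfg$include), unlist(cfg$exclude))
}

#' Default e-cigarette keyword syntax
#'
#' The shipped default contains every general term, use-related term and
#' brand name published for the original 55-keyword search (the full list was
#' never published; the config file is user-editable).
#'
#' @return A [keyword_syntax()] object.
#' @export
default_keyword_syntax <- function() {
  read_keyword_syntax(system.file("extdata", "keywords.yml",
                                  package = "vapewatch"))
}

term_pattern <- function(term) {
  if (grepl(" ", term, fixed = TRUE)) {
    # multiword phrase: plain casefolded substring
    fixed(term)
  } else {
    regex(paste0("\\b", escape_regex(term), "\\b"))
  }
}

escape_regex <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\-])", "\\\\\\1", x,
                                 perl = TRUE)

matches_any_term <- function(text_lower, terms) {
  if (length(terms) == 0) return(rep(FALSE, length(text_lower)))
  hit <- rep(FALSE, length(text_lower))
  for (term in terms) {
    hit <- hit | str_detect(text_lower, term_pattern(term))
  }
  hit
}

#' Filter a corpus to on-topic tweets
#'
#' Retains exactly the tweets whose casefolded text contains at least one
#' inclusion term and no exclusion term. The filter is idempotent and
#' preserves input order.
#'
#' @param corpus A corpus tibble.
#' @param syntax A [keyword_syntax()]; defaults to the shipped e-cigarette
#'   syntax.
#' @return The retained subset, order preserved.
#' @export
#' @examples
#' \dontrun{
#' corpus |> filter_keywords()
#' }
filter_keywords <- function(corpus, syntax = default_keyword_syntax()) {
  stopifnot(inherits(syntax, "keyword_syntax"))
  text_lower <- str_to_lower(corpus$text)
  keep <- matches_any_term(text_lower, syntax$include) &
    !matches_any_term(text_lower, syntax$exclude)
  corpus[keep, , drop = FALSE]
}
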