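# Hashtag / URL extraction and offline URL unshortening.
#
# The published hashtag and URL regexes are typographically corrupted in
# print; the patterns below reconstruct the evident intent: a hashtag is "#"
# followed by a letter then letters/digits/underscore, and a URL is
# scheme "://" host(.host)+ with an optional whitespace-free path.

HASHTAG_PATTERN <- "#[A-Za-z][A-Za-z0-9_]*"
URL_PATTERN <- "[A-Za-z][A-Za-z0-9+.-]*://[^\\s/]+(?:/[^\\s]*)?"

#' Extract hashtags from tweet text
#'
#' Maximal `#word` tokens whose first character after `#` is a letter,
#' continuing over letters, digits and underscore, in left-to-right order.
#' Pure and deterministic; duplicates are kept if duplicated in the text.
#'
#' @param text Character vector of tweet texts.
#' @return A list of character vectors, one per input text.
#' @export
#' @examples
#' extract_hashtags("Vaping in the bathroom #whatofit")
extract_hashtags <- function(text) {
  str_extract_all(text, HASHTAG_PATTERN)
}

#' Extract URLs from tweet text
#'
#' Substrings of the form `scheme://host[.domain...][/path]`, left-to-right;
#' the path extends to the next whitespace.
#'
#' @inheritParams extract_hashtags
#' @return A list of character vectors, one per input text.
#' @export
#' @examples
#' extract_urls("Get 20% off http://bit.ly/abc123 today")
extract_urls <- function(text) {
  out <- str_extract_all(text, URL_PATTERN)
  # require a dotted host so "foo://bar" noise is not treated as a link
  map(out, function(u) u[grepl("://[^/\\s]+\\.[^/\\s]+", u, perl = TRUE)])
}

#' Offline URL resolver
#'
#' A lookup table replacing the live unshortening services the original
#' analysis called: shortened links resolve through a two-column map
#' (`raw`, `final`). Chains (`a -> b`, `b -> c`) are followed up to
#' `max_depth` steps, so resolution terminates on cyclic maps.
#'
#' @param map A data frame with columns `raw` and `final`, or a path to a
#'   two-column TSV with that header.
#' @param max_depth Maximum chain length to follow.
#' @return A `url_resolver` object with a `lookup(raw)` semantic used by
#'   [unshorten_url()].
#' @export
url_resolver <- function(map = data.frame(raw = character(0), final = character(0)),
                         max_depth = 5) {
  if (is.character(map) && length(map) == 1) {
    map <- readr::read_tsv(map, col_types = "cc", progress = FALSE)
  }
  stopifnot(all(c("raw", "final") %in% names(map)))
  structure(
    list(table = setNames(as.character(map$final), as.character(map$raw)),
         max_depth = max_depth),
    class = "url_resolver"
  )
}

#' Default offline resolver shipped with the package
#' @return A [url_resolver()].
#' @export
default_url_resolver <- function() {
  url_resolver(system.file("extdata", "url_map.tsv", package = "vapewatch"))
}

#' Resolve possibly-shortened URLs
#'
#' Known raw URLs map to their final destination (`resolved = TRUE`);
#' unknown URLs pass through unchanged (`resolved = FALSE`). Resolver
#' failures are logged and treated as unknown — unshortening never aborts
#' the pipeline. Idempotent on already-final URLs.
#'
#' @param raw_url Character vector of URLs.
#' @param resolver A [url_resolver()].
#' @return A tibble with columns `raw`, `final`, `resolved`.
#' @export
unshorten_url <- function(raw_url, resolver = default_url_resolver()) {
  res <- map(raw_url, function(u) {
    tryCatch({
      cur <- u
      hops <- 0L
      while (hops < resolver$max_depth && !is.na(resolver$table[cur])) {
        cur <- unname(resolver$table[cur])
        hops <- hops + 1L
      }
      list(final = cur, resolved = hops > 0L)
    }, error = function(e) {
      warn(paste0("resolver failed for ", u, ": ", conditionMessage(e)))
      list(final = u, resolved = FALSE)
    })
  })
  tibble(
    raw = raw_url,
    final = map_chr(res, "final"),
    resolved = map_lgl(res, "resolved")
  )
}

#' Extract per-tweet entity sets
#'
#' Runs hashtag and URL extraction over a corpus and resolves every URL
#' through the supplied offline resolver.
#'
#' @param corpus A corpus tibble.
#' @param resolver A [url_resolver()].
#' @return A tibble with one row per tweet: `tweet_id`, list-columns
#'   `hashtags` and `urls`, and a nested `resolved` tibble of
#'   (`raw`, `final`, `resolved`) with one row per raw URL.
#' @export
extract_entities <- function(corpus, resolver = default_url_resolver()) {
  hashtags <- extract_hashtags(corpus$text)
  urls <- extract_urls(corpus$text)
  tibble(
    tweet_id = corpus$tweet_id,
    hashtags = hashtags,
    urls = urls,
    resolved = map(urls, unshorten_url, resolver = resolver)
  )
}
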