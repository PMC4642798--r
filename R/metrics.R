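# Surveillance aggregates: time series by class, shares, promotion and
# brand counts, handle/link rankings, and follower-burst flags.

#' Percentage share, reported to two decimals
#'
#' @param numerator,denominator Non-negative counts (vectorized, recycled);
#'   `numerator <= denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator`, rounded to 2 decimals.
#' @export
#' @examples
#' share(1559508, 1669123)
share <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("share: denominator must be positive")
  if (any(numerator < 0)) abort("share: numerator must be non-negative")
  if (any(numerator > denominator)) {
    abort("share: numerator must not exceed denominator")
  }
  round(100 * numerator / denominator, 2)
}

#' Tweet counts per calendar period and class
#'
#' Weekly bins are ISO calendar weeks (Monday start) in UTC, labeled by the
#' week's start date; yearly bins by calendar year. Empty bins between the
#' first and last tweet are emitted with zero counts, so period counts
#' always sum to the corpus size.
#'
#' @param labeled A corpus tibble with a `label` column.
#' @param bin `"week"` or `"year"`.
#' @return A tibble `period`, `label`, `n`.
#' @export
time_series <- function(labeled, bin = c("week", "year")) {
  bin <- match.arg(bin)
  if (!"label" %in% names(labeled)) abort("time_series needs a label column")
  if (nrow(labeled) == 0) {
    return(tibble(period = if (bin == "week") as.Date(character(0))
                  else integer(0),
                  label = character(0), n = integer(0)))
  }
  classes <- sort(unique(labeled$label))
  if (bin == "week") {
    period <- lubridate::floor_date(lubridate::with_tz(labeled$timestamp, "UTC"),
                                    unit = "week", week_start = 1)
    period <- as.Date(period)
    all_periods <- seq(min(period), max(period), by = "7 days")
  } else {
    period <- lubridate::year(lubridate::with_tz(labeled$timestamp, "UTC"))
    all_periods <- seq(min(period), max(period))
  }
  tibble(period = period, label = labeled$label) |>
    count(.data$period, .data$label) |>
    complete(period = all_periods, label = classes, fill = list(n = 0L)) |>
    arrange(.data$period, .data$label)
}

#' Count promotion-term mentions in advertising tweets
#'
#' A tweet counts toward every term its casefolded text contains;
#' "percent off" additionally matches the spelling "% off".
#'
#' @param ad_corpus A corpus tibble (the advertising subset).
#' @param terms Promotion terms to count.
#' @return A tibble `term`, `n`.
#' @export
count_promotions <- function(ad_corpus,
                             terms = c("promotion", "coupon", "percent off",
                                       "discount")) {
  text <- str_to_lower(ad_corpus$text)
  n <- vapply(terms, function(term) {
    hit <- str_detect(text, fixed(term))
    if (term == "percent off") hit <- hit | str_detect(text, fixed("% off"))
    sum(hit)
  }, integer(1))
  tibble(term = terms, n = unname(n))
}

#' Brand lexicon shipped with the package
#' @param path Optional YAML file (brand -> matching variants) overriding
#'   the shipped lexicon.
#' @return A named list of casefolded, deduplicated variant vectors.
#' @export
brand_lexicon <- function(path = system.file("extdata", "brands.yml",
                                             package = "vapewatch")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(length(cfg) > 0)
  map(cfg, function(v) unique(str_to_lower(unlist(v))))
}

#' Count brand mentions
#'
#' Word-boundary, casefolded matching of every lexicon variant. A tweet
#' counts once per distinct brand; `any_brand` counts tweets mentioning at
#' least one brand, so `any_brand` never exceeds the sum of per-brand
#' counts.
#'
#' @param corpus A corpus tibble.
#' @param lexicon A [brand_lexicon()].
#' @return A list: `brands` (tibble `brand`, `n`), `any_brand` (integer).
#' @export
count_brands <- function(corpus, lexicon = brand_lexicon()) {
  text <- str_to_lower(corpus$text)
  per_brand <- map(lexicon, function(variants) {
    pat <- paste0("\\b(", paste(escape_regex(variants), collapse = "|"),
                  ")\\b")
    str_detect(text, pat)
  })
  any_hit <- Reduce(`|`, per_brand, init = rep(FALSE, length(text)))
  list(
    brands = tibble(brand = names(lexicon),
                    n = unname(map_int(per_brand, sum))),
    any_brand = sum(any_hit)
  )
}

#' Most active handles
#'
#' Ranked by tweet count, descending; ties broken lexicographically by
#' handle. `follower_count` is the latest observed value for the handle.
#'
#' @param corpus A corpus tibble.
#' @param k Number of handles to return.
#' @return A tibble `handle`, `n`, `follower_count`.
#' @export
rank_handles <- function(corpus, k = 5L) {
  stopifnot(k >= 1)
  corpus |>
    group_by(.data$handle) |>
    summarise(
      n = n(),
      follower_count = .data$follower_count[which.max(.data$timestamp)],
      .groups = "drop"
    ) |>
    arrange(desc(.data$n), .data$handle) |>
    head(k)
}

#' Most shared links
#'
#' Ranked on resolved final URLs (raw URLs where unresolved); a tweet
#' counts once per distinct final URL. Ties break lexicographically.
#'
#' @param entities An [extract_entities()] result.
#' @param k Number of links to return.
#' @return A tibble `url`, `n`.
#' @export
rank_links <- function(entities, k = 5L) {
  stopifnot(k >= 1)
  long <- entities |>
    select("tweet_id", "resolved") |>
    unnest("resolved")
  if (nrow(long) == 0) return(tibble(url = character(0), n = integer(0)))
  long |>
    distinct(.data$tweet_id, url = .data$final) |>
    count(.data$url, name = "n") |>
    arrange(desc(.data$n), .data$url) |>
    head(k)
}

#' Per-handle follower trajectories
#'
#' @param corpus A corpus tibble.
#' @return A tibble `handle`, `samples` (list of time-ordered tibbles with
#'   `timestamp`, `follower_count`).
#' @export
follower_trajectories <- function(corpus) {
  corpus |>
    arrange(.data$timestamp) |>
    group_by(.data$handle) |>
    summarise(samples = list(pick("timestamp", "follower_count")),
              .groups = "drop")
}

#' Flag abrupt follower-growth bursts
#'
#' Splits a handle's trajectory into consecutive windows of
#' `window_days` and flags any window whose follower gain exceeds
#' `factor` times the handle's median per-window gain. Handles with zero
#' median gain (flat accounts) are flagged on absolute gain above `floor`.
#' A large burst of followers in a short window is a purchased-follower /
#' spam signal; organic accounts accrue followers steadily.
#'
#' @param trajectory A tibble with `timestamp`, `follower_count` (at least
#'   3 samples; fewer yields a warning and no flags).
#' @param window_days Window length in days.
#' @param factor Multiple of the median per-window gain that counts as a
#'   burst.
#' @param floor Absolute per-window gain threshold used when the median
#'   gain is zero.
#' @return A tibble of flagged windows: `window_start`, `window_end`,
#'   `gain`, `median_gain`.
#' @export
flag_follower_bursts <- function(trajectory, window_days = 30, factor = 10,
                                 floor = 1000) {
  empty <- tibble(window_start = as.POSIXct(character(0), tz = "UTC"),
                  window_end = as.POSIXct(character(0), tz = "UTC"),
                  gain = numeric(0), median_gain = numeric(0))
  if (nrow(trajectory) < 3) {
    warn("flag_follower_bursts: fewer than 3 samples; no windows evaluated")
    return(empty)
  }
  traj <- arrange(trajectory, .data$timestamp)
  t <- as.numeric(traj$timestamp)
  w <- window_days * 86400
  bounds <- seq(t[1], t[length(t)] + w, by = w)
  if (length(bounds) < 2) return(empty)
  # follower count at each boundary: last observation carried forward
  f <- stats::approx(t, traj$follower_count, xout = bounds,
                     method = "constant", rule = 2, ties = "ordered")$y
  gains <- diff(f)
  med <- median(gains)
  flagged <- if (med > 0) gains > factor * med else gains > floor
  tibble(
    window_start = as.POSIXct(bounds[-length(bounds)], tz = "UTC",
                              origin = "1970-01-01"),
    window_end = as.POSIXct(bounds[-1], tz = "UTC", origin = "1970-01-01"),
    gain = gains, median_gain = med
  )[flagged, , drop = FALSE]
}

#' Flag burst handles across a corpus
#'
#' Applies [flag_follower_bursts()] to every handle with at least 3
#' samples.
#'
#' @param corpus A corpus tibble.
#' @inheritParams flag_follower_bursts
#' @return A tibble `handle`, `n_flagged_windows`, for handles with at
#'   least one flagged window.
#' @export
flag_burst_handles <- function(corpus, window_days = 30, factor = 10,
                               floor = 1000) {
  traj <- follower_trajectories(corpus)
  traj <- traj[map_int(traj$samples, nrow) >= 3, , drop = FALSE]
  flags <- map_int(traj$samples, function(s) {
    nrow(flag_follower_bursts(s, window_days, factor, floor))
  })
  tibble(handle = traj$handle, n_flagged_windows = flags) |>
    filter(.data$n_flagged_windows > 0) |>
    arrange(desc(.data$n_flagged_windows), .data$handle)
}

#' Corpus-level surveillance summary
#'
#' Mirrors the structure of the published characteristics table: yearly
#' counts, class shares, retweet shares by class, promotion-term and brand
#' shares within each class, most active handles per class, most shared
#' links among advertising tweets, and (optionally) the place-category
#' table for nonadvertising tweets.
#'
#' @param labeled A corpus tibble with a `label` column.
#' @param entities Optional [extract_entities()] result (enables link
#'   ranking).
#' @param brands A [brand_lexicon()].
#' @param places Optional [extract_places()] result.
#' @param top_k Rows in the handle/link rankings.
#' @return A `surveillance_summary` object; `tidy()` renders it as one
#'   long tibble.
#' @export
summarize_surveillance <- function(labeled, entities = NULL,
                                   brands = brand_lexicon(), places = NULL,
                                   top_k = 5L) {
  stopifnot("label" %in% names(labeled))
  n_total <- nrow(labeled)
  ads <- filter(labeled, .data$label == "advertising")
  nonads <- filter(labeled, .data$label == "nonadvertising")

  class_counts <- labeled |> count(.data$label)
  pct_of <- function(n, den) if (den > 0) share(n, den) else rep(NA_real_, length(n))
  brand_counts <- function(sub) {
    if (nrow(sub) == 0) return(NULL)
    bc <- count_brands(sub, brands)
    list(per_brand = mutate(bc$brands, pct = share(.data$n, nrow(sub))),
         any_brand = bc$any_brand,
         any_brand_pct = share(bc$any_brand, nrow(sub)))
  }

  structure(
    list(
      n_total = n_total,
      yearly_counts = time_series(labeled, "year"),
      class_counts = mutate(class_counts, pct = pct_of(.data$n, n_total)),
      retweet_share_by_class = labeled |>
        group_by(.data$label) |>
        summarise(n_retweets = sum(.data$is_retweet),
                  pct = pct_of(sum(.data$is_retweet), n()),
                  .groups = "drop"),
      promotion_shares = if (nrow(ads) > 0) {
        count_promotions(ads) |> mutate(pct = share(.data$n, nrow(ads)))
      },
      brand_shares = list(advertising = brand_counts(ads),
                          nonadvertising = brand_counts(nonads)),
      top_handles = list(
        advertising = if (nrow(ads) > 0) rank_handles(ads, top_k),
        nonadvertising = if (nrow(nonads) > 0) rank_handles(nonads, top_k)
      ),
      top_links = if (!is.null(entities) && nrow(ads) > 0) {
        rank_links(semi_join(entities, ads, by = "tweet_id"), top_k)
      },
      place_table = if (!is.null(places)) place_table(places)
    ),
    class = "surveillance_summary"
  )
}

#' @export
print.surveillance_summary <- function(x, ...) {
  cat("<surveillance_summary> ", x$n_total, " tweets\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

#' Long-format rendering of a surveillance summary
#'
#' @param x A [summarize_surveillance()] result.
#' @param ... Unused.
#' @return A tibble `section`, `item`, `n`, `pct` mirroring the published
#'   table's row structure.
#' @method tidy surveillance_summary
#' @export
tidy.surveillance_summary <- function(x, ...) {
  rows <- list(
    tibble(section = "tweets by year",
           item = as.character(x$yearly_counts$period),
           n = x$yearly_counts$n, pct = NA_real_) |>
      group_by(.data$item) |>
      summarise(section = "tweets by year", n = sum(.data$n),
                pct = NA_real_, .groups = "drop") |>
      select("section", "item", "n", "pct"),
    tibble(section = "class", item = x$class_counts$label,
           n = x$class_counts$n, pct = x$class_counts$pct),
    tibble(section = "retweet share",
           item = x$retweet_share_by_class$label,
           n = x$retweet_share_by_class$n_retweets,
           pct = x$retweet_share_by_class$pct)
  )
  if (!is.null(x$promotion_shares)) {
    rows <- c(rows, list(tibble(section = "promotion (advertising)",
                                item = x$promotion_shares$term,
                                n = x$promotion_shares$n,
                                pct = x$promotion_shares$pct)))
  }
  for (cls in names(x$brand_shares)) {
    b <- x$brand_shares[[cls]]
    if (is.null(b)) next
    rows <- c(rows, list(
      tibble(section = paste0("brands (", cls, ")"), item = "any brand",
             n = b$any_brand, pct = b$any_brand_pct),
      tibble(section = paste0("brands (", cls, ")"), item = b$per_brand$brand,
             n = b$per_brand$n, pct = b$per_brand$pct)
    ))
  }
  for (cls in names(x$top_handles)) {
    h <- x$top_handles[[cls]]
    if (is.null(h)) next
    rows <- c(rows, list(tibble(section = paste0("top handles (", cls, ")"),
                                item = h$handle, n = h$n, pct = NA_real_)))
  }
  if (!is.null(x$top_links)) {
    rows <- c(rows, list(tibble(section = "top links (advertising)",
                                item = x$top_links$url, n = x$top_links$n,
                                pct = NA_real_)))
  }
  if (!is.null(x$place_table)) {
    rows <- c(rows, list(tibble(section = "places mentioned",
                                item = x$place_table$category,
                                n = x$place_table$n,
                                pct = x$place_table$pct)))
  }
  list_rbind(rows)
}
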