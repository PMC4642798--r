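# Shared fixture builders. All fixtures are constructed in code; nothing is
# downloaded or read from outside the package.

mk_corpus <- function(texts,
                      handle = "someone",
                      timestamp = as.POSIXct("2012-06-01 10:00:00",
                                             tz = "UTC") + seq_along(texts),
                      follower_count = 10L, following_count = 20L,
                      statuses_count = 100L, is_retweet = FALSE) {
  tweet_corpus(tibble::tibble(
    tweet_id = sprintf("t%03d", seq_along(texts)),
    handle = handle, timestamp = timestamp, text = texts,
    follower_count = follower_count, following_count = following_count,
    statuses_count = statuses_count, is_retweet = is_retweet
  ))
}

quoted_place_tweets <- function() {
  readr::read_csv(system.file("extdata", "quoted_place_tweets.csv",
                              package = "vapewatch"),
                  col_types = "cc", progress = FALSE)
}

# A small labeled corpus where class is decided by clearly separable planted
# text/metadata signals (promo text + URL vs personal usage reports).
mk_labeled_separable <- function(n = 120, seed = 1) {
  sim <- generate_tweets(generator_config(n_tweets = n, seed = seed))
  labels <- setNames(sim$truth$label, sim$truth$tweet_id)
  dplyr::mutate(sim$corpus, label = unname(labels[tweet_id]),
                label_source = "synthetic")
}
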