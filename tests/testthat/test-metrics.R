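# Surveillance aggregates.

test_that("share computes exact two-decimal percentages and validates input", {
  expect_equal(share(1559508, 1669123), 93.43)
  expect_equal(share(447579, 1559508), 28.70)
  expect_equal(share(0, 10), 0)
  expect_error(share(1, 0), "positive")
  expect_error(share(5, 4), "exceed")
})

test_that("time series counts per bin, emits empty bins, and conserves totals", {
  ts3 <- mk_corpus(c("a", "b", "c"),
                   timestamp = as.POSIXct(c("2012-06-05", "2012-06-06",
                                            "2012-06-07"), tz = "UTC"))
  labeled <- dplyr::mutate(ts3, label = c("advertising", "advertising",
                                          "nonadvertising"))
  wk <- time_series(labeled, "week")
  expect_equal(sum(wk$n[wk$label == "advertising"]), 2L)
  expect_equal(sum(wk$n[wk$label == "nonadvertising"]), 1L)

  sim <- generate_tweets(generator_config(n_tweets = 800, seed = 31))
  labels <- setNames(sim$truth$label, sim$truth$tweet_id)
  lab <- dplyr::mutate(sim$corpus, label = unname(labels[tweet_id]))
  for (bin in c("week", "year")) {
    ts <- time_series(lab, bin)
    expect_equal(sum(ts$n), nrow(lab))
  }
  # a gap week appears with zero count
  gap <- dplyr::mutate(
    mk_corpus(c("a", "b"),
              timestamp = as.POSIXct(c("2012-06-05", "2012-07-05"),
                                     tz = "UTC")),
    label = "advertising")
  wk2 <- time_series(gap, "week")
  expect_true(any(wk2$n == 0))
  expect_equal(sum(wk2$n), 2L)
})

test_that("yearly proportions of a generated corpus follow the volume weights", {
  sim <- generate_tweets(generator_config(n_tweets = 4000, seed = 17))
  labels <- setNames(sim$truth$label, sim$truth$tweet_id)
  lab <- dplyr::mutate(sim$corpus, label = unname(labels[tweet_id]))
  yr <- time_series(lab, "year") |>
    dplyr::count(period, wt = n, name = "n")
  weights <- c(82, 10870, 141405, 746541, 643900, 64734)
  p <- weights / sum(weights)
  phat <- yr$n[match(2008:2013, yr$period)] / sum(yr$n)
  phat[is.na(phat)] <- 0
  se <- sqrt(p * (1 - p) / 4000)
  expect_true(all(abs(phat - p) <= 3 * se + 1e-9))
})

test_that("promotion terms count per tweet, including the % off spelling", {
  ads <- mk_corpus(c(
    "Get 20% off at checkout with coupon code-twitter",
    "big discount today only",
    "no promo words here"
  ))
  counts <- count_promotions(ads)
  expect_equal(counts$n[counts$term == "coupon"], 1L)
  expect_equal(counts$n[counts$term == "percent off"], 1L)
  expect_equal(counts$n[counts$term == "discount"], 1L)
  expect_equal(counts$n[counts$term == "promotion"], 0L)
})

test_that("brand counting is word-bounded and any-brand counts tweets once", {
  corpus <- mk_corpus(c(
    "loving my blu ecig",
    "blue skies today",            # no word-boundary match for "blu"
    "blu and green smoke together"
  ))
  bc <- count_brands(corpus)
  expect_equal(bc$brands$n[bc$brands$brand == "blu"], 2L)
  expect_equal(bc$brands$n[bc$brands$brand == "Green Smoke"], 1L)
  expect_equal(bc$any_brand, 2L)
  expect_lte(bc$any_brand, sum(bc$brands$n))
  expect_true(all(bc$brands$n <= bc$any_brand))
})

test_that("handle and link rankings sort by count with lexicographic ties", {
  corpus <- mk_corpus(rep("x ecig", 7),
                      handle = c(rep("busy", 4), "bee", "bee", "ant"))
  top <- rank_handles(corpus, 3)
  expect_equal(top$handle, c("busy", "bee", "ant"))
  expect_equal(top$n, c(4L, 2L, 1L))
  tied <- mk_corpus(rep("x", 4), handle = c("zeta", "zeta", "alpha", "alpha"))
  expect_equal(rank_handles(tied, 2)$handle, c("alpha", "zeta"))

  ents <- extract_entities(mk_corpus(c(
    "go http://bit.ly/vapedeal", "go http://bit.ly/vapedeal",
    "go http://other.example.com/page"
  )))
  links <- rank_links(ents, 2)
  expect_equal(links$url[1], "http://vaporgod.example.com/shop")
  expect_equal(links$n[1], 2L)
})

test_that("the designated spam handle ranks first on the synthetic corpus", {
  sim <- generate_tweets(generator_config(n_tweets = 1500, seed = 23))
  labels <- setNames(sim$truth$label, sim$truth$tweet_id)
  ads <- sim$corpus[unname(labels[sim$corpus$tweet_id]) == "advertising", ]
  top <- rank_handles(ads, 1)
  spam_counts <- dplyr::count(
    sim$truth[sim$truth$archetype == "spammer", ], handle, sort = TRUE)
  expect_equal(top$handle, spam_counts$handle[1])
})

test_that("burst flagging fires on step jumps but not linear growth", {
  days <- seq(0, 300, by = 5)
  base_time <- as.POSIXct("2012-01-01", tz = "UTC")
  linear <- tibble::tibble(timestamp = base_time + days * 86400,
                           follower_count = 1000 + 50 * days)
  expect_equal(nrow(flag_follower_bursts(linear)), 0L)

  step <- tibble::tibble(timestamp = base_time + days * 86400,
                         follower_count = 1000 + 10000 * (days >= 150))
  flags <- flag_follower_bursts(step)
  expect_equal(nrow(flags), 1L)
  expect_gte(flags$gain, 10000)

  short <- linear[1:2, ]
  expect_warning(out <- flag_follower_bursts(short), "fewer than 3")
  expect_equal(nrow(out), 0L)
})

test_that("only the planted burst handle is flagged on the default synthetic corpus", {
  sim <- generate_tweets(generator_config(seed = 0))
  flagged <- suppressWarnings(flag_burst_handles(sim$corpus))
  expect_equal(flagged$handle, sim$burst_handle)
})

test_that("the surveillance summary is internally consistent", {
  sim <- generate_tweets(generator_config(n_tweets = 1000, seed = 29))
  labels <- setNames(sim$truth$label, sim$truth$tweet_id)
  lab <- dplyr::mutate(sim$corpus, label = unname(labels[tweet_id]))
  ents <- extract_entities(lab)
  summ <- summarize_surveillance(lab, entities = ents)
  expect_equal(sum(summ$class_counts$n), nrow(lab))
  # the two class shares sum to one (within the 2-decimal reporting grid)
  expect_lte(abs(sum(summ$class_counts$pct) - 100), 0.011)
  expect_equal(sum(summ$yearly_counts$n), nrow(lab))
  long <- tidy(summ)
  expect_true(all(c("section", "item", "n", "pct") %in% names(long)))
  expect_true(all(long$pct >= 0 & long$pct <= 100, na.rm = TRUE))
})
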