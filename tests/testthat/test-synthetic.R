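# Synthetic corpus generator: determinism, truth consistency, calibration.

test_that("a fixed seed gives byte-identical output", {
  a <- generate_tweets(generator_config(n_tweets = 250, seed = 7))
  b <- generate_tweets(generator_config(n_tweets = 250, seed = 7))
  expect_identical(a, b)
  c <- generate_tweets(generator_config(n_tweets = 250, seed = 8))
  expect_false(identical(a$corpus$text, c$corpus$text))
})

test_that("ground truth is consistent with the emitted text", {
  sim <- generate_tweets(generator_config(n_tweets = 800, seed = 13))
  with_brand <- which(lengths(sim$truth$brands) > 0)
  for (i in with_brand) {
    for (b in sim$truth$brands[[i]]) {
      expect_match(tolower(sim$corpus$text[i]), tolower(b), fixed = TRUE)
    }
  }
  with_place <- which(!is.na(sim$truth$place_category))
  for (i in with_place) {
    expect_match(sim$corpus$text[i], sim$truth$place_phrase[i], fixed = TRUE)
  }
  with_coupon <- which(sim$truth$has_coupon)
  expect_true(all(grepl("coupon", sim$corpus$text[with_coupon])))
})

test_that("generator marginals are recovered within three standard errors", {
  cfg <- generator_config(n_tweets = 10000, seed = 42)
  sim <- generate_tweets(cfg)
  tr <- sim$truth

  check3se <- function(phat, p, n) {
    se <- sqrt(p * (1 - p) / n)
    expect_lte(abs(phat - p), 3 * se + 1e-12)
  }
  n <- nrow(tr)
  check3se(mean(tr$label == "advertising"), cfg$advertising_fraction, n)

  ads <- tr$label == "advertising"
  rt <- setNames(sim$corpus$is_retweet, sim$corpus$tweet_id)[tr$tweet_id]
  check3se(mean(rt[ads]), cfg$retweet_prob_ad, sum(ads))
  check3se(mean(rt[!ads]), cfg$retweet_prob_nonad, sum(!ads))
  check3se(mean(tr$has_coupon[ads]), cfg$coupon_prob, sum(ads))
  check3se(mean(tr$has_percent_off[ads]), cfg$percent_off_prob, sum(ads))
  check3se(mean(tr$has_discount[ads]), cfg$discount_prob, sum(ads))
  check3se(mean(tr$has_promotion[ads]), cfg$promotion_prob, sum(ads))
  for (b in names(cfg$brand_probs)) {
    phat <- mean(vapply(tr$brands[ads], function(x) b %in% x, logical(1)))
    check3se(phat, cfg$brand_probs[[b]], sum(ads))
  }
  check3se(mean(!is.na(tr$place_category[!ads])), cfg$place_mention_prob,
           sum(!ads))
})

test_that("the place-category distribution matches its configuration", {
  cfg <- generator_config(n_tweets = 3000, advertising_fraction = 0,
                          place_mention_prob = 1, seed = 3)
  sim <- generate_tweets(cfg)
  tab <- table(factor(sim$truth$place_category,
                      levels = names(cfg$place_distribution)))
  phat <- as.numeric(tab) / sum(tab)
  p <- unname(cfg$place_distribution)
  se <- sqrt(p * (1 - p) / sum(tab))
  expect_true(all(abs(phat - p) <= 3 * se + 1e-9))
})

test_that("training samples honor size, mix, seed, and feasibility", {
  sim <- generate_tweets(generator_config(n_tweets = 2500, seed = 19))
  lab <- make_training_sample(sim$corpus, sim$truth, seed = 4)
  expect_equal(nrow(lab), 507L)
  expect_equal(sum(lab$label == "advertising"), 395L)
  expect_true(all(lab$label_source == "synthetic"))
  lab2 <- make_training_sample(sim$corpus, sim$truth, seed = 4)
  expect_identical(lab, lab2)

  small <- make_training_sample(sim$corpus, sim$truth, n = 10,
                                ad_fraction = 0.5, seed = 1)
  expect_equal(unname(table(small$label)["advertising"]), 5L)
  expect_error(
    make_training_sample(sim$corpus, sim$truth, n = 5000, ad_fraction = 0.1,
                         seed = 1),
    "infeasible")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(advertising_fraction = 1.4), "0, 1")
  expect_error(generator_config(n_tweets = 0), "positive")
  bad_dist <- setNames(rep(0.1, 20), vapewatch:::PLACE_CATEGORIES)
  expect_error(generator_config(place_distribution = bad_dist), "sum to 1")
})
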