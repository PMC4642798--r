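# Seeded synthetic tweet corpora with known ground truth.
#
# Text is template-based, never free-form: every planted signal (class,
# brand, promotion term, place phrase) is known exactly, so each pipeline
# stage can be scored against truth. Advertising tweets are storefront
# promos (flavor + percent-off + coupon code + link) or promotional phrases
# buried in nonsense word salad, the two archetypes observed among real
# e-cigarette spam; nonadvertising tweets are personal usage reports, a
# small fraction carrying a usage verb plus an in/at/on place phrase drawn
# from the place-category distribution. Account metadata follows handle
# archetypes: affiliate spammers (huge statuses counts, few followers),
# vendors (steadily growing followers), one vendor with a step-burst
# follower jump, and consumers.

PLACE_CATEGORIES <- c(
  "class", "house/room/in bed", "school", "public place", "bathroom",
  "work", "in front of someone", "car", "restaurant", "movie theater",
  "airplanes/airport", "store", "bars/clubs", "dormitory", "library",
  "mall", "bowling alley", "cafe/coffee shop", "hospital", "locker room"
)

# Observed category counts among the 471 published place tweets; the
# default place distribution is proportional to these.
PLACE_REFERENCE_COUNTS <- c(184, 59, 57, 41, 27, 21, 12, 11, 10, 9, 8, 7, 6,
                            6, 4, 3, 2, 2, 1, 1)

PLACE_PHRASES <- c(
  "class" = "in class",
  "house/room/in bed" = "in my room",
  "school" = "at school",
  "public place" = "in public",
  "bathroom" = "in the bathroom",
  "work" = "at work",
  "in front of someone" = "in front of everyone",
  "car" = "in the car",
  "restaurant" = "in a restaurant",
  "movie theater" = "at the movies",
  "airplanes/airport" = "on the plane",
  "store" = "in the store",
  "bars/clubs" = "at the bar",
  "dormitory" = "in my dorm",
  "library" = "in the library",
  "mall" = "at the mall",
  "bowling alley" = "at the bowling alley",
  "cafe/coffee shop" = "in a coffee shop",
  "hospital" = "in the hospital",
  "locker room" = "in the locker room"
)

YEAR_REFERENCE_COUNTS <- c("2008" = 82, "2009" = 10870, "2010" = 141405,
                           "2011" = 746541, "2012" = 643900, "2013" = 64734)

#' Configuration of the synthetic tweet generator
#'
#' Defaults are the documented marginal rates of the surveilled corpus:
#' 93.43% advertising; retweet rates 28.7% (advertising) and 11.6%
#' (nonadvertising); promotion-term rates of 9.8% / 7.69% / 7.61% / 0.89%
#' (promotion, coupon, percent off, discount) among advertising tweets;
#' brand-mention rates from the published per-brand shares; 0.43% of
#' nonadvertising tweets carrying a place-of-use phrase, distributed over
#' the 20 place categories proportionally to the published counts; and
#' yearly tweet volumes over 2008-07-01..2013-02-28 proportional to the
#' published yearly counts.
#'
#' @param n_tweets Corpus size.
#' @param advertising_fraction Fraction of topical tweets that advertise.
#' @param retweet_prob_ad,retweet_prob_nonad Retweet probability per class.
#' @param promotion_prob,coupon_prob,percent_off_prob,discount_prob
#'   Promotion-term probabilities among advertising tweets.
#' @param brand_probs Named per-brand mention probabilities for advertising
#'   tweets.
#' @param brand_probs_nonad Named per-brand mention probabilities for
#'   nonadvertising tweets.
#' @param place_mention_prob Fraction of nonadvertising tweets carrying a
#'   place phrase.
#' @param place_distribution Named probabilities over the 20 place
#'   categories (must sum to 1).
#' @param ad_url_prob,nonad_url_prob Probability that a tweet carries a
#'   link.
#' @param offtopic_fraction Fraction of tweets about other topics (no
#'   e-cigarette keyword); useful for exercising the keyword filter.
#' @param spam_handle_count Number of affiliate-spammer handles.
#' @param vendor_handle_count Number of steady-growth vendor handles (one
#'   additional vendor handle always carries a step-burst follower jump).
#' @param date_range Character vector `c(start, end)` of the posting window.
#' @param year_weights Named yearly volume weights.
#' @param seed Integer seed; a fixed seed makes [generate_tweets()] output
#'   byte-identical across runs.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_tweets = 2000L,
                             advertising_fraction = 0.9343,
                             retweet_prob_ad = 0.287,
                             retweet_prob_nonad = 0.116,
                             promotion_prob = 0.098,
                             coupon_prob = 0.0769,
                             percent_off_prob = 0.0761,
                             discount_prob = 0.0089,
                             brand_probs = c("blu" = 0.0599, "V2" = 0.0205,
                                             "Green Smoke" = 0.0178,
                                             "Premium" = 0.0071,
                                             "Luci" = 0.0060),
                             brand_probs_nonad = c("blu" = 0.0089,
                                                   "Vapor4Life" = 0.0073,
                                                   "Volcano" = 0.0066,
                                                   "NicStick" = 0.0055,
                                                   "eSmoke" = 0.0028),
                             place_mention_prob = 0.0043,
                             place_distribution = NULL,
                             ad_url_prob = 0.9,
                             nonad_url_prob = 0.05,
                             offtopic_fraction = 0,
                             spam_handle_count = 5L,
                             vendor_handle_count = 3L,
                             date_range = c("2008-07-01", "2013-02-28"),
                             year_weights = YEAR_REFERENCE_COUNTS,
                             seed = 0L) {
  if (is.null(place_distribution)) {
    place_distribution <- setNames(
      PLACE_REFERENCE_COUNTS / sum(PLACE_REFERENCE_COUNTS), PLACE_CATEGORIES)
  }
  cfg <- list(
    n_tweets = as.integer(n_tweets),
    advertising_fraction = advertising_fraction,
    retweet_prob_ad = retweet_prob_ad,
    retweet_prob_nonad = retweet_prob_nonad,
    promotion_prob = promotion_prob,
    coupon_prob = coupon_prob,
    percent_off_prob = percent_off_prob,
    discount_prob = discount_prob,
    brand_probs = brand_probs,
    brand_probs_nonad = brand_probs_nonad,
    place_mention_prob = place_mention_prob,
    place_distribution = place_distribution,
    ad_url_prob = ad_url_prob,
    nonad_url_prob = nonad_url_prob,
    offtopic_fraction = offtopic_fraction,
    spam_handle_count = as.integer(spam_handle_count),
    vendor_handle_count = as.integer(vendor_handle_count),
    date_range = date_range,
    year_weights = year_weights,
    seed = as.integer(seed)
  )
  probs <- c(cfg$advertising_fraction, cfg$retweet_prob_ad,
             cfg$retweet_prob_nonad, cfg$promotion_prob, cfg$coupon_prob,
             cfg$percent_off_prob, cfg$discount_prob, cfg$brand_probs,
             cfg$brand_probs_nonad, cfg$place_mention_prob,
             cfg$place_distribution, cfg$ad_url_prob, cfg$nonad_url_prob,
             cfg$offtopic_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("generator_config: all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$place_distribution) - 1) > 1e-8) {
    abort("generator_config: place_distribution must sum to 1")
  }
  if (cfg$n_tweets < 1) abort("generator_config: n_tweets must be positive")
  if (!setequal(names(cfg$place_distribution), PLACE_CATEGORIES)) {
    abort("generator_config: place_distribution must cover the 20 categories")
  }
  structure(cfg, class = "generator_config")
}

with_local_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(code)
}

SALAD_WORDS <- c("bass", "viol", "brace", "healthiness", "tabulate",
                 "marquee", "gadfly", "sonata", "pretzel", "lantern",
                 "cobweb", "meadow", "quartz", "ribbon", "saddle", "thimble")

PROMO_FLAVORS <- c("vanilla cupcake", "mint chocolate", "mango", "cherry",
                   "espresso", "menthol", "apple pie", "caramel",
                   "strawberry", "peach")

AD_URLS <- c("http://bit.ly/vapedeal", "http://bit.ly/ecigkit",
             "http://t.co/blusale", "http://tinyurl.com/sbsmoke",
             "http://ow.ly/v2promo", "http://vaporgod.example.com/shop",
             "http://ecigreviewhub.example.com/best")

NONAD_TEMPLATES <- c(
  "just tried an ecig for the first time and i kind of like it",
  "thinking about switching to vaping for good",
  "my ecig battery died again ugh",
  "vaping has honestly helped me cut back so much",
  "anyone know a good ecig flavor to try",
  "this ecig tastes like mint heaven",
  "day three with the ecig and no analogs",
  "might get a new ecig this weekend"
)

PLACE_OPENERS <- c("caught my friend", "this guy is",
                   "cant believe my roommate is", "someone was",
                   "my neighbor keeps", "she was just", "two kids were",
                   "dude next to me is")

PLACE_VERBS <- c("vaping", "smoking his ecig", "vaping her ecig",
                 "smoking an ecig")

PLACE_CLOSERS <- c("", " smh", " lol", " again", " #wtf", " so strange")

OFFTOPIC_TEMPLATES <- c(
  "had a great day at the gym this morning",
  "traffic on the highway is terrible today",
  "cannot wait for the game tonight",
  "new phone battery lasts forever somehow",
  "coffee first then everything else",
  "weekend plans are finally coming together"
)

year_window <- function(year, date_range) {
  start <- max(as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC"),
               as.POSIXct(paste0(date_range[1], " 00:00:00"), tz = "UTC"))
  end <- min(as.POSIXct(paste0(year, "-12-31 23:59:59"), tz = "UTC"),
             as.POSIXct(paste0(date_range[2], " 23:59:59"), tz = "UTC"))
  c(start, end)
}

#' Generate a synthetic tweet corpus with ground truth
#'
#' @param config A [generator_config()].
#' @return A list with `corpus` (a corpus tibble, ordered by timestamp) and
#'   `truth` (one row per tweet: `tweet_id`, `is_topical`, `label`,
#'   `archetype`, `handle`, `brands` list-column, the planted promotion
#'   flags, `place_category`, `place_phrase`). A fixed seed gives
#'   byte-identical output.
#' @export
#' @examples
#' sim <- generate_tweets(generator_config(n_tweets = 50, seed = 7))
#' dplyr::count(sim$truth, label)
generate_tweets <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- config$n_tweets

    is_offtopic <- runif(n) < config$offtopic_fraction
    is_ad <- !is_offtopic & runif(n) < config$advertising_fraction
    label <- ifelse(is_offtopic, NA_character_,
                    ifelse(is_ad, "advertising", "nonadvertising"))

    # timestamps: year drawn by volume weight, uniform within the year's
    # window clipped to the date range
    years <- as.integer(names(config$year_weights))
    yr <- sample(years, n, replace = TRUE,
                 prob = config$year_weights / sum(config$year_weights))
    ts <- as.POSIXct(vapply(yr, function(y) {
      w <- year_window(y, config$date_range)
      as.numeric(w[1]) + runif(1) * (as.numeric(w[2]) - as.numeric(w[1]))
    }, numeric(1)), tz = "UTC", origin = "1970-01-01")
    ts <- as.POSIXct(floor(as.numeric(ts)), tz = "UTC",
                     origin = "1970-01-01")

    # handle pools per archetype
    rand_chars <- function(k, len) {
      vapply(seq_len(k), function(i) {
        paste(sample(c(letters, 0:9), len, replace = TRUE), collapse = "")
      }, character(1))
    }
    spam_handles <- paste0("zq", rand_chars(config$spam_handle_count, 8))
    vendor_handles <- paste0(
      c("vaporgod_shop", "ecigdeals_net", "cloudvape_store",
        paste0("vendor", seq_len(max(0, config$vendor_handle_count - 3)),
               "_shop"))[seq_len(config$vendor_handle_count)])
    burst_handle <- "vapekingdom_promo"
    affiliate_handles <- paste0("ecignews", rand_chars(8, 4))
    n_consumers <- max(50L, ceiling(n / 8))
    consumer_handles <- sprintf("%s%04d",
                                sample(c("vapefan", "cloudchaser", "quitter",
                                         "ecigcurious", "mistyvaper"),
                                       n_consumers, replace = TRUE),
                                seq_len(n_consumers))

    archetype <- character(n)
    handle <- character(n)
    ad_idx <- which(is_ad)
    archetype[ad_idx] <- sample(c("spammer", "vendor", "affiliate"),
                                length(ad_idx), replace = TRUE,
                                prob = c(0.45, 0.35, 0.20))
    sp <- ad_idx[archetype[ad_idx] == "spammer"]
    handle[sp] <- sample(spam_handles, length(sp), replace = TRUE,
                         prob = c(0.35, rep(0.65 / (length(spam_handles) - 1),
                                            length(spam_handles) - 1)))
    vd <- ad_idx[archetype[ad_idx] == "vendor"]
    vendor_pool <- c(vendor_handles, burst_handle)
    handle[vd] <- sample(vendor_pool, length(vd), replace = TRUE)
    af <- ad_idx[archetype[ad_idx] == "affiliate"]
    handle[af] <- sample(affiliate_handles, length(af), replace = TRUE)
    co <- which(!is_ad)
    archetype[co] <- "consumer"
    handle[co] <- sample(consumer_handles, length(co), replace = TRUE)

    # planted signals
    has_promotion <- is_ad & runif(n) < config$promotion_prob
    has_coupon <- is_ad & runif(n) < config$coupon_prob
    has_percent_off <- is_ad & runif(n) < config$percent_off_prob
    has_discount <- is_ad & runif(n) < config$discount_prob

    nonad_idx <- which(!is_ad & !is_offtopic)
    has_place <- rep(FALSE, n)
    has_place[nonad_idx] <- runif(length(nonad_idx)) < config$place_mention_prob
    place_category <- rep(NA_character_, n)
    place_category[has_place] <- sample(
      names(config$place_distribution), sum(has_place), replace = TRUE,
      prob = config$place_distribution)
    place_phrase <- ifelse(has_place, PLACE_PHRASES[place_category],
                           NA_character_)

    plant_brands <- function(idx, probs) {
      out <- vector("list", n)
      for (b in names(probs)) {
        hit <- idx[runif(length(idx)) < probs[[b]]]
        for (i in hit) out[[i]] <- c(out[[i]], b)
      }
      out
    }
    brands <- plant_brands(ad_idx, config$brand_probs)
    # place tweets use the place template, so brands are planted only on
    # non-place nonadvertising tweets (truth must match the emitted text)
    brands_nonad <- plant_brands(which(!is_ad & !is_offtopic & !has_place),
                                 config$brand_probs_nonad)
    for (i in seq_len(n)) {
      b <- brands[[i]] %||% brands_nonad[[i]] %||% character(0)
      brands[i] <- list(b)
    }

    has_url <- ifelse(is_ad, runif(n) < config$ad_url_prob,
                      !is_offtopic & runif(n) < config$nonad_url_prob)
    url <- ifelse(has_url, sample(AD_URLS, n, replace = TRUE), "")
    # the dominant spam handle pushes a single destination relentlessly
    url[has_url & handle == spam_handles[1]] <- AD_URLS[1]

    # text assembly
    text <- character(n)
    salad <- is_ad & (archetype != "vendor") & runif(n) < 0.7
    for (i in seq_len(n)) {
      if (is_offtopic[i]) {
        text[i] <- sample(OFFTOPIC_TEMPLATES, 1)
      } else if (is_ad[i]) {
        base <- if (salad[i]) {
          w <- sample(SALAD_WORDS, 3)
          paste0("Buy electronic smoke the e cigarette ", w[1], " ", w[2],
                 " safeguarding ", w[3], " the healthiness but the",
                 " e-cigarettes on sale")
        } else {
          paste0("Try our great-tasting ", sample(PROMO_FLAVORS, 1),
                 " flavored ecigarette eliquid!")
        }
        bits <- c(
          if (has_percent_off[i]) paste0(" Get ", sample(c(10, 15, 20, 25), 1),
                                         "% off at checkout"),
          if (has_coupon[i]) " with coupon code twitter",
          if (has_discount[i]) " big discount today",
          if (has_promotion[i]) " special promotion this week",
          if (length(brands[[i]]) > 0) {
            paste0(" get your ", paste(brands[[i]], collapse = " and "),
                   " starter kit")
          },
          if (nzchar(url[i])) paste0(" ", url[i])
        )
        text[i] <- paste0(base, paste(bits, collapse = ""))
      } else {
        base <- if (has_place[i]) {
          paste0(sample(PLACE_OPENERS, 1), " ", sample(PLACE_VERBS, 1), " ",
                 place_phrase[i], sample(PLACE_CLOSERS, 1))
        } else if (length(brands[[i]]) > 0) {
          paste0("my ", paste(brands[[i]], collapse = " and "),
                 " ecig is actually pretty great")
        } else {
          sample(NONAD_TEMPLATES, 1)
        }
        text[i] <- paste0(base, if (nzchar(url[i])) paste0(" ", url[i]))
      }
    }

    is_retweet <- runif(n) < ifelse(is_ad, config$retweet_prob_ad,
                                    ifelse(is_offtopic, 0.05,
                                           config$retweet_prob_nonad))

    # metadata per handle archetype
    all_handles <- c(spam_handles, vendor_handles, burst_handle,
                     affiliate_handles, consumer_handles)
    base_followers <- setNames(numeric(length(all_handles)), all_handles)
    base_followers[spam_handles] <- round(runif(length(spam_handles), 100, 1500))
    base_followers[vendor_handles] <- 2000
    base_followers[burst_handle] <- 400
    base_followers[affiliate_handles] <-
      round(runif(length(affiliate_handles), 300, 3000))
    base_followers[consumer_handles] <-
      round(exp(rnorm(length(consumer_handles), 5.5, 1)))
    base_statuses <- setNames(numeric(length(all_handles)), all_handles)
    base_statuses[spam_handles] <- round(runif(length(spam_handles), 5e4, 15e4))
    base_statuses[c(vendor_handles, burst_handle)] <-
      round(runif(length(vendor_handles) + 1, 1e4, 8e4))
    base_statuses[affiliate_handles] <-
      round(runif(length(affiliate_handles), 5e3, 4e4))
    base_statuses[consumer_handles] <-
      round(runif(length(consumer_handles), 300, 2e4))
    base_following <- setNames(numeric(length(all_handles)), all_handles)
    base_following[spam_handles] <- round(runif(length(spam_handles), 2e3, 2e4))
    base_following[c(vendor_handles, burst_handle)] <-
      round(runif(length(vendor_handles) + 1, 100, 2000))
    base_following[affiliate_handles] <-
      round(runif(length(affiliate_handles), 500, 5e3))
    base_following[consumer_handles] <-
      round(runif(length(consumer_handles), 50, 1500))
    vendor_total_growth <- setNames(
      8000 + 2000 * seq_along(vendor_handles), vendor_handles)

    # posting rank within handle (by time) drives statuses counts and the
    # vendors' steady follower growth
    ord <- order(ts)
    rank_in_handle <- integer(n)
    rank_in_handle[ord] <- ave(seq_along(ord), handle[ord],
                               FUN = seq_along)
    n_by_handle <- table(handle)

    follower_count <- base_followers[handle]
    for (v in vendor_handles) {
      idx <- which(handle == v)
      if (length(idx) > 0) {
        follower_count[idx] <- base_followers[v] +
          round(rank_in_handle[idx] * vendor_total_growth[v] /
                  max(1, n_by_handle[[v]]))
      }
    }
    burst_time <- as.POSIXct("2011-11-15 00:00:00", tz = "UTC")
    bidx <- which(handle == burst_handle)
    follower_count[bidx] <- base_followers[burst_handle] +
      ifelse(ts[bidx] >= burst_time, 12000, 0)
    statuses_count <- base_statuses[handle] + rank_in_handle

    corpus <- tibble(
      tweet_id = sprintf("syn%07d", seq_len(n)),
      handle = unname(handle),
      timestamp = ts,
      text = text,
      follower_count = as.integer(unname(follower_count)),
      following_count = as.integer(unname(base_following[handle])),
      statuses_count = as.integer(unname(statuses_count)),
      is_retweet = is_retweet
    )
    truth <- tibble(
      tweet_id = corpus$tweet_id,
      is_topical = !is_offtopic,
      label = label,
      archetype = archetype,
      handle = corpus$handle,
      brands = brands,
      has_promotion = has_promotion,
      has_coupon = has_coupon,
      has_percent_off = has_percent_off,
      has_discount = has_discount,
      has_url = has_url,
      place_category = place_category,
      place_phrase = place_phrase
    )
    o <- order(corpus$timestamp, corpus$tweet_id)
    list(corpus = tweet_corpus(corpus[o, ]), truth = truth[o, ],
         burst_handle = burst_handle)
  })
}

#' Draw a labeled training sample from a synthetic corpus
#'
#' Emulates manual coding of a random subset: a stratified sample with a
#' requested class mix, labeled from ground truth with
#' `label_source = "synthetic"`. The default mix matches the published
#' training set: 507 tweets, 78% advertising.
#'
#' @param corpus,truth A [generate_tweets()] result's components.
#' @param n Sample size.
#' @param ad_fraction Fraction of the sample that is advertising
#'   (`round(n * ad_fraction)` tweets).
#' @param seed Integer seed.
#' @return A labeled corpus tibble of `n` rows with `label` and
#'   `label_source` columns.
#' @export
make_training_sample <- function(corpus, truth, n = 507L, ad_fraction = 0.78,
                                 seed = 0L) {
  n <- as.integer(n)
  n_ad <- as.integer(round(n * ad_fraction))
  n_nonad <- n - n_ad
  ad_ids <- truth$tweet_id[!is.na(truth$label) & truth$label == "advertising"]
  nonad_ids <- truth$tweet_id[!is.na(truth$label) &
                                truth$label == "nonadvertising"]
  if (length(ad_ids) < n_ad || length(nonad_ids) < n_nonad) {
    abort(paste0("infeasible class mix: need ", n_ad, " advertising and ",
                 n_nonad, " nonadvertising tweets, have ", length(ad_ids),
                 " and ", length(nonad_ids)))
  }
  with_local_seed(seed, {
    ids <- sample(c(sample(ad_ids, n_ad), sample(nonad_ids, n_nonad)))
    labels <- setNames(truth$label, truth$tweet_id)
    corpus |>
      filter(.data$tweet_id %in% ids) |>
      mutate(label = unname(labels[.data$tweet_id]),
             label_source = "synthetic")
  })
}
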