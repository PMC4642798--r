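# Place-of-use extraction: usage filter, cleaning, tagging, chunking,
# filtering, categorization.

test_that("usage filter matches the six inflected forms plus infinitives only", {
  corpus <- mk_corpus(c(
    "my teacher yells at me everyday for vaping in class",
    "I love my vape pen",
    "he smokes his ecig at work",
    "able to smoke in my room again",
    "smoke detectors everywhere"      # bare noun use, not infinitive
  ))
  kept <- usage_filter(corpus)
  expect_equal(kept$tweet_id, c("t001", "t003", "t004"))
})

test_that("cleaning strips mentions, hashtags, interjections and expands slang in order", {
  expect_equal(clean_tweet("Vaping in the bathroom #whatofit"),
               "Vaping in the bathroom")
  expect_equal(clean_tweet("lol smh vaping in class"), "vaping in class")
  expect_equal(clean_tweet("ur vaping at work"), "you're vaping at work")
  expect_equal(clean_tweet("@buddy vaping in class"), "vaping in class")
  # non-person "in front of" is subordinate; person objects survive
  expect_equal(clean_tweet("vaping in front of the store"), "vaping")
  expect_equal(clean_tweet("vaping in front of my mom"),
               "vaping in front of my mom")
})

test_that("the tagger emits Penn tags deterministically", {
  tags <- pos_tag("vaping in class")
  expect_equal(tags$tag[tags$token == "in"], "IN")
  expect_equal(tags$tag[tags$token == "vaping"], "VBG")
  expect_equal(nrow(pos_tag("")), 0L)
  # head nouns of the quoted tweets tag as nouns
  for (row in seq_len(nrow(quoted_place_tweets()))) {
    text <- clean_tweet(quoted_place_tweets()$text[row])
    tags <- pos_tag(text)
    heads <- c("class", "bathroom", "room", "office")
    expect_true(any(startsWith(tags$tag[tags$token %in% heads], "NN")))
  }
})

test_that("chunking collects objects up to the next verb, preposition or wh-adverb", {
  ph <- chunk_prepositional_phrases(
    pos_tag("smoking an electronic cigarette in class"))
  expect_equal(ph$preposition, "in")
  expect_equal(ph$object[[1]], "class")

  ph2 <- chunk_prepositional_phrases(
    pos_tag("vaping in class when nobody watches"))
  expect_equal(ph2$object[[1]], "class")  # stops before the wh-adverb

  ph3 <- chunk_prepositional_phrases(pos_tag("smoking in my room again doe !"))
  expect_equal(ph3$object[[1]], c("my", "room", "again", "doe"))
})

test_that("only in/at/on phrases survive the preposition filter, order kept", {
  tagged <- pos_tag("vaped around campus during lunch at work in class")
  ph <- chunk_prepositional_phrases(tagged)
  kept <- filter_prepositions(ph)
  expect_equal(kept$preposition, c("at", "in"))
})

test_that("phrases headed by non-location nouns are excluded", {
  keep_or_drop <- function(text) {
    nrow(filter_non_locations(
      chunk_prepositional_phrases(pos_tag(text))))
  }
  expect_equal(keep_or_drop("vaping at night"), 0L)
  expect_equal(keep_or_drop("vaping in life"), 0L)
  expect_equal(keep_or_drop("vaping in class"), 1L)
})

test_that("place categorization maps heads and multiword synonyms", {
  expect_equal(categorize_place(c("my", "room")), "house/room/in bed")
  expect_equal(categorize_place(c("the", "bathroom")), "bathroom")
  expect_equal(categorize_place(c("my", "office")), "work")
  expect_equal(categorize_place(c("the", "locker", "room")), "locker room")
  expect_equal(categorize_place(c("a", "coffee", "shop")), "cafe/coffee shop")
  expect_equal(categorize_place("zorblax"), "uncategorized")
})

test_that("the full pipeline recovers the documented categories of the quoted tweets", {
  q <- quoted_place_tweets()
  corpus <- mk_corpus(q$text)
  mentions <- extract_places(corpus)
  expect_equal(nrow(mentions), nrow(q))
  expect_equal(mentions$category, q$expected_category)
  expect_true(all(mentions$preposition %in% c("in", "at", "on")))
})

test_that("each tweet contributes at most one mention and percentages sum to 100", {
  corpus <- mk_corpus(c(
    "vaping in class then at work",          # two candidate phrases
    "smoking his ecig in the bathroom",
    "vaping at school"
  ))
  mentions <- extract_places(corpus)
  expect_equal(nrow(mentions), 3L)
  expect_equal(anyDuplicated(mentions$tweet_id), 0L)
  tab <- place_table(mentions)
  expect_lte(abs(sum(tab$pct) - 100), 0.1)
})

test_that("a corpus without usage verbs yields an empty table", {
  corpus <- mk_corpus(c("my ecig is great", "new vape pen day"))
  mentions <- extract_places(corpus)
  expect_equal(nrow(mentions), 0L)
  expect_equal(nrow(place_table(mentions)), 0L)
})

test_that("planted place categories are recovered for at least 90% of template tweets", {
  cfg <- generator_config(n_tweets = 400, advertising_fraction = 0,
                          place_mention_prob = 1, seed = 11)
  sim <- generate_tweets(cfg)
  mentions <- extract_places(sim$corpus)
  joined <- dplyr::inner_join(
    mentions, sim$truth[, c("tweet_id", "place_category")], by = "tweet_id")
  expect_gte(nrow(joined) / nrow(sim$corpus), 0.9)
  expect_gte(mean(joined$category == joined$place_category), 0.9)
})
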