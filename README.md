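# vapewatch

Infoveillance of e-cigarette marketing and places of use in tweet corpora.

E-cigarette vendors, affiliate marketers and spam bots advertise openly on
Twitter, and consumers tweet about using e-cigarettes in classrooms,
offices and other smoke-free places. Both signals matter to tobacco-control
researchers and regulators, and neither is available from any registry.
`vapewatch` is a tidyverse-style R package that turns a raw tweet table
into surveillance outputs:

* **Topical filtering** — an editable include/exclude keyword syntax
  defines "tweets about e-cigarettes" (word-boundary matching for tokens,
  substring matching for phrases).
* **Advertising classification** — binary presence features for every
  n-gram of length 1–4, x<sub>ij</sub> ∈ {0,1}, plus five metadata features
  (follower, following and statuses counts at time of tweet, has-URL,
  retweet flag); features with zero impurity importance in an
  extremely-randomized-trees ensemble are discarded; a 10-tree random
  forest is scored by stratified 10-fold cross-validation against the
  majority-class baseline (accuracy, pooled precision/recall with
  advertising as positive class).
* **Place-of-use extraction** — from nonadvertising tweets with an active
  usage verb (*smoking, vaping, smokes, vapes, smoked, vaped*), after
  rule-based cleaning and part-of-speech tagging, prepositional phrases
  are chunked (preposition + tokens up to the next verb, preposition,
  wh-adverb or punctuation), restricted to *in/at/on*, filtered against
  non-location head nouns ("at night", "in life"), and mapped through a
  synonym lexicon onto 20 place categories.
* **Surveillance aggregates** — weekly/yearly series by class, retweet,
  promotion and brand shares (`share(n, d) = 100·n/d` to 2 decimals), most
  active handles, most shared (unshortened) links, and follower-growth
  burst flags (window gain > 10× the handle's median 30-day gain).
* **Synthetic corpora** — a seeded generator with per-tweet ground truth
  reproducing the documented corpus marginals, so the whole pipeline is
  testable offline.

## Worked example

```r
library(vapewatch)

sim     <- generate_tweets(generator_config(n_tweets = 2000, seed = 1))
labeled <- make_training_sample(sim$corpus, sim$truth,
                                n = 507, ad_fraction = 0.78, seed = 1)
report  <- run_pipeline(sim$corpus, labeled, k = 10, seed = 1)

report$stage_counts
#> # A tibble: 4 × 3
#>   stage     n_in n_out
#> 1 filter    2000  2000
#> 2 entities  2000  2000
#> 3 classify  2000  2000
#> 4 places     137     2

glance(report$cv_report)
#>   mean_cv_accuracy baseline_accuracy precision recall n_features_initial n_features_selected
#> 1                1         0.7790927         1      1               1931                 256
```

Cross-validated accuracy is 1 on this synthetic corpus because the planted
advertising signals (coupon codes, price templates, links, spam metadata)
are fully separable — the corpus is a correctness harness, not a difficulty
benchmark. The baseline 0.779 is the majority-class prevalence of the
507-tweet training sample (78% advertising); 256 of 1,931 features carry
nonzero screening importance.

Place extraction on a real quoted tweet:

```r
quoted <- tweet_corpus(tibble::tibble(
  tweet_id = "q1", handle = "observer",
  timestamp = as.POSIXct("2012-06-01", tz = "UTC"),
  text = "Is this guy really smoking an electronic cigarette in class? #Yes #wtf",
  follower_count = 1L, following_count = 1L, statuses_count = 1L,
  is_retweet = FALSE))
extract_places(quoted)
#>   tweet_id preposition object category
#> 1       q1          in  class    class
```

Burst detection singles out the planted purchased-follower handle:

```r
flag_burst_handles(sim$corpus)
#> # A tibble: 1 × 2
#>   handle            n_flagged_windows
#> 1 vapekingdom_promo                 1
```

And the single rounding point of all reported percentages:

```r
share(1559508, 1669123)
#> [1] 93.43
```

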