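# Featurization, feature selection, forest fitting, cross-validation.

test_that("featurization enumerates all n-grams up to length 4 plus 5 metadata columns", {
  corpus <- mk_corpus("alpha bravo charlie delta echo")
  f <- featurize_tweets(corpus, fit = TRUE)
  # 5 unigrams + 4 bigrams + 3 trigrams + 2 four-grams = 14
  expect_length(f$vocabulary, 14L)
  expect_equal(ncol(f$matrix), 14L + 5L)
  expect_true(all(f$matrix[, seq_len(14)] %in% c(0, 1)))
})

test_that("presence encoding is binary even for repeated tokens", {
  corpus <- mk_corpus("buzz buzz buzz")
  f <- featurize_tweets(corpus, fit = TRUE)
  expect_equal(max(f$matrix[, match("buzz", f$vocabulary)]), 1)
})

test_that("metadata block ends with has_url and is_retweet indicators", {
  corpus <- mk_corpus("deal here http://x.example.com/p", is_retweet = TRUE)
  f <- featurize_tweets(corpus, fit = TRUE)
  p <- ncol(f$matrix)
  expect_equal(unname(as.vector(f$matrix[1, (p - 1):p])), c(1, 1))
})

test_that("transform with a fixed vocabulary introduces no new columns", {
  train <- mk_corpus(c("known words here", "more known text"))
  f <- featurize_tweets(train, fit = TRUE)
  test <- mk_corpus("entirely novel vocabulary appears")
  ft <- featurize_tweets(test, fit = FALSE, vocabulary = f$vocabulary)
  expect_equal(ncol(ft$matrix), ncol(f$matrix))
  expect_equal(sum(ft$matrix[, seq_along(f$vocabulary)]), 0)
})

test_that("selection keeps a subset, never a constant column, and finds the separating token", {
  set.seed(3)
  n <- 80
  texts <- ifelse(seq_len(n) <= n / 2,
                  paste("coupon deal", sample(c("now", "today"), n, TRUE)),
                  paste("my vape story", sample(c("one", "two"), n, TRUE)))
  corpus <- mk_corpus(texts)
  labels <- rep(c("advertising", "nonadvertising"), each = n / 2)
  f <- featurize_tweets(corpus, fit = TRUE)
  sel <- select_features(f, labels, seed = 1)
  expect_true(all(sel$kept %in% seq_len(ncol(f$matrix))))
  coupon_col <- match("coupon", f$vocabulary)
  expect_true(coupon_col %in% sel$kept)
  # a column that is constant has zero importance and is never kept
  const_cols <- which(apply(as.matrix(f$matrix), 2, function(x) {
    length(unique(x)) == 1
  }))
  expect_length(intersect(sel$kept, const_cols), 0L)
})

test_that("the kept feature set is invariant to row order", {
  labeled <- mk_labeled_separable(n = 120, seed = 4)
  f <- featurize_tweets(labeled, fit = TRUE)
  sel1 <- select_features(f, labeled$label, seed = 2)
  perm <- sample(nrow(labeled))
  f2 <- featurize_tweets(labeled[perm, ], fit = FALSE,
                         vocabulary = f$vocabulary)
  sel2 <- select_features(f2, labeled$label[perm], seed = 2)
  expect_setequal(feature_names(f)[sel1$kept], feature_names(f)[sel2$kept])
})

test_that("selection requires both classes", {
  corpus <- mk_corpus(c("a b", "c d"))
  f <- featurize_tweets(corpus, fit = TRUE)
  expect_error(select_features(f, c("advertising", "advertising"), seed = 1),
               "both classes")
})

test_that("the forest is deterministic under a fixed seed and separates on has_url", {
  set.seed(9)
  n <- 60
  has_url <- rep(c(TRUE, FALSE), n / 2)
  texts <- ifelse(has_url, "look here http://x.example.com/p", "look here")
  corpus <- mk_corpus(texts)
  labels <- ifelse(has_url, "advertising", "nonadvertising")
  f <- featurize_tweets(corpus, fit = TRUE)
  sel <- select_features(f, labels, seed = 5)
  fit1 <- fit_ad_forest(sel$features, labels, seed = 5)
  fit2 <- fit_ad_forest(sel$features, labels, seed = 5)
  test_corpus <- mk_corpus(c("fresh text http://y.example.com/q", "fresh text"))
  tf <- featurize_tweets(test_corpus, fit = FALSE, vocabulary = f$vocabulary)
  p1 <- as.character(vapewatch:::predict_forest(fit1,
                                                tf$matrix[, sel$kept, drop = FALSE]))
  p2 <- as.character(vapewatch:::predict_forest(fit2,
                                                tf$matrix[, sel$kept, drop = FALSE]))
  expect_identical(p1, p2)
  expect_equal(p1, c("advertising", "nonadvertising"))
  expect_error(fit_ad_forest(f, rep("advertising", n), seed = 1),
               "each class")
})

test_that("fitting on the reduced matrix equals fitting on the full matrix restricted to kept columns", {
  labeled <- mk_labeled_separable(n = 100, seed = 6)
  f <- featurize_tweets(labeled, fit = TRUE)
  sel <- select_features(f, labeled$label, seed = 3)
  fit_reduced <- fit_ad_forest(sel$features, labeled$label, seed = 3)
  restricted <- f
  restricted$matrix <- f$matrix[, sel$kept, drop = FALSE]
  fit_restricted <- fit_ad_forest(restricted, labeled$label, seed = 3)
  pr <- vapewatch:::predict_forest(fit_reduced, sel$features$matrix)
  pf <- vapewatch:::predict_forest(fit_restricted, restricted$matrix)
  expect_identical(as.character(pr), as.character(pf))
})

test_that("cross-validation reports coherent, bounded metrics", {
  labeled <- mk_labeled_separable(n = 150, seed = 8)
  rep <- cross_validate_ads(labeled, k = 5, seed = 0)
  expect_equal(mean(rep$per_fold_accuracies), rep$mean_cv_accuracy,
               tolerance = 1e-12)
  g <- glance(rep)
  fracs <- c(g$mean_cv_accuracy, g$baseline_accuracy, g$precision, g$recall)
  expect_true(all(fracs >= 0 & fracs <= 1))
  expect_lte(g$n_features_selected, g$n_features_initial)
  # baseline is exactly the majority-class prevalence
  expect_equal(g$baseline_accuracy,
               max(prop.table(table(labeled$label))),
               ignore_attr = TRUE)
  expect_equal(nrow(tidy(rep)), 5L)
  expect_error(cross_validate_ads(labeled, k = 1000, seed = 0), "exceed")
})

test_that("prediction labels every tweet and an empty corpus yields empty output", {
  labeled <- mk_labeled_separable(n = 100, seed = 10)
  model <- train_ad_classifier(labeled, seed = 0)
  out <- predict_ads(model, labeled)
  expect_equal(nrow(out), nrow(labeled))
  expect_true(all(out$label %in% c("advertising", "nonadvertising")))
  expect_true(all(out$label_source == "predicted"))
  # training tweets re-predicted: in-sample accuracy at least the CV estimate
  cv <- cross_validate_ads(labeled, k = 5, seed = 0)
  expect_gte(mean(out$label == labeled$label), cv$mean_cv_accuracy - 1e-9)
  empty <- labeled[0, ]
  expect_equal(nrow(predict_ads(model, empty)), 0L)
})

test_that("a held-out synthetic sample is classified close to the cv estimate", {
  sim <- generate_tweets(generator_config(n_tweets = 600, seed = 12))
  labels <- setNames(sim$truth$label, sim$truth$tweet_id)
  labeled <- dplyr::mutate(sim$corpus, label = unname(labels[tweet_id]))
  train_idx <- seq_len(400)
  model <- train_ad_classifier(labeled[train_idx, ], seed = 0)
  cv <- cross_validate_ads(labeled[train_idx, ], k = 5, seed = 0)
  holdout <- labeled[-train_idx, ]
  acc <- mean(predict_ads(model, holdout)$label == holdout$label)
  expect_lte(abs(acc - cv$mean_cv_accuracy), 0.05)
})
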