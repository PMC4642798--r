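# Advertising vs nonadvertising tweet classification.
#
# Features are binary presence indicators for every n-gram of length 1 to 4
# in the (casefolded, URL-stripped) text, plus five raw account-metadata
# features: follower count, following count, statuses count, has-URL, and
# the retweet flag — all recorded at the time of the tweet. Feature
# selection keeps the columns with nonzero impurity importance in an
# extremely-randomized-trees ensemble; the classifier proper is a 10-tree
# random forest. Trees are scale-invariant, so metadata enters unscaled.

CLASS_LEVELS <- c("advertising", "nonadvertising")
METADATA_FEATURES <- c("follower_count", "following_count", "statuses_count",
                       "has_url", "is_retweet")

#' Turn a corpus into a binary n-gram + metadata feature matrix
#'
#' @param corpus A corpus tibble (a label column, if present, is ignored).
#' @param fit If `TRUE`, learn the n-gram vocabulary from this corpus;
#'   otherwise encode against `vocabulary`, introducing no new columns.
#' @param vocabulary Character vector of n-grams (required when
#'   `fit = FALSE`).
#' @param max_n Longest n-gram length.
#' @return A `tweet_features` object: sparse matrix `matrix`
#'   (tweets x features; n-gram block then the 5 metadata columns),
#'   `vocabulary`, `row_ids`.
#' @export
featurize_tweets <- function(corpus, fit = TRUE, vocabulary = NULL,
                             max_n = 4L) {
  if (nrow(corpus) == 0) abort("cannot featurize an empty corpus")
  if (!fit && is.null(vocabulary)) {
    abort("vocabulary must be supplied when fit = FALSE")
  }
  grams <- map(tokenize_for_ngrams(corpus$text), function(tok) {
    unique(ngrams_up_to(tok, max_n))
  })
  if (fit) {
    vocabulary <- unique(unlist(grams, use.names = FALSE))
  }
  idx <- map(grams, function(g) {
    m <- match(g, vocabulary)
    m[!is.na(m)]
  })
  i <- rep(seq_along(idx), lengths(idx))
  j <- unlist(idx, use.names = FALSE)
  ngram_block <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(corpus), length(vocabulary))
  )
  has_url <- as.integer(lengths(extract_urls(corpus$text)) > 0)
  meta <- cbind(
    corpus$follower_count, corpus$following_count, corpus$statuses_count,
    has_url, as.integer(corpus$is_retweet)
  )
  m <- cbind(ngram_block, Matrix::Matrix(meta, sparse = TRUE))
  colnames(m) <- c(sprintf("ng%06d", seq_along(vocabulary)), METADATA_FEATURES)
  structure(
    list(matrix = m, vocabulary = vocabulary, row_ids = corpus$tweet_id),
    class = "tweet_features"
  )
}

#' @export
print.tweet_features <- function(x, ...) {
  cat("<tweet_features> ", nrow(x$matrix), " tweets x ", ncol(x$matrix),
      " features (", length(x$vocabulary), " n-grams + ",
      ncol(x$matrix) - length(x$vocabulary), " metadata)\n", sep = "")
  invisible(x)
}

#' Feature names of a feature matrix (n-grams, then metadata)
#' @param features A `tweet_features` object.
#' @return Character vector of human-readable feature names.
#' @export
feature_names <- function(features) {
  c(features$vocabulary, METADATA_FEATURES)
}

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("labels must be one of ", paste(CLASS_LEVELS, collapse = "/"),
                 "; found: ", paste(bad, collapse = ", ")))
  }
  factor(labels, levels = CLASS_LEVELS)
}

#' Tree-importance feature selection
#'
#' Fits an extremely-randomized-trees ensemble (random split thresholds, no
#' bootstrap) and keeps exactly the features with importance greater than
#' zero. Rows are untouched; the kept set is a column subset and is
#' invariant to row order.
#'
#' @param features A [featurize_tweets()] result.
#' @param labels Class labels, one per row (both classes must be present).
#' @param seed Integer seed for the ensemble.
#' @param num_trees Ensemble size for the importance fit.
#' @param max_depth Optional depth cap for the screening trees (`NULL` grows
#'   them to purity).
#' @return A list: `features` (reduced `tweet_features`), `kept` (integer
#'   column indices into the original matrix), `importance` (numeric, all
#'   columns).
#' @export
select_features <- function(features, labels, seed = 0L, num_trees = 100L,
                            max_depth = NULL) {
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2) {
    abort("feature selection needs both classes present in the labels")
  }
  fit <- ranger::ranger(
    x = as.matrix(features$matrix), y = y,
    num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, max.depth = max_depth,
    respect.unordered.factors = "ignore",
    importance = "impurity", seed = seed, num.threads = 1
  )
  imp <- ranger::importance(fit)
  kept <- which(imp > 0)
  reduced <- features
  reduced$matrix <- features$matrix[, kept, drop = FALSE]
  reduced$kept <- unname(kept)
  list(features = reduced, kept = unname(kept), importance = unname(imp))
}

#' Fit the advertising random forest on a (reduced) feature matrix
#'
#' @param features A (typically reduced) `tweet_features` object.
#' @param labels Class labels, one per row; at least two rows per class.
#' @param seed Integer seed; the same data and seed give identical models.
#' @param num_trees Forest size.
#' @return A fitted `ranger` forest.
#' @export
fit_ad_forest <- function(features, labels, seed = 0L, num_trees = 10L) {
  y <- as_label_factor(labels)
  if (any(table(y) < 2)) {
    abort("need at least two tweets of each class to fit the forest")
  }
  ranger::ranger(
    x = as.matrix(features$matrix), y = y,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
}

predict_forest <- function(forest, matrix) {
  x <- as.matrix(matrix)
  predict(forest, data = as.data.frame(x), num.threads = 1)$predictions
}

#' Train the deployable advertising classifier
#'
#' Full training path: featurize (fit the vocabulary), select features on
#' the whole training set, fit the random forest on the kept columns. The
#' returned object bundles everything needed to classify new corpora.
#'
#' @param labeled A corpus tibble with a `label` column
#'   ("advertising"/"nonadvertising").
#' @param seed Integer seed for selection and forest.
#' @param num_trees Forest size.
#' @param select_trees Ensemble size of the importance selector.
#' @return An `ad_classifier` object (forest, vocabulary, kept columns,
#'   feature counts).
#' @export
train_ad_classifier <- function(labeled, seed = 0L, num_trees = 10L,
                                select_trees = 100L) {
  feats <- featurize_tweets(labeled, fit = TRUE)
  sel <- select_features(feats, labeled$label, seed = seed,
                         num_trees = select_trees)
  forest <- fit_ad_forest(sel$features, labeled$label, seed = seed,
                          num_trees = num_trees)
  structure(
    list(
      forest = forest,
      vocabulary = feats$vocabulary,
      kept = sel$kept,
      n_features_initial = ncol(feats$matrix),
      n_features_selected = length(sel$kept),
      seed = seed
    ),
    class = "ad_classifier"
  )
}

#' @export
print.ad_classifier <- function(x, ...) {
  cat("<ad_classifier> random forest (", x$forest$num.trees, " trees), ",
      x$n_features_selected, "/", x$n_features_initial,
      " features kept\n", sep = "")
  invisible(x)
}

#' Label a corpus with a trained classifier
#'
#' @param model An [train_ad_classifier()] result.
#' @param corpus A corpus tibble; may be empty.
#' @return The corpus with `label` and `label_source = "predicted"` columns
#'   appended; exactly one label per tweet.
#' @export
predict_ads <- function(model, corpus) {
  if (nrow(corpus) == 0) {
    return(mutate(corpus, label = character(0), label_source = character(0)))
  }
  feats <- featurize_tweets(corpus, fit = FALSE, vocabulary = model$vocabulary)
  pred <- predict_forest(model$forest,
                         feats$matrix[, model$kept, drop = FALSE])
  corpus |>
    mutate(label = as.character(pred), label_source = "predicted")
}

#' Stratified k-fold cross-validation of the advertising classifier
#'
#' Each fold refits the entire pipeline on its training split — vocabulary,
#' feature selection and forest — so no information leaks from held-out
#' tweets. Precision and recall are pooled over folds with "advertising" as
#' the positive class; the baseline is the majority-class prevalence.
#'
#' @param labeled A labeled corpus tibble (both classes present,
#'   `nrow >= k`).
#' @param k Number of folds.
#' @param seed Integer seed governing fold assignment and all tree fits.
#' @param num_trees,select_trees Forest / selector ensemble sizes.
#' @return An `ad_cv_report` object; see [tidy.ad_cv_report()] and
#'   [glance.ad_cv_report()].
#' @export
cross_validate_ads <- function(labeled, k = 10L, seed = 0L, num_trees = 10L,
                               select_trees = 100L) {
  y <- as_label_factor(labeled$label)
  n <- nrow(labeled)
  if (k > n) abort("k must not exceed the number of labeled tweets")
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present")

  folds <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }

  fold_acc <- numeric(k)
  pred_all <- character(n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    feats_tr <- featurize_tweets(labeled[train, ], fit = TRUE)
    sel <- select_features(feats_tr, y[train], seed = seed + f,
                           num_trees = select_trees)
    forest <- fit_ad_forest(sel$features, y[train], seed = seed + f,
                            num_trees = num_trees)
    feats_te <- featurize_tweets(labeled[test, ], fit = FALSE,
                                 vocabulary = feats_tr$vocabulary)
    pred <- predict_forest(forest, feats_te$matrix[, sel$kept, drop = FALSE])
    pred_all[test] <- as.character(pred)
    fold_acc[f] <- mean(as.character(pred) == as.character(y[test]))
  }

  tp <- sum(pred_all == "advertising" & y == "advertising")
  fp <- sum(pred_all == "advertising" & y == "nonadvertising")
  fn <- sum(pred_all == "nonadvertising" & y == "advertising")

  full <- featurize_tweets(labeled, fit = TRUE)
  sel_full <- select_features(full, y, seed = seed, num_trees = select_trees)

  structure(
    list(
      mean_cv_accuracy = mean(fold_acc),
      per_fold_accuracies = fold_acc,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      baseline_accuracy = max(prop.table(table(y))),
      n_features_initial = ncol(full$matrix),
      n_features_selected = length(sel_full$kept),
      k = k, n = n, seed = seed
    ),
    class = "ad_cv_report"
  )
}

#' @export
print.ad_cv_report <- function(x, ...) {
  cat("<ad_cv_report> ", x$k, "-fold CV on ", x$n, " tweets\n",
      "  mean accuracy ", sprintf("%.3f", x$mean_cv_accuracy),
      " (baseline ", sprintf("%.3f", x$baseline_accuracy), ")\n",
      "  precision ", sprintf("%.3f", x$precision),
      ", recall ", sprintf("%.3f", x$recall), "\n",
      "  features ", x$n_features_selected, "/", x$n_features_initial,
      " kept\n", sep = "")
  invisible(x)
}

#' Per-fold accuracies of a cross-validation report
#' @param x An `ad_cv_report`.
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @method tidy ad_cv_report
#' @export
tidy.ad_cv_report <- function(x, ...) {
  tibble(fold = seq_len(x$k), accuracy = x$per_fold_accuracies)
}

#' One-row summary of a cross-validation report
#' @inheritParams tidy.ad_cv_report
#' @return A one-row tibble of the report scalars.
#' @method glance ad_cv_report
#' @export
glance.ad_cv_report <- function(x, ...) {
  tibble(
    mean_cv_accuracy = x$mean_cv_accuracy,
    baseline_accuracy = x$baseline_accuracy,
    precision = x$precision,
    recall = x$recall,
    n_features_initial = x$n_features_initial,
    n_features_selected = x$n_features_selected,
    k = x$k, n = x$n
  )
}

# Save/restore the global RNG state so seeded model fits do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
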