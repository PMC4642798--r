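# One-call orchestration: filter -> entities -> classify -> places ->
# summarize, with stage bookkeeping and a machine-readable report.

#' Run the full surveillance pipeline
#'
#' Applies the keyword filter, extracts entities, trains the advertising
#' classifier on the supplied labeled sample and labels the filtered
#' corpus, extracts place mentions from the predicted nonadvertising
#' tweets, and assembles the surveillance summary. Any stage failure aborts
#' with the stage name. All non-timing report fields are deterministic
#' under a fixed seed.
#'
#' @param corpus A corpus tibble (raw, unfiltered).
#' @param labeled A labeled corpus tibble used to train the classifier
#'   (e.g. from [make_training_sample()]).
#' @param syntax A [keyword_syntax()].
#' @param resolver A [url_resolver()].
#' @param brands A [brand_lexicon()].
#' @param rules,exclusions,lexicon Place-extraction configuration.
#' @param k Cross-validation folds for the classifier report (`cv = FALSE`
#'   skips cross-validation).
#' @param seed Integer seed for every stochastic stage.
#' @param cv Compute the cross-validated classifier report?
#' @param top_k Rows in handle/link rankings.
#' @return A `run_report` object: `stage_counts`, `timings_s`, `cv_report`,
#'   `model`, `labeled_corpus`, `places`, `summary`, `seed`.
#' @export
run_pipeline <- function(corpus, labeled,
                         syntax = default_keyword_syntax(),
                         resolver = default_url_resolver(),
                         brands = brand_lexicon(),
                         rules = default_cleaning_rules(),
                         exclusions = default_exclusion_nouns(),
                         lexicon = place_lexicon(),
                         k = 10L, seed = 0L, cv = TRUE, top_k = 5L) {
  stage_counts <- list()
  timings <- list()
  run_stage <- function(name, n_in, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    stage_counts[[name]] <<- tibble(stage = name, n_in = n_in,
                                    n_out = stage_n(out))
    out
  }
  stage_n <- function(x) {
    if (is.data.frame(x)) nrow(x)
    else if (is.list(x) && is.data.frame(x$labeled)) nrow(x$labeled)
    else NA_integer_
  }

  filtered <- run_stage("filter", nrow(corpus),
                        filter_keywords(corpus, syntax))
  entities <- run_stage("entities", nrow(filtered),
                        extract_entities(filtered, resolver))

  t0 <- Sys.time()
  cv_report <- if (cv) {
    cross_validate_ads(labeled, k = k, seed = seed)
  }
  model <- train_ad_classifier(labeled, seed = seed)
  predicted <- predict_ads(model, filtered)
  timings[["classify"]] <- as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))
  stage_counts[["classify"]] <- tibble(stage = "classify",
                                       n_in = nrow(filtered),
                                       n_out = nrow(predicted))

  nonads <- filter(predicted, .data$label == "nonadvertising")
  places <- run_stage("places", nrow(nonads),
                      extract_places(nonads, rules, exclusions, lexicon))
  summary <- summarize_surveillance(predicted, entities = entities,
                                    brands = brands, places = places,
                                    top_k = top_k)
  structure(
    list(
      stage_counts = list_rbind(stage_counts),
      timings_s = timings,
      cv_report = cv_report,
      model = model,
      labeled_corpus = predicted,
      entities = entities,
      places = places,
      summary = summary,
      seed = seed
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, "\n", sep = "")
  print(x$stage_counts)
  if (!is.null(x$cv_report)) print(x$cv_report)
  invisible(x)
}

#' Write a run report as JSON
#'
#' Serializes the machine-readable parts of a [run_pipeline()] report
#' (stage counts, timings, classifier report, place table, summary rows,
#' seed); the fitted model itself is omitted.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- list(
    seed = report$seed,
    stage_counts = report$stage_counts,
    timings_s = report$timings_s,
    classifier = if (!is.null(report$cv_report)) {
      as.list(glance(report$cv_report))
    },
    place_table = place_table(report$places),
    summary = tidy(report$summary)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
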