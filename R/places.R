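# Where people use e-cigarettes: rule-based prepositional-phrase extraction
# from nonadvertising tweets.
#
# The pipeline is: keep tweets with an active usage verb; clean microtext
# noise (@-mentions, hashtags, interjections, subordinate phrases, slang);
# tag parts of speech with a lightweight rule tagger; chunk each preposition
# together with the following words up to the next verb, preposition,
# wh-adverb or sentence punctuation; keep only the top three
# location-bearing prepositions (in/at/on); drop phrases headed by a
# non-location noun; and map the survivors onto the 20 place categories
# through a synonym lexicon. Statistical parsers perform poorly on tweet
# grammar, which is why every step here is an explicit rule.

USAGE_VERB_FORMS <- c("smoking", "vaping", "smokes", "vapes", "smoked", "vaped")
TOP_PREPOSITIONS <- c("in", "at", "on")

#' Filter nonadvertising tweets to active-usage reports
#'
#' Retains tweets containing one of the six inflected usage verb forms
#' (smoking, vaping, smokes, vapes, smoked, vaped) as a word. The bare forms
#' "smoke"/"vape" are matched only in infinitive position ("to smoke", "to
#' vape"), where they unambiguously describe usage rather than a product
#' ("I love my vape pen" is not a usage report).
#'
#' @param corpus A corpus tibble (typically the nonadvertising subset).
#' @param verbs Inflected verb forms to match anywhere.
#' @return The retained subset, order preserved.
#' @export
usage_filter <- function(corpus, verbs = USAGE_VERB_FORMS) {
  text <- str_to_lower(corpus$text)
  pat <- paste0("\\b(", paste(verbs, collapse = "|"), ")\\b")
  infinitive <- "\\bto\\s+(smoke|vape)\\b"
  corpus[str_detect(text, pat) | str_detect(text, infinitive), , drop = FALSE]
}

#' Cleaning rules for tweet normalization
#'
#' @param interjections Tokens removed wherever they occur ("lol", "smh",
#'   expletives, ...).
#' @param subordinate_phrases Subordinate prepositional phrases removed
#'   verbatim ("in the middle", ...).
#' @param slang_map Named character vector/list of slang -> expansion
#'   ("ur" -> "you're").
#' @param in_front_person_words Words counting as a person after
#'   "in front of"; with a person object the phrase is kept (it is a genuine
#'   "in front of someone" place mention), otherwise "in front (of X)" is
#'   removed as subordinate.
#' @return A `cleaning_rules` object.
#' @export
cleaning_rules <- function(interjections, subordinate_phrases, slang_map,
                           in_front_person_words = character(0)) {
  slang_map <- unlist(slang_map)
  stopifnot(length(interjections) > 0, length(subordinate_phrases) > 0,
            length(slang_map) > 0)
  names(slang_map) <- str_to_lower(names(slang_map))
  structure(
    list(
      interjections = str_to_lower(interjections),
      subordinate_phrases = str_to_lower(subordinate_phrases),
      slang_map = slang_map,
      in_front_person_words = str_to_lower(in_front_person_words)
    ),
    class = "cleaning_rules"
  )
}

#' Read cleaning rules from a YAML config file
#' @param path YAML file with `interjections`, `subordinate_phrases`,
#'   `slang_map`, `in_front_person_words` sections.
#' @return A [cleaning_rules()] object.
#' @export
read_cleaning_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  cleaning_rules(unlist(cfg$interjections), unlist(cfg$subordinate_phrases),
                 cfg$slang_map, unlist(cfg$in_front_person_words))
}

#' Default cleaning rules shipped with the package
#' @return A [cleaning_rules()] object.
#' @export
default_cleaning_rules <- function() {
  read_cleaning_rules(system.file("extdata", "cleaning_rules.yml",
                                  package = "vapewatch"))
}

#' Normalize tweet text before tagging
#'
#' Applies, in order: strip @-mentions; strip hashtags; remove interjection
#' tokens; remove subordinate prepositional phrases (including non-person
#' "in front (of ...)"); expand slang; collapse whitespace. Letter case is
#' otherwise preserved.
#'
#' @param text Character vector.
#' @param rules A [cleaning_rules()] object.
#' @return Cleaned character vector of the same length.
#' @export
#' @examples
#' clean_tweet("lol smh vaping in class")
#' clean_tweet("ur vaping at work")
clean_tweet <- function(text, rules = default_cleaning_rules()) {
  x <- str_replace_all(text, "@[A-Za-z0-9_]+", " ")
  x <- str_replace_all(x, HASHTAG_PATTERN, " ")
  inter_pat <- regex(paste0("\\b(", paste(escape_regex(rules$interjections),
                                          collapse = "|"), ")\\b"),
                     ignore_case = TRUE)
  x <- str_replace_all(x, inter_pat, " ")
  # "in front of X": subordinate unless X is a person
  if (length(rules$in_front_person_words) > 0) {
    front_pat <- regex(paste0(
      "\\bin front( of(\\s+(?:the|a|an|my|your|his|her|our|their))?",
      "\\s+([A-Za-z']+))?"), ignore_case = TRUE)
    x <- stringr::str_replace_all(x, front_pat, function(m) {
      obj <- str_to_lower(str_extract(m, "[A-Za-z']+$"))
      if (!is.na(obj) && obj %in% rules$in_front_person_words) m else " "
    })
  }
  for (phrase in rules$subordinate_phrases) {
    x <- str_replace_all(x, regex(escape_regex(phrase), ignore_case = TRUE),
                         " ")
  }
  for (slang in names(rules$slang_map)) {
    x <- str_replace_all(
      x,
      regex(paste0("\\b", escape_regex(slang), "\\b"), ignore_case = TRUE),
      rules$slang_map[[slang]]
    )
  }
  str_squish(x)
}

# ---- rule-based part-of-speech tagger -------------------------------------

TAG_LEXICON <- local({
  lex <- list(
    IN = c("in", "at", "on", "of", "for", "with", "from", "by", "during",
           "around", "over", "under", "near", "inside", "outside", "before",
           "after", "behind", "about", "into", "onto", "off", "through",
           "between", "against", "without", "within", "beside", "above",
           "below", "across", "along", "past", "till", "until", "since",
           "upon", "toward", "towards"),
    TO = "to",
    WRB = c("when", "whenever", "where", "wherever", "why", "how"),
    DT = c("the", "a", "an", "this", "that", "these", "those", "some", "any",
           "every", "each", "no", "another", "all", "both"),
    "PRP$" = c("my", "your", "his", "her", "its", "our", "their"),
    PRP = c("i", "you", "he", "she", "it", "we", "they", "me", "him", "us",
            "them", "myself", "himself", "herself", "themselves", "someone",
            "everyone", "everybody", "anybody", "nobody", "somebody"),
    MD = c("can", "could", "will", "would", "shall", "should", "may",
           "might", "must"),
    VB = c("be", "get", "go", "see", "say", "think", "know", "like", "love",
           "want", "need", "make", "let", "keep", "catch", "watch", "yell",
           "smell", "stop", "start", "try", "hate"),
    VBZ = c("is", "has", "does", "gets", "goes", "sees", "says", "makes",
            "lets", "keeps", "watches", "yells", "smokes", "vapes", "smells",
            "stops", "starts", "tries", "hates", "loves", "likes", "wants",
            "needs", "thinks", "knows"),
    VBP = c("am", "are", "have", "do"),
    VBD = c("was", "were", "had", "did", "got", "went", "saw", "said",
            "made", "caught", "kept"),
    VBN = c("been", "gone", "seen", "done"),
    VBG = c("being", "having", "doing", "going", "getting"),
    RB = c("not", "very", "really", "just", "too", "so", "again", "still",
           "now", "here", "there", "always", "never", "often", "rather",
           "soon", "then", "maybe", "probably", "literally", "indoors"),
    CC = c("and", "or", "but", "nor"),
    UH = c("oh", "hey", "wow", "yeah", "yes"),
    # common -ing/-ed lookalikes that are nouns, exempt from suffix rules
    NN = c("thing", "something", "nothing", "anything", "everything",
           "morning", "evening", "building", "ceiling", "bowling",
           "wedding", "king", "ring", "spring", "string", "wing",
           "sibling", "clothing", "lightning")
  )
  out <- setNames(rep(names(lex), lengths(lex)), unlist(lex))
  out
})

PUNCT_TOKENS <- c(",", ".", "!", "?", ";", ":", "(", ")", "\"")

tag_token <- function(token) {
  low <- str_to_lower(token)
  if (token %in% PUNCT_TOKENS) return(token)
  hit <- TAG_LEXICON[low]
  if (!is.na(hit)) return(unname(hit))
  if (grepl("^[0-9]+([.,][0-9]+)?%?$", token)) return("CD")
  n <- nchar(low)
  if (n >= 5 && endsWith(low, "ing")) return("VBG")
  if (n >= 4 && endsWith(low, "ed")) return("VBD")
  if (n >= 4 && endsWith(low, "ly")) return("RB")
  if (n >= 4 && endsWith(low, "s") && !endsWith(low, "ss")) return("NNS")
  "NN"
}

#' Part-of-speech tag a cleaned tweet
#'
#' A deterministic rule tagger for microtext emitting Penn Treebank tags: a
#' closed-class lexicon (prepositions, determiners, pronouns, auxiliaries,
#' common verbs, wh-adverbs), digit and suffix rules (-ing, -ed, -ly,
#' plural -s), punctuation tagged as itself, and nouns as the default open
#' class. The downstream chunker consumes only the verb/preposition/
#' wh-adverb/punctuation distinctions and the noun tags for head-finding,
#' which this tagger resolves reliably on cleaned tweets.
#'
#' @param text A single string (one cleaned tweet).
#' @return A tibble with columns `token`, `tag`, one row per token.
#' @export
#' @examples
#' pos_tag("vaping in class")
pos_tag <- function(text) {
  stopifnot(length(text) == 1)
  tokens <- tokenize_for_tagging(text)
  if (length(tokens) == 0) {
    return(tibble(token = character(0), tag = character(0)))
  }
  tibble(token = tokens, tag = vapply(tokens, tag_token, character(1),
                                      USE.NAMES = FALSE))
}

is_boundary_tag <- function(tag) {
  startsWith(tag, "VB") | tag %in% c("IN", "TO", "WRB", "MD") |
    tag %in% PUNCT_TOKENS
}

#' Chunk prepositional phrases from tagged tokens
#'
#' For every token tagged as a preposition, collects the subsequent tokens
#' up to (exclusive) the next verb, preposition, wh-adverb or sentence
#' punctuation. Phrases with an empty object are dropped.
#'
#' @param tagged A [pos_tag()] result.
#' @return A tibble with one row per phrase: `preposition` (lowercase),
#'   list-columns `object` (tokens) and `object_tags`.
#' @export
#' @examples
#' chunk_prepositional_phrases(pos_tag("smoking an electronic cigarette in class"))
chunk_prepositional_phrases <- function(tagged) {
  n <- nrow(tagged)
  starts <- which(tagged$tag %in% c("IN", "TO"))
  rows <- map(starts, function(s) {
    e <- s
    while (e < n && !is_boundary_tag(tagged$tag[e + 1])) e <- e + 1
    if (e == s) return(NULL)
    obj <- (s + 1):e
    list(preposition = str_to_lower(tagged$token[s]),
         object = tagged$token[obj],
         object_tags = tagged$tag[obj])
  })
  rows <- rows[!map_lgl(rows, is.null)]
  tibble(
    preposition = map_chr(rows, "preposition"),
    object = map(rows, "object"),
    object_tags = map(rows, "object_tags")
  )
}

#' Keep only phrases with a location-bearing preposition
#'
#' The three prepositions that dominate genuine place mentions are "in",
#' "at" and "on"; rarer ones ("around", "during", ...) are discarded.
#'
#' @param phrases A [chunk_prepositional_phrases()] result.
#' @param prepositions Prepositions to keep (case-insensitive).
#' @return The retained subset, order preserved.
#' @export
filter_prepositions <- function(phrases, prepositions = TOP_PREPOSITIONS) {
  phrases[str_to_lower(phrases$preposition) %in%
            str_to_lower(prepositions), , drop = FALSE]
}

#' Exclusion nouns shipped with the package
#' @return Lowercase, deduplicated character vector of non-location nouns.
#' @export
default_exclusion_nouns <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "exclusion_nouns.yml",
                                     package = "vapewatch"))
  unique(str_to_lower(unlist(cfg$non_location_nouns)))
}

DETERMINER_WORDS <- c("the", "a", "an", "this", "that", "these", "those",
                      "some", "any", "my", "your", "his", "her", "its",
                      "our", "their")

strip_possessive <- function(token) sub("'s$", "", token)

depluralize <- function(token) {
  ifelse(nchar(token) > 3 & endsWith(token, "s") & !endsWith(token, "ss"),
         sub("s$", "", token), token)
}

# Head of the object: last noun-tagged token after dropping determiners and
# possessives; falls back to the last remaining token.
object_head <- function(object, object_tags) {
  keep <- !(object_tags %in% c("DT", "PRP$")) &
    !(str_to_lower(object) %in% DETERMINER_WORDS)
  object <- object[keep]
  object_tags <- object_tags[keep]
  if (length(object) == 0) return(NA_character_)
  nouns <- which(startsWith(object_tags, "N"))
  pick <- if (length(nouns) > 0) max(nouns) else length(object)
  strip_possessive(str_to_lower(object[pick]))
}

#' Drop phrases whose object head is not a physical location
#'
#' @param phrases A phrase tibble (from [chunk_prepositional_phrases()]).
#' @param exclusions Lowercase non-location nouns; phrases whose object head
#'   noun (or its singular form) is in this list are removed.
#' @return The retained subset.
#' @export
#' @examples
#' ph <- chunk_prepositional_phrases(pos_tag("vaping at night"))
#' filter_non_locations(ph)
filter_non_locations <- function(phrases, exclusions = default_exclusion_nouns()) {
  if (nrow(phrases) == 0) return(phrases)
  heads <- map2_chr(phrases$object, phrases$object_tags, object_head)
  drop <- !is.na(heads) &
    (heads %in% exclusions | depluralize(heads) %in% exclusions)
  phrases[!drop, , drop = FALSE]
}

#' Place-category lexicon shipped with the package
#' @param path Optional YAML file (category -> synonym list) overriding the
#'   shipped lexicon.
#' @return A `place_lexicon` object.
#' @export
place_lexicon <- function(path = system.file("extdata", "place_lexicon.yml",
                                             package = "vapewatch")) {
  cfg <- yaml::read_yaml(path)
  entries <- imap(cfg, function(terms, category) {
    tibble(term = str_to_lower(unlist(terms)), category = category)
  }) |> list_rbind()
  entries <- entries |> mutate(n_tokens = lengths(str_split(.data$term, " ")))
  structure(
    list(
      categories = names(cfg),
      single = entries |> filter(.data$n_tokens == 1),
      multi = entries |> filter(.data$n_tokens > 1) |>
        arrange(desc(.data$n_tokens))
    ),
    class = "place_lexicon"
  )
}

#' Map a prepositional-phrase object onto a place category
#'
#' Multiword lexicon entries ("locker room", "coffee shop") are matched as
#' consecutive tokens anywhere in the object and take priority; otherwise
#' object tokens are scanned right to left (skipping determiners and
#' possessives, tolerating trailing slang) for a single-word synonym, also
#' trying the singular form. Unmatched objects map to "uncategorized".
#'
#' @param object Character vector of object tokens.
#' @param lexicon A [place_lexicon()].
#' @return A single category string.
#' @export
#' @examples
#' categorize_place(c("my", "room"))
#' categorize_place(c("the", "bathroom"))
categorize_place <- function(object, lexicon = place_lexicon()) {
  toks <- str_to_lower(strip_possessive(object))
  toks <- toks[!(toks %in% DETERMINER_WORDS)]
  if (length(toks) == 0) return("uncategorized")
  joined <- paste(toks, collapse = " ")
  for (i in seq_len(nrow(lexicon$multi))) {
    if (str_detect(joined,
                   paste0("\\b", escape_regex(lexicon$multi$term[i]), "\\b"))) {
      return(lexicon$multi$category[i])
    }
  }
  single <- setNames(lexicon$single$category, lexicon$single$term)
  for (tok in rev(toks)) {
    hit <- single[tok]
    if (!is.na(hit)) return(unname(hit))
    hit <- single[depluralize(tok)]
    if (!is.na(hit)) return(unname(hit))
  }
  "uncategorized"
}

#' Extract place-of-use mentions from nonadvertising tweets
#'
#' Composes the full pipeline: usage filter, cleaning, tagging, chunking,
#' top-3 preposition restriction, non-location exclusion, and place
#' categorization. Each tweet contributes at most one mention: the first
#' surviving phrase in text order. Retweets are processed like any other
#' tweet; the category counts are counts of tweets.
#'
#' @param corpus A corpus tibble of nonadvertising tweets.
#' @param rules A [cleaning_rules()].
#' @param exclusions Non-location nouns (see [default_exclusion_nouns()]).
#' @param lexicon A [place_lexicon()].
#' @param verbs Usage verb forms (see [usage_filter()]).
#' @return A tibble of place mentions: `tweet_id`, `preposition`,
#'   `object` (space-joined tokens), `category`.
#' @seealso [place_table()] for the Table-1-style category count table.
#' @export
extract_places <- function(corpus,
                           rules = default_cleaning_rules(),
                           exclusions = default_exclusion_nouns(),
                           lexicon = place_lexicon(),
                           verbs = USAGE_VERB_FORMS) {
  usage <- usage_filter(corpus, verbs = verbs)
  if (nrow(usage) == 0) {
    return(tibble(tweet_id = character(0), preposition = character(0),
                  object = character(0), category = character(0)))
  }
  cleaned <- clean_tweet(usage$text, rules)
  rows <- map(seq_len(nrow(usage)), function(i) {
    phrases <- chunk_prepositional_phrases(pos_tag(cleaned[i])) |>
      filter_prepositions() |>
      filter_non_locations(exclusions)
    if (nrow(phrases) == 0) return(NULL)
    first <- phrases[1, ]
    tibble(
      tweet_id = usage$tweet_id[i],
      preposition = first$preposition,
      object = paste(first$object[[1]], collapse = " "),
      category = categorize_place(first$object[[1]], lexicon)
    )
  })
  rows <- rows[!map_lgl(rows, is.null)]
  if (length(rows) == 0) {
    return(tibble(tweet_id = character(0), preposition = character(0),
                  object = character(0), category = character(0)))
  }
  list_rbind(rows)
}

#' Category count table over place mentions
#'
#' Counts tweets per place category with percentages of the categorized
#' total (uncategorized mentions are excluded from the table and its
#' denominator); percentages sum to 100 up to rounding.
#'
#' @param mentions An [extract_places()] result.
#' @return A tibble `category`, `n`, `pct` (2 decimals), sorted by
#'   descending count, ties broken alphabetically.
#' @export
place_table <- function(mentions) {
  categorized <- mentions |> filter(.data$category != "uncategorized")
  if (nrow(categorized) == 0) {
    return(tibble(category = character(0), n = integer(0), pct = numeric(0)))
  }
  categorized |>
    count(.data$category, name = "n") |>
    mutate(pct = share(.data$n, sum(.data$n))) |>
    arrange(desc(.data$n), .data$category)
}
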