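# Internal tokenizers shared by the featurizer and the place extractor.

# Classifier tokenization: casefold, strip URLs (captured separately by the
# has_url metadata feature), separate punctuation, split on whitespace.
# Hashtag and @-mention tokens survive as words.
tokenize_for_ngrams <- function(text) {
  x <- str_to_lower(text)
  x <- str_replace_all(x, URL_PATTERN, " ")
  x <- str_replace_all(x, "[^a-z0-9'#@_-]+", " ")
  str_split(str_squish(x), " ")
}

# Contiguous n-grams of length 1..max_n, joined by single spaces.
ngrams_up_to <- function(tokens, max_n = 4L) {
  tokens <- tokens[nzchar(tokens)]
  L <- length(tokens)
  if (L == 0) return(character(0))
  out <- vector("list", max_n)
  out[[1]] <- tokens
  if (max_n > 1) {
    for (n in 2:max_n) {
      if (L < n) break
      starts <- seq_len(L - n + 1L)
      out[[n]] <- vapply(starts, function(s) {
        paste(tokens[s:(s + n - 1L)], collapse = " ")
      }, character(1))
    }
  }
  unlist(out, use.names = FALSE)
}

# Place-extraction tokenization: whitespace split with sentence punctuation
# kept as its own tokens (punctuation delimits phrase chunks downstream).
tokenize_for_tagging <- function(text) {
  x <- str_replace_all(text, "([,.!?;:()\"])", " \\1 ")
  toks <- str_split(str_squish(x), " ")[[1]]
  toks[nzchar(toks)]
}
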