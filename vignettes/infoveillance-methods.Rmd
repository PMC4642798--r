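---
title: "Methods: e-cigarette Twitter infoveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: e-cigarette Twitter infoveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapewatch)
```

## The surveillance problem

Public-health agencies have no registry of who markets e-cigarettes or where
people use them; both phenomena surface on Twitter years before they appear
in survey data. vapewatch implements a complete infoveillance pipeline over
a tweet corpus: define topical tweets with a keyword syntax, separate
*advertising* from *nonadvertising* tweets with a supervised classifier,
mine the nonadvertising stream for physical *places of e-cigarette use*,
and aggregate marketing indicators (promotion and brand shares, dominant
handles and links, follower-growth anomalies) that distinguish legitimate
vendors from affiliate spammers.

Because firehose-scale Twitter data cannot be redistributed, the package
ships a seeded synthetic generator that emulates the statistical structure
of such a corpus. Every stage is exercised end-to-end against generator
ground truth; nothing in the test suite requires a download.

## Topical filtering

A corpus is a tibble of tweets with posting metadata recorded *at the time
of the tweet* (follower, following and statuses counts, retweet flag).
`filter_keywords()` keeps tweets whose casefolded text matches at least one
inclusion term and no exclusion term (other smoked products such as hookah
or marijuana share vocabulary with e-cigarettes and are excluded
explicitly). Single-token terms match on word boundaries — "vaping" must
not fire inside unrelated words — while multiword phrases such as "green
smoke" match as substrings. The original search used 55 keywords of which
only a subset was ever published; the shipped `keywords.yml` contains every
published term and is deliberately user-editable rather than pretending to
completeness.

## Advertising classification

The classifier follows the standard sparse-text recipe:

* **Features.** Binary presence indicators for every n-gram of length 1–4
  over casefolded, URL-stripped, punctuation-separated tokens, plus five
  raw metadata features: follower count, following count, statuses count,
  a has-URL flag, and the retweet flag. URLs are removed from the token
  stream precisely because the has-URL flag captures them; left in, every
  shortened link would mint useless singleton n-grams. Metadata is not
  scaled: both tree models are invariant to monotone transformations.
* **Screening.** An extremely-randomized-trees ensemble (uniform random
  split thresholds, no bootstrap, 100 fully grown trees, `mtry = sqrt(p)`)
  is fitted once and every feature with impurity importance exactly zero is
  discarded. On a 507-tweet synthetic training sample this reduces ~1,900
  features to a few hundred. The ensemble size is a package default chosen
  for stable importance rankings; it is exposed as `select_trees`.
* **Model.** A 10-tree random forest on the reduced matrix. Ten trees is
  deliberately small — the published configuration — and is enough because
  the retained features are individually strong.
* **Scoring.** Stratified 10-fold cross-validation. Stratification matters:
  at a 78/22 class mix and n = 507, unstratified folds can lose the
  minority class entirely. Feature screening is refit *inside every fold*;
  screening on the full data before splitting would leak held-out
  information into the reported accuracy. The deployed model
  (`train_ad_classifier()`) screens on all training data, which is the
  correct asymmetry: leakage is a property of evaluation, not deployment.
  Precision and recall are pooled over folds with advertising as the
  positive class; `baseline_accuracy` is exactly the majority-class
  prevalence.

All tree fits run single-threaded with caller-supplied seeds, so every
report is reproducible to the digit. One numerical note: the features are
numeric 0/1 columns, so the screening ensemble explicitly disables
unordered-factor partition handling, which does not apply to binary
presence data.

## Place-of-use extraction

Statistical parsers degrade badly on tweet grammar, so extraction is a
fixed rule cascade, each stage independently testable:

1. **Usage filter.** Keep tweets containing one of the six inflected usage
   forms *smoking, vaping, smokes, vapes, smoked, vaped* as a word. The
   bare stems "smoke"/"vape" are accepted only in infinitive position
   ("able **to smoke** in my room"), never as bare tokens — "I love my
   vape pen" names a product, not an act. This infinitive extension is the
   package's resolution of a genuine tension in the documented rule set:
   the six-form list alone rejects a canonical worked example that the
   reference category counts include.
2. **Cleaning.** Strip @-mentions and hashtags; delete interjections
   ("lol", "smh", expletives); delete subordinate prepositional phrases
   ("in the middle"); expand microtext slang ("ur" → "you're"). The phrase
   "in front of X" is ambiguous: it is subordinate filler when X is not a
   person ("in front of the store") but a genuine place mention when X is
   a person — "in front of someone" is itself a reporting category. The
   cleaner therefore removes it only for non-person objects, against a
   configurable person-word list.
3. **Tagging.** `pos_tag()` is a deterministic rule tagger for microtext
   emitting Penn Treebank tags: a closed-class lexicon (prepositions,
   determiners, pronouns, auxiliaries, common verbs, wh-adverbs), digit
   and suffix rules (-ing, -ed, -ly, plural -s, with a noun-exception list
   for "bowling", "morning", "thing", ...), default noun. The chunker
   consumes only the verb / preposition / wh-adverb / punctuation
   distinctions plus noun tags for head-finding, all of which these rules
   resolve reliably on cleaned tweets; no statistical tagger is installed
   or needed.
4. **Chunking.** For each preposition, collect following tokens until the
   next verb, preposition, wh-adverb — or sentence punctuation, a package
   addition: commas and terminal punctuation delimit clauses in exactly
   the way the verb/preposition boundaries intend ("…in my room again
   doe!" must not swallow the exclamation mark).
5. **Preposition restriction.** Keep only *in*, *at*, *on* — the three
   prepositions that dominate genuine place mentions; the next most
   frequent ("around", "during") contribute a handful of tweets and mostly
   noise.
6. **Non-location exclusion.** Drop phrases whose object *head noun* (last
   noun-tagged token after removing determiners and possessives) is a
   configured non-location noun ("at night", "in life", "on twitter").
7. **Categorization.** Map the object through a synonym lexicon onto the
   20 place categories. Multiword entries match first and anywhere in the
   object, so "locker room" is not absorbed by "room" (house/room/in bed)
   nor "coffee shop" by "shop" (store). Single-word lookup then scans
   right-to-left from the head, tolerating trailing slang ("my room again
   doe" still lands on "room"), with a crude singularization for plural
   heads. Unmatched objects are "uncategorized" and excluded from the
   category table and its percentage denominator.

One tweet contributes at most one mention — the first surviving phrase in
text order — because the reporting unit of the category table is the tweet,
not the phrase. Retweets are not collapsed.

## Surveillance aggregates

`share()` is the single rounding point of the package: `100·n/d` to two
decimals. Weekly series use ISO calendar weeks (Monday start) in UTC, with
empty weeks emitted as zeros so that period counts always sum to the corpus
size. Promotion counting treats "% off" as a spelling of "percent off".
Brand matching is word-bounded and casefolded ("blu" must not fire inside
"blue"); a tweet counts once per distinct brand, and once total for the
any-brand figure. Rankings break count ties lexicographically so results
are order-independent.

`flag_follower_bursts()` operationalizes a qualitative observation —
spammers buy followers in blocks while legitimate accounts grow steadily —
as: split a handle's follower trajectory into consecutive 30-day windows
(last observation carried forward at window boundaries) and flag windows
whose gain exceeds 10× the handle's median window gain; flat accounts
(median 0) are flagged on absolute gain above 1,000. The 30-day/10×/1,000
defaults are package choices for a phenomenon described only qualitatively;
all three are parameters.

## The synthetic generator

`generate_tweets()` emits a corpus plus per-tweet ground truth. Text is
template-based, never free-form, so every planted signal is known exactly:
advertising tweets are storefront promos ("Try our great-tasting vanilla
cupcake flavored ecigarette eliquid! Get 20% off at checkout with coupon
code…") or promotional phrases buried in nonsense word salad, the two spam
archetypes seen in real e-cigarette advertising; nonadvertising tweets are
personal usage reports, a configurable fraction carrying a usage verb plus
an in/at/on place phrase. Defaults are the documented corpus marginals:
93.43% advertising, retweet rates 28.7%/11.6% by class, coupon 7.69%,
percent-off 7.61%, discount 0.89%, promotion 9.8%, published per-brand
rates, 0.43% of nonadvertising tweets with a place phrase distributed
proportionally to the published category counts, and yearly volumes over
2008-07-01..2013-02-28 proportional to the published yearly counts.
Handle archetypes drive metadata: affiliate spammers (tens of thousands of
statuses, few followers, one dominant handle pushing a single shortened
link), vendors with steady per-post follower growth, exactly one vendor
with a +12,000 follower step in November 2011, and consumers with static
follower counts.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data — is the hard part of the real problem:
spelling chaos, sarcasm, borderline promotional content, organic-looking
spam, topic drift, and vocabulary far larger than any template pool. The
synthetic corpus shows the pipeline is *correct*; only manual coding on
real tweets could show it is *accurate* in the wild. The published
reference points (0.907 mean CV accuracy; 15,313 initial and 2,167
selected features on 507 manually coded tweets) depend on unpublished
texts and are documented here as non-reproducible context, not as targets.

## Problem sizes and determinism

The shipped tests and the acceptance script use corpora of 400–2,000
tweets (10,000 for generator calibration), 10-fold cross-validation on
2,000 labeled tweets, and a single permuted-label null run — sizes the
package's own defaults handle in about a minute while leaving every
statistical conclusion unambiguous. Every stochastic step (generation,
fold assignment, both tree ensembles, permutation) takes an explicit
integer seed, the generator is byte-identical under a fixed seed, and all
model fits are single-threaded, so repeated runs agree exactly.

## Known limitations

* The keyword list, cleaning rules, exclusion nouns, place lexicon and
  brand lexicon ship with every published item plus small documented
  extensions; all five are plain YAML and meant to be edited.
* The rule tagger is built for cleaned tweet fragments, not open text;
  its default-noun policy is exactly right for head-finding but would be
  poor as a general-purpose tagger.
* The URL resolver is an offline map (plus optional chaining, depth 5);
  live unshortening services are out of scope by design, so unknown
  shortened links simply rank under their short form.
* Date bounds of the reference corpus are ambiguous in the source
  material (May vs July 2008); the package treats date ranges strictly as
  user parameters and takes no position.
* The published yearly counts sum to 1,607,532, not the published total
  of 1,669,123; `share()` reproduces each printed pair as printed, and the
  package's own conservation invariant applies to its own outputs only.
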