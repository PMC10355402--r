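---
title: "Methods: active-learning surveillance of vaccine misinformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-learning surveillance of vaccine misinformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During mass vaccination campaigns a measurable fraction of social-media
posts spreads misinformation — unsupported treatment advice, unfounded
claims about vaccine consequences, conspiracy narratives. Public-health
surveillance wants three things from a tweet collection: a classifier that
separates misinformation from factual content without hand-labeling
millions of posts, the distribution of misinformation over time and
countries, and a profile of the accounts doing the spreading (demographics,
engagement metrics, bot-likeness). `misinfotrack` implements that pipeline
end to end and, because large tweet collections cannot be redistributed,
ships a synthetic corpus generator that reproduces the statistical
structure the analyses rely on, so every stage is testable offline.

## Labeled-set bootstrap

The training set is bootstrapped the way annotation studies typically do
it. A manually annotated seed set provides high-quality labels of both
classes; written guideline criteria (shipped as an editable CSV and exposed
through `screen_with_guidelines()`) support the annotators. Pattern matches
against those criteria are *advisory only*: they never override a manual
label, because the guidelines were written for humans and any regex
encoding of them is best-effort.

Class imbalance (misinformation is roughly 6% of traffic) is addressed by
*keyword augmentation*: `keyword_augment()` pulls additional weak positives
from the unlabeled pool with an include/exclude term query. A tweet
qualifies when it contains at least one indicator term ("5g", "poison",
"microchip", "hoax", ...) and no exclusion term ("misleading",
"conspiracy") — the exclusions matter because tweets *about* misinformation
(debunking, warning) share vocabulary with tweets spreading it. Matching is
case-insensitive on word boundaries: "5G" matches "5g tower" but not
"15GB". The literature on this workflow leaves the exact query
unspecified, so the default term lists are configurable, and when more
tweets match than requested the selection is taken in pool order (a seeded
random mode exists) so reruns are reproducible. `merge_label_sets()`
combines the two sources with a manual-wins rule and reports the class
balance.

## Classifier and featurization

The classifier is a linear support vector machine: L2-regularized hinge
loss, trained by dual coordinate descent on sparse matrices (implemented in
C++; deterministic given data, hyperparameters, and the seed that fixes the
sweep order). The decision value \(f(x) = w \cdot x + b\) is the scaled
distance of a document to the separating hyperplane; the predicted class is
1 exactly when \(f(x) > 0\). Regularization strength defaults to \(C = 1\),
the standard default for this classifier family; the intercept is trained
as an augmented constant feature, so it is lightly regularized.

Featurization is not dictated by the method, so the package uses a standard
strong baseline for short texts: lowercase word unigrams and bigrams,
minimum document frequency 2, tf-idf weighting with smooth idf
\(\ln((1+n)/(1+\mathrm{df}))+1\) and L2 row normalization. The vocabulary
is fitted on the initial labeled set and frozen for the whole
active-learning run, which keeps decision values comparable across
iterations; per-iteration refitting is available but changes the geometry
under the selection rule.

## Active learning

Labels are expensive, so the pool-based loop queries them where they help
most. Each iteration: score the unlabeled pool with the current model,
select the `batch_size` (default 100) tweets with the smallest
\(|f(x)|\) — the ones the model is least confident about — send them to the
oracle, move them into the training set, retrain, and evaluate by
stratified randomized cross-validation (default \(k = 5\); the number of
folds is a convention choice, seeded shuffling makes it reproducible). The
loop stops after `max_iterations` (default 50, i.e. a 5,000-label budget)
or pool exhaustion.

"Least confident" admits two readings when cross-validation is in play:
the absolute decision value of the single current model, or the average of
\(|f(x)|\) over the \(k\) fold models. The package defaults to the single
current model and offers `uncertainty = "cv_average"` as the alternative;
on the synthetic corpora the two select heavily overlapping batches. Ties
in \(|f(x)|\) break by ascending tweet id, for determinism. The oracle in
tests and in the shipped pipeline is the generator's truth table wrapped by
`make_oracle()`, which also counts queries so the labeling budget of a run
is measurable.

Evaluation metrics (accuracy, precision, recall, F-score) are computed for
the misinformation class; the F-score is the harmonic mean of precision
and recall. Note one behaviour worth knowing: cross-validation accuracy
*on the growing labeled set* can decline across iterations even as held-out
accuracy improves, because uncertainty sampling deliberately concentrates
hard boundary cases in the labeled set. Sample-efficiency claims are
therefore always checked on held-out data.

## Geography and time

Profile locations are free text. `map_location()` normalizes them with a
gazetteer (a flat CSV of country/region/province/city terms), tokenizing on
commas and whitespace and matching longest terms first. The policy is
deliberately conservative: a location maps to a country only when all
matched terms agree on one country; empty, unmatched, or conflicting
locations (e.g. "Georgia", a US state and a country) return the `UNMAPPED`
sentinel rather than a guess. Location mapping over-claims are a known
hazard of this analysis, and a conservative, auditable rule was chosen over
recall.

`country_summaries()` counts tweets and misinformation per country
(per-tweet, not per-user: a user posting 10 times contributes 10), with an
`UNMAPPED` row so counts always conserve. Ratios are exact fractions;
`format_ratio()` renders them at one decimal place with half-up rounding
("7.0%", never "7%"), which reproduces every percentage in the published
per-country table from its printed counts.

Time series use ISO-8601 weeks keyed `"YYYY-WW"`; ISO rules settle
year-boundary weeks unambiguously (2020 has 53 ISO weeks). 2020-11-01
falls in week 2020-44. Interior weeks with no tweets are zero-filled.
Min-max normalization is \((v - \min)/(\max - \min)\), with the degenerate
all-constant series mapping to all zeros; `annotate_peak()` returns the
earliest week attaining the maximum raw count.

## Account profiling

Demographics arrive as probability vectors from an external multimodal
inference service (age over \(\le\)18 / 19–29 / 30–39 / \(\ge\)40, gender,
organization status) — the package consumes them, never computes them.
`assign_demographics()` takes the per-attribute argmax; exact ties resolve
by a fixed category order (youngest first, female first, org first) and are
flagged. Because upstream inference is costly, only a seeded 10% user
sample carries demographics (`sample_users()`).

An account is a *misinformation spreader* if it authored at least one
misinformation-labeled tweet, and a *fact sharer* if it authored at least
one fact-labeled tweet; the two sets may overlap and the dual-membership
count is reported. This is the simplest auditable membership rule; the
analyses it feeds (mean followers/friends/favourites per class,
verified:unverified, male:female and non-org:org ratios, cross-class
fact-over-misinformation ratios) are all order-invariant. Bot behaviour is
likewise an input: six scores in \([0,1]\) (overall, astroturf,
fake-follower, self-declared, financial, spammer) per account;
`bot_comparison()` reports per-category means over a seeded sample of
1,000 accounts per class, falling back to the whole class with a warning
when it is smaller.

## The synthetic generator

`generate_corpus()` produces corpora with the structure the analyses
assume, under defaults chosen once to match the study conditions:

* **Prevalence** 6% misinformation.
* **Texts** are bag-of-token samples from class-conditional distributions
  sharing a Zipf-weighted background vaccine vocabulary; misinformation
  texts carry indicator terms at a 25% token rate, fact texts at 1.5%
  (plus a small rate of debunking terms such as "misleading" and
  "conspiracy", so the augmentation query's exclusions are exercised). No
  grammar is simulated — downstream featurization is order-insensitive, so
  token bags are sufficient lexical signal.
* **Calendar**: ISO weeks 2020-44 through 2021-21, flat base intensity with
  multiplicative surges — weeks 2020-50/51 (×4, the December
  emergency-authorization surge), 2021-10 (×3, the March volume peak), and
  misinformation-specific surges in 2020-52/2021-01 (×2.5), echoing the
  December–January misinformation peaks.
* **Countries**: a mixture dominated by English-speaking countries (US
  0.40, UK 0.107, ...), with profile locations drawn from the gazetteer's
  terms for the user's country and a 12% unmappable-free-text fraction.
* **Accounts**: each user has a latent type (8% misinformation spreaders).
  Engagement counts are log-normal (sdlog 1 — heavy-tailed, like real
  follower counts) with means encoding the reported contrasts: followers
  2,500 (fact) vs 500 (misinformation), a 5× gap; favourites 12,000 vs
  8,760 (27% fewer); friends 800 vs 1,000 (25% more); verified probability
  0.06 vs 0.02 (3×). Age mixtures make \(\ge\)40 the modal misinformation
  group with 19–29 posting about half as much.
* **Bot scores**: Beta distributions parameterized by (mean,
  concentration 10), respecting the \([0,1]\) support; astroturf means
  0.25 (misinformation) vs 0.12 (fact), overall 0.35 vs 0.25, self-declared
  and fake-follower mildly elevated, financial and spammer equal across
  classes.
* **Authorship** is heavy-tailed (weights \(u^{-0.6}\)): large collections
  have several times more tweets than users, so multi-tweet authors are the
  norm. The true tweets-per-user law is not documented anywhere we know of;
  this default is a modeling choice and is configurable.

Misinformation tweets are authored only by misinformation-type users (and
vice versa), which makes class-conditional account statistics crisp; the
profiling code itself never assumes this and handles dual membership.
Determinism contract: a config (including its seed) generates
byte-identical corpora; all randomness flows through one local RNG that is
restored afterwards.

What passing tests on this generator do **not** show: real tweets have
grammar, sarcasm, code-switching and topic drift, none of which the bag
model produces, so classifier metrics on synthetic corpora say nothing
quantitative about real-data performance. Published real-data figures
(92% accuracy, 87% F-score on 7.2M proprietary tweets with external
inference services) are not reproducible at package scale and are not
asserted anywhere; the test suite instead checks the *mechanics* (budget
conservation, selection-rule equivalence to an exhaustive sort,
sample-efficiency of uncertainty sampling over random sampling at equal
budget) and *parameter recovery* (configured class contrasts re-estimated
within three standard errors).

## Numerical and design choices

* Half-up rounding for percentage rendering (R's `round()` is half-even);
  published tables with comma decimals are treated as typographic variants.
* SVM optimizer: tolerance 1e-4 on the maximal projected gradient, epoch
  cap 1000; the sweep order is a seeded shuffle, so training is exactly
  reproducible.
* `train_model()` refuses single-class input by naming the missing class;
  stratified cross-validation refuses classes smaller than \(k\).
* Degenerate inputs are values, not errors, where the analysis has a
  natural reading: empty series stay empty, constant series normalize to
  zero, a class with zero verified accounts has verified ratio 0, unmatched
  tweets are retained for content/timeline analyses and excluded from
  account profiling.
* Problem sizes in the test and acceptance runs — a 20,000-tweet corpus for
  the full 50-iteration budget check, 4,000-tweet corpora over 20 seeded
  replicates for the uncertainty-vs-random comparison, 1,000 accounts per
  class for parameter recovery — were chosen as the smallest sizes at which
  the checked quantities are statistically stable.

## Known limitations

* The gazetteer ships small (a term table for the countries the generator
  emits); real deployments should substitute a full one — coverage is a
  data concern, not code.
* The guideline criteria file encodes example patterns, not annotator
  judgment; it is advisory by construction.
* No retweet/network structure is generated or analyzed; spreader
  profiling is per-account, not per-cascade.
* Decision values are uncalibrated margins, not probabilities.
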