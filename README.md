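# misinfotrack

Surveillance of vaccine misinformation in Twitter-like corpora: who spreads
it, where, and when. The package is aimed at infodemiology / digital
public-health researchers who have (or simulate) a large collection of
vaccine-related tweets and want to

1. **bootstrap a labeled training set** from a small manual annotation pass
   plus keyword-query weak labeling,
2. **train a misinformation classifier with pool-based active learning**,
   spending an expert-labeling budget where the model is least confident,
3. **profile the spread** by country, by ISO week, and by account
   characteristics (demographics, engagement metrics, six-category bot
   scores).

Because large tweet collections are proprietary, the package includes a
first-class synthetic corpus generator whose defaults mirror the structure
such collections exhibit (≈6% misinformation prevalence,
class-discriminative vocabulary, English-speaking-country mixture,
event-driven weekly surges, class-conditional account statistics), so the
whole pipeline runs and is tested fully offline.

## The method in brief

The classifier is a linear SVM: L2-regularized hinge loss

```
min_w  0.5 ||w||^2 + C Σ_i max(0, 1 − y_i (w·x_i + b)),   C = 1
```

over tf-idf features (lowercase unigrams + bigrams, min document frequency
2, smooth idf, L2-normalized rows), trained by dual coordinate descent
(C++, deterministic under a seed). The decision value `f(x) = w·x + b` is
the distance-like margin to the separating hyperplane: `f(x) > 0` predicts
misinformation (class 1).

Active learning runs for up to 50 iterations. Each iteration selects the
100 pool tweets with the smallest `|f(x)|` (ties broken by ascending tweet
id), queries the labeling oracle, moves them into the training set,
retrains, and evaluates by stratified randomized 5-fold cross-validation —
a 5,000-label budget at the defaults. The vocabulary is fitted on the seed
set and frozen so decision values stay comparable across iterations.

Downstream, profile locations are normalized to countries with a
conservative gazetteer rule (conflicts and misses map to `UNMAPPED`, never
a guess), misinformation ratios are reported per country with half-up
one-decimal rendering, weekly series are ISO-week bucketed, zero-filled and
min-max normalized, and accounts are compared between the
misinformation-spreading and fact-sharing classes (membership: authored ≥1
tweet of the class).

## Worked example

```r
library(misinfotrack)

gen <- generate_corpus(generator_config(n_tweets = 5000, seed = 42))
gen$corpus
#> <misinfo_corpus>
#>   tweets:    5000
#>   users:     1667
#>   labels:    0
#>   unmatched: 0 tweet(s) without a user record

# 1. bootstrap labels: 400 oracle-labeled seeds + keyword augmentation
oracle <- make_oracle(gen$truth)           # simulated expert, counts queries
boot <- bootstrap_labels(gen$corpus$tweets, oracle, n_manual = 400,
                         query = augmentation_query(target_additions = 100),
                         seed = 1)
str(boot$report)
#> List of 4
#>  $ n_fact          : int 375
#>  $ n_misinformation: int 65
#>  $ total           : int 440
#>  $ n_overlap       : int 0

# 2. active learning: 10 iterations x 50 uncertainty-selected tweets
texts <- setNames(gen$corpus$tweets$text, gen$corpus$tweets$id)
res <- run_active_learning(texts, boot$labels[, c("tweet_id", "label")],
                           oracle, batch_size = 50, max_iterations = 10,
                           seed = 1)
tail(res$history[, c("iteration", "n_labeled", "accuracy", "f_score")], 1)
#>   iteration n_labeled accuracy f_score
#> 1        10       940    0.870   0.639
oracle_queries(oracle)   # manual seed (400) + keyword review (100+) + AL (500)
#> [1] 1000

# 3. classify everything, then summarize and profile
corpus <- set_corpus_labels(gen$corpus,
                            predict_corpus(res$model, res$featurizer, gen$corpus))
corpus <- map_corpus_countries(corpus)

cs <- country_summaries(corpus)
cs$ratio_percent <- format_ratio(cs$misinformation_ratio)
head(cs, 3)
#>   country  n_tweets n_misinformation misinformation_ratio ratio_percent
#> 1 UNMAPPED     1859               77              0.0414   4.1%
#> 2 US           1690              104              0.0615   6.2%
#> 3 UK            369               22              0.0596   6.0%

annotate_peak(minmax_normalize(weekly_series(corpus, class = "misinformation")))
#> $week
#> [1] "2020-50"     # the December surge week
#> $count
#> [1] 28

engagement_comparison(corpus)
#> <comparison_report>
#>   misinformation: 109 accounts | verified:unverified 0.009 | followers 493 | friends 1400 | favourites 8243
#>   fact: 1374 accounts | verified:unverified 0.059 | followers 2591 | friends 769 | favourites 11984
#>   fact/misinfo ratios: followers 5.26, friends 0.55, favourites 1.45, verified 6.32
#>   dual-membership accounts: 48
```

Reading the output: the cross-validated accuracy/F-score track the model on
its own (deliberately hard) labeled set; the country table reports exact
ratios plus their rendered percentages, with unmappable profile locations
aggregated under `UNMAPPED`; the peak annotation returns the earliest week
attaining the maximum misinformation count; and the comparison report shows
the expected class contrasts — fact-sharing accounts have ~5× the
followers, more favourites given and more verified badges, misinformation
spreaders have more friends.

The same stages are available as subcommands of a thin CLI
(`inst/cli/misinfo.R`): `generate`, `augment`, `train-al`, `classify`,
`summarize`, `profile`, composing through a run directory, plus
`run_pipeline()` / `pipeline` which chains everything and writes a manifest
with MD5 content hashes (equal seeds ⇒ identical manifests).

See `vignettes/misinfotrack-methods.Rmd` for the model, the generator's
defaults and what they emulate, and the design decisions.

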