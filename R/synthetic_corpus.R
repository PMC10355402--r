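#' @title Synthetic Twitter-like corpus generator
#' @description
#' Downstream stages are exercised on generated corpora that mirror the
#' statistical structure of large COVID-19 vaccine tweet collections:
#' roughly 6% misinformation prevalence; tweet texts drawn from
#' class-conditional bag-of-token distributions that share a background
#' vaccine vocabulary, with misinformation-indicator terms ("5g",
#' "microchip", "hoax", ...) concentrated in the misinformation class;
#' weekly volume over 2020-W44..2021-W21 with event-driven surges
#' (December emergency-use authorizations, the March volume peak);
#' a country mixture dominated by English-speaking countries; per-class
#' account engagement (fact-sharing accounts have about five times the
#' followers, 27% more favourites given, fewer friends, and three times the
#' verified rate of misinformation spreaders); demographic probability
#' vectors; and six-category bot scores with elevated astroturf means in
#' the misinformation class (0.25 vs 0.12).
#'
#' Texts are order-free token bags: the downstream featurization is
#' order-insensitive, so no grammar is simulated.
#' @name synthetic_corpus
NULL

default_background_vocab <- function() {
  c("vaccine", "vaccines", "covid", "coronavirus", "dose", "doses", "shot",
    "jab", "pfizer", "moderna", "astrazeneca", "johnson", "vaccination",
    "vaccinated", "appointment", "clinic", "pharmacy", "rollout", "booster",
    "immunity", "immune", "antibodies", "variant", "strain", "pandemic",
    "virus", "health", "public", "news", "update", "today", "tomorrow",
    "week", "month", "people", "everyone", "family", "friends", "mask",
    "masks", "distancing", "lockdown", "cases", "deaths", "hospital",
    "nurse", "doctor", "doctors", "science", "scientists", "study", "data",
    "trial", "trials", "efficacy", "effective", "safety", "safe", "side",
    "effects", "arm", "sore", "fever", "tired", "waiting", "line", "queue",
    "eligible", "age", "group", "priority", "essential", "workers",
    "teachers", "elderly", "parents", "kids", "children", "school",
    "work", "office", "travel", "passport", "border", "flight", "summer",
    "winter", "spring", "christmas", "holiday", "government", "minister",
    "president", "approval", "approved", "authorization", "emergency",
    "fda", "who", "cdc", "nhs", "supply", "shipment", "distribution",
    "centre", "center", "site", "online", "register", "registration",
    "first", "second", "finally", "got", "getting", "received", "take",
    "taking", "need", "want", "hope", "think", "know", "feel", "great",
    "good", "bad", "happy", "relieved", "grateful", "thank", "thanks",
    "please", "share", "read", "watch", "video", "article", "thread")
}

default_misinfo_terms <- function() {
  c("5g", "microchip", "hoax", "poison", "plandemic", "bioweapon",
    "depopulation", "sheeple", "magnetic", "untested", "experimental",
    "agenda", "control", "tracking", "dna", "toxins", "infertility")
}

default_fact_terms <- function() {
  c("evidence", "peer", "reviewed", "published", "confirmed", "protect",
    "protection", "recommended", "guidance", "official")
}

# exclude-term vocabulary: fact-class tweets occasionally *discuss* or debunk
# misinformation, which is what the augmentation query's exclusions catch
default_debunk_terms <- function() {
  c("misleading", "conspiracy", "debunked", "fact-check")
}

zipf_weights <- function(terms) {
  w <- 1 / seq_along(terms)
  setNames(w / sum(w), terms)
}

default_vocab_fact <- function() {
  bg <- zipf_weights(default_background_vocab())
  fact <- zipf_weights(default_fact_terms())
  mis <- zipf_weights(default_misinfo_terms())
  deb <- zipf_weights(default_debunk_terms())
  c(bg * 0.90, fact * 0.06, mis * 0.015, deb * 0.025)
}

default_vocab_misinfo <- function() {
  bg <- zipf_weights(default_background_vocab())
  fact <- zipf_weights(default_fact_terms())
  mis <- zipf_weights(default_misinfo_terms())
  deb <- zipf_weights(default_debunk_terms())
  c(bg * 0.70, fact * 0.02, mis * 0.25, deb * 0.03)
}

default_country_mixture <- function() {
  c(US = 0.40, UK = 0.107, India = 0.063, Canada = 0.062, Australia = 0.0145,
    Nigeria = 0.0139, Ireland = 0.0111, `South Africa` = 0.0097,
    France = 0.0078, Japan = 0.019, `South Korea` = 0.009, Singapore = 0.006,
    Spain = 0.012, Germany = 0.016, Netherlands = 0.009, other = 0.24)
}

default_surge_events <- function() {
  tibble::tibble(
    week = c("2020-50", "2020-51", "2021-10", "2020-52", "2021-01"),
    scope = "global",
    class = c("all", "all", "all", "misinformation", "misinformation"),
    multiplier = c(4, 4, 3, 2.5, 2.5)
  )
}

default_account_params <- function() {
  list(
    # log-normal engagement: stated means, sdlog 1 (heavy-tailed, like
    # real follower counts); fact accounts ~5x followers, ~27% more
    # favourites given; misinformation accounts ~25% more friends
    followers_mean = c(fact = 2500, misinfo = 500),
    friends_mean = c(fact = 800, misinfo = 1000),
    favourites_mean = c(fact = 12000, misinfo = 8760),
    sdlog = 1,
    verified_prob = c(fact = 0.06, misinfo = 0.02),
    org_prob = c(fact = 0.15, misinfo = 0.05),
    male_prob = c(fact = 0.55, misinfo = 0.52),
    # age mixture over <=18, 19-29, 30-39, >=40; misinformation volume is
    # dominated by >=40, with 19-29 posting about half as much
    age_mix = list(
      fact = c(0.15, 0.30, 0.30, 0.25),
      misinfo = c(0.20, 0.185, 0.245, 0.37)
    )
  )
}

default_bot_params <- function() {
  list(
    mean = list(
      fact = c(overall = 0.25, astroturf = 0.12, fake_follower = 0.12,
               self_declared = 0.13, financial = 0.05, spammer = 0.06),
      misinfo = c(overall = 0.35, astroturf = 0.25, fake_follower = 0.18,
                  self_declared = 0.20, financial = 0.05, spammer = 0.06)
    ),
    concentration = 10
  )
}

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline is meant to emulate;
#' see the package vignette for the rationale behind each value.
#'
#' @param n_tweets number of tweets to generate.
#' @param misinfo_prevalence fraction of misinformation tweets (default
#'   0.06).
#' @param date_range inclusive ISO week range, default
#'   `c("2020-44", "2021-21")`.
#' @param country_mixture named country weights (must sum to 1 within 1e-6);
#'   the reserved name `"other"` produces minor unlisted countries.
#' @param surge_events tibble (`week`, `scope`, `class`, `multiplier`)
#'   multiplying the weekly intensity; `scope` is `"global"` or a country,
#'   `class` is `"all"` or `"misinformation"`.
#' @param vocab_fact,vocab_misinfo named token-probability vectors for the
#'   two classes (shared background vocabulary plus class terms).
#' @param account_params per-class engagement/demographic distributions,
#'   see `default_account_params()`.
#' @param bot_params per-class Beta (mean, concentration) for the six
#'   bot-score categories, see `default_bot_params()`.
#' @param n_users size of the author pool (default `ceiling(n_tweets / 3)`);
#'   authorship is heavy-tailed, so some users tweet many times.
#' @param user_misinfo_fraction fraction of the user pool that are
#'   misinformation spreaders (default 0.08).
#' @param unmappable_fraction fraction of users whose profile location is
#'   free text no gazetteer can map (default 0.12).
#' @param tokens_per_tweet mean token count of a generated text.
#' @param seed RNG seed; the same config generates byte-identical corpora.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_tweets = 10000L,
                             misinfo_prevalence = 0.06,
                             date_range = c("2020-44", "2021-21"),
                             country_mixture = default_country_mixture(),
                             surge_events = default_surge_events(),
                             vocab_fact = default_vocab_fact(),
                             vocab_misinfo = default_vocab_misinfo(),
                             account_params = default_account_params(),
                             bot_params = default_bot_params(),
                             n_users = NULL,
                             user_misinfo_fraction = 0.08,
                             unmappable_fraction = 0.12,
                             tokens_per_tweet = 11,
                             seed = 1L) {
  if (n_tweets < 1) stop("n_tweets must be at least 1")
  if (misinfo_prevalence < 0 || misinfo_prevalence > 1) {
    stop("misinfo_prevalence must be in [0, 1]")
  }
  if (length(vocab_fact) == 0 || length(vocab_misinfo) == 0) {
    stop("class vocabularies must be non-empty", call. = FALSE)
  }
  if (abs(sum(country_mixture) - 1) > 1e-6) {
    stop("country_mixture must sum to 1", call. = FALSE)
  }
  structure(
    list(n_tweets = as.integer(n_tweets),
         misinfo_prevalence = misinfo_prevalence,
         date_range = date_range, country_mixture = country_mixture,
         surge_events = surge_events,
         vocab_fact = vocab_fact / sum(vocab_fact),
         vocab_misinfo = vocab_misinfo / sum(vocab_misinfo),
         account_params = account_params, bot_params = bot_params,
         n_users = as.integer(n_users %null% max(2L, ceiling(n_tweets / 3))),
         user_misinfo_fraction = user_misinfo_fraction,
         unmappable_fraction = unmappable_fraction,
         tokens_per_tweet = tokens_per_tweet,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

rbeta_mean <- function(n, mean, concentration) {
  mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  rbeta(n, mean * concentration, (1 - mean) * concentration)
}

# probability vector over `k` categories whose argmax is `pick`
argmax_probs <- function(pick, k) {
  p <- runif(k, 0.02, 0.30)
  p[pick] <- runif(1, 1.2, 2.5) * max(p)
  p / sum(p)
}

sample_week_keys <- function(n, cfg, class) {
  weeks <- iso_week_seq(cfg$date_range[1], cfg$date_range[2])
  w <- setNames(rep(1, length(weeks)), weeks)
  ev <- cfg$surge_events
  if (!is.null(ev) && nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      if (ev$class[i] != "all" && ev$class[i] != class) next
      if (!ev$week[i] %in% weeks) next
      w[ev$week[i]] <- w[ev$week[i]] * ev$multiplier[i]
    }
  }
  sample(weeks, n, replace = TRUE, prob = w / sum(w))
}

unmappable_locations <- function() {
  c("the moon", "everywhere and nowhere", "worldwide", "earth",
    "in my head", "your heart", "127.0.0.1", "hell", "somewhere",
    "wonderland", "milky way", "internet", "")
}

location_for_country <- function(country, gaz_split) {
  if (country == "other") return("somewhere else")
  terms <- gaz_split[[country]]
  if (is.null(terms)) return(country)
  pick <- sample(terms, 1)
  style <- runif(1)
  if (style < 0.45) pick
  else if (style < 0.8) paste0(pick, ", ", country)
  else country
}

generate_users <- function(cfg, gaz) {
  n <- cfg$n_users
  ap <- cfg$account_params
  type <- ifelse(runif(n) < cfg$user_misinfo_fraction, "misinfo", "fact")
  # avoid degenerate pools so both tweet classes always find an author
  if (!any(type == "misinfo")) type[1] <- "misinfo"
  if (!any(type == "fact")) type[1] <- "fact"
  country <- sample(names(cfg$country_mixture), n, replace = TRUE,
                    prob = cfg$country_mixture)
  gaz_split <- split(gaz$term[gaz$n_tokens >= 1], gaz$country)
  # drop the deliberately ambiguous terms from location generation
  amb <- names(table(unique(gaz[, c("term", "country")])$term)[
    table(unique(gaz[, c("term", "country")])$term) > 1])
  gaz_split <- lapply(gaz_split, function(t) setdiff(t, amb))
  loc <- vapply(country, location_for_country, character(1),
                gaz_split = gaz_split)
  junk <- runif(n) < cfg$unmappable_fraction
  loc[junk] <- sample(unmappable_locations(), sum(junk), replace = TRUE)

  lmean <- function(m) log(m) - ap$sdlog^2 / 2
  followers <- as.integer(round(rlnorm(n, lmean(ap$followers_mean[type]), ap$sdlog)))
  friends <- as.integer(round(rlnorm(n, lmean(ap$friends_mean[type]), ap$sdlog)))
  favourites <- as.integer(round(rlnorm(n, lmean(ap$favourites_mean[type]), ap$sdlog)))
  verified <- runif(n) < ap$verified_prob[type]
  org <- runif(n) < ap$org_prob[type]
  male <- runif(n) < ap$male_prob[type]
  age <- vapply(type, function(tp) {
    sample.int(4, 1, prob = ap$age_mix[[tp]])
  }, integer(1))

  tibble::tibble(
    id = sprintf("u%06d", seq_len(n)),
    screen_name = sprintf("user%06d", seq_len(n)),
    name = paste("User", seq_len(n)),
    profile_location = unname(loc),
    description = ifelse(type == "misinfo",
                         "independent thinker. do your own research",
                         "sharing news and updates"),
    followers_count = pmax(followers, 0L),
    friends_count = pmax(friends, 0L),
    favourites_count = pmax(favourites, 0L),
    verified = unname(verified),
    type = unname(type), org = unname(org), male = unname(male),
    age_group_idx = unname(age)
  )
}

generate_demographics <- function(users) {
  n <- nrow(users)
  age <- t(vapply(users$age_group_idx, argmax_probs, numeric(4), k = 4))
  gender <- t(vapply(ifelse(users$male, 1L, 2L), argmax_probs, numeric(2), k = 2))
  org <- t(vapply(ifelse(users$org, 1L, 2L), argmax_probs, numeric(2), k = 2))
  colnames(age) <- paste0("age_", c("le18", "19_29", "30_39", "ge40"))
  colnames(gender) <- c("gender_male", "gender_female")
  colnames(org) <- c("org_org", "org_non_org")
  dplyr::bind_cols(tibble::tibble(user_id = users$id),
                   tibble::as_tibble(age), tibble::as_tibble(gender),
                   tibble::as_tibble(org))
}

generate_bot_scores <- function(users, bp) {
  out <- tibble::tibble(user_id = users$id)
  for (cat in .bot_categories) {
    mu <- vapply(users$type, function(tp) bp$mean[[tp]][[cat]], numeric(1))
    out[[cat]] <- rbeta_mean(nrow(users), mu, bp$concentration)
  }
  out
}

generate_text <- function(vocab, n_tokens) {
  paste(sample(names(vocab), n_tokens, replace = TRUE, prob = vocab),
        collapse = " ")
}

#' Generate a synthetic corpus with ground-truth labels
#'
#' Deterministic given the config seed: the same config yields
#' byte-identical tables. Truth labels are returned separately from the
#' corpus, as the simulated analogue of expert knowledge.
#'
#' @param config a [generator_config()].
#' @param gazetteer gazetteer used to draw mappable profile locations
#'   (default: the shipped one).
#' @return list with `corpus` (a `misinfo_corpus` including demographics
#'   and bot scores) and `truth` (tibble `tweet_id`, `label`).
#' @export
generate_corpus <- function(config = generator_config(),
                            gazetteer = load_gazetteer()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    users <- generate_users(config, gazetteer)
    demographics <- generate_demographics(users)
    bot_scores <- generate_bot_scores(users, config$bot_params)

    n <- config$n_tweets
    label <- as.integer(runif(n) < config$misinfo_prevalence)
    # heavy-tailed authorship: a few prolific accounts, many occasional ones
    author_weight <- runif(nrow(users))^(-0.6)
    idx_mis <- which(users$type == "misinfo")
    idx_fact <- which(users$type == "fact")
    author <- integer(n)
    if (any(label == 1L)) {
      author[label == 1L] <- sample(idx_mis, sum(label == 1L), replace = TRUE,
                                    prob = author_weight[idx_mis])
    }
    if (any(label == 0L)) {
      author[label == 0L] <- sample(idx_fact, sum(label == 0L), replace = TRUE,
                                    prob = author_weight[idx_fact])
    }

    week <- character(n)
    if (any(label == 1L)) {
      week[label == 1L] <- sample_week_keys(sum(label == 1L), config,
                                            "misinformation")
    }
    if (any(label == 0L)) {
      week[label == 0L] <- sample_week_keys(sum(label == 0L), config, "all")
    }
    start <- iso_week_start(week)
    date <- as.POSIXct(start, tz = "UTC") +
      floor(runif(n, 0, 7 * 24 * 3600)) # whole seconds within the ISO week

    n_tok <- pmax(4L, rpois(n, config$tokens_per_tweet))
    text <- vapply(seq_len(n), function(i) {
      generate_text(if (label[i] == 1L) config$vocab_misinfo else config$vocab_fact,
                    n_tok[i])
    }, character(1))

    id <- sprintf("t%07d", seq_len(n))
    username <- users$screen_name[author]
    has_link <- runif(n) < 0.2
    outlinks <- lapply(seq_len(n), function(i) {
      if (has_link[i]) sprintf("https://example.org/a/%d", i) else character(0)
    })
    tweets <- tibble::tibble(
      id = id, date = date, text = text,
      url = sprintf("https://twitter.com/%s/status/%s", username, id),
      username = username, outlinks = outlinks,
      retweet_count = rpois(n, ifelse(label == 1L, 3, 5)),
      reply_count = rpois(n, 2),
      like_count = rpois(n, ifelse(label == 1L, 6, 10)),
      quote_count = rpois(n, 1)
    )
    truth <- tibble::tibble(tweet_id = id, label = label)
    corpus <- join_corpus(
      tweets,
      users[, c("id", "screen_name", "name", "profile_location", "description",
                "followers_count", "friends_count", "favourites_count",
                "verified")],
      demographics = demographics, bot_scores = bot_scores
    )
    # latent user type kept alongside for test-time parameter recovery
    attr(corpus, "user_type") <- setNames(users$type, users$id)
    list(corpus = corpus, truth = truth)
  })
}

#' Simulated labeling expert
#'
#' Wraps a truth table into an oracle function for [run_active_learning()]:
#' a pure lookup that counts how many labels it has been asked for, so the
#' labeling budget of a run can be measured.
#'
#' @param truth tibble with `tweet_id` and `label`.
#' @return a function `ids -> labels` with a query counter readable via
#'   [oracle_queries()]; unknown ids are an error.
#' @export
make_oracle <- function(truth) {
  assert_columns(truth, c("tweet_id", "label"), "truth")
  lut <- setNames(as.integer(truth$label), truth$tweet_id)
  count <- 0L
  oracle <- function(ids) {
    unknown <- setdiff(ids, names(lut))
    if (length(unknown) > 0) {
      stop("oracle queried for unknown tweet id(s): ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    count <<- count + length(ids)
    unname(lut[ids])
  }
  class(oracle) <- c("misinfo_oracle", "function")
  oracle
}

#' Number of labels an oracle has been asked for
#'
#' @param oracle a [make_oracle()] function.
#' @return integer query count.
#' @export
oracle_queries <- function(oracle) {
  stopifnot(inherits(oracle, "misinfo_oracle"))
  environment(oracle)$count
}
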