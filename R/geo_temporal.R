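#' @title Location normalization and misinformation summaries by place and week
#' @description
#' Self-reported profile locations are free text ("Toronto, Ontario",
#' "earth", "Lagos Nigeria"). They are normalized to canonical country names
#' with a gazetteer: a flat term table mapping country, region, province and
#' city names to a country. A location maps to a country only when its
#' matched terms agree on a single country; conflicting or absent matches
#' yield the `"UNMAPPED"` sentinel rather than a guess.
#' @name geo_temporal
NULL

#' Sentinel country for locations that cannot be normalized
#' @export
UNMAPPED <- "UNMAPPED"

#' Load a gazetteer term table
#'
#' @param path CSV with columns `term`, `country`. Defaults to the small
#'   gazetteer shipped with the package (English-speaking countries plus the
#'   other countries the generator emits). Terms are matched
#'   case-insensitively; a term listed under two countries (e.g. "georgia")
#'   is an intentional ambiguity and resolves to `UNMAPPED`.
#' @return tibble with columns `term`, `country`, `n_tokens`.
#' @export
load_gazetteer <- function(path = NULL) {
  path <- path %null% system.file("extdata", "gazetteer.csv",
                                  package = "misinfotrack")
  gaz <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  assert_columns(gaz, c("term", "country"), "gazetteer")
  gaz$term <- tolower(trimws(gaz$term))
  gaz$n_tokens <- lengths(strsplit(gaz$term, "[[:space:]]+"))
  # every canonical country must be findable under its own name
  missing_self <- setdiff(tolower(unique(gaz$country)), gaz$term)
  if (length(missing_self) > 0) {
    stop("gazetteer lacks self-entries for: ",
         paste(missing_self, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(gaz, dplyr::desc(.data$n_tokens), .data$term)
}

#' Map free-text profile locations to countries
#'
#' Tokenizes on commas and whitespace, scans for gazetteer terms as
#' contiguous token runs (longest terms first; tokens consumed by a longer
#' match are not reused), and returns the country when all surviving
#' matches agree. Empty strings, unmatched text, and terms pointing at two
#' different countries all return [UNMAPPED].
#'
#' @param location character vector of profile locations.
#' @param gazetteer as returned by [load_gazetteer()].
#' @return character vector of canonical countries or [UNMAPPED].
#' @export
map_location <- function(location, gazetteer) {
  max_len <- max(gazetteer$n_tokens)
  lut <- split(gazetteer$country, gazetteer$term)
  vapply(as.character(location), function(loc) {
    if (is.na(loc) || !nzchar(trimws(loc))) return(UNMAPPED)
    toks <- strsplit(tolower(loc), "[,[:space:]]+")[[1]]
    toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) return(UNMAPPED)
    used <- rep(FALSE, length(toks))
    countries <- character(0)
    for (len in seq(min(max_len, length(toks)), 1L)) {
      if (length(toks) < len) next
      for (start in seq_len(length(toks) - len + 1L)) {
        span <- start:(start + len - 1L)
        if (any(used[span])) next
        cand <- paste(toks[span], collapse = " ")
        hit <- lut[[cand]]
        if (!is.null(hit)) {
          used[span] <- TRUE
          countries <- c(countries, unique(hit))
        }
      }
    }
    countries <- unique(countries)
    if (length(countries) == 1) countries else UNMAPPED
  }, character(1), USE.NAMES = FALSE)
}

#' Derive the country of every user in a corpus
#'
#' @param corpus a `misinfo_corpus`.
#' @param gazetteer as returned by [load_gazetteer()].
#' @return the corpus with a `country` column on `users`.
#' @export
map_corpus_countries <- function(corpus, gazetteer = load_gazetteer()) {
  stopifnot(inherits(corpus, "misinfo_corpus"))
  corpus$users$country <- map_location(corpus$users$profile_location, gazetteer)
  corpus
}

tweet_class_table <- function(corpus) {
  stopifnot(inherits(corpus, "misinfo_corpus"))
  if (is.null(corpus$labels)) {
    stop("corpus has no labels; classify it first", call. = FALSE)
  }
  lab <- corpus$labels[, c("tweet_id", "label")]
  dplyr::left_join(corpus$tweets, lab, by = c(id = "tweet_id"))
}

#' Per-country tweet and misinformation counts
#'
#' One row per country with at least one tweet, plus an `UNMAPPED` row
#' aggregating tweets whose author has no mappable location (or no user
#' record at all). Ratios are exact fractions; use [format_ratio()] for the
#' percentage rendering.
#'
#' @param corpus a labeled `misinfo_corpus` whose users carry a `country`
#'   column (see [map_corpus_countries()]).
#' @return tibble with `country`, `n_tweets`, `n_misinformation`,
#'   `misinformation_ratio`, sorted by `n_tweets` descending.
#' @export
country_summaries <- function(corpus) {
  if (!"country" %in% names(corpus$users)) {
    stop("users have no 'country' column; run map_corpus_countries() first",
         call. = FALSE)
  }
  tw <- tweet_class_table(corpus)
  tw$country <- corpus$users$country[match(tw$user_id, corpus$users$id)]
  tw$country[is.na(tw$country)] <- UNMAPPED
  tw |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      n_tweets = dplyr::n(),
      n_misinformation = sum(.data$label == 1L, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      misinformation_ratio = ifelse(.data$n_tweets > 0,
                                    .data$n_misinformation / .data$n_tweets, 0)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_tweets))
}

#' Render a misinformation ratio as a percentage
#'
#' One decimal place, half-up rounding, trailing ".0" kept (a ratio of
#' exactly 7% renders as `"7.0%"`).
#'
#' @param ratio numeric in `[0, 1]`.
#' @return character vector like `"6.8%"`.
#' @export
format_ratio <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0 | ratio > 1)) {
    stop("ratio must be in [0, 1]", call. = FALSE)
  }
  sprintf("%.1f%%", round_half_up(ratio * 100, 1))
}

#' Weekly tweet counts
#'
#' Buckets tweets by the ISO-8601 week of their UTC timestamp, fills
#' interior weeks with zero counts, and optionally restricts to one country
#' and/or the misinformation class.
#'
#' @param corpus a `misinfo_corpus` (labels required when
#'   `class = "misinformation"`; countries required when filtering).
#' @param country optional canonical country filter.
#' @param class `"all"` or `"misinformation"`.
#' @return tibble with `week` (`"YYYY-WW"`) and `count`, strictly increasing
#'   week keys; empty input gives an empty series.
#' @export
weekly_series <- function(corpus, country = NULL, class = c("all", "misinformation")) {
  class <- match.arg(class)
  tw <- corpus$tweets
  if (!is.null(country)) {
    if (!"country" %in% names(corpus$users)) {
      stop("users have no 'country' column; run map_corpus_countries() first",
           call. = FALSE)
    }
    ctry <- corpus$users$country[match(tw$user_id, corpus$users$id)]
    ctry[is.na(ctry)] <- UNMAPPED
    tw <- tw[ctry == country, , drop = FALSE]
  }
  if (class == "misinformation") {
    lab <- corpus$labels
    if (is.null(lab)) stop("corpus has no labels; classify it first", call. = FALSE)
    keep <- lab$tweet_id[lab$label == 1L]
    tw <- tw[tw$id %in% keep, , drop = FALSE]
  }
  if (nrow(tw) == 0) {
    return(tibble::tibble(week = character(0), count = integer(0)))
  }
  wk <- iso_week_key(tw$date)
  counts <- table(wk)
  all_weeks <- iso_week_seq(min(wk), max(wk))
  tibble::tibble(
    week = all_weeks,
    count = as.integer(ifelse(all_weeks %in% names(counts),
                              counts[all_weeks], 0L))
  )
}

#' Min-max normalize a weekly series
#'
#' Adds a `normalized` column: `(v - min) / (max - min)`. A constant series
#' (max equals min) normalizes to all zeros.
#'
#' @param series tibble with `week` and `count` (from [weekly_series()]).
#' @return the series with a `normalized` column in `[0, 1]`.
#' @export
minmax_normalize <- function(series) {
  if (nrow(series) == 0) stop("cannot normalize an empty series", call. = FALSE)
  v <- as.numeric(series$count)
  rng <- range(v)
  series$normalized <- if (rng[2] == rng[1]) rep(0, length(v)) else {
    (v - rng[1]) / (rng[2] - rng[1])
  }
  series
}

#' Peak week of a series
#'
#' @param series tibble with `week` and `count`.
#' @return list with `week` (the earliest week attaining the maximum raw
#'   count) and `count`.
#' @export
annotate_peak <- function(series) {
  if (nrow(series) == 0) stop("cannot annotate an empty series", call. = FALSE)
  i <- which.max(series$count) # which.max returns the first (earliest) maximum
  list(week = series$week[i], count = as.integer(series$count[i]))
}
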