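#' @title Tweet, user and label tables
#' @description
#' The pipeline works on three flat tables. A *tweet* row is one post with
#' its text, UTC timestamp, author username and engagement counts; a *user*
#' row is the author metadata (profile location, follower/friend/favourite
#' totals, verified flag); a *label* row assigns a tweet to class 1
#' (misinformation) or 0 (fact) together with the provenance of that
#' assignment (`manual`, `keyword_augmented`, `oracle`, `predicted`) and,
#' for predicted labels, the signed decision value of the classifier.
#'
#' Tables are read from JSONL (one record per line) or headed CSV. Raw
#' Twitter-API camelCase field names (`retweetCount`, `screenName`,
#' `profileLocation`, ...) and snake_case names are both accepted; columns
#' are normalized to snake_case internally, and the raw `tweet` column name
#' is accepted as an alias for `text`.
#' @name data_model
NULL

# canonical column -> accepted aliases (first alias is the raw API name)
.tweet_aliases <- list(
  id = "id", date = "date", text = "tweet", url = "url",
  username = "username", outlinks = "outlinks",
  retweet_count = "retweetCount", reply_count = "replyCount",
  like_count = "likeCount", quote_count = "quoteCount"
)
.user_aliases <- list(
  id = "id", screen_name = "screenName", name = "name",
  profile_location = "profileLocation", description = "description",
  followers_count = "followersCount", friends_count = "friendsCount",
  favourites_count = "favouritesCount", verified = "verified",
  country = "country", profile_image_ref = "profileImageRef"
)
.label_aliases <- list(
  tweet_id = "tweetId", label = "label", source = "source",
  confidence = "confidence"
)

.schema_required <- list(
  tweet = c("id", "date", "text", "url", "username", "outlinks",
            "retweet_count", "reply_count", "like_count", "quote_count"),
  user = c("id", "screen_name", "name", "profile_location", "description",
           "followers_count", "friends_count", "favourites_count", "verified"),
  label = c("tweet_id", "label", "source")
)

.schema_aliases <- function(schema) {
  switch(schema,
    tweet = .tweet_aliases,
    user = .user_aliases,
    label = .label_aliases,
    stop("unknown schema: ", schema)
  )
}

normalize_names <- function(df, schema) {
  aliases <- .schema_aliases(schema)
  nm <- names(df)
  for (canon in names(aliases)) {
    hit <- which(nm %in% c(canon, aliases[[canon]]))
    if (length(hit) > 0) nm[hit[1]] <- canon
  }
  names(df) <- nm
  df
}

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%d")
  for (f in fmts) {
    todo <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = f, tz = "UTC")
  }
  out
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# outlinks: list-column of character vectors <-> JSON array strings (CSV cells)
outlinks_to_json <- function(outlinks) {
  vapply(outlinks, function(v) {
    as.character(jsonlite::toJSON(as.character(v %null% character(0))))
  }, character(1))
}

outlinks_from_json <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    as.character(jsonlite::fromJSON(s))
  })
}

validate_table <- function(df, schema) {
  required <- .schema_required[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema '", schema, "': missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (schema == "tweet") {
    raw_date <- df$date
    df$date <- parse_utc(df$date)
    bad <- which(is.na(df$date))
    if (length(bad) > 0) {
      stop("unparseable date in row(s) ", paste(head(bad, 10), collapse = ", "),
           " (e.g. '", as.character(raw_date[bad[1]]), "')", call. = FALSE)
    }
    if (!is.list(df$outlinks)) df$outlinks <- outlinks_from_json(df$outlinks)
    for (col in c("retweet_count", "reply_count", "like_count", "quote_count")) {
      df[[col]] <- as.integer(df[[col]])
      bad <- which(is.na(df[[col]]) | df[[col]] < 0)
      if (length(bad) > 0) {
        stop("column '", col, "': negative or non-numeric count in row(s) ",
             paste(head(bad, 10), collapse = ", "), call. = FALSE)
      }
    }
    df$id <- as.character(df$id)
    dup <- df$id[duplicated(df$id)]
    if (length(dup) > 0) {
      stop("duplicate tweet id(s): ", paste(head(unique(dup), 5), collapse = ", "),
           call. = FALSE)
    }
  } else if (schema == "user") {
    for (col in c("followers_count", "friends_count", "favourites_count")) {
      df[[col]] <- as.integer(df[[col]])
      bad <- which(is.na(df[[col]]) | df[[col]] < 0)
      if (length(bad) > 0) {
        stop("column '", col, "': negative or non-numeric count in row(s) ",
             paste(head(bad, 10), collapse = ", "), call. = FALSE)
      }
    }
    df$verified <- as.logical(df$verified)
    df$id <- as.character(df$id)
    dup <- tolower(df$screen_name)[duplicated(tolower(df$screen_name))]
    if (length(dup) > 0) {
      stop("duplicate screen_name(s) in user table: ",
           paste(head(unique(dup), 5), collapse = ", "), call. = FALSE)
    }
  } else if (schema == "label") {
    df$label <- as.integer(df$label)
    bad <- which(!df$label %in% c(0L, 1L))
    if (length(bad) > 0) {
      stop("label must be 0 or 1; offending row(s): ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    }
    df$tweet_id <- as.character(df$tweet_id)
    if (!"confidence" %in% names(df)) df$confidence <- NA_real_
    df$confidence <- suppressWarnings(as.numeric(df$confidence))
  }
  tibble::as_tibble(df)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

#' Read a tweet, user or label table
#'
#' Reads a headed CSV or JSONL (one JSON object per line) file, accepts
#' camelCase or snake_case column names, validates the rows against the
#' schema, and returns a tibble with snake_case columns. Malformed rows
#' (unparseable dates, negative counts, out-of-range labels) raise errors
#' that name the offending rows.
#'
#' @param path file to read.
#' @param schema one of `"tweet"`, `"user"`, `"label"`.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension if `NULL`.
#' @return a validated tibble.
#' @export
read_corpus_table <- function(path, schema = c("tweet", "user", "label"),
                              format = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %null% guess_format(path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      df <- tibble::as_tibble(setNames(
        rep(list(character(0)), length(.schema_required[[schema]])),
        .schema_required[[schema]]
      ))
      if (schema == "tweet") {
        df$outlinks <- list()
        df$date <- parse_utc(character(0))
      }
      return(validate_table(df, schema))
    }
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    nm <- names(recs[[1]])
    df <- tibble::as_tibble(lapply(setNames(nm, nm), function(col) {
      vals <- lapply(recs, function(r) r[[col]])
      if (col %in% c("outlinks", "outlinks_json")) {
        lapply(vals, function(v) as.character(v %null% character(0)))
      } else {
        unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
      }
    }))
  } else {
    # na = character(): empty cells stay empty strings (profile_location may
    # legitimately be ""), nothing becomes NA on the way back in
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE)
  }
  df <- normalize_names(df, schema)
  validate_table(df, schema)
}

#' Write a tweet, user or label table
#'
#' Inverse of [read_corpus_table()]: writes UTF-8 CSV (with the `outlinks`
#' list-column serialized as a JSON array string) or JSONL. Timestamps are
#' written as ISO-8601 UTC (`...Z`), so a write-then-read round trip
#' preserves every field.
#'
#' @param df table to write (as returned by the readers or the generator).
#' @param path output file.
#' @param schema one of `"tweet"`, `"user"`, `"label"`.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_corpus_table <- function(df, path, schema = c("tweet", "user", "label"),
                               format = NULL) {
  schema <- match.arg(schema)
  format <- format %null% guess_format(path)
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  if (schema == "tweet") {
    out$date <- format_utc(out$date)
    if (format == "csv") {
      out$outlinks <- outlinks_to_json(out$outlinks)
    }
  }
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(out) > 0) {
      for (i in seq_len(nrow(out))) {
        rec <- lapply(out[i, , drop = FALSE], function(col) {
          v <- if (is.list(col)) col[[1]] else col
          v
        })
        writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")),
                   con)
      }
    }
  } else {
    readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  }
  invisible(path)
}

#' Join tweet and user tables into a corpus
#'
#' Tweets are matched to user records case-insensitively on
#' `username`/`screen_name`. Tweets whose author has no user record are
#' flagged in `unmatched` but retained: they still contribute to content
#' and timeline analyses, and are only excluded from account profiling.
#'
#' @param tweets validated tweet table.
#' @param users validated user table; duplicate screen names are an error.
#' @param labels optional label table (`tweet_id`, `label`, `source`,
#'   `confidence`).
#' @param demographics optional tibble keyed by `user_id` with the three
#'   demographic probability vectors (see [assign_demographics()]).
#' @param bot_scores optional tibble keyed by `user_id` with the six
#'   bot-score categories in `[0, 1]`.
#' @return an object of class `misinfo_corpus`: a list with elements
#'   `tweets`, `users`, `labels`, `demographics`, `bot_scores` and
#'   `unmatched` (ids of tweets without a user record).
#' @export
join_corpus <- function(tweets, users, labels = NULL, demographics = NULL,
                        bot_scores = NULL) {
  assert_columns(tweets, c("id", "username", "text", "date"), "tweets")
  assert_columns(users, c("screen_name"), "users")
  key <- tolower(users$screen_name)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicate screen_name(s) in user table: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(labels)) {
    extra <- setdiff(labels$tweet_id, tweets$id)
    if (length(extra) > 0) {
      stop("label table refers to unknown tweet id(s): ",
           paste(head(extra, 5), collapse = ", "), call. = FALSE)
    }
  }
  idx <- match(tolower(tweets$username), key)
  tweets$user_id <- ifelse(is.na(idx), NA_character_, users$id[idx])
  unmatched <- tweets$id[is.na(idx)]
  structure(
    list(tweets = tibble::as_tibble(tweets), users = tibble::as_tibble(users),
         labels = if (is.null(labels)) NULL else tibble::as_tibble(labels),
         demographics = demographics, bot_scores = bot_scores,
         unmatched = unmatched),
    class = "misinfo_corpus"
  )
}

#' @export
print.misinfo_corpus <- function(x, ...) {
  cat("<misinfo_corpus>\n")
  cat("  tweets:    ", nrow(x$tweets), "\n", sep = "")
  cat("  users:     ", nrow(x$users), "\n", sep = "")
  cat("  labels:    ", if (is.null(x$labels)) 0 else nrow(x$labels), "\n", sep = "")
  cat("  unmatched: ", length(x$unmatched), " tweet(s) without a user record\n",
      sep = "")
  invisible(x)
}

#' Attach (or replace) final labels on a corpus
#'
#' @param corpus a `misinfo_corpus`.
#' @param labels a label table covering tweets of the corpus.
#' @return the corpus with `labels` set.
#' @export
set_corpus_labels <- function(corpus, labels) {
  stopifnot(inherits(corpus, "misinfo_corpus"))
  extra <- setdiff(labels$tweet_id, corpus$tweets$id)
  if (length(extra) > 0) {
    stop("label table refers to unknown tweet id(s): ",
         paste(head(extra, 5), collapse = ", "), call. = FALSE)
  }
  corpus$labels <- tibble::as_tibble(labels)
  corpus
}
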