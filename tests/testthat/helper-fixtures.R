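# Shared fixtures, built in code.

tiny_users <- function() {
  tibble::tibble(
    id = c("u1", "u2"),
    screen_name = c("alice", "bob"),
    name = c("Alice", "Bob"),
    profile_location = c("Toronto, Ontario", "London"),
    description = c("", ""),
    followers_count = c(10L, 20L),
    friends_count = c(5L, 8L),
    favourites_count = c(100L, 50L),
    verified = c(TRUE, FALSE)
  )
}

tiny_tweets <- function(usernames = c("alice", "bob", "alice")) {
  n <- length(usernames)
  tibble::tibble(
    id = sprintf("t%02d", seq_len(n)),
    date = as.POSIXct("2020-11-01 12:00:00", tz = "UTC") + seq_len(n) * 3600,
    text = paste("vaccine update number", seq_len(n)),
    url = paste0("https://twitter.com/x/status/", seq_len(n)),
    username = usernames,
    outlinks = rep(list(character(0)), n),
    retweet_count = seq_len(n),
    reply_count = rep(0L, n),
    like_count = rep(1L, n),
    quote_count = rep(0L, n)
  )
}

# small generated corpus shared across tests (cached per session)
shared_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(generator_config(n_tweets = 2000, seed = 42))
    }
    cache
  }
})

# hand-built labeled corpus: two classes with known account characteristics
labeled_toy_corpus <- function() {
  users <- tibble::tibble(
    id = sprintf("u%d", 1:6),
    screen_name = sprintf("acct%d", 1:6),
    name = sprintf("Account %d", 1:6),
    profile_location = c("New York", "London", "Toronto", "Lagos", "", "nowhere"),
    description = "",
    followers_count = c(100L, 200L, 300L, 10L, 20L, 30L),
    friends_count = c(50L, 60L, 70L, 80L, 90L, 100L),
    favourites_count = c(500L, 600L, 700L, 100L, 200L, 300L),
    verified = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  tweets <- tiny_tweets(c("acct1", "acct2", "acct3", "acct4", "acct5", "acct6"))
  labels <- tibble::tibble(
    tweet_id = tweets$id,
    label = c(0L, 0L, 0L, 1L, 1L, 1L),
    source = "manual", confidence = NA_real_
  )
  join_corpus(tweets, users, labels = labels)
}

# larger corpus for distribution-recovery checks (cached per session)
shared_gen10k <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(generator_config(n_tweets = 10000, seed = 7))
    }
    cache
  }
})

# temp file under the session tempdir (cleaned up when the session ends)
scratch_file <- function(ext = "") {
  tempfile(fileext = ext)
}
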