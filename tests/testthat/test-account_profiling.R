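demo_row <- function(age = c(0.25, 0.25, 0.25, 0.25), gender = c(0.5, 0.5),
                     org = c(0.5, 0.5), id = "u1") {
  tibble::tibble(
    user_id = id,
    age_le18 = age[1], age_19_29 = age[2], age_30_39 = age[3], age_ge40 = age[4],
    gender_male = gender[1], gender_female = gender[2],
    org_org = org[1], org_non_org = org[2]
  )
}

test_that("demographics are assigned by argmax with fixed tie preferences", {
  a <- assign_demographics(demo_row(age = c(0.1, 0.2, 0.3, 0.4),
                                    gender = c(0.7, 0.3), org = c(0.2, 0.8)))
  expect_equal(a$age_group, ">=40")
  expect_equal(a$gender, "male")
  expect_equal(a$org_status, "non-org")
  expect_false(a$tie)

  # highest probability on the under-18 bin -> first age category
  b <- assign_demographics(demo_row(age = c(0.4, 0.3, 0.2, 0.1),
                                    gender = c(0.7, 0.3), org = c(0.2, 0.8)))
  expect_equal(b$age_group, "<=18")

  # uniform gender -> female, tie flagged
  tie <- suppressMessages(
    assign_demographics(demo_row(age = c(0.1, 0.2, 0.3, 0.4),
                                 gender = c(0.5, 0.5), org = c(0.2, 0.8))))
  expect_equal(tie$gender, "female")
  expect_true(tie$tie)
})

test_that("invalid probability vectors are rejected", {
  expect_error(assign_demographics(demo_row(age = c(0.5, 0.2, 0.2, 0.2))),
               "sum to 1")
})

test_that("argmax assignment is permutation-consistent", {
  set.seed(50)
  for (rep in 1:10) {
    p <- runif(4)
    p <- p / sum(p)
    perm <- sample(4)
    a <- assign_demographics(demo_row(age = p, gender = c(0.6, 0.4),
                                      org = c(0.6, 0.4)))
    b <- assign_demographics(demo_row(age = p[perm], gender = c(0.6, 0.4),
                                      org = c(0.6, 0.4)))
    groups <- c("<=18", "19-29", "30-39", ">=40")
    expect_equal(b$age_group, groups[which(perm == match(a$age_group, groups))])
  }
})

test_that("user sampling is seeded, exact in size, and total at fraction 1", {
  gen <- shared_gen()
  users <- gen$corpus$users
  s1 <- sample_users(users, 0.10, seed = 5)
  expect_equal(nrow(s1), round(0.1 * nrow(users)))
  s2 <- sample_users(users, 0.10, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_users(users, 0.10, seed = 6)))
  expect_equal(nrow(sample_users(users, 1)), nrow(users))
  expect_error(sample_users(users, 0), "fraction")
})

test_that("age distribution counts misinformation tweets and conserves totals", {
  gen <- shared_gen10k()
  corpus <- set_corpus_labels(gen$corpus, tibble::tibble(
    tweet_id = gen$truth$tweet_id, label = gen$truth$label,
    source = "oracle", confidence = NA_real_))
  assigned <- assign_demographics(corpus$demographics)
  ages <- age_distribution(corpus, assigned = assigned)
  expect_setequal(ages$age_group, c("<=18", "19-29", "30-39", ">=40"))
  expect_equal(sum(ages$count), sum(gen$truth$label))
  # generator mixture: >=40 is the modal misinformation age group
  expect_equal(ages$age_group[which.max(ages$count)], ">=40")

  # per-user mode counts each spreader once
  ages_u <- age_distribution(corpus, assigned = assigned, mode = "users")
  n_spreaders <- length(unique(
    corpus$tweets$user_id[corpus$tweets$id %in%
                            gen$truth$tweet_id[gen$truth$label == 1L]]))
  expect_equal(sum(ages_u$count), n_spreaders)

  # no misinformation -> all-zero counts
  all_fact <- corpus
  all_fact$labels$label <- 0L
  expect_equal(sum(age_distribution(all_fact, assigned = assigned)$count), 0)
})

test_that("identical class populations give unit cross-class ratios", {
  users <- tibble::tibble(
    id = sprintf("u%d", 1:6),
    screen_name = sprintf("s%d", 1:6),
    name = "x", profile_location = "", description = "",
    followers_count = rep(c(10L, 20L, 30L), 2),
    friends_count = rep(c(5L, 6L, 7L), 2),
    favourites_count = rep(c(1L, 2L, 3L), 2),
    verified = rep(c(TRUE, FALSE, FALSE), 2)
  )
  tweets <- tiny_tweets(sprintf("s%d", 1:6))
  labels <- tibble::tibble(tweet_id = tweets$id,
                           label = c(0L, 0L, 0L, 1L, 1L, 1L),
                           source = "manual", confidence = NA_real_)
  corpus <- join_corpus(tweets, users, labels = labels)
  rep_ <- engagement_comparison(corpus)
  expect_equal(rep_$fact_over_misinfo$followers, 1)
  expect_equal(rep_$fact_over_misinfo$friends, 1)
  expect_equal(rep_$fact_over_misinfo$favourites, 1)
  expect_equal(rep_$fact_over_misinfo$verified, 1)
  expect_equal(rep_$n_dual_membership, 0)
})

test_that("a class with no verified accounts has verified ratio 0", {
  corpus <- labeled_toy_corpus() # misinformation authors are all unverified
  rep_ <- engagement_comparison(corpus)
  expect_equal(rep_$per_class$misinformation$verified_unverified_ratio, 0)
  expect_equal(rep_$per_class$fact$verified_unverified_ratio, 2)
})

test_that("an absent class is marked absent", {
  corpus <- labeled_toy_corpus()
  corpus$labels$label <- 0L
  rep_ <- engagement_comparison(corpus)
  expect_true("misinformation" %in% rep_$absent_classes)
  expect_null(rep_$fact_over_misinfo)
})

test_that("comparison statistics are invariant to account ordering", {
  gen <- shared_gen()
  corpus <- set_corpus_labels(gen$corpus, tibble::tibble(
    tweet_id = gen$truth$tweet_id, label = gen$truth$label,
    source = "oracle", confidence = NA_real_))
  r1 <- engagement_comparison(corpus)
  shuffled <- corpus
  set.seed(60)
  shuffled$users <- shuffled$users[sample(nrow(shuffled$users)), ]
  shuffled$tweets <- shuffled$tweets[sample(nrow(shuffled$tweets)), ]
  r2 <- engagement_comparison(shuffled)
  expect_equal(r1$fact_over_misinfo, r2$fact_over_misinfo)
  expect_equal(r1$per_class$fact$mean_followers,
               r2$per_class$fact$mean_followers)
})

test_that("bot comparison reports per-category means and sample sizes", {
  gen <- shared_gen()
  corpus <- set_corpus_labels(gen$corpus, tibble::tibble(
    tweet_id = gen$truth$tweet_id, label = gen$truth$label,
    source = "oracle", confidence = NA_real_))
  rep_ <- suppressWarnings(bot_comparison(corpus, sample_size = 1000, seed = 2))
  n_classes <- length(rep_$sample_sizes)
  expect_equal(n_classes, 2)
  # both class pools here are smaller than 1,000 -> all used, one warning each
  w <- capture_warnings(bot_comparison(corpus, sample_size = 1000, seed = 2))
  expect_length(w, 2)
  expect_match(w, "using all", all = TRUE)
  expect_true(all(rep_$means$astroturf >= 0 & rep_$means$astroturf <= 1))
  expect_gt(rep_$means$astroturf[rep_$means$class == "misinformation"],
            rep_$means$astroturf[rep_$means$class == "fact"])

  # all-zero score vectors -> all-zero means
  zeroed <- corpus
  zeroed$bot_scores[, -1] <- 0
  rz <- suppressWarnings(bot_comparison(zeroed, sample_size = 10, seed = 2))
  expect_true(all(as.matrix(rz$means[, -1]) == 0))

  # determinism and reported sizes
  rep2 <- suppressWarnings(bot_comparison(corpus, sample_size = 50, seed = 2))
  rep3 <- suppressWarnings(bot_comparison(corpus, sample_size = 50, seed = 2))
  expect_equal(rep2$means, rep3$means)
  expect_equal(unname(rep2$sample_sizes), pmin(50L, unname(rep_$sample_sizes)))
})

test_that("generator defaults reproduce the qualitative class contrasts", {
  gen <- generate_corpus(generator_config(n_tweets = 6000, seed = 23))
  corpus <- set_corpus_labels(gen$corpus, tibble::tibble(
    tweet_id = gen$truth$tweet_id, label = gen$truth$label,
    source = "oracle", confidence = NA_real_))
  eng <- engagement_comparison(corpus)
  expect_gt(eng$fact_over_misinfo$followers, 1)  # facts: more followers
  expect_gt(eng$fact_over_misinfo$favourites, 1) # facts: more favourites given
  expect_gt(eng$fact_over_misinfo$verified, 1)   # facts: more verified
  expect_lt(eng$fact_over_misinfo$friends, 1)    # misinformation: more friends
  bots <- suppressWarnings(bot_comparison(corpus, sample_size = 1000, seed = 3))
  m <- bots$means[bots$means$class == "misinformation", ]
  f <- bots$means[bots$means$class == "fact", ]
  expect_gt(m$astroturf, f$astroturf)
  expect_gt(m$overall, f$overall)
})
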