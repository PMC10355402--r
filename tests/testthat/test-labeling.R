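test_that("guideline screening returns advisory polarities", {
  criteria <- load_guidelines()
  r1 <- screen_with_guidelines(
    "I don't need vaccine because I already got COVID and I have anti-bodies")
  expect_equal(r1$advisory, "misinformation")
  expect_true("unproven-treatment" %in% r1$matched)

  r2 <- screen_with_guidelines("nothing relevant here at all")
  expect_equal(r2$advisory, "no-match")
  expect_length(r2$matched, 0)

  # both polarities matched -> reported, no single advisory
  r3 <- screen_with_guidelines(
    "just got vaccinated but they put microchips in the vaccines")
  expect_equal(r3$advisory, "conflict")
  expect_length(r3$matched, 2)
})

test_that("criteria are pattern-backed or explicitly manual-only", {
  criteria <- load_guidelines()
  expect_true(all(lengths(criteria$patterns) > 0 | criteria$manual_only))
})

test_that("keyword query selects include-term tweets and honours exclusions", {
  pool <- tibble::tibble(
    id = sprintf("t%d", 1:5),
    text = c(
      "vaccines contain a microchip",
      paste("The conspiracy theorists believe that if you have the new COVID",
            "vaccine, your body will turn into a 5G antenna"),
      "got my first dose today, feeling fine",
      "the vaccine is a HOAX people",
      "I have 15GB of data left" # no word-boundary hit on "5G"
    )
  )
  res <- keyword_augment(pool, augmentation_query(target_additions = 10)) |>
    suppressWarnings()
  expect_setequal(res$labels$tweet_id, c("t1", "t4"))
  expect_true(all(res$labels$label == 1L))
  expect_true(all(res$labels$source == "keyword_augmented"))
  expect_equal(res$report$matched_terms[res$report$tweet_id == "t1"], "microchip")
})

test_that("selection caps at target_additions in pool order and warns when short", {
  pool <- tibble::tibble(id = sprintf("t%02d", 1:8),
                         text = rep("this hoax again", 8))
  q <- augmentation_query(include_terms = "hoax", exclude_terms = character(0),
                          target_additions = 3)
  res <- keyword_augment(pool, q)
  expect_equal(res$labels$tweet_id, c("t01", "t02", "t03"))

  q2 <- augmentation_query(include_terms = "hoax", exclude_terms = character(0),
                           target_additions = 99)
  expect_warning(res2 <- keyword_augment(pool, q2), "only 8")
  expect_equal(nrow(res2$labels), 8)
})

test_that("include/exclude overlap is rejected", {
  expect_error(augmentation_query(include_terms = c("hoax"),
                                  exclude_terms = c("Hoax")), "overlap")
})

test_that("selection is monotone in the term sets", {
  gen <- shared_gen()
  pool <- gen$corpus$tweets[1:1000, c("id", "text")]
  base_q <- augmentation_query(include_terms = c("5g", "hoax"),
                               exclude_terms = "conspiracy",
                               target_additions = 10000)
  base <- suppressWarnings(keyword_augment(pool, base_q))$labels$tweet_id
  # adding an include term never removes a selected tweet
  more_inc <- augmentation_query(include_terms = c("5g", "hoax", "microchip"),
                                 exclude_terms = "conspiracy",
                                 target_additions = 10000)
  sel2 <- suppressWarnings(keyword_augment(pool, more_inc))$labels$tweet_id
  expect_true(all(base %in% sel2))
  # adding an exclude term never adds one
  more_exc <- augmentation_query(include_terms = c("5g", "hoax"),
                                 exclude_terms = c("conspiracy", "misleading"),
                                 target_additions = 10000)
  sel3 <- suppressWarnings(keyword_augment(pool, more_exc))$labels$tweet_id
  expect_true(all(sel3 %in% base))
})

test_that("keyword selection equals a brute-force containment scan", {
  gen <- shared_gen()
  pool <- gen$corpus$tweets[1:1000, c("id", "text")]
  q <- augmentation_query(target_additions = 10000)
  got <- suppressWarnings(keyword_augment(pool, q))$labels$tweet_id

  contains <- function(text, term) {
    grepl(sprintf("(?<![[:alnum:]])%s(?![[:alnum:]])", term), text,
          perl = TRUE, ignore.case = TRUE)
  }
  expected <- pool$id[vapply(pool$text, function(tx) {
    any(vapply(q$include_terms, contains, logical(1), text = tx)) &&
      !any(vapply(q$exclude_terms, contains, logical(1), text = tx))
  }, logical(1))]
  expect_equal(got, expected)
})

test_that("merging reproduces class-balance bookkeeping", {
  manual <- tibble::tibble(
    tweet_id = sprintf("m%04d", 1:5000),
    label = c(rep(0L, 4395), rep(1L, 605)),
    source = "manual", confidence = NA_real_
  )
  augmented <- tibble::tibble(
    tweet_id = sprintf("a%04d", 1:4000),
    label = 1L, source = "keyword_augmented", confidence = NA_real_
  )
  res <- merge_label_sets(manual, augmented)
  expect_equal(res$report$n_fact, 4395)
  expect_equal(res$report$n_misinformation, 4605)
  expect_equal(res$report$total, 9000)
  expect_equal(res$report$n_overlap, 0)
})

test_that("empty augmentation and manual-wins overlap are handled", {
  manual <- tibble::tibble(tweet_id = c("x", "y"), label = c(0L, 1L),
                           source = "manual", confidence = NA_real_)
  empty_aug <- manual[0, ]
  res <- merge_label_sets(manual, empty_aug)
  expect_equal(res$report$total, 2)
  expect_equal(res$report$n_fact, 1)

  aug <- tibble::tibble(tweet_id = "x", label = 1L,
                        source = "keyword_augmented", confidence = NA_real_)
  res2 <- merge_label_sets(manual, aug)
  expect_equal(res2$labels$label[res2$labels$tweet_id == "x"], 0L)
  expect_equal(res2$report$n_overlap, 1)

  conflicted <- tibble::tibble(tweet_id = c("x", "x"), label = c(0L, 1L),
                               source = "manual", confidence = NA_real_)
  expect_error(merge_label_sets(conflicted, empty_aug), "conflicting duplicate")
})
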