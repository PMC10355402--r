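# small AL problem shared by several tests
small_al_setup <- function(n_init = 60, n_total = 600, seed = 8) {
  gen <- generate_corpus(generator_config(n_tweets = n_total,
                                          misinfo_prevalence = 0.15,
                                          seed = seed))
  texts <- setNames(gen$corpus$tweets$text, gen$corpus$tweets$id)
  init <- gen$truth[seq_len(n_init), c("tweet_id", "label")]
  if (length(unique(init$label)) < 2) stop("fixture seed gave one class")
  list(texts = texts, init = init, truth = gen$truth,
       oracle = make_oracle(gen$truth))
}

test_that("uncertainty ranking picks the smallest absolute decision values", {
  ids <- c("a", "b", "c", "d")
  dec <- c(2.0, -0.1, 0.5, -3.0)
  expect_equal(rank_uncertain(ids, dec, 2), c("b", "c"))
  # batch >= pool returns everything, still uncertainty-ordered
  expect_equal(rank_uncertain(ids, dec, 10), c("b", "c", "a", "d"))
  # ties break by ascending id
  expect_equal(rank_uncertain(c("z", "a"), c(0.5, -0.5), 1), "a")
})

test_that("uncertainty ranking equals an exhaustive sort oracle on random pools", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    ids <- sprintf("id%04d", sample(9999, n))
    dec <- round(rnorm(n), 2) # rounding forces ties
    k <- sample(1:n, 1)
    expected <- ids[order(abs(dec), ids)][seq_len(k)]
    expect_equal(rank_uncertain(ids, dec, k), expected)
  }
})

test_that("a step moves exactly one batch from pool to labeled set", {
  s <- small_al_setup()
  state <- al_state(s$texts, s$init, batch_size = 50, evaluate = FALSE)
  expect_equal(nrow(state$labeled), 60)
  expect_length(state$pool, 540)

  state2 <- al_step(state, s$oracle)
  expect_equal(nrow(state2$labeled), 110)
  expect_length(state2$pool, 490)
  expect_equal(state2$iteration, 1L)
  # disjointness and budget conservation
  expect_length(intersect(state2$labeled$tweet_id, state2$pool), 0)
  expect_equal(nrow(state2$labeled) + length(state2$pool), 600)
  # batch labels agree with truth
  new_ids <- setdiff(state2$labeled$tweet_id, state$labeled$tweet_id)
  expect_equal(
    state2$labeled$label[match(new_ids, state2$labeled$tweet_id)],
    s$truth$label[match(new_ids, s$truth$tweet_id)]
  )
})

test_that("a pool smaller than the batch is exhausted and stops the run", {
  s <- small_al_setup(n_init = 570, n_total = 600)
  state <- al_state(s$texts, s$init, batch_size = 100, evaluate = FALSE)
  expect_length(state$pool, 30)
  state <- al_step(state, s$oracle)
  expect_equal(nrow(state$labeled), 600)
  expect_true(state$stopped)
  expect_equal(oracle_queries(s$oracle), 30L)
})

test_that("an oracle failure leaves the state unchanged", {
  s <- small_al_setup()
  state <- al_state(s$texts, s$init, batch_size = 50, evaluate = FALSE)
  bad_oracle <- function(ids) stop("annotator unavailable")
  expect_error(al_step(state, bad_oracle), "annotator unavailable")
  expect_equal(nrow(state$labeled), 60)
  expect_length(state$pool, 540)
})

test_that("zero iterations returns the initial model with empty history", {
  s <- small_al_setup()
  res <- run_active_learning(s$texts, s$init, s$oracle, max_iterations = 0,
                             evaluate = FALSE)
  expect_equal(nrow(res$history), 0)
  expect_equal(res$state$iteration, 0L)
  expect_s3_class(res$model, "linear_svm")
  expect_equal(oracle_queries(s$oracle), 0L)
})

test_that("a full run records one history row per iteration and freezes the vocabulary", {
  s <- small_al_setup()
  res <- run_active_learning(s$texts, s$init, s$oracle, batch_size = 50,
                             max_iterations = 4, cv_folds = 3)
  expect_equal(nrow(res$history), 4)
  expect_equal(res$history$n_labeled, 60 + 50 * (1:4))
  expect_equal(oracle_queries(s$oracle), 200L)
  expect_true(all(c("accuracy", "precision", "recall", "f_score") %in%
                    names(res$history)))
  # vocabulary fitted on the seed set and frozen
  fz0 <- fit_featurizer(s$texts[s$init$tweet_id])
  expect_identical(names(res$featurizer$vocabulary), names(fz0$vocabulary))
})

test_that("cv-averaged uncertainty is accepted and selects a full batch", {
  s <- small_al_setup()
  state <- al_state(s$texts, s$init, batch_size = 20, evaluate = FALSE,
                    uncertainty = "cv_average", cv_folds = 3)
  batch <- select_uncertain(state)
  expect_length(batch, 20)
  expect_true(all(batch %in% state$pool))
})

test_that("indicator terms carry the largest positive weights", {
  gen <- generate_corpus(generator_config(n_tweets = 3000, seed = 19))
  fz <- fit_featurizer(gen$corpus$tweets$text, ngram_max = 1)
  m <- train_model(featurize(fz, gen$corpus$tweets$text), gen$truth$label)
  top <- names(sort(m$weights, decreasing = TRUE))[1:15]
  indicators <- c("5g", "microchip", "hoax", "poison", "plandemic")
  expect_gte(length(intersect(top, indicators)), 3)
})

test_that("predicted labels follow the decision sign and match prevalence", {
  gen <- shared_gen()
  texts <- setNames(gen$corpus$tweets$text, gen$corpus$tweets$id)
  res <- run_active_learning(texts, gen$truth[1:300, ],
                             make_oracle(gen$truth), batch_size = 100,
                             max_iterations = 3, evaluate = FALSE)
  pred <- predict_corpus(res$model, res$featurizer, gen$corpus)
  expect_equal(nrow(pred), nrow(gen$corpus$tweets))
  expect_equal(pred$label, as.integer(pred$confidence > 0))
  expect_true(all(pred$source == "predicted"))
  truth_prev <- mean(gen$truth$label)
  expect_lt(abs(mean(pred$label) - truth_prev), 0.02)
})

test_that("learning curve on held-out data is non-decreasing within noise", {
  # mean held-out accuracy over seeds, compared at a small and a large budget
  accs <- vapply(1:6, function(seed) {
    gen <- generate_corpus(generator_config(n_tweets = 1200,
                                            misinfo_prevalence = 0.15,
                                            seed = seed))
    texts <- setNames(gen$corpus$tweets$text, gen$corpus$tweets$id)
    held <- gen$truth[1001:1200, ]
    train_truth <- gen$truth[1:1000, ]
    init <- train_truth[1:50, ]
    oracle <- make_oracle(train_truth)
    pool <- setdiff(train_truth$tweet_id, init$tweet_id)
    acc_at <- function(iters) {
      res <- run_active_learning(texts, init, oracle, pool_ids = pool,
                                 batch_size = 50, max_iterations = iters,
                                 evaluate = FALSE)
      x <- featurize(res$featurizer, texts[held$tweet_id])
      mean(predict(res$model, x) == held$label)
    }
    c(small = acc_at(1), large = acc_at(8))
  }, numeric(2))
  expect_gte(mean(accs["large", ] - accs["small", ]), -0.005)
})
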