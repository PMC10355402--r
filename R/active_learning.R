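#' @title Pool-based active learning with uncertainty batches
#' @description
#' Labeling tweets is expensive, so the classifier is grown by pool-based
#' active learning: starting from a labeled seed set, the linear SVM is
#' trained, the unlabeled pool is scored with the decision function, and
#' the `batch_size` pool tweets with the smallest absolute decision value —
#' the ones closest to the separating hyperplane, i.e. the ones the model
#' is least confident about — are sent to the labeling oracle (a human
#' expert in production, the generator's truth table in tests). The newly
#' labeled tweets move from the pool into the training set, the model is
#' retrained and evaluated by stratified cross-validation, and the loop
#' repeats until `max_iterations` (default 50 iterations of 100 samples) or
#' pool exhaustion.
#'
#' The default reads "lowest average absolute confidence" as the absolute
#' decision value of the single current model; `uncertainty = "cv_average"`
#' instead averages `|decision|` over the cross-validation fold models.
#' @name active_learning
NULL

#' Initialize an active-learning state
#'
#' Fits the featurizer on the labeled seed texts (the vocabulary is then
#' frozen for the whole run), featurizes the full corpus once, and trains
#' the initial model.
#'
#' @param texts named character vector mapping tweet id to text, covering
#'   the labeled set and the pool.
#' @param labeled tibble with `tweet_id` and `label` (0/1) — the seed set;
#'   must contain both classes.
#' @param pool_ids ids of the unlabeled pool; defaults to all ids of
#'   `texts` not in `labeled`.
#' @param batch_size tweets queried per iteration (default 100).
#' @param max_iterations stopping criterion (default 50).
#' @param cost SVM regularization strength.
#' @param seed seed for the optimizer and cross-validation shuffles.
#' @param uncertainty `"single"` (default): `|decision|` of the current
#'   model; `"cv_average"`: mean `|decision|` over the `cv_folds` fold
#'   models.
#' @param cv_folds folds for evaluation (and for `"cv_average"` scoring).
#' @param evaluate if `TRUE` (default), run cross-validation on the labeled
#'   set after every retrain and record the metrics in the history.
#' @return an `al_state` object.
#' @export
al_state <- function(texts, labeled, pool_ids = NULL, batch_size = 100L,
                     max_iterations = 50L, cost = 1, seed = 1L,
                     uncertainty = c("single", "cv_average"), cv_folds = 5L,
                     evaluate = TRUE) {
  uncertainty <- match.arg(uncertainty)
  assert_columns(labeled, c("tweet_id", "label"), "labeled set")
  if (is.null(names(texts))) stop("texts must be named by tweet id")
  pool_ids <- pool_ids %null% setdiff(names(texts), labeled$tweet_id)
  if (length(intersect(labeled$tweet_id, pool_ids)) > 0) {
    stop("labeled set and pool overlap", call. = FALSE)
  }
  missing <- setdiff(c(labeled$tweet_id, pool_ids), names(texts))
  if (length(missing) > 0) {
    stop("texts missing for id(s): ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  featurizer <- fit_featurizer(texts[labeled$tweet_id])
  all_ids <- c(labeled$tweet_id, pool_ids)
  features <- featurize(featurizer, texts[all_ids])
  rownames(features) <- all_ids
  state <- structure(
    list(
      labeled = tibble::tibble(tweet_id = as.character(labeled$tweet_id),
                               label = as.integer(labeled$label)),
      pool = as.character(pool_ids),
      features = features, featurizer = featurizer,
      model = NULL, iteration = 0L,
      batch_size = as.integer(batch_size),
      max_iterations = as.integer(max_iterations),
      cost = cost, seed = as.integer(seed),
      uncertainty = uncertainty, cv_folds = as.integer(cv_folds),
      evaluate = isTRUE(evaluate),
      history = tibble::tibble(), stopped = FALSE
    ),
    class = "al_state"
  )
  retrain(state)
}

labeled_features <- function(state) {
  state$features[state$labeled$tweet_id, , drop = FALSE]
}

retrain <- function(state) {
  state$model <- train_model(labeled_features(state), state$labeled$label,
                             cost = state$cost, seed = state$seed)
  state
}

#' Rank pool ids by uncertainty
#'
#' The pure selection rule: the `batch_size` ids with the smallest absolute
#' decision value, ties broken by ascending id.
#'
#' @param ids pool ids.
#' @param decision their signed decision values.
#' @param batch_size batch size.
#' @return `min(batch_size, length(ids))` selected ids.
#' @export
rank_uncertain <- function(ids, decision, batch_size) {
  stopifnot(length(ids) == length(decision))
  ord <- order(abs(decision), ids)
  ids[ord][seq_len(min(batch_size, length(ids)))]
}

pool_uncertainty <- function(state) {
  px <- state$features[state$pool, , drop = FALSE]
  if (state$uncertainty == "single") {
    abs(decision_function(state$model, px))
  } else {
    lx <- labeled_features(state)
    labels <- state$labeled$label
    k <- state$cv_folds
    fold <- integer(length(labels))
    with_local_seed(state$seed + state$iteration, {
      for (cl in c(0L, 1L)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    absd <- vapply(seq_len(k), function(f) {
      m <- train_model(lx[fold != f, , drop = FALSE], labels[fold != f],
                       cost = state$cost, seed = state$seed)
      abs(decision_function(m, px))
    }, numeric(nrow(px)))
    rowMeans(absd)
  }
}

#' Select the next uncertainty batch
#'
#' @param state an `al_state` with a trained model.
#' @return character vector of pool ids (empty when the pool is exhausted);
#'   the ids stay in the pool until [al_step()] moves them.
#' @export
select_uncertain <- function(state) {
  stopifnot(inherits(state, "al_state"))
  if (length(state$pool) == 0) return(character(0))
  rank_uncertain(state$pool, pool_uncertainty(state), state$batch_size)
}

#' One active-learning iteration
#'
#' Selects the uncertainty batch, queries the oracle, moves the batch from
#' the pool to the labeled set, retrains, evaluates, and appends a history
#' record. If the oracle fails on any id the state is returned unchanged.
#'
#' @param state an `al_state`.
#' @param oracle a function mapping a character vector of tweet ids to 0/1
#'   labels (see [make_oracle()]).
#' @return the updated `al_state`; `stopped` is set once the pool is empty.
#' @export
al_step <- function(state, oracle) {
  stopifnot(inherits(state, "al_state"))
  batch <- select_uncertain(state)
  if (length(batch) == 0) {
    state$stopped <- TRUE
    return(state)
  }
  new_labels <- as.integer(oracle(batch)) # oracle error -> abort, state unchanged
  state$pool <- setdiff(state$pool, batch)
  state$labeled <- dplyr::bind_rows(
    state$labeled, tibble::tibble(tweet_id = batch, label = new_labels)
  )
  state <- retrain(state)
  state$iteration <- state$iteration + 1L
  record <- tibble::tibble(
    iteration = state$iteration,
    n_labeled = nrow(state$labeled),
    n_pool = length(state$pool),
    batch = length(batch)
  )
  if (state$evaluate) {
    cv <- cross_validate(labeled_features(state), state$labeled$label,
                         k = state$cv_folds, seed = state$seed + state$iteration,
                         cost = state$cost)
    record <- dplyr::bind_cols(record, tibble::as_tibble(as.list(cv$mean)))
  }
  state$history <- dplyr::bind_rows(state$history, record)
  if (length(state$pool) == 0) state$stopped <- TRUE
  state
}

#' Run the full active-learning loop
#'
#' @inheritParams al_state
#' @param oracle labeling function (see [make_oracle()]).
#' @param ... passed to [al_state()].
#' @return list with `model` (final `linear_svm`), `featurizer`, `history`
#'   (one row per completed iteration) and the final `state`.
#' @export
run_active_learning <- function(texts, labeled, oracle, pool_ids = NULL, ...) {
  state <- al_state(texts, labeled, pool_ids = pool_ids, ...)
  while (state$iteration < state$max_iterations && !state$stopped) {
    state <- al_step(state, oracle)
  }
  list(model = state$model, featurizer = state$featurizer,
       history = state$history, state = state)
}

#' @export
print.al_state <- function(x, ...) {
  cat("<al_state> iteration ", x$iteration, "/", x$max_iterations,
      ": ", nrow(x$labeled), " labeled, ", length(x$pool), " in pool",
      if (x$stopped) " (stopped)" else "", "\n", sep = "")
  invisible(x)
}

#' Predict labels for every tweet of a corpus
#'
#' @param model a trained `linear_svm`.
#' @param featurizer the `text_featurizer` the model was trained with.
#' @param corpus a `misinfo_corpus`.
#' @return label table (`tweet_id`, `label`, `source = "predicted"`,
#'   `confidence` = signed decision value), one row per tweet.
#' @export
predict_corpus <- function(model, featurizer, corpus) {
  stopifnot(inherits(corpus, "misinfo_corpus"))
  d <- decision_function(model, featurize(featurizer, corpus$tweets$text))
  tibble::tibble(
    tweet_id = corpus$tweets$id,
    label = as.integer(d > 0),
    source = "predicted",
    confidence = d
  )
}
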