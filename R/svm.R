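#' @title Linear support vector classifier
#' @description
#' The classifier is an L2-regularized hinge-loss (L1-loss) linear SVM,
#' trained by dual coordinate descent on sparse feature matrices. Its
#' signed decision value `w . x + b` — the (scaled) distance of a sample to
#' the separating hyperplane — is what drives uncertainty sampling: the
#' predicted class is 1 iff the decision value is positive, and samples
#' with small `|decision|` are the ones the model is least confident about.
#' Training is deterministic given the data, the hyperparameters and the
#' seed (the seed fixes the coordinate-descent sweep order).
#' @name linear_svm
#' @useDynLib misinfotrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Train a linear SVM
#'
#' @param x feature matrix (`dgCMatrix` or dense), one row per sample.
#' @param labels integer vector of 0/1 class labels (1 = misinformation).
#' @param cost regularization strength C of the hinge objective
#'   `0.5 ||w||^2 + C sum hinge` (default 1).
#' @param max_epochs optimizer sweep cap (default 1000).
#' @param tol stopping tolerance on the maximal projected gradient.
#' @param seed seed for the coordinate sweep order.
#' @return a `linear_svm` object with `weights`, `bias`, and optimizer
#'   metadata.
#' @export
train_model <- function(x, labels, cost = 1, max_epochs = 1000L, tol = 1e-4,
                        seed = 1L) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  present <- sort(unique(labels))
  if (length(present) < 2) {
    stop("training data contains a single class (missing class ",
         setdiff(c(0L, 1L), present), ")", call. = FALSE)
  }
  x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  if (nrow(x) != length(labels)) stop("nrow(x) != length(labels)")
  y <- ifelse(labels == 1L, 1, -1)
  fit <- .dcd_svm(Matrix::t(x), y, cost, as.integer(max_epochs), tol,
                  as.integer(seed), 1.0)
  structure(
    list(
      weights = setNames(fit$weights, colnames(x)),
      bias = fit$bias,
      cost = cost, tol = tol, max_epochs = as.integer(max_epochs),
      seed = as.integer(seed),
      epochs = fit$epochs, converged = fit$converged
    ),
    class = "linear_svm"
  )
}

#' Signed decision values of a linear SVM
#'
#' @param model a `linear_svm`.
#' @param x feature matrix with the same columns the model was trained on.
#' @return numeric vector `w . x + b`; positive means class 1.
#' @export
decision_function <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  as.numeric(x %*% model$weights) + model$bias
}

#' @export
predict.linear_svm <- function(object, x, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  d <- decision_function(object, x)
  if (type == "decision") d else as.integer(d > 0)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("<linear_svm> ", length(x$weights), " features, C = ", x$cost,
      ", ", x$epochs, " epochs",
      if (x$converged) " (converged)" else " (epoch cap reached)", "\n", sep = "")
  invisible(x)
}

#' Classification metrics for the misinformation class
#'
#' @param truth integer 0/1 truth labels.
#' @param predicted integer 0/1 predictions.
#' @return list with `accuracy`, `precision`, `recall` and `f_score`
#'   (harmonic mean of precision and recall for class 1; 0 when undefined).
#' @export
compute_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = mean(truth == predicted), precision = precision,
       recall = recall, f_score = f)
}

#' Stratified randomized cross-validation
#'
#' Folds are a seeded shuffled partition, stratified by class so every fold
#' contains both classes. Metrics are computed per fold for the
#' misinformation class and averaged.
#'
#' @param x feature matrix.
#' @param labels 0/1 labels.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param cost SVM regularization strength.
#' @return list with `folds` (per-fold metric tibble) and `mean` (named
#'   numeric vector of averaged metrics).
#' @export
cross_validate <- function(x, labels, k = 5L, seed = 1L, cost = 1) {
  labels <- as.integer(labels)
  if (k < 2) stop("k must be at least 2")
  if (min(table(factor(labels, levels = c(0, 1)))) < k) {
    stop("a class has fewer than k = ", k,
         " members and cannot be stratified", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  per_fold <- lapply(seq_len(k), function(f) {
    test <- fold == f
    m <- train_model(x[!test, , drop = FALSE], labels[!test], cost = cost,
                     seed = seed)
    pred <- predict(m, x[test, , drop = FALSE])
    c(fold = f, unlist(compute_metrics(labels[test], pred)))
  })
  folds <- tibble::as_tibble(do.call(rbind, per_fold))
  list(folds = folds,
       mean = colMeans(folds[, c("accuracy", "precision", "recall", "f_score")]))
}

#' Persist a model and its featurizer as structured text
#'
#' @param model a `linear_svm`.
#' @param featurizer the fitted `text_featurizer` it was trained with.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, featurizer, path) {
  obj <- list(
    model = list(weights = unname(model$weights), bias = model$bias,
                 cost = model$cost, tol = model$tol,
                 max_epochs = model$max_epochs, seed = model$seed),
    featurizer = list(vocabulary = names(featurizer$vocabulary),
                      idf = unname(featurizer$idf),
                      ngram_max = featurizer$ngram_max,
                      min_df = featurizer$min_df, n_docs = featurizer$n_docs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model persisted by [write_model()]
#'
#' @param path JSON file.
#' @return list with `model` (`linear_svm`) and `featurizer`
#'   (`text_featurizer`).
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vocab <- obj$featurizer$vocabulary
  featurizer <- structure(
    list(vocabulary = setNames(seq_along(vocab), vocab),
         idf = setNames(obj$featurizer$idf, vocab),
         ngram_max = as.integer(obj$featurizer$ngram_max),
         min_df = as.integer(obj$featurizer$min_df),
         n_docs = as.integer(obj$featurizer$n_docs)),
    class = "text_featurizer"
  )
  model <- structure(
    list(weights = setNames(obj$model$weights, vocab), bias = obj$model$bias,
         cost = obj$model$cost, tol = obj$model$tol,
         max_epochs = as.integer(obj$model$max_epochs),
         seed = as.integer(obj$model$seed),
         epochs = NA_integer_, converged = NA),
    class = "linear_svm"
  )
  list(model = model, featurizer = featurizer)
}
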