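#' @title Text featurization
#' @description
#' Tweets are featurized as tf-idf weighted bags of lowercase word unigrams
#' and bigrams — a standard strong baseline for short-text classification.
#' The vocabulary is fitted once on the initial labeled set and frozen, so
#' decision values stay comparable across active-learning iterations;
#' out-of-vocabulary terms in later texts are ignored.
#'
#' Weighting: raw term count times smooth inverse document frequency
#' `idf(t) = ln((1 + n) / (1 + df(t))) + 1`, followed by L2 row
#' normalization.
#' @name featurize
NULL

tokenize_words <- function(texts) {
  texts <- tolower(as.character(texts))
  toks <- strsplit(texts, "[^a-z0-9']+")
  lapply(toks, function(t) t[nzchar(t)])
}

add_ngrams <- function(tokens, ngram_max) {
  if (ngram_max < 2) return(tokens)
  lapply(tokens, function(t) {
    out <- t
    if (length(t) >= 2 && ngram_max >= 2) {
      out <- c(out, paste(t[-length(t)], t[-1]))
    }
    out
  })
}

doc_term_triplets <- function(tokens, vocab_index = NULL) {
  counts <- lapply(tokens, function(t) {
    if (length(t) == 0) return(integer(0))
    table(t)
  })
  i <- rep(seq_along(counts), vapply(counts, length, integer(1)))
  term <- unlist(lapply(counts, names), use.names = FALSE)
  x <- unlist(lapply(counts, as.integer), use.names = FALSE)
  if (!is.null(vocab_index)) {
    j <- vocab_index[term]
    keep <- !is.na(j)
    list(i = i[keep], j = unname(j[keep]), x = x[keep])
  } else {
    list(i = i, term = term, x = x)
  }
}

#' Fit a tf-idf featurizer
#'
#' @param texts character vector of training texts.
#' @param ngram_max 1 for unigrams only, 2 (default) adds bigrams.
#' @param min_df minimum document frequency for a term to enter the
#'   vocabulary (default 2).
#' @return a `text_featurizer`: vocabulary (term to column map), idf
#'   weights, and the fitting parameters.
#' @export
fit_featurizer <- function(texts, ngram_max = 2L, min_df = 2L) {
  if (length(texts) == 0) stop("cannot fit a featurizer on zero texts")
  tokens <- add_ngrams(tokenize_words(texts), ngram_max)
  trip <- doc_term_triplets(tokens)
  # (doc, term) pairs are unique by construction, so this is document frequency
  df_counts <- table(trip$term)
  vocab <- sort(names(df_counts)[df_counts >= min_df])
  if (length(vocab) == 0) {
    stop("empty vocabulary: no term reaches min_df = ", min_df, call. = FALSE)
  }
  n <- length(texts)
  df_v <- as.integer(df_counts[vocab])
  structure(
    list(
      vocabulary = setNames(seq_along(vocab), vocab),
      idf = setNames(log((1 + n) / (1 + df_v)) + 1, vocab),
      ngram_max = as.integer(ngram_max),
      min_df = as.integer(min_df),
      n_docs = n
    ),
    class = "text_featurizer"
  )
}

#' Transform texts into a sparse tf-idf matrix
#'
#' @param featurizer a fitted `text_featurizer`.
#' @param texts character vector.
#' @return a `dgCMatrix` with one row per text and one column per
#'   vocabulary term; texts containing only out-of-vocabulary terms give
#'   all-zero rows.
#' @export
featurize <- function(featurizer, texts) {
  if (!inherits(featurizer, "text_featurizer")) {
    stop("featurizer is not fitted; call fit_featurizer() first", call. = FALSE)
  }
  tokens <- add_ngrams(tokenize_words(texts), featurizer$ngram_max)
  trip <- doc_term_triplets(tokens, vocab_index = featurizer$vocabulary)
  x <- trip$x * unname(featurizer$idf[trip$j])
  m <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = x,
    dims = c(length(texts), length(featurizer$vocabulary)),
    dimnames = list(NULL, names(featurizer$vocabulary))
  )
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% m
}
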