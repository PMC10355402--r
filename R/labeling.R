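#' @title Bootstrapping a labeled training set
#' @description
#' The training set is bootstrapped in three steps mirroring standard
#' practice in misinformation annotation studies: (1) a manually annotated
#' seed set, labeled under written guideline criteria; (2) keyword
#' augmentation — a weak-labeling query that pulls additional probable
#' misinformation tweets from the unlabeled pool by requiring at least one
#' *include* term (e.g. "5G", "poison", "microchip", "hoax") and no
#' *exclude* term (e.g. "misleading", "conspiracy", which mark tweets that
#' talk *about* misinformation rather than spread it); and (3) a merge with
#' class-balance bookkeeping in which manual labels always win.
#' @name labeling
NULL

#' Load guideline criteria
#'
#' The shipped criteria file is a best-effort, editable encoding of
#' annotation-guideline examples (unproven treatments, unsupported claims
#' about vaccine consequences, conspiracy narratives vs. personal
#' vaccination experience, hopes, advertisement, politics). Pattern matches
#' are advisory: they support, and never replace, manual annotation.
#'
#' @param path CSV with columns `id`, `polarity`
#'   (`misinformation`/`non-misinformation`), `description`, `patterns`
#'   (`;`-separated case-insensitive regular expressions; empty means
#'   manual-only). Defaults to the shipped file.
#' @return tibble of criteria with a `patterns` list-column and a
#'   `manual_only` flag.
#' @export
load_guidelines <- function(path = NULL) {
  path <- path %null% system.file("extdata", "guidelines.csv",
                                  package = "misinfotrack")
  cr <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  assert_columns(cr, c("id", "polarity", "description", "patterns"), "criteria")
  bad <- setdiff(unique(cr$polarity), c("misinformation", "non-misinformation"))
  if (length(bad) > 0) stop("unknown polarity: ", paste(bad, collapse = ", "))
  cr$patterns <- lapply(cr$patterns, function(p) {
    if (is.na(p) || !nzchar(p)) character(0) else trimws(strsplit(p, ";")[[1]])
  })
  cr$manual_only <- lengths(cr$patterns) == 0
  tibble::as_tibble(cr)
}

#' Screen a text against guideline criteria
#'
#' Returns the matched criteria and an advisory label: the shared polarity
#' of the matches, `"no-match"` when nothing matches, or `"conflict"` when
#' criteria of both polarities match. Advisory labels never override manual
#' annotation.
#'
#' @param text a single tweet text.
#' @param criteria tibble from [load_guidelines()].
#' @return list with `advisory` (`"misinformation"`, `"non-misinformation"`,
#'   `"no-match"` or `"conflict"`) and `matched` (criterion ids).
#' @export
screen_with_guidelines <- function(text, criteria = load_guidelines()) {
  stopifnot(length(text) == 1)
  hit <- vapply(seq_len(nrow(criteria)), function(i) {
    pats <- criteria$patterns[[i]]
    length(pats) > 0 &&
      any(vapply(pats, function(p) grepl(p, text, ignore.case = TRUE, perl = TRUE),
                 logical(1)))
  }, logical(1))
  matched <- criteria$id[hit]
  pols <- unique(criteria$polarity[hit])
  advisory <- if (length(pols) == 0) "no-match"
              else if (length(pols) > 1) "conflict"
              else pols
  list(advisory = advisory, matched = matched)
}

#' Build an augmentation query
#'
#' @param include_terms terms indicating misinformation; a tweet qualifies
#'   when it contains at least one (case-insensitive, word-boundary match,
#'   so "5G" matches "5g" but not "15GB").
#' @param exclude_terms disqualifying terms marking tweets that discuss or
#'   debunk misinformation.
#' @param target_additions maximum number of weak labels to return.
#' @return an `augmentation_query` object.
#' @export
augmentation_query <- function(include_terms = default_include_terms(),
                               exclude_terms = default_exclude_terms(),
                               target_additions = 4000L) {
  include_terms <- tolower(include_terms)
  exclude_terms <- tolower(exclude_terms)
  overlap <- intersect(include_terms, exclude_terms)
  if (length(overlap) > 0) {
    stop("include and exclude terms overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  if (length(include_terms) == 0) stop("include_terms must be non-empty")
  structure(list(include_terms = include_terms, exclude_terms = exclude_terms,
                 target_additions = as.integer(target_additions)),
            class = "augmentation_query")
}

#' Default misinformation-indicator include terms
#'
#' The four canonical indicators plus further common misinformation markers;
#' the full list is a configurable modeling choice.
#' @export
default_include_terms <- function() {
  c("5g", "poison", "microchip", "hoax",
    "plandemic", "bioweapon", "depopulation", "sheeple", "magnetic",
    "untested", "big pharma lies")
}

#' Default exclude terms (tweets about misinformation, not spreading it)
#' @export
default_exclude_terms <- function() {
  c("misleading", "conspiracy")
}

#' Weakly label probable misinformation tweets by keyword query
#'
#' A pool tweet is selected iff its text contains at least one include term
#' and no exclude term (case-insensitive word-boundary containment). At most
#' `query$target_additions` records are returned, taken in pool order so the
#' selection is reproducible; set `shuffle_seed` for a seeded random subset
#' instead. Selected ids and their matched terms are reported for manual
#' review.
#'
#' @param pool tweet table of unlabeled tweets.
#' @param query an [augmentation_query()].
#' @param shuffle_seed optional seed; when given, over-full matches are
#'   subsampled at random instead of truncated in pool order.
#' @return list with `labels` (tibble `tweet_id`, `label = 1`,
#'   `source = "keyword_augmented"`) and `report` (tibble `tweet_id`,
#'   `matched_terms`). Warns when fewer matches exist than requested.
#' @export
keyword_augment <- function(pool, query = augmentation_query(),
                            shuffle_seed = NULL) {
  assert_columns(pool, c("id", "text"), "pool")
  stopifnot(inherits(query, "augmentation_query"))
  inc <- lapply(query$include_terms, term_hits, texts = pool$text)
  inc_any <- Reduce(`|`, inc)
  exc_any <- if (length(query$exclude_terms) == 0) {
    rep(FALSE, nrow(pool))
  } else {
    Reduce(`|`, lapply(query$exclude_terms, term_hits, texts = pool$text))
  }
  selected <- which(inc_any & !exc_any)
  if (length(selected) < query$target_additions) {
    warning("only ", length(selected), " of the requested ",
            query$target_additions, " pool tweets match the query",
            call. = FALSE)
  } else if (length(selected) > query$target_additions) {
    if (!is.null(shuffle_seed)) {
      selected <- with_local_seed(shuffle_seed,
                                  sort(sample(selected, query$target_additions)))
    } else {
      selected <- selected[seq_len(query$target_additions)]
    }
  }
  matched_terms <- vapply(selected, function(i) {
    hits <- query$include_terms[vapply(inc, `[`, logical(1), i)]
    paste(hits, collapse = ";")
  }, character(1))
  list(
    labels = tibble::tibble(
      tweet_id = pool$id[selected], label = 1L,
      source = "keyword_augmented", confidence = NA_real_
    ),
    report = tibble::tibble(tweet_id = pool$id[selected],
                            matched_terms = matched_terms)
  )
}

#' Merge manual and keyword-augmented label sets
#'
#' Manual labels always win on overlap; conflicting duplicate manual labels
#' (the same tweet manually labeled both 0 and 1) are a hard error. The
#' balance report gives the per-class counts of the merged set.
#'
#' @param manual tibble of manual labels (`tweet_id`, `label`, `source`).
#' @param augmented tibble of weak labels (from [keyword_augment()]).
#' @return list with `labels` (merged tibble, one row per tweet) and
#'   `report` (list: `n_fact`, `n_misinformation`, `total`, `n_overlap`).
#' @export
merge_label_sets <- function(manual, augmented) {
  assert_columns(manual, c("tweet_id", "label"), "manual labels")
  dup <- manual |>
    dplyr::distinct(.data$tweet_id, .data$label) |>
    dplyr::count(.data$tweet_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("conflicting duplicate manual labels for tweet id(s): ",
         paste(head(dup$tweet_id, 5), collapse = ", "), call. = FALSE)
  }
  manual <- dplyr::distinct(manual, .data$tweet_id, .keep_all = TRUE)
  if (!"source" %in% names(manual)) manual$source <- "manual"
  if (!"confidence" %in% names(manual)) manual$confidence <- NA_real_
  overlap <- intersect(manual$tweet_id, augmented$tweet_id)
  keep_aug <- augmented[!augmented$tweet_id %in% overlap, , drop = FALSE]
  merged <- dplyr::bind_rows(
    manual[, c("tweet_id", "label", "source", "confidence")],
    keep_aug[, c("tweet_id", "label", "source", "confidence")]
  )
  list(
    labels = tibble::as_tibble(merged),
    report = list(
      n_fact = sum(merged$label == 0L),
      n_misinformation = sum(merged$label == 1L),
      total = nrow(merged),
      n_overlap = length(overlap)
    )
  )
}
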