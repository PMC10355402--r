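#' @title Profiling misinformation-spreading accounts
#' @description
#' Account-level analyses compare *misinformation spreaders* with
#' *fact sharers*. An account belongs to a class when it authored at least
#' one tweet of that class (final labels), so an account can appear in both
#' classes; dual memberships are counted and reported. Demographic
#' attributes come from externally inferred probability vectors (age over
#' four bins, gender, organization status) and are assigned by argmax; bot
#' behaviour comes from externally supplied six-category scores in
#' `[0, 1]`. Neither is ever computed from text or images here — they are
#' inputs emulating the upstream inference services.
#' @name account_profiling
NULL

demographic_cols <- list(
  age = list(cols = c("age_le18", "age_19_29", "age_30_39", "age_ge40"),
             categories = .age_groups),
  gender = list(cols = c("gender_male", "gender_female"),
                categories = c("male", "female")),
  org = list(cols = c("org_org", "org_non_org"),
             categories = c("org", "non-org"))
)

# tie rule: fixed category order — youngest age first, female first, org first
.tie_preference <- list(
  age = c(1L, 2L, 3L, 4L),
  gender = c(2L, 1L),
  org = c(1L, 2L)
)

#' Assign demographic categories by argmax
#'
#' Each attribute takes the category with the highest probability. Exact
#' ties resolve by a fixed preference order (youngest age group, female,
#' org) and are flagged.
#'
#' @param demographics tibble keyed by `user_id` with probability columns
#'   `age_le18`, `age_19_29`, `age_30_39`, `age_ge40`, `gender_male`,
#'   `gender_female`, `org_org`, `org_non_org`. Each vector must sum to 1
#'   within `tolerance`.
#' @param tolerance allowed deviation of each probability vector's sum
#'   from 1 (default 1e-6).
#' @return tibble with `user_id`, `age_group`, `gender`, `org_status` and a
#'   logical `tie` flag.
#' @export
assign_demographics <- function(demographics, tolerance = 1e-6) {
  out <- tibble::tibble(user_id = demographics$user_id)
  any_tie <- rep(FALSE, nrow(demographics))
  for (attr in names(demographic_cols)) {
    spec <- demographic_cols[[attr]]
    assert_columns(demographics, spec$cols, "demographics")
    m <- as.matrix(demographics[, spec$cols])
    if (any(m < 0 | m > 1)) {
      stop("demographic probabilities must be in [0, 1]", call. = FALSE)
    }
    sums <- rowSums(m)
    bad <- which(abs(sums - 1) > tolerance)
    if (length(bad) > 0) {
      stop("demographic '", attr, "' vectors do not sum to 1 in row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    pref <- .tie_preference[[attr]]
    pick <- apply(m, 1, function(p) {
      best <- which(p == max(p))
      if (length(best) == 1) best else best[order(match(best, pref))][1]
    })
    tie <- apply(m, 1, function(p) sum(p == max(p)) > 1)
    any_tie <- any_tie | tie
    col <- switch(attr, age = "age_group", gender = "gender", org = "org_status")
    out[[col]] <- spec$categories[pick]
  }
  out$tie <- any_tie
  if (any(any_tie)) {
    message(sum(any_tie), " demographic tie(s) resolved by fixed category order")
  }
  out
}

#' Seeded uniform sample of users
#'
#' @param users user table.
#' @param fraction sampled fraction in (0, 1], default 0.10 (demographic
#'   inference is expensive upstream, so only a tenth of accounts carry it).
#' @param seed sampling seed; the same seed returns the same subset.
#' @return `round(fraction * nrow(users))` rows, without replacement.
#' @export
sample_users <- function(users, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- nrow(users)
  if (n == 0) return(users)
  k <- round(fraction * n)
  with_local_seed(seed, users[sort(sample.int(n, k)), , drop = FALSE])
}

# per-class user-id sets under the authored->=1-tweet membership rule
class_user_ids <- function(corpus) {
  tw <- tweet_class_table(corpus)
  tw <- tw[!is.na(tw$user_id) & !is.na(tw$label), , drop = FALSE]
  list(
    misinformation = unique(tw$user_id[tw$label == 1L]),
    fact = unique(tw$user_id[tw$label == 0L])
  )
}

#' Misinformation volume by author age group
#'
#' Counts misinformation tweets per age group of their (sampled,
#' demographics-assigned) authors. `mode = "users"` counts unique authors
#' instead of tweets.
#'
#' @param corpus a labeled `misinfo_corpus` with `demographics`.
#' @param assigned optional pre-assigned demographics (from
#'   [assign_demographics()]); computed from `corpus$demographics` if
#'   missing.
#' @param mode `"tweets"` (default: content volume) or `"users"`.
#' @return tibble with `age_group` and `count` (all four groups, zero
#'   filled).
#' @export
age_distribution <- function(corpus, assigned = NULL, mode = c("tweets", "users")) {
  mode <- match.arg(mode)
  if (is.null(assigned)) {
    if (is.null(corpus$demographics)) {
      stop("corpus has no demographics", call. = FALSE)
    }
    assigned <- assign_demographics(corpus$demographics)
  }
  tw <- tweet_class_table(corpus)
  tw <- tw[!is.na(tw$label) & tw$label == 1L & !is.na(tw$user_id), , drop = FALSE]
  tw$age_group <- assigned$age_group[match(tw$user_id, assigned$user_id)]
  tw <- tw[!is.na(tw$age_group), , drop = FALSE]
  if (mode == "users") {
    tw <- dplyr::distinct(tw, .data$user_id, .keep_all = TRUE)
  }
  counts <- table(factor(tw$age_group, levels = .age_groups))
  tibble::tibble(age_group = .age_groups, count = as.integer(counts))
}

class_user_stats <- function(users, ids) {
  sub <- users[users$id %in% ids, , drop = FALSE]
  n_verified <- sum(sub$verified)
  list(
    n_accounts = nrow(sub),
    n_verified = n_verified,
    verified_unverified_ratio =
      if (nrow(sub) == n_verified) Inf else n_verified / (nrow(sub) - n_verified),
    mean_followers = mean(sub$followers_count),
    mean_friends = mean(sub$friends_count),
    mean_favourites = mean(sub$favourites_count)
  )
}

#' Compare engagement and demographics between classes
#'
#' For each class (misinformation spreaders, fact sharers): the
#' verified:unverified account ratio, male:female and non-org:org ratios
#' (over accounts with assigned demographics), and mean follower, friend
#' and favourite counts. Cross-class ratios are fact over misinformation
#' for every metric. Means are computed over accounts with available data
#' and the denominators are reported.
#'
#' @param corpus a labeled `misinfo_corpus`.
#' @param assigned optional demographics assignments; when `NULL` and the
#'   corpus carries demographics they are assigned on the fly, otherwise
#'   gender/org ratios are `NA`.
#' @return a `comparison_report` list with per-class stats and
#'   `fact_over_misinfo` ratios.
#' @export
engagement_comparison <- function(corpus, assigned = NULL) {
  ids <- class_user_ids(corpus)
  if (is.null(assigned) && !is.null(corpus$demographics)) {
    assigned <- assign_demographics(corpus$demographics)
  }
  per_class <- lapply(ids, function(class_ids) {
    if (length(class_ids) == 0) return(NULL) # class absent
    stats <- class_user_stats(corpus$users, class_ids)
    if (!is.null(assigned)) {
      sub <- assigned[assigned$user_id %in% class_ids, , drop = FALSE]
      n_male <- sum(sub$gender == "male")
      n_female <- sum(sub$gender == "female")
      n_org <- sum(sub$org_status == "org")
      n_nonorg <- sum(sub$org_status == "non-org")
      stats$n_with_demographics <- nrow(sub)
      stats$male_female_ratio <- if (n_female == 0) Inf else n_male / n_female
      stats$nonorg_org_ratio <- if (n_org == 0) Inf else n_nonorg / n_org
    } else {
      stats$n_with_demographics <- 0L
      stats$male_female_ratio <- NA_real_
      stats$nonorg_org_ratio <- NA_real_
    }
    stats
  })
  dual <- length(intersect(ids$misinformation, ids$fact))
  ratios <- if (!is.null(per_class$fact) && !is.null(per_class$misinformation)) {
    m <- per_class$misinformation
    f <- per_class$fact
    list(
      followers = f$mean_followers / m$mean_followers,
      friends = f$mean_friends / m$mean_friends,
      favourites = f$mean_favourites / m$mean_favourites,
      verified = if (m$verified_unverified_ratio == 0) Inf else
        f$verified_unverified_ratio / m$verified_unverified_ratio
    )
  } else {
    NULL
  }
  structure(
    list(per_class = per_class, fact_over_misinfo = ratios,
         n_dual_membership = dual,
         absent_classes = names(per_class)[vapply(per_class, is.null, logical(1))]),
    class = "comparison_report"
  )
}

#' Compare bot-score categories between classes
#'
#' Draws a seeded sample of accounts per class (all of them, with a
#' warning, when a class is smaller than `sample_size`) and reports the
#' mean of each of the six bot-score categories.
#'
#' @param corpus a labeled `misinfo_corpus` with `bot_scores`.
#' @param sample_size accounts sampled per class (default 1000).
#' @param seed sampling seed.
#' @return a `bot_comparison_report`: per-class tibble of category means
#'   plus the per-class sample sizes.
#' @export
bot_comparison <- function(corpus, sample_size = 1000L, seed = 1L) {
  if (is.null(corpus$bot_scores)) stop("corpus has no bot scores", call. = FALSE)
  ids <- class_user_ids(corpus)
  scores <- corpus$bot_scores
  per_class <- list()
  sizes <- list()
  with_local_seed(seed, {
    for (cl in names(ids)) {
      avail <- intersect(ids[[cl]], scores$user_id)
      if (length(avail) < sample_size) {
        warning("class '", cl, "' has only ", length(avail),
                " scored accounts (requested ", sample_size, "); using all",
                call. = FALSE)
        take <- avail
      } else {
        take <- sample(avail, sample_size)
      }
      sub <- scores[scores$user_id %in% take, .bot_categories, drop = FALSE]
      per_class[[cl]] <- colMeans(as.matrix(sub))
      sizes[[cl]] <- length(take)
    }
  })
  structure(
    list(
      means = tibble::as_tibble(cbind(
        tibble::tibble(class = names(per_class)),
        do.call(rbind, per_class)
      )),
      sample_sizes = unlist(sizes)
    ),
    class = "bot_comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (cl in names(x$per_class)) {
    s <- x$per_class[[cl]]
    if (is.null(s)) { cat("  ", cl, ": absent\n", sep = ""); next }
    cat(sprintf("  %s: %d accounts | verified:unverified %.3f | followers %.0f | friends %.0f | favourites %.0f\n",
                cl, s$n_accounts, s$verified_unverified_ratio,
                s$mean_followers, s$mean_friends, s$mean_favourites))
  }
  if (!is.null(x$fact_over_misinfo)) {
    r <- x$fact_over_misinfo
    cat(sprintf("  fact/misinfo ratios: followers %.2f, friends %.2f, favourites %.2f, verified %.2f\n",
                r$followers, r$friends, r$favourites, r$verified))
  }
  cat("  dual-membership accounts:", x$n_dual_membership, "\n")
  invisible(x)
}
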