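#' @importFrom rlang %||% .data
#' @importFrom stats rbeta rlnorm rpois runif setNames predict
#' @importFrom utils head
NULL

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so package functions never disturb the global stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# --- ISO-8601 week handling -------------------------------------------------
# Week keys are "YYYY-WW" (ISO week-numbering year, zero-padded ISO week).

#' ISO week key of a date or timestamp
#'
#' @param x a `Date` or `POSIXct` vector (timestamps are read in UTC).
#' @return character vector of `"YYYY-WW"` ISO week keys.
#' @examples
#' iso_week_key(as.Date("2020-11-01")) # "2020-44"
#' @export
iso_week_key <- function(x) {
  if (inherits(x, "POSIXct")) {
    format(x, "%G-%V", tz = "UTC")
  } else {
    format(as.Date(x), "%G-%V")
  }
}

# Monday (as Date) of an ISO "YYYY-WW" week key.
iso_week_start <- function(key) {
  parts <- strsplit(key, "-", fixed = TRUE)
  vapply(parts, function(p) {
    year <- as.integer(p[[1]])
    week <- as.integer(p[[2]])
    jan4 <- as.Date(sprintf("%d-01-04", year))
    # ISO weekday: Monday = 1 .. Sunday = 7
    wd <- as.integer(format(jan4, "%u"))
    monday_w1 <- jan4 - (wd - 1L)
    as.numeric(monday_w1 + (week - 1L) * 7L)
  }, numeric(1)) |>
    as.Date(origin = "1970-01-01")
}

# All ISO week keys from `from` to `to` inclusive (both "YYYY-WW").
iso_week_seq <- function(from, to) {
  start <- iso_week_start(from)
  end <- iso_week_start(to)
  if (end < start) stop("week range is reversed: ", from, " .. ", to)
  iso_week_key(seq(start, end, by = "7 days"))
}

# --- term matching ----------------------------------------------------------

# Case-insensitive word-boundary regex for a literal term. Boundaries are
# non-alphanumeric, so "5G" matches "5g tower" but not "15GB".
term_regex <- function(term) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
  sprintf("(?<![[:alnum:]])%s(?![[:alnum:]])", esc)
}

term_hits <- function(texts, term) {
  grepl(term_regex(term), texts, perl = TRUE, ignore.case = TRUE)
}

# --- misc -------------------------------------------------------------------

# Half-up rounding to `digits` decimal places (R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%null%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
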