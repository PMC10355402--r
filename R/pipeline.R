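#' @title End-to-end pipeline and run manifest
#' @description
#' [run_pipeline()] chains the stages — corpus generation (or loading),
#' label bootstrapping (manual seed emulation plus keyword augmentation),
#' active-learning training, corpus-wide classification, country and weekly
#' summaries, and account profiling — into a run directory. Every output
#' file is listed in a JSON manifest with its MD5 content hash, so two runs
#' with the same configuration and seeds can be compared file by file.
#' Stage failures keep earlier outputs and are recorded in the manifest.
#' @name reporting_cli
NULL

#' Pipeline configuration
#'
#' @param generator a [generator_config()] (used unless `tweets_path` is
#'   given).
#' @param tweets_path,users_path optional paths to existing tweet/user
#'   tables; when set, the generator is skipped and the oracle must come
#'   from a label file at `truth_path`.
#' @param truth_path optional label table acting as the oracle for loaded
#'   corpora.
#' @param n_manual size of the emulated manually-annotated seed set
#'   (default 500).
#' @param query an [augmentation_query()].
#' @param batch_size,max_iterations active-learning loop controls
#'   (defaults 100 and 50).
#' @param cv_folds folds for evaluation.
#' @param evaluate_every run cross-validation on every iteration (`1`,
#'   default) or only record set sizes.
#' @param sample_fraction fraction of users profiled demographically
#'   (default 0.10).
#' @param bot_sample_size accounts per class for the bot comparison
#'   (default 1000).
#' @param gazetteer_path optional gazetteer CSV (default: shipped).
#' @param format output table format, `"csv"` or `"jsonl"`.
#' @param seed master seed recorded in the manifest and used for every
#'   stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            tweets_path = NULL, users_path = NULL,
                            truth_path = NULL,
                            n_manual = 500L,
                            query = augmentation_query(target_additions = 400L),
                            batch_size = 100L, max_iterations = 50L,
                            cv_folds = 5L, evaluate_every = 1L,
                            sample_fraction = 0.10, bot_sample_size = 1000L,
                            gazetteer_path = NULL,
                            format = c("csv", "jsonl"), seed = 1L) {
  format <- match.arg(format)
  structure(
    list(generator = generator, tweets_path = tweets_path,
         users_path = users_path, truth_path = truth_path,
         n_manual = as.integer(n_manual), query = query,
         batch_size = as.integer(batch_size),
         max_iterations = as.integer(max_iterations),
         cv_folds = as.integer(cv_folds),
         evaluate_every = as.integer(evaluate_every),
         sample_fraction = sample_fraction,
         bot_sample_size = as.integer(bot_sample_size),
         gazetteer_path = gazetteer_path, format = format,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(df, path, progress = FALSE)
  path
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stages <- list()
  log_lines <- character(0)
  log_stage <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format_utc(Sys.time()), stage, msg)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    ok <- !inherits(res, "error")
    # timing goes to the log, not the manifest, so equal-seed runs produce
    # byte-identical manifests
    stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      error = if (ok) NULL else conditionMessage(res)
    )
    secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_stage(name, sprintf("%s (%.1fs)",
                            if (ok) "ok" else paste("FAILED:", conditionMessage(res)),
                            secs))
    if (!ok) NULL else res
  }
  ext <- config$format

  # -- stage 1: corpus ------------------------------------------------------
  gen <- run_stage("generate", function() {
    if (!is.null(config$tweets_path)) {
      tweets <- read_corpus_table(config$tweets_path, "tweet")
      users <- read_corpus_table(config$users_path, "user")
      truth <- if (is.null(config$truth_path)) NULL else {
        lab <- read_corpus_table(config$truth_path, "label")
        tibble::tibble(tweet_id = lab$tweet_id, label = lab$label)
      }
      list(corpus = join_corpus(tweets, users), truth = truth)
    } else {
      cfg <- config$generator
      cfg$seed <- config$seed
      generate_corpus(cfg)
    }
  })
  if (is.null(gen)) return(finish_manifest(config, out_dir, files, stages, log_lines))
  corpus <- gen$corpus
  truth <- gen$truth
  files <- c(files,
    write_corpus_table(corpus$tweets[, setdiff(names(corpus$tweets), "user_id")],
                       file.path(out_dir, paste0("tweets.", ext)), "tweet"),
    write_corpus_table(corpus$users, file.path(out_dir, paste0("users.", ext)),
                       "user"))

  if (is.null(truth)) {
    stages$augment <- stages$train_al <- list(status = "skipped (no truth/oracle)")
    return(finish_manifest(config, out_dir, files, stages, log_lines))
  }
  oracle <- make_oracle(truth)

  # -- stage 2: label bootstrap --------------------------------------------
  boot <- run_stage("augment", function() {
    merged <- bootstrap_labels(corpus$tweets, oracle,
                               n_manual = config$n_manual,
                               query = config$query, seed = config$seed)
    files <<- c(files,
      write_stage_csv(merged$labels, out_dir, "labels_bootstrap.csv"),
      write_stage_csv(merged$aug_report, out_dir, "augmentation_report.csv"),
      write_stage_csv(tibble::as_tibble(merged$report), out_dir,
                      "balance_report.csv"))
    merged
  })
  if (is.null(boot)) return(finish_manifest(config, out_dir, files, stages, log_lines))

  # -- stage 3: active learning --------------------------------------------
  al <- run_stage("train_al", function() {
    texts <- setNames(corpus$tweets$text, corpus$tweets$id)
    run_active_learning(
      texts, boot$labels[, c("tweet_id", "label")], oracle,
      batch_size = config$batch_size, max_iterations = config$max_iterations,
      cv_folds = config$cv_folds, seed = config$seed,
      evaluate = config$evaluate_every == 1L
    )
  })
  if (is.null(al)) return(finish_manifest(config, out_dir, files, stages, log_lines))
  files <- c(files, {
    p <- file.path(out_dir, "model.json")
    write_model(al$model, al$featurizer, p)
    p
  }, write_stage_csv(al$history, out_dir, "metrics_history.csv"))

  # -- stage 4: classify ----------------------------------------------------
  cls <- run_stage("classify", function() {
    predicted <- predict_corpus(al$model, al$featurizer, corpus)
    # known labels (manual/augmented/oracle) override predictions
    known <- al$state$labeled
    idx <- match(known$tweet_id, predicted$tweet_id)
    predicted$label[idx] <- known$label
    predicted$source[idx] <- "oracle"
    predicted
  })
  if (is.null(cls)) return(finish_manifest(config, out_dir, files, stages, log_lines))
  corpus <- set_corpus_labels(corpus, cls)
  files <- c(files, write_stage_csv(cls, out_dir, "labels_final.csv"))

  # -- stage 5: summarize ---------------------------------------------------
  summ <- run_stage("summarize", function() {
    corpus <<- map_corpus_countries(corpus, load_gazetteer(config$gazetteer_path))
    cs <- country_summaries(corpus)
    cs$ratio_percent <- format_ratio(cs$misinformation_ratio)
    wk_all <- minmax_normalize(weekly_series(corpus, class = "all"))
    wk_mis <- minmax_normalize(weekly_series(corpus, class = "misinformation"))
    peak <- annotate_peak(wk_mis)
    files <<- c(files,
      write_stage_csv(cs, out_dir, "country_summaries.csv"),
      write_stage_csv(wk_all, out_dir, "weekly_all.csv"),
      write_stage_csv(wk_mis, out_dir, "weekly_misinformation.csv"))
    list(peak = peak)
  })

  # -- stage 6: profile -----------------------------------------------------
  run_stage("profile", function() {
    sampled <- sample_users(corpus$users, config$sample_fraction,
                            seed = config$seed)
    assigned <- if (!is.null(corpus$demographics)) {
      assign_demographics(
        corpus$demographics[corpus$demographics$user_id %in% sampled$id, ])
    } else {
      NULL
    }
    eng <- engagement_comparison(corpus, assigned = assigned)
    out <- list(
      engagement = eng$per_class, fact_over_misinfo = eng$fact_over_misinfo,
      n_dual_membership = eng$n_dual_membership
    )
    if (!is.null(assigned)) {
      ages <- age_distribution(corpus, assigned = assigned)
      files <<- c(files, write_stage_csv(ages, out_dir, "age_distribution.csv"))
    }
    if (!is.null(corpus$bot_scores)) {
      bots <- bot_comparison(corpus, config$bot_sample_size, seed = config$seed)
      out$bot_means <- bots$means
      out$bot_sample_sizes <- as.list(bots$sample_sizes)
      files <<- c(files, write_stage_csv(bots$means, out_dir, "bot_comparison.csv"))
    }
    p <- file.path(out_dir, "profiling_report.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA, force = TRUE)
    files <<- c(files, p)
    out
  })

  finish_manifest(config, out_dir, files, stages, log_lines)
}

finish_manifest <- function(config, out_dir, files, stages, log_lines) {
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest <- list(
    seed = config$seed,
    format = config$format,
    stages = stages,
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
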