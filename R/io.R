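# Trial-log format, configuration, pipeline driver and run manifests.

TRIAL_COLUMNS <- c("session_id", "trial_index", "block_index",
                   "position_in_block", "difficulty", "h", "mu_db", "d",
                   "is_correction")

#' Write a trial log as tab-delimited text
#'
#' One row per trial with an explicit header; columns `session_id`,
#' `trial_index`, `block_index`, `position_in_block`, `difficulty`, `h`,
#' `mu_db`, `d`, `is_correction`. UTF-8, human-diffable.
#'
#' @param trials a `trial_log` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  tr <- pool_trials(trials)
  tr$is_correction <- as.integer(tr$is_correction)
  utils::write.table(tr[, TRIAL_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a trial log
#'
#' Schema violations are reported with row numbers: indicators outside
#' `{0, 1}`, a positive level on a no-signal row (or a zero level on a
#' signal row), and non-increasing trial indices within a session all
#' reject the file. The derived `outcome` column is filled for rows with
#' decisions.
#'
#' @param path a tab-delimited trial log written by [write_trials()].
#' @return A `trial_log` data frame.
#' @export
read_trials <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          fileEncoding = "UTF-8")
  missing <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing))
    stop("trial log lacks columns: ", paste(missing, collapse = ", "))
  bad_rows <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop(sprintf("%s at row(s) %s", what,
                   paste(utils::head(which(cond), 5), collapse = ", ")))
  }
  bad_rows(!tr$h %in% c(0, 1), "signal indicator h outside {0,1}")
  bad_rows(!is.na(tr$d) & !tr$d %in% c(0, 1), "decision d outside {0,1}")
  bad_rows(tr$h == 0 & tr$mu_db != 0, "positive level on no-signal trial")
  bad_rows(tr$h == 1 & tr$mu_db <= 0, "non-positive level on signal trial")
  for (sid in unique(tr$session_id)) {
    idx <- tr$trial_index[tr$session_id == sid]
    if (any(diff(idx) <= 0))
      stop("trial_index not strictly increasing in session ", sid)
  }
  tr$is_correction <- as.logical(tr$is_correction)
  tr$outcome <- ifelse(is.na(tr$d), NA_character_,
                       classify_outcome(tr$h, ifelse(is.na(tr$d), 0, tr$d)))
  structure(tr, class = c("trial_log", "data.frame"))
}

# stable md5 of a config, via its canonical JSON serialisation
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the simulate / summarise / fit / evaluate pipeline
#'
#' Executes a full synthetic-study pipeline from a structured configuration:
#' simulate a corpus from ground-truth parameters, write the trial logs and
#' summaries, fit the requested model variants by stochastic gradient
#' ascent, tabulate next-trial predictive capacity, and write a manifest
#' (config hash, seed, package version) sufficient to reproduce the outputs
#' byte-for-byte. Artifacts are staged in a temporary directory and moved
#' into `out_dir` only on success, so a failure leaves prior artifacts
#' untouched.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   `seed`, `out_dir`, `format`, `block_length`, `n_sessions`,
#'   `max_trials`, `params` (named ground-truth values), optional `levels`
#'   (defaults to the [fixture_psychometric()] level sets), optional
#'   `variants` (character vector; empty to skip fitting), optional
#'   `sga_iters` (3-vector overriding the schedule lengths, for quick runs).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  stopifnot(!is.null(config$seed), !is.null(config$out_dir),
            !is.null(config$format), !is.null(config$params))
  params <- do.call(model_params, as.list(config$params))
  ls <- if (!is.null(config$levels)) level_set(min(config$levels),
                                               max(config$levels))
        else select_levels_from_sigmoid(fixture_psychometric(params))
  design <- if (config$format == "alternating_blocks")
    session_design("alternating_blocks",
                   block_length = config$block_length %||% 8L,
                   easy_levels = ls$easy, hard_levels = ls$hard,
                   max_trials = config$max_trials %||% 120L)
  else
    session_design(config$format, all_levels = ls$levels,
                   max_trials = config$max_trials %||% 100L)
  stage <- tempfile("critdyn_run_")
  dir.create(stage)
  seed <- as.integer(config$seed)
  sessions <- simulate_corpus(params, design, config$n_sessions %||% 10L,
                              seed)
  write_trials(sessions, file.path(stage, "trials.tsv"))
  params_to_json(params, file.path(stage, "ground_truth.json"))
  pooled <- pool_trials(sessions)
  analysable <- pooled[!pooled$is_correction, ]
  if (config$format == "alternating_blocks") {
    bs <- fit_block_exponentials(
      wrap_block_positions(analysable, design$block_length))
    utils::write.table(as.data.frame(bs), file.path(stage, "block_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ef <- attr(bs, "exp_fit")
    jsonlite::write_json(list(B = ef$B, time_constant = ef$time_constant,
                              curves = ef$curves),
                         file.path(stage, "block_exponential_fit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  roc <- conditional_roc(pooled)
  utils::write.table(as.data.frame(roc), file.path(stage, "conditional_roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  variants <- config$variants %||% character(0)
  fits <- list()
  if (length(variants)) {
    schedule <- NULL
    if (!is.null(config$sga_iters))
      schedule <- data.frame(iters = as.integer(config$sga_iters),
                             eta = c(0.1, 0.01, 0.001),
                             lam_free = c(FALSE, TRUE, TRUE))
    for (v in variants) {
      fits[[v]] <- fit_sga(sessions, variant = v, seed = seed + 1L,
                           schedule = schedule)
      jsonlite::write_json(
        list(variant = v, params = unclass(fits[[v]]$params),
             loglik = fits[[v]]$loglik, trace = fits[[v]]$trace),
        file.path(stage, sprintf("fit_%s.json", v)),
        auto_unbox = TRUE, digits = NA)
    }
    tab <- prediction_table(pooled, fits)
    utils::write.table(tab, file.path(stage, "prediction_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(config = config, config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("critdyn")),
                   files = sort(list.files(stage)))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  unlink(stage, recursive = TRUE)
  invisible(manifest)
}
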