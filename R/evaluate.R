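# Model comparison: mean squared distances between empirical and model
# summary points, and next-trial predictive capacity with a paired
# one-sided test.

#' Mean squared distance between empirical and model summaries
#'
#' `msd_block` averages the squared Euclidean distance between the
#' per-position (hit, false alarm) points of two block summaries;
#' `msd_roc` does the same over the eight previous-outcome-conditioned ROC
#' markers (two difficulties times four outcomes). Points are matched by
#' position / difficulty and condition; a shape mismatch errors.
#'
#' @param empirical,model lists with components `block` (a `block_summary`)
#'   and/or `roc` (a `conditional_roc`); either component may be omitted
#'   from both.
#' @return An object of class `fit_quality`: `msd_block`, `msd_roc`,
#'   `n_points_block`, `n_points_roc` (components `NA` when not supplied).
#' @export
fit_quality <- function(empirical, model) {
  out <- list(msd_block = NA_real_, msd_roc = NA_real_,
              n_points_block = NA_integer_, n_points_roc = NA_integer_)
  if (!is.null(empirical$block) || !is.null(model$block)) {
    e <- empirical$block; m <- model$block
    if (is.null(e) || is.null(m) || nrow(e) != nrow(m) ||
        !all(e$position == m$position))
      stop("block summaries do not match in shape")
    out$msd_block <- mean((e$p_hit - m$p_hit)^2 + (e$p_fa - m$p_fa)^2)
    out$n_points_block <- nrow(e)
  }
  if (!is.null(empirical$roc) || !is.null(model$roc)) {
    e <- empirical$roc; m <- model$roc
    if (is.null(e) || is.null(m)) stop("roc summaries do not match in shape")
    e <- e[e$condition != "all", ]
    key <- paste(e$difficulty, e$condition)
    idx <- match(key, paste(m$difficulty, m$condition))
    if (any(is.na(idx))) stop("roc summaries do not match in shape")
    out$msd_roc <- mean((e$p_fa - m$p_fa[idx])^2 +
                          (e$p_hit - m$p_hit[idx])^2)
    out$n_points_roc <- nrow(e)
  }
  structure(out, class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("<fit_quality> msd block: %s (n = %s); msd ROC: %s (n = %s)\n",
              format(x$msd_block, digits = 3), x$n_points_block,
              format(x$msd_roc, digits = 3), x$n_points_roc))
  invisible(x)
}

#' Next-trial predictive capacity of a parameter set
#'
#' The model's prediction for trial `n` compares the signal level to the
#' criterion `c_n` computed from the outcomes of all the subject's decisions
#' up to trial `n - 1` (a deterministic, noise-free comparison): predict
#' "yes" iff `mu_n > c_n`, with ties going to "no". Agreement is counted
#' over all trials.
#'
#' @param trials a `trial_log` or list of them.
#' @param params a [model_params()] object (typically a fitted set).
#' @param variant label stored in the report.
#' @return An object of class `prediction_report`: `variant`, `n_trials`,
#'   `n_yes`, `n_predicted`, and the per-trial agreement indicator vector
#'   `agreement` (in pooled trial order, used for paired tests).
#' @export
predictive_capacity <- function(trials, params, variant = params$variant) {
  sessions <- split_sessions(trials)
  agree <- unlist(lapply(sessions, function(tr) {
    cn <- session_recursions(tr, params)$c
    pred <- as.integer(tr$mu_db > cn)
    pred == tr$d
  }), use.names = FALSE)
  n <- length(agree)
  structure(list(variant = variant, n_trials = n,
                 n_yes = sum(pool_trials(trials)$d),
                 n_predicted = sum(agree), agreement = agree),
            class = "prediction_report")
}

#' Paired one-sided test of two prediction reports
#'
#' Tests whether the first model predicts decisions better than the second,
#' using a one-sided sign test on the paired per-trial agreement
#' indicators. Differences are -1, 0 or +1, so the signed-rank and sign
#' tests coincide up to the handling of zeros, which are dropped; with no
#' nonzero differences the p-value is 1.
#'
#' @param better,worse `prediction_report` objects over the same trials.
#' @return The one-sided p-value.
#' @export
prediction_test <- function(better, worse) {
  if (better$n_trials != worse$n_trials)
    stop("reports cover different numbers of trials")
  diff <- as.integer(better$agreement) - as.integer(worse$agreement)
  nz <- diff != 0
  if (!any(nz)) return(1)
  stats::binom.test(sum(diff[nz] > 0), sum(nz),
                    alternative = "greater")$p.value
}

#' Tabulate predictive capacity across model variants
#'
#' @param trials a `trial_log` or list of them.
#' @param fits named list of [model_params()] (or `fit_result`) objects;
#'   the p-value column tests each variant against the first entry
#'   (conventionally the static no-shift baseline).
#' @return A data frame with one row per variant: `variant`, `n_trials`,
#'   `n_yes`, `n_predicted`, `p_vs_baseline`.
#' @export
prediction_table <- function(trials, fits) {
  reports <- lapply(fits, function(f) {
    p <- if (inherits(f, "fit_result")) f$params else f
    predictive_capacity(trials, p)
  })
  base <- reports[[1]]
  data.frame(
    variant = names(fits),
    n_trials = vapply(reports, `[[`, numeric(1), "n_trials"),
    n_yes = vapply(reports, `[[`, numeric(1), "n_yes"),
    n_predicted = vapply(reports, `[[`, numeric(1), "n_predicted"),
    p_vs_baseline = vapply(reports, function(r)
      prediction_test(r, base), numeric(1)),
    row.names = NULL)
}
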