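# Stimulus side of a session: block schedules, within-block permutation,
# level-set selection from a psychometric fit.

#' Run code under a local RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Describe the stimulus design of a session
#'
#' @param format one of `"alternating_blocks"`, `"random"`,
#'   `"random_with_corrections"`.
#' @param block_length trials per block, `L` (8 or 24 in the experiments;
#'   must be divisible by 4). Blocked format only.
#' @param easy_levels,hard_levels two dB levels each, blocked format only.
#' @param all_levels dB levels for the unblocked formats.
#' @param p_signal probability of a signal trial (0.5 throughout).
#' @param max_trials session cap.
#' @param seed RNG seed used when a schedule is generated from the design.
#' @return An object of class `session_design`.
#' @export
session_design <- function(format = c("alternating_blocks", "random",
                                      "random_with_corrections"),
                           block_length = 8L,
                           easy_levels = NULL, hard_levels = NULL,
                           all_levels = NULL,
                           p_signal = 0.5, max_trials = 120L, seed = NULL) {
  format <- match.arg(format)
  d <- list(format = format, block_length = as.integer(block_length),
            easy_levels = easy_levels, hard_levels = hard_levels,
            all_levels = all_levels, p_signal = p_signal,
            max_trials = as.integer(max_trials), seed = seed)
  class(d) <- "session_design"
  if (p_signal < 0 || p_signal > 1) stop("p_signal must lie in [0, 1]")
  if (max_trials < 1) stop("max_trials must be positive")
  if (format == "alternating_blocks") {
    if (is.null(easy_levels) || is.null(hard_levels))
      stop("blocked format requires easy_levels and hard_levels")
    if (block_length %% 4 != 0)
      stop("block_length must be divisible by 4 to balance two levels")
  } else {
    if (is.null(all_levels) || length(all_levels) == 0)
      stop("unblocked formats require a nonempty all_levels")
  }
  d
}

#' Build an alternating-block stimulus schedule
#'
#' Blocks of `L` trials alternate between the easy and the hard level set,
#' starting with an easy block. Each block contains exactly `L/2` no-signal
#' trials and `L/(2 k)` trials at each of the `k` levels of its set, in a
#' uniformly random within-block permutation (not i.i.d. sampling). The
#' session is truncated at `max_trials`, possibly mid-block.
#'
#' @param design a [session_design()] with `format = "alternating_blocks"`.
#' @param seed RNG seed; defaults to `design$seed`.
#' @return A data frame with one row per trial: `h`, `mu`, `block_index`,
#'   `position_in_block`, `difficulty` (`"easy"`/`"hard"`).
#' @export
make_block_schedule <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "session_design"))
  if (design$format != "alternating_blocks")
    stop("make_block_schedule requires the alternating_blocks format")
  L <- design$block_length
  n_blocks <- ceiling(design$max_trials / L)
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      easy <- b %% 2 == 1
      levels <- if (easy) design$easy_levels else design$hard_levels
      k <- length(levels)
      if (L %% (2 * k) != 0)
        stop("block_length must be divisible by twice the level-set size")
      mu <- c(rep(0, L / 2), rep(levels, each = L / (2 * k)))
      ord <- sample.int(L)
      data.frame(h = as.integer(mu[ord] > 0), mu = mu[ord],
                 block_index = b, position_in_block = seq_len(L),
                 difficulty = if (easy) "easy" else "hard")
    })
    out <- do.call(rbind, blocks)
    utils::head(out, design$max_trials)
  })
}

#' Build a randomised-level stimulus schedule
#'
#' Each trial is independently a signal trial with probability `p_signal`;
#' on signal trials the level is drawn uniformly from `all_levels`.
#'
#' @param design a [session_design()] with an unblocked format.
#' @param seed RNG seed; defaults to `design$seed`.
#' @return A data frame with columns `h`, `mu`, `block_index`,
#'   `position_in_block`, `difficulty` (the latter three `NA` here).
#' @export
make_random_schedule <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "session_design"))
  if (design$format == "alternating_blocks")
    stop("make_random_schedule requires an unblocked format")
  n <- design$max_trials
  with_seed(seed, {
    h <- as.integer(stats::runif(n) < design$p_signal)
    mu <- numeric(n)
    lv <- design$all_levels
    mu[h == 1] <- lv[sample.int(length(lv), sum(h), replace = TRUE)]
    data.frame(h = h, mu = mu, block_index = NA_integer_,
               position_in_block = NA_integer_, difficulty = NA_character_)
  })
}

#' Make a stimulus schedule for any design
#'
#' Dispatches to [make_block_schedule()] or [make_random_schedule()].
#'
#' @inheritParams make_block_schedule
#' @return A schedule data frame (see the two builders).
#' @export
make_schedule <- function(design, seed = design$seed) {
  if (design$format == "alternating_blocks") make_block_schedule(design, seed)
  else make_random_schedule(design, seed)
}

#' A level set spanning part of the psychometric curve
#'
#' @param s_minus,s_plus lowest and highest level, dB.
#' @return An object of class `level_set` with four levels uniformly spaced
#'   in dB between `s_minus` and `s_plus`; the lower pair is the hard set,
#'   the upper pair the easy set.
#' @export
level_set <- function(s_minus, s_plus) {
  if (!(is.finite(s_minus) && is.finite(s_plus)) || s_minus >= s_plus)
    stop("need finite s_minus < s_plus")
  levels <- seq(s_minus, s_plus, length.out = 4)
  structure(list(s_minus = s_minus, s_plus = s_plus, levels = levels,
                 hard = levels[1:2], easy = levels[3:4]),
            class = "level_set")
}

#' Choose easy and hard level sets from a fitted psychometric curve
#'
#' Reads off the levels at which the fitted sigmoid attains 10% and 90% of
#' its rise above chance — so the four uniformly spaced levels between them
#' span the centre ~80% of the psychometric curve. The lower pair forms the
#' hard set and the upper pair the easy set.
#'
#' @param fit a `psychometric_fit` from [fit_sigmoid()], or any list with
#'   `mid` and `slope` fields.
#' @return A [level_set()].
#' @export
select_levels_from_sigmoid <- function(fit) {
  if (is.null(fit$slope) || !is.finite(fit$slope) || fit$slope <= 0)
    stop("sigmoid fit must have a finite positive slope")
  s_minus <- fit$mid + fit$slope * stats::qnorm(0.1)
  s_plus <- fit$mid + fit$slope * stats::qnorm(0.9)
  level_set(s_minus, s_plus)
}
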