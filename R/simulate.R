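# Generative simulation of complete sessions: the data stand-in for the
# behavioural experiments. Decisions are produced by the criterion-shift
# model itself, including correction-trial chains for the retrospective
# psychometric format.

#' Reference parameter sets for the five subjects
#'
#' The published maximum-likelihood parameter sets for the full model, one
#' row per subject and trial format. These are used as ground truth for the
#' synthetic benchmark fixtures and recovery studies.
#'
#' @param row one of `"f1_blocks8"`, `"f2_blocks8"`, `"f2_random"`,
#'   `"f3_random_ct"`, `"f4_random_ct"`, `"f5_random_ct"`.
#' @return A [model_params()] object.
#' @export
reference_params <- function(row = c("f1_blocks8", "f2_blocks8", "f2_random",
                                     "f3_random_ct", "f4_random_ct",
                                     "f5_random_ct")) {
  row <- match.arg(row)
  tab <- list(
    f1_blocks8   = c(6.38, 0.89, 2.30, 4.28, -5.28, 1.83, 2.02, 0.07),
    f2_blocks8   = c(4.16, 0.85, 2.04, 3.33, -1.81, 0.70, 2.06, 0.05),
    f2_random    = c(3.65, 0.87, 1.44, 3.87, -3.51, 0.92, 0.10, 0.06),
    f3_random_ct = c(12.36, 0.83, 7.81, 8.25, -1.13, 1.81, 2.62, 0.04),
    f4_random_ct = c(10.89, 0.96, 5.31, 6.72, -7.99, 6.31, 0.97, 0.03),
    f5_random_ct = c(9.41, 0.70, 5.63, 6.79, -2.60, 1.85, 2.18, 0.04))
  v <- tab[[row]]
  model_params(sigma = v[1], a = v[2], c1 = v[3],
               b11 = v[4], b01 = v[5], b10 = v[6], b00 = v[7], lam = v[8])
}

# One generative pass over a schedule. Per executed trial the RNG draws are
# consumed in a fixed order -- signal noise, lapse, lapse-coin, shift noise
# (all four every trial, used or not) -- so traces are reproducible and
# correction-trial insertion keeps upstream draws aligned.
simulate_stream <- function(schedule, params, corrections = FALSE,
                            max_trials = Inf) {
  n_sched <- nrow(schedule)
  cap <- as.integer(min(max_trials,
                        if (corrections) 50L * n_sched else n_sched))
  s_h <- as.integer(schedule$h); s_mu <- as.numeric(schedule$mu)
  s_b <- schedule$block_index; s_p <- schedule$position_in_block
  s_d <- as.character(schedule$difficulty)
  h <- integer(cap); mu <- numeric(cap); d <- integer(cap)
  corr <- logical(cap); bidx <- rep(NA_integer_, cap); pos <- bidx
  diff <- character(cap); ctrace <- numeric(cap)
  # outcome index 1..4 = hit, miss, FA, CR; shift lookup in that order
  b <- unname(shift_vector(params))
  sd_eps <- params$shift_noise_sd
  a <- params$a; c1 <- params$c1; sig <- params$sigma; lam <- params$lam
  c_n <- c1
  i <- 0L           # schedule pointer
  k <- 0L           # emitted trial counter
  pending <- FALSE  # repeat the current schedule row as a correction trial
  while (k < cap && (i < n_sched || pending)) {
    if (!pending) i <- i + 1L
    is_corr <- pending
    pending <- FALSE
    k <- k + 1L
    x <- stats::rnorm(1, s_mu[i], sig)
    lapse <- stats::runif(1) < lam
    coin <- stats::runif(1) < 0.5
    eps <- if (sd_eps > 0) stats::rnorm(1, 0, sd_eps) else 0
    dec <- if (lapse) as.integer(coin) else as.integer(x > c_n)
    out_i <- if (s_h[i] == 1L) (if (dec == 1L) 1L else 2L)
             else (if (dec == 1L) 3L else 4L)
    h[k] <- s_h[i]; mu[k] <- s_mu[i]; d[k] <- dec; corr[k] <- is_corr
    bidx[k] <- s_b[i]; pos[k] <- s_p[i]
    diff[k] <- s_d[i]; ctrace[k] <- c_n
    c_n <- c_n + a * (c1 - c_n) + b[out_i] + eps
    if (corrections && dec != s_h[i])
      pending <- TRUE
  }
  list(h = h[1:k], mu = mu[1:k], d = d[1:k], is_correction = corr[1:k],
       block_index = bidx[1:k], position_in_block = pos[1:k],
       difficulty = diff[1:k], criterion_trace = ctrace[1:k])
}

#' Simulate one session of the criterion-shift model
#'
#' Runs the generative model over a stimulus schedule: on each trial an
#' internal variate `x ~ N(mu, sigma)` is drawn, a lapse occurs with
#' probability `lam` (the decision is then an unbiased coin), otherwise the
#' response is "yes" iff `x` exceeds the current criterion; the criterion is
#' then updated by [update_criterion()]. Deterministic given the seed.
#'
#' @param schedule a schedule data frame (see [make_schedule()]) with columns
#'   `h`, `mu` and optionally `block_index`, `position_in_block`,
#'   `difficulty`.
#' @param params a [model_params()] object (ground truth).
#' @param seed RNG seed.
#' @param session_id identifier stored in the trial log.
#' @param corrections insert correction-trial chains (see
#'   [apply_correction_policy()]).
#' @return A `trial_log` data frame with columns `session_id`, `trial_index`,
#'   `block_index`, `position_in_block`, `difficulty`, `h`, `mu_db`, `d`,
#'   `is_correction`, `outcome`, and attributes `criterion_trace`, `params`,
#'   `seed`.
#' @export
simulate_session <- function(schedule, params, seed = NULL,
                             session_id = "s1", corrections = FALSE) {
  validate_params(params)
  if (nrow(schedule) == 0) stop("schedule must be nonempty")
  if (!all(c("h", "mu") %in% names(schedule)))
    stop("schedule needs columns h and mu")
  for (col in c("block_index", "position_in_block", "difficulty"))
    if (is.null(schedule[[col]])) schedule[[col]] <- NA
  st <- with_seed(seed, simulate_stream(schedule, params, corrections))
  log <- data.frame(session_id = session_id,
                    trial_index = seq_along(st$h),
                    block_index = st$block_index,
                    position_in_block = st$position_in_block,
                    difficulty = st$difficulty,
                    h = st$h, mu_db = st$mu, d = st$d,
                    is_correction = st$is_correction)
  log$outcome <- classify_outcome(log$h, log$d)
  structure(log, class = c("trial_log", "data.frame"),
            criterion_trace = st$criterion_trace, params = params,
            seed = seed)
}

#' Simulate a session with the correction-trial policy
#'
#' In the retrospective psychometric format every incorrect (non-correction)
#' trial is followed by a repeat of the identical `(h, mu)` stimulus, flagged
#' `is_correction = TRUE`; repeats chain until a correct response. Correction
#' trials drive criterion updates like any other trial but are excluded from
#' summary statistics downstream. When the input is an already-simulated
#' session, its schedule is replayed under the same seed, so an error-free
#' session is returned unchanged.
#'
#' @param x a schedule data frame, a [session_design()] with
#'   `format = "random_with_corrections"`, or a simulated `trial_log`.
#' @param params a [model_params()] object; defaults to the `params`
#'   attribute when `x` is a simulated session.
#' @param seed RNG seed; defaults likewise.
#' @param session_id identifier stored in the trial log.
#' @return A `trial_log` as for [simulate_session()], with correction trials
#'   inserted.
#' @export
apply_correction_policy <- function(x, params = attr(x, "params"),
                                    seed = attr(x, "seed"),
                                    session_id = "s1") {
  if (inherits(x, "session_design")) {
    if (x$format != "random_with_corrections")
      stop("correction trials apply only to the random_with_corrections ",
           "format (they were omitted during blocked sessions)")
    x <- make_random_schedule(x, seed)
  }
  if (inherits(x, "trial_log")) {
    if (any(!is.na(x$difficulty)))
      stop("correction trials apply only to the random_with_corrections ",
           "format (they were omitted during blocked sessions)")
    session_id <- x$session_id[1]
    x <- x[!x$is_correction, c("h", "mu_db")]
    names(x) <- c("h", "mu")
  }
  if (!is.na(x$difficulty[1] %||% NA))
    stop("correction trials apply only to unblocked schedules")
  simulate_session(x, params, seed = seed, session_id = session_id,
                   corrections = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical psychometric world used for the synthetic fixtures
#'
#' The experiments chose level sets from a measured psychometric curve. For
#' a simulated observer no curve is measured, so the fixtures adopt the
#' curve of the matching static observer: sigmoid midpoint `2 * sigma` and
#' slope `sigma` (detection threshold about twice the internal noise SD, a
#' curve width set by the noise), zero psychometric lapse.
#'
#' @param params a [model_params()] object.
#' @return A list with `mid` and `slope`, usable by
#'   [select_levels_from_sigmoid()].
#' @export
fixture_psychometric <- function(params) {
  list(mid = 2 * params$sigma, slope = params$sigma, lapse_psy = 0)
}

#' Simulate a multi-session benchmark corpus
#'
#' @param params ground-truth [model_params()].
#' @param design a [session_design()].
#' @param n_sessions number of sessions.
#' @param seed integer seed; session `i` uses seed `seed + i`.
#' @return A list of `trial_log` objects.
#' @export
simulate_corpus <- function(params, design, n_sessions, seed) {
  lapply(seq_len(n_sessions), function(i) {
    sched <- make_schedule(design, seed = seed + i)
    simulate_session(sched, params, seed = seed + 1000L + i,
                     session_id = sprintf("s%03d", i),
                     corrections = design$format == "random_with_corrections")
  })
}

#' Seeded benchmark fixtures for the three session formats
#'
#' Emits ground-truth-labelled synthetic corpora: an alternating 8-trial
#' block corpus at the subject-1 parameters (~6,500 trials, the scale of the
#' largest blocked corpus), a randomised-level corpus and a correction-trial
#' corpus at the subject-2 random-format parameters. Level sets come from
#' [fixture_psychometric()] via [select_levels_from_sigmoid()].
#'
#' @param seed integer seed.
#' @param n_sessions_blocked,n_sessions_random sizes (sessions of 120 / 100
#'   trials).
#' @return A named list of fixtures; each has `sessions` (list of
#'   `trial_log`), `params`, and `design`.
#' @export
make_benchmark_suite <- function(seed, n_sessions_blocked = 54L,
                                 n_sessions_random = 8L) {
  out <- list()
  p1 <- reference_params("f1_blocks8")
  ls1 <- select_levels_from_sigmoid(fixture_psychometric(p1))
  d1 <- session_design("alternating_blocks", block_length = 8L,
                       easy_levels = ls1$easy, hard_levels = ls1$hard,
                       max_trials = 120L)
  out$ferret1_blocks8 <- list(
    sessions = simulate_corpus(p1, d1, n_sessions_blocked, seed),
    params = p1, design = d1)
  p2 <- reference_params("f2_random")
  ls2 <- select_levels_from_sigmoid(fixture_psychometric(p2))
  d2 <- session_design("random", all_levels = ls2$levels, max_trials = 100L)
  out$ferret2_random <- list(
    sessions = simulate_corpus(p2, d2, n_sessions_random, seed + 10000L),
    params = p2, design = d2)
  d3 <- session_design("random_with_corrections", all_levels = ls2$levels,
                       max_trials = 100L)
  out$ferret2_random_ct <- list(
    sessions = simulate_corpus(p2, d3, n_sessions_random, seed + 20000L),
    params = p2, design = d3)
  out
}
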