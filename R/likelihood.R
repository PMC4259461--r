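# Exact log-likelihood of decision sequences and its analytic gradient.
# Because every previous outcome is observed, the criterion is a
# deterministic linear recursion of the observed history; both the
# criterion trace and the parameter sensitivities are first-order linear
# recursions, evaluated with stats::filter.

PARAM_NAMES <- c("sigma", "a", "c1", "b11", "b01", "b10", "b00", "lam")

# split a pooled trial table into per-session tables, preserving order
split_sessions <- function(trials) {
  tr <- pool_trials(trials)
  split(tr, factor(tr$session_id, levels = unique(tr$session_id)))
}

# criterion trace and sensitivities for one session's observed outcomes
session_recursions <- function(tr, params, need_grad = FALSE) {
  N <- nrow(tr)
  a <- params$a; c1 <- params$c1
  b <- unname(shift_vector(params))
  k <- match(tr$outcome, OUTCOMES)
  u <- a * c1 + b[k]
  ctr <- if (N == 1) c1 else
    c(c1, as.numeric(stats::filter(u[-N], 1 - a, method = "recursive",
                                   init = c1)))
  if (!need_grad) return(list(c = ctr))
  filt <- function(x) {
    if (N == 1) return(0)
    c(0, as.numeric(stats::filter(x[-N], 1 - a, method = "recursive",
                                  init = 0)))
  }
  s_c1 <- if (N == 1) 1 else
    c(1, as.numeric(stats::filter(rep(a, N - 1), 1 - a,
                                  method = "recursive", init = 1)))
  s_a <- filt(c1 - ctr)
  s_b <- lapply(1:4, function(j) filt(as.numeric(k == j)))
  list(c = ctr, s_c1 = s_c1, s_a = s_a, s_b = s_b)
}

#' Log-likelihood of decision sequences under the criterion-shift model
#'
#' The criterion applied on each trial is a deterministic function of the
#' observed history (it resets to `c1` at every session start), so the
#' log-likelihood is the sum over trials of `log P(d_n | c_n, mu_n)`, with
#' the yes-probability from [response_probability()]. Fitting assumes
#' `shift_noise_sd = 0`.
#'
#' @param trials a `trial_log` or list of them; decisions must be present.
#' @param params a [model_params()] object.
#' @param include_corrections if `FALSE`, correction trials still drive the
#'   criterion recursion but contribute no likelihood terms.
#' @return The log-likelihood (scalar), with attribute `criterion_trace`
#'   (list per session). `-Inf` (with a `zero_prob_trials` attribute) if any
#'   observed decision has probability zero.
#' @export
log_likelihood <- function(trials, params, include_corrections = TRUE) {
  validate_params(params)
  if (params$shift_noise_sd != 0)
    stop("fitting requires shift_noise_sd = 0")
  sessions <- split_sessions(trials)
  ll <- 0
  traces <- list()
  zero <- character(0)
  for (nm in names(sessions)) {
    tr <- sessions[[nm]]
    if (any(is.na(tr$d))) stop("decisions must be present")
    rec <- session_recursions(tr, params)
    traces[[nm]] <- rec$c
    py <- response_probability(rec$c, tr$mu_db, params)
    p <- ifelse(tr$d == 1, py, 1 - py)
    w <- if (include_corrections) rep(TRUE, nrow(tr)) else !tr$is_correction
    if (any(p[w] == 0)) {
      zero <- c(zero, sprintf("%s:%d", nm, tr$trial_index[w & p == 0]))
      ll <- -Inf
      next
    }
    ll <- ll + sum(log(p[w]))
  }
  structure(ll, criterion_trace = traces,
            zero_prob_trials = if (length(zero)) zero else NULL)
}

#' Analytic gradient of the log-likelihood
#'
#' Forward sensitivity recursion: the derivative of the criterion trace with
#' respect to each parameter obeys
#' `dc[n+1] = (1 - a) dc[n] + d(a c1 + b_outcome)`, propagated alongside the
#' trace itself; per-trial terms then follow from the chain rule through the
#' yes-probability. Validated against central finite differences.
#'
#' @inheritParams log_likelihood
#' @return Named numeric vector of length 8 (`sigma`, `a`, `c1`, `b11`,
#'   `b01`, `b10`, `b00`, `lam`), on the natural parameter scale.
#' @export
ll_gradient <- function(trials, params, include_corrections = TRUE) {
  validate_params(params)
  sessions <- split_sessions(trials)
  g <- stats::setNames(numeric(8), PARAM_NAMES)
  sig <- params$sigma; lam <- params$lam
  for (tr in sessions) {
    rec <- session_recursions(tr, params, need_grad = TRUE)
    z <- (tr$mu_db - rec$c) / sig
    phi <- stats::dnorm(z)
    Phi <- stats::pnorm(z)
    py <- lam / 2 + (1 - lam) * Phi
    p <- ifelse(tr$d == 1, py, 1 - py)
    w <- if (include_corrections) rep(1, nrow(tr))
         else as.numeric(!tr$is_correction)
    gp <- w * ifelse(tr$d == 1, 1 / p, -1 / p)   # dlogP/dPyes
    dpy_dc <- -(1 - lam) * phi / sig
    gc <- gp * dpy_dc                            # dlogP/dc_n
    g["sigma"] <- g["sigma"] + sum(gp * (-(1 - lam) * phi * z / sig))
    g["lam"] <- g["lam"] + sum(gp * (0.5 - Phi))
    g["c1"] <- g["c1"] + sum(gc * rec$s_c1)
    g["a"] <- g["a"] + sum(gc * rec$s_a)
    for (j in 1:4)
      g[.SHIFT_NAMES[j]] <- g[.SHIFT_NAMES[j]] + sum(gc * rec$s_b[[j]])
  }
  g
}

#' Finite-difference gradient (validation oracle)
#'
#' Central differences of [log_likelihood()] over the eight parameters.
#'
#' @inheritParams log_likelihood
#' @param h relative step size.
#' @return Named numeric vector like [ll_gradient()].
#' @export
ll_gradient_fd <- function(trials, params, include_corrections = TRUE,
                           h = 1e-5) {
  vapply(PARAM_NAMES, function(nm) {
    step <- h * max(1, abs(params[[nm]]))
    up <- params; up[[nm]] <- params[[nm]] + step
    dn <- params; dn[[nm]] <- params[[nm]] - step
    (as.numeric(log_likelihood(trials, up, include_corrections)) -
       as.numeric(log_likelihood(trials, dn, include_corrections))) /
      (2 * step)
  }, numeric(1))
}
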