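# Descriptive analyses: bias-free proportion correct, sigmoid psychometric
# regression, block-position wrapping, shared-decay exponential regression,
# and ROC markers conditioned on the previous trial's outcome.

#' Bias-free proportion correct from hit and false-alarm rates
#'
#' The proportion correct an unbiased observer would achieve at the measured
#' sensitivity: \deqn{PC_{max} = \Phi[(z(H) - z(F))/2],} where `z` is the
#' normal quantile function. Rates of exactly 0 or 1 are clamped to
#' `1/(2N)` and `1 - 1/(2N)` (the standard correction), which requires the
#' relevant trial count.
#'
#' @param hit_rate,fa_rate hit and false-alarm rates (vectorised).
#' @param n_signal,n_noise trial counts behind each rate; only needed when a
#'   rate is exactly 0 or 1.
#' @return `PC_max`, a probability; 0.5 when `hit_rate == fa_rate`.
#' @export
pc_max <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL) {
  clamp <- function(r, n, what) {
    bad <- r <= 0 | r >= 1
    if (any(bad)) {
      if (is.null(n)) stop("rate of 0 or 1 needs a trial count (", what,
                           ") for clamping")
      r[bad] <- pmin(pmax(r[bad], 1 / (2 * n[bad])), 1 - 1 / (2 * n[bad]))
    }
    r
  }
  if (!is.null(n_signal)) n_signal <- rep_len(n_signal, length(hit_rate))
  if (!is.null(n_noise)) n_noise <- rep_len(n_noise, length(fa_rate))
  h <- clamp(hit_rate, n_signal, "n_signal")
  f <- clamp(fa_rate, n_noise, "n_noise")
  stats::pnorm((stats::qnorm(h) - stats::qnorm(f)) / 2)
}

#' Evaluate the psychometric sigmoid
#'
#' \deqn{PC(s) = 0.5 + (0.5 - \lambda_{psy})\,\Phi((s - mid)/slope),} so the
#' asymptote at high levels is `1 - lapse_psy`.
#'
#' @param s signal level, dB (vectorised).
#' @param mid,slope sigmoid midpoint and spread, dB.
#' @param lapse_psy asymptote deficit in `[0, 0.5]`.
#' @return Predicted `PC_max` values.
#' @export
psychometric_sigmoid <- function(s, mid, slope, lapse_psy = 0) {
  0.5 + (0.5 - lapse_psy) * stats::pnorm((s - mid) / slope)
}

#' Fit a sigmoid to psychometric points by least squares
#'
#' Minimises the mean squared error between measured `PC_max` points and
#' [psychometric_sigmoid()] over midpoint, slope and psychometric lapse
#' (Nelder-Mead, as in the original MATLAB `fminsearch` fit). The reference
#' level `db_ref` is read off where the fitted curve attains 5% of its rise
#' above chance.
#'
#' @param points data frame with columns `level` and `pc` (and optionally
#'   `n`); at least 4 distinct levels.
#' @return An object of class `psychometric_fit`: `mid`, `slope`,
#'   `lapse_psy`, `db_ref`, `points`, `mse`, `convergence`.
#' @export
fit_sigmoid <- function(points) {
  stopifnot(all(c("level", "pc") %in% names(points)))
  if (length(unique(points$level)) < 4)
    stop("need at least 4 distinct levels")
  if (stats::sd(points$pc) < 1e-8)
    stop("flat psychometric data: slope is unidentifiable")
  obj <- function(par) {
    mid <- par[1]; slope <- exp(par[2]); lapse <- 0.5 * stats::plogis(par[3])
    mean((points$pc - psychometric_sigmoid(points$level, mid, slope,
                                           lapse))^2)
  }
  rng <- range(points$level)
  init <- c(mean(rng), log(max(diff(rng) / 4, 1e-3)), stats::qlogis(0.04))
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  # polish from the first solution; fminsearch-style restarts
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0)
    warning("sigmoid fit did not converge (code ", opt$convergence, ")")
  mid <- opt$par[1]; slope <- exp(opt$par[2])
  lapse <- 0.5 * stats::plogis(opt$par[3])
  structure(list(mid = mid, slope = slope, lapse_psy = lapse,
                 db_ref = mid + slope * stats::qnorm(0.05),
                 points = points, mse = opt$value,
                 convergence = opt$convergence),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> mid = %.3f dB, slope = %.3f dB, lapse = %.4f\n",
    x$mid, x$slope, x$lapse_psy))
  cat(sprintf("  reference level (5%% rise): %.3f dB; mse = %.3g\n",
              x$db_ref, x$mse))
  invisible(x)
}

# rbind a trial_log or a list of them into one plain data frame
pool_trials <- function(trials) {
  if (inherits(trials, "data.frame")) return(as.data.frame(trials))
  do.call(rbind, lapply(trials, as.data.frame))
}

#' Wrap blocked sessions onto one easy+hard cycle
#'
#' Pools trials from all sessions by their session position modulo one
#' easy+hard cycle of `2L` positions (so for `L = 8`, easy position 1 pools
#' session positions 1, 17, 33, ...). Per position it computes the hit
#' probability (over signal trials), false-alarm probability (over no-signal
#' trials), and the observed proportions of correct and "yes" responses.
#' Positions with no eligible trials give `NaN`, not 0.
#'
#' @param trials a `trial_log` or list of them (blocked format, no
#'   correction trials).
#' @param L block length.
#' @return A `block_summary` data frame with one row per cycle position:
#'   `position`, `difficulty`, `p_hit`, `n_signal`, `p_fa`, `n_noise`,
#'   `p_correct`, `p_yes`, `n`.
#' @export
wrap_block_positions <- function(trials, L) {
  tr <- pool_trials(trials)
  if (any(tr$is_correction))
    stop("blocked summaries expect correction-free logs")
  cyc <- ((tr$trial_index - 1) %% (2 * L)) + 1
  pos <- seq_len(2 * L)
  rate <- function(keep, pos_i) {
    sel <- keep & cyc == pos_i
    c(if (any(sel)) mean(tr$d[sel]) else NaN, sum(sel))
  }
  hit <- vapply(pos, function(p) rate(tr$h == 1, p), numeric(2))
  fa <- vapply(pos, function(p) rate(tr$h == 0, p), numeric(2))
  yes <- vapply(pos, function(p) rate(rep(TRUE, nrow(tr)), p), numeric(2))
  pcor <- vapply(pos, function(p) {
    sel <- cyc == p
    if (any(sel)) mean(tr$d[sel] == tr$h[sel]) else NaN
  }, numeric(1))
  out <- data.frame(position = pos,
                    difficulty = rep(c("easy", "hard"), each = L),
                    p_hit = hit[1, ], n_signal = as.integer(hit[2, ]),
                    p_fa = fa[1, ], n_noise = as.integer(fa[2, ]),
                    p_correct = pcor, p_yes = yes[1, ],
                    n = as.integer(yes[2, ]))
  structure(out, class = c("block_summary", "data.frame"), L = L)
}

#' Fit exponential transition curves with a shared decay constant
#'
#' Fits \deqn{y(n) = y_\infty + (y_0 - y_\infty)\,e^{-B (n - 1)}} (with `n`
#' the 1-based position within a block) jointly to the four per-position
#' curves — hit and false-alarm probability in easy and hard blocks —
#' minimising the summed squared error with a single shared decay constant
#' `B`. The per-curve asymptote and initial value enter linearly, so the fit
#' is a one-dimensional search over `B` with ordinary least squares inside.
#' Curves for the probability of a correct and of a "yes" response are
#' derived from the fitted hit/FA curves (signal probability 0.5). If all
#' curves are flat `B` is reported as 0 with `flat = TRUE`.
#'
#' @param summary a `block_summary` from [wrap_block_positions()]; all `4 L`
#'   hit/FA points must be defined.
#' @param B_max upper bound of the decay-constant search (per trial).
#' @return The summary with attribute `exp_fit`: a list with `B`,
#'   `time_constant` (`1/B` trials), per-curve data frame `curves`
#'   (`difficulty`, `statistic`, `y0`, `y_inf`, `amplitude`), fitted values
#'   `fitted` (per position: hit, fa, correct, yes), `sse`, `flat`.
#' @export
fit_block_exponentials <- function(summary, B_max = 10) {
  stopifnot(inherits(summary, "block_summary"))
  L <- attr(summary, "L")
  ys <- list(easy_hit = summary$p_hit[1:L],
             easy_fa = summary$p_fa[1:L],
             hard_hit = summary$p_hit[L + 1:L],
             hard_fa = summary$p_fa[L + 1:L])
  if (!all(vapply(ys, function(y) all(is.finite(y)), logical(1))))
    stop("all 4L hit/FA positions must be defined")
  nn <- seq_len(L) - 1
  fit_at <- function(B) {
    x <- exp(-B * nn)
    lapply(ys, function(y) {
      if (stats::sd(x) < 1e-8) {        # B ~ 0: regressor collinear with
        co <- c(mean(y), 0)             # the intercept; fit the mean only
      } else {
        co <- stats::coef(stats::lm(y ~ x))
        co[is.na(co)] <- 0
      }
      fitted <- co[1] + co[2] * x
      list(y_inf = unname(co[1]), amp = unname(co[2]), fitted = fitted,
           sse = sum((y - fitted)^2))
    })
  }
  sse_at <- function(B) sum(vapply(fit_at(B), `[[`, numeric(1), "sse"))
  opt <- stats::optimize(sse_at, c(0, B_max), tol = 1e-8)
  B <- opt$minimum
  parts <- fit_at(B)
  flat <- max(abs(vapply(parts, `[[`, numeric(1), "amp"))) < 1e-6
  if (flat) {
    B <- 0
    parts <- fit_at(0)
  }
  curves <- data.frame(
    difficulty = c("easy", "easy", "hard", "hard"),
    statistic = c("hit", "fa", "hit", "fa"),
    y_inf = vapply(parts, `[[`, numeric(1), "y_inf"),
    amplitude = vapply(parts, `[[`, numeric(1), "amp"))
  curves$y0 <- curves$y_inf + curves$amplitude
  hit_fit <- c(parts$easy_hit$fitted, parts$hard_hit$fitted)
  fa_fit <- c(parts$easy_fa$fitted, parts$hard_fa$fitted)
  fitted <- data.frame(position = summary$position, hit = hit_fit,
                       fa = fa_fit,
                       correct = 0.5 * hit_fit + 0.5 * (1 - fa_fit),
                       yes = 0.5 * hit_fit + 0.5 * fa_fit)
  attr(summary, "exp_fit") <- list(
    B = B, time_constant = if (B > 0) 1 / B else Inf, curves = curves,
    fitted = fitted, sse = sum(vapply(parts, `[[`, numeric(1), "sse")),
    flat = flat, at_bound = B > 0.99 * B_max)
  summary
}

#' Decay time constant of a fitted block transition
#'
#' @param x a `block_summary` carrying an `exp_fit` attribute, or a numeric
#'   decay constant `B`.
#' @return The time constant `1/B`, in trials.
#' @export
decay_time_constant <- function(x) {
  B <- if (is.numeric(x)) x else attr(x, "exp_fit")$B
  if (is.null(B)) stop("no exponential fit found")
  1 / B
}

#' ROC markers conditioned on the previous trial's outcome
#'
#' For each difficulty class this computes five (false-alarm, hit) markers:
#' the unconditional rates, and the rates over trials whose immediate
#' predecessor was a hit, miss, false alarm or correct rejection. The first
#' trial of each session lacks a predecessor and is excluded; correction
#' trials are excluded both as conditioned trials and as predecessors. For
#' blocked logs the difficulty class is the block difficulty; for unblocked
#' logs signal trials are classed by level and the false-alarm coordinate
#' (from no-signal trials, which have no level) is shared across classes.
#'
#' @param trials a `trial_log` or list of them.
#' @return A `conditional_roc` data frame: `difficulty`, `condition`
#'   (`"all"` or an outcome), `p_fa`, `p_hit`, `n_noise`, `n_signal`,
#'   ellipse half-widths `ell_fa`, `ell_hit` (95% binomial normal
#'   approximation), and `d_prime` of the unconditional marker (the
#'   equal-variance isosensitivity curve through it is
#'   `p_hit = pnorm(qnorm(p_fa) + d_prime)`).
#' @export
conditional_roc <- function(trials) {
  tr <- pool_trials(trials)
  blocked <- !all(is.na(tr$difficulty))
  cls <- if (blocked) tr$difficulty else ifelse(tr$h == 1,
                                                sprintf("%g", tr$mu_db),
                                                NA_character_)
  # eligibility: same session, consecutive indices, no corrections either side
  ns <- nrow(tr)
  prev_ok <- c(FALSE, tr$session_id[-1] == tr$session_id[-ns] &
                        tr$trial_index[-1] == tr$trial_index[-ns] + 1)
  elig <- prev_ok & !tr$is_correction & c(FALSE, !tr$is_correction[-ns])
  prev_out <- c(NA_character_, tr$outcome[-ns])
  classes <- sort(unique(stats::na.omit(cls)))
  conds <- c("all", OUTCOMES)
  rows <- lapply(classes, function(cl) {
    in_cls_sig <- elig & tr$h == 1 & !is.na(cls) & cls == cl
    in_fa <- elig & tr$h == 0 & (if (blocked) cls == cl else TRUE)
    do.call(rbind, lapply(conds, function(cd) {
      keep <- if (cd == "all") rep(TRUE, ns) else prev_out == cd & !is.na(prev_out)
      sh <- in_cls_sig & keep
      sf <- in_fa & keep
      nh <- sum(sh); nf <- sum(sf)
      ph <- if (nh > 0) mean(tr$d[sh]) else NaN
      pf <- if (nf > 0) mean(tr$d[sf]) else NaN
      data.frame(difficulty = cl, condition = cd, p_fa = pf, p_hit = ph,
                 n_noise = nf, n_signal = nh,
                 ell_fa = if (nf > 0) 1.96 * sqrt(pf * (1 - pf) / nf) else NaN,
                 ell_hit = if (nh > 0) 1.96 * sqrt(ph * (1 - ph) / nh) else NaN)
    }))
  })
  out <- do.call(rbind, rows)
  uncond <- out[out$condition == "all", ]
  dp <- stats::setNames(
    stats::qnorm(pmin(pmax(uncond$p_hit, 1e-12), 1 - 1e-12)) -
      stats::qnorm(pmin(pmax(uncond$p_fa, 1e-12), 1 - 1e-12)),
    uncond$difficulty)
  out$d_prime <- dp[out$difficulty]
  rownames(out) <- NULL
  structure(out, class = c("conditional_roc", "data.frame"))
}
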