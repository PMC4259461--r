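# Parameter estimation: stochastic gradient ascent on the exact likelihood
# with the published annealing schedule, and the coarse/fine brute-force
# grid fit in ROC space used for the decay-free variant.

# transform between natural and unconstrained fitting scales
to_phi <- function(p) c(log(p$sigma), stats::qlogis(min(max(p$a, 1e-8),
                                                        1 - 1e-8)),
                        p$c1, p$b11, p$b01, p$b10, p$b00,
                        stats::qlogis(min(max(p$lam, 1e-8), 1 - 1e-8)))

from_phi <- function(phi, variant, shift_noise_sd = 0) {
  phi <- unname(phi)
  p <- model_params(sigma = exp(phi[1]), a = stats::plogis(phi[2]),
                    c1 = phi[3], b11 = phi[4], b01 = phi[5], b10 = phi[6],
                    b00 = phi[7], lam = stats::plogis(phi[8]),
                    shift_noise_sd = shift_noise_sd, variant = "full")
  constrain_variant(p, variant)
}

# natural-scale gradient -> gradient on the transformed scale
grad_phi <- function(g, p) {
  unname(c(g["sigma"] * p$sigma, g["a"] * p$a * (1 - p$a), g["c1"],
           g["b11"], g["b01"], g["b10"], g["b00"],
           g["lam"] * p$lam * (1 - p$lam)))
}

#' Fit the model by stochastic gradient ascent
#'
#' One ascent step is taken per session, with sessions drawn randomly
#' without replacement (reshuffling once the set is exhausted). The
#' annealing schedule is: 100 iterations at step size `eta = 0.1` with the
#' lapse probability held at 0.05, then 1000 iterations at `eta = 0.01` and
#' 1000 at `eta = 0.001` with the lapse free. Constrained parameters are
#' ascended on transformed scales (log for `sigma`, logit for `a` and
#' `lam`); variant-frozen parameters are not updated. As a numerical
#' safeguard each transformed-scale step component is clipped at magnitude
#' 1. Deterministic given `seed`.
#'
#' @param sessions a `trial_log` or list of them (decisions present).
#' @param variant one of [VARIANTS].
#' @param seed integer seed for the session draws.
#' @param init optional initial [model_params()]; by default shifts start at
#'   zero, `sigma` at half the mean signal level, `a` at 0.5, `c1` at 0 and
#'   `lam` at 0.05.
#' @param schedule data frame with columns `iters`, `eta`, `lam_free`
#'   overriding the default annealing schedule.
#' @param include_corrections passed to the likelihood.
#' @param polish if `TRUE`, finish with a deterministic quasi-Newton ascent
#'   (BFGS on the transformed scale, analytic gradients, all sessions) from
#'   the stochastic endpoint. The original procedure verified convergence
#'   visually; the polish step is this package's numerical stand-in for that
#'   judgement and makes nested-variant likelihood comparisons meaningful.
#' @return An object of class `fit_result`: `variant`, `params`, `loglik`
#'   (over all sessions at the fitted parameters), `trace` (per-iteration
#'   session log-likelihood), `method = "sga"`, `settings`, `seed`.
#' @export
fit_sga <- function(sessions, variant = "full", seed = 1L, init = NULL,
                    schedule = NULL, include_corrections = TRUE,
                    polish = FALSE) {
  variant <- match.arg(variant, VARIANTS)
  if (inherits(sessions, "data.frame")) sessions <- split_sessions(sessions)
  if (length(sessions) < 1) stop("need at least one session")
  if (is.null(schedule))
    schedule <- data.frame(iters = c(100L, 1000L, 1000L),
                           eta = c(0.1, 0.01, 0.001),
                           lam_free = c(FALSE, TRUE, TRUE))
  if (is.null(init)) {
    mus <- unlist(lapply(sessions, function(s) s$mu_db[s$h == 1]))
    init <- model_params(sigma = max(mean(mus) / 2, 0.5), a = 0.5, c1 = 0,
                         lam = 0.05)
  }
  init <- constrain_variant(init, variant)
  frozen_idx <- match(variant_frozen(variant), PARAM_NAMES)
  phi <- to_phi(init)
  trace <- numeric(sum(schedule$iters))
  it <- 0L
  with_seed(seed, {
    order_pool <- integer(0)
    for (ph in seq_len(nrow(schedule))) {
      for (rep_i in seq_len(schedule$iters[ph])) {
        it <- it + 1L
        if (length(order_pool) == 0)
          order_pool <- sample.int(length(sessions))
        s <- sessions[[order_pool[1]]]
        order_pool <- order_pool[-1]
        p <- from_phi(phi, variant)
        trace[it] <- as.numeric(
          log_likelihood(s, p, include_corrections))
        if (!is.finite(trace[it]))
          stop("log-likelihood diverged at iteration ", it,
               " (see trace up to this point)")
        g <- grad_phi(ll_gradient(s, p, include_corrections), p)
        step <- schedule$eta[ph] * g
        step <- pmin(pmax(step, -1), 1)
        if (length(frozen_idx)) step[frozen_idx] <- 0
        if (!schedule$lam_free[ph]) step[8] <- 0
        phi <- phi + step
      }
    }
  })
  pooled <- pool_trials(sessions)
  params_sga <- from_phi(phi, variant)
  loglik_sga <- as.numeric(log_likelihood(pooled, params_sga,
                                          include_corrections))
  if (polish) {
    free <- setdiff(seq_along(PARAM_NAMES), frozen_idx)
    obj <- function(phi_free) {
      phi[free] <- phi_free
      -as.numeric(log_likelihood(pooled, from_phi(phi, variant),
                                 include_corrections))
    }
    grd <- function(phi_free) {
      phi[free] <- phi_free
      p <- from_phi(phi, variant)
      -grad_phi(ll_gradient(pooled, p, include_corrections), p)[free]
    }
    opt <- stats::optim(phi[free], obj, grd, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    phi[free] <- opt$par
  }
  params <- from_phi(phi, variant)
  ll <- as.numeric(log_likelihood(pooled, params, include_corrections))
  structure(list(variant = variant, params = params, loglik = ll,
                 params_sga = params_sga, loglik_sga = loglik_sga,
                 trace = trace, method = "sga",
                 settings = list(schedule = schedule, init = init,
                                 include_corrections = include_corrections,
                                 polish = polish),
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> variant: %s, method: %s\n", x$variant, x$method))
  if (!is.null(x$loglik)) cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  if (!is.null(x$distance))
    cat(sprintf("  ROC distance: %.4f (%d candidates evaluated)\n",
                x$distance, x$n_evaluated))
  print(x$params)
  invisible(x)
}

#' Specification of the brute-force parameter grid
#'
#' The coarse pass divides each shift range and the sigma range into
#' `*_points` cells and evaluates the cell centres — `6^5 = 7776`
#' combinations at the defaults. Refinement subdivides the best cell of
#' each parameter into `refine_factor` sub-cells, so the default fine-grid
#' granularity is `20/36 ~ 0.56` dB for shifts and `9/36 = 0.25` dB for
#' sigma.
#'
#' @param shift_range,shift_points range and cell count for each `b_ij`.
#' @param sigma_range,sigma_points range and cell count for `sigma`.
#' @param refine_levels number of refinement passes.
#' @param refine_factor sub-cells per parameter per refinement.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shift_range = c(-10, 10), shift_points = 6L,
                      sigma_range = c(3, 12), sigma_points = 6L,
                      refine_levels = 1L, refine_factor = 6L) {
  if (shift_points < 2 || sigma_points < 2) stop("need at least 2 points")
  if (diff(shift_range) <= 0 || diff(sigma_range) <= 0)
    stop("ranges must be ordered")
  structure(list(shift_range = shift_range,
                 shift_points = as.integer(shift_points),
                 sigma_range = sigma_range,
                 sigma_points = as.integer(sigma_points),
                 refine_levels = as.integer(refine_levels),
                 refine_factor = as.integer(refine_factor)),
            class = "grid_spec")
}

# centres of `points` equal cells over `range`
cell_centers <- function(range, points) {
  w <- diff(range) / points
  range[1] + (seq_len(points) - 0.5) * w
}

#' Enumerate the candidates of the coarse grid pass
#'
#' @param spec a [grid_spec()].
#' @return Data frame with columns `b11`, `b01`, `b10`, `b00`, `sigma`; one
#'   row per candidate, in the row-major enumeration order used to break
#'   ties (first encountered wins).
#' @export
grid_candidates <- function(spec) {
  b <- cell_centers(spec$shift_range, spec$shift_points)
  s <- cell_centers(spec$sigma_range, spec$sigma_points)
  expand.grid(b11 = b, b01 = b, b10 = b, b00 = b, sigma = s,
              KEEP.OUT.ATTRS = FALSE)
}

#' Grid spacing after refinement
#'
#' @param spec a [grid_spec()].
#' @return Named vector with the fine-pass spacing of `shift` and `sigma`
#'   (one refinement level).
#' @export
grid_fine_spacing <- function(spec) {
  c(shift = diff(spec$shift_range) / spec$shift_points / spec$refine_factor,
    sigma = diff(spec$sigma_range) / spec$sigma_points / spec$refine_factor)
}

# conditional-ROC prediction for one no-decay candidate under the blocked
# design; returns the 8 conditioned markers keyed difficulty:condition
predict_roc_markers <- function(cand, easy_levels, hard_levels, L, lam,
                                p_signal = 0.5, step_div = 10,
                                max_leakage = 0.05) {
  params <- model_params(sigma = cand$sigma, a = 0, c1 = 0,
                         b11 = cand$b11, b01 = cand$b01, b10 = cand$b10,
                         b00 = cand$b00, lam = lam, variant = "no_decay")
  grid <- default_grid(params, step_div = step_div)
  ke <- build_kernel(params, stimulus_context(easy_levels, p_signal, "easy"),
                     grid, max_leakage = max_leakage)
  kh <- build_kernel(params, stimulus_context(hard_levels, p_signal, "hard"),
                     grid, max_leakage = max_leakage)
  sol <- blocked_stationary(ke, kh, L = L, tol = 1e-10)
  roc <- predicted_summaries(sol)$roc
  roc[roc$condition != "all", ]
}

# mean Euclidean distance between matched conditioned markers
roc_marker_distance <- function(emp, mod) {
  key <- paste(emp$difficulty, emp$condition)
  mkey <- paste(mod$difficulty, mod$condition)
  idx <- match(key, mkey)
  if (any(is.na(idx))) stop("model markers do not cover empirical markers")
  mean(sqrt((emp$p_fa - mod$p_fa[idx])^2 + (emp$p_hit - mod$p_hit[idx])^2))
}

#' Brute-force grid fit of the no-decay model in ROC space
#'
#' Evaluates every candidate of the coarse grid — all combinations of the
#' shift values and sigma values, `6^5 = 7776` at the default
#' [grid_spec()] — by the mean Euclidean distance in linear ROC space
#' between the eight empirical previous-outcome-conditioned markers (two
#' difficulties times four outcomes) and the Markov-model predictions, then
#' refines by subdividing the best cell of each parameter. Candidates whose
#' kernel escapes the solver grid or fails to converge score `Inf`. Ties
#' are broken by enumeration order (first encountered).
#'
#' @param emp_roc a [conditional_roc()] of the blocked data (difficulties
#'   `"easy"`/`"hard"`); the eight conditioned markers must be defined.
#' @param easy_levels,hard_levels the block level sets, dB.
#' @param L block length.
#' @param spec a [grid_spec()].
#' @param lam lapse probability held fixed during the grid fit.
#' @param p_signal signal probability.
#' @param step_div solver grid resolution (`sigma / step_div`).
#' @return A `fit_result` with `method = "grid"`, the winning `params`,
#'   `distance`, `n_evaluated` (per pass), `distances` (coarse-pass vector)
#'   and the `spec`.
#' @export
fit_grid <- function(emp_roc, easy_levels, hard_levels, L = 8L,
                     spec = grid_spec(), lam = 0.05, p_signal = 0.5,
                     step_div = 10) {
  emp <- emp_roc[emp_roc$condition != "all", ]
  if (any(!is.finite(emp$p_fa)) || any(!is.finite(emp$p_hit)))
    stop("empirical conditioned markers must all be defined")
  score <- function(cand) {
    tryCatch(roc_marker_distance(
      emp, predict_roc_markers(cand, easy_levels, hard_levels, L, lam,
                               p_signal, step_div)),
      error = function(e) Inf)
  }
  run_pass <- function(cands) {
    d <- vapply(seq_len(nrow(cands)), function(i) score(cands[i, ]),
                numeric(1))
    list(cands = cands, d = d, best = cands[which.min(d), ],
         dmin = min(d))
  }
  coarse <- run_pass(grid_candidates(spec))
  best <- coarse$best
  dmin <- coarse$dmin
  n_eval <- nrow(coarse$cands)
  w_shift <- diff(spec$shift_range) / spec$shift_points
  w_sigma <- diff(spec$sigma_range) / spec$sigma_points
  for (lev in seq_len(spec$refine_levels)) {
    sub <- function(center, w) cell_centers(center + c(-w, w) / 2,
                                            spec$refine_factor)
    cands <- expand.grid(b11 = sub(best$b11, w_shift),
                         b01 = sub(best$b01, w_shift),
                         b10 = sub(best$b10, w_shift),
                         b00 = sub(best$b00, w_shift),
                         sigma = sub(best$sigma, w_sigma),
                         KEEP.OUT.ATTRS = FALSE)
    fine <- run_pass(cands)
    n_eval <- c(n_eval, nrow(cands))
    if (fine$dmin < dmin) {
      best <- fine$best
      dmin <- fine$dmin
    }
    w_shift <- w_shift / spec$refine_factor
    w_sigma <- w_sigma / spec$refine_factor
  }
  params <- model_params(sigma = best$sigma, a = 0, c1 = 0,
                         b11 = best$b11, b01 = best$b01, b10 = best$b10,
                         b00 = best$b00, lam = lam, variant = "no_decay")
  structure(list(variant = "no_decay", params = params, distance = dmin,
                 distances = coarse$d, n_evaluated = n_eval,
                 method = "grid", settings = list(spec = spec, lam = lam),
                 seed = NULL),
            class = "fit_result")
}
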