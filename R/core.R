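# Elementary model computations: yes-probability, outcome classification,
# criterion update. Everything else in the package is built on these.

#' Probability of a "yes" response
#'
#' On a non-lapse trial the observer responds "yes" when the noisy internal
#' variable, normal with mean `mu` and standard deviation `sigma`, exceeds
#' the criterion `c`. Lapses (probability `lam`) respond by an unbiased coin.
#' Hence
#' \deqn{P(\mathrm{yes}) = \lambda/2 + (1-\lambda)\,\Phi((\mu - c)/\sigma).}
#'
#' @param c criterion, dB (vectorised).
#' @param mu signal level in dB above the reference (0 on no-signal trials;
#'   vectorised).
#' @param params a [model_params()] object.
#' @return Probability of responding yes, in `[lam/2, 1 - lam/2]`.
#' @export
response_probability <- function(c, mu, params) {
  validate_params(params)
  if (!all(is.finite(c)) || !all(is.finite(mu)))
    stop("criterion and level must be finite")
  params$lam / 2 +
    (1 - params$lam) * stats::pnorm((mu - c) / params$sigma)
}

#' Classify the joint trial outcome
#'
#' Maps signal presence `h` and decision `d` (both 0/1) to one of the four
#' outcome labels: (1,1) hit, (1,0) miss, (0,1) false alarm, (0,0) correct
#' rejection.
#'
#' @param h signal indicator, 0 or 1 (vectorised).
#' @param d decision indicator, 0 or 1 (vectorised).
#' @return Character vector of [OUTCOMES] labels.
#' @export
classify_outcome <- function(h, d) {
  if (!all(h %in% c(0, 1)) || !all(d %in% c(0, 1)))
    stop("h and d must be 0 or 1")
  out <- ifelse(h == 1,
                ifelse(d == 1, "hit", "miss"),
                ifelse(d == 1, "false_alarm", "correct_rejection"))
  out
}

#' Update the decision criterion after a trial
#'
#' The criterion decays a fraction `a` of the way toward the resting value
#' `c1` and is shifted by the amount associated with the trial's outcome:
#' \deqn{c_{n+1} = c_n + a\,(c_1 - c_n) + b_{\mathrm{outcome}} + \epsilon,}
#' where \eqn{\epsilon} is optional zero-mean Gaussian jitter. With `a = 1`
#' the result is `c1 + b + noise` exactly (no memory of `c_n`); with `a = 0`
#' shifts accumulate additively.
#'
#' @param c_n current criterion, dB.
#' @param outcome one of [OUTCOMES].
#' @param params a [model_params()] object.
#' @param noise_draw optional explicit noise value, dB. If `NULL` (default) a
#'   draw from `N(0, shift_noise_sd)` is taken when `shift_noise_sd > 0`, else
#'   zero.
#' @return The next criterion value, dB.
#' @export
update_criterion <- function(c_n, outcome, params, noise_draw = NULL) {
  validate_params(params)
  if (!is.finite(c_n)) stop("criterion must be finite")
  outcome <- match.arg(outcome, OUTCOMES)
  if (is.null(noise_draw)) {
    noise_draw <- if (params$shift_noise_sd > 0)
      stats::rnorm(1, 0, params$shift_noise_sd) else 0
  }
  c_n + params$a * (params$c1 - c_n) +
    shift_vector(params)[[outcome]] + noise_draw
}
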