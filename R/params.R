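#' Trial outcome labels
#'
#' The four joint outcomes of signal presence and decision in a yes-no task,
#' in the canonical order used throughout the package.
#'
#' @format Character vector of length four:
#'   `"hit"`, `"miss"`, `"false_alarm"`, `"correct_rejection"`.
#' @export
OUTCOMES <- c("hit", "miss", "false_alarm", "correct_rejection")

# names of the shift parameter paired with each outcome, same order
.SHIFT_NAMES <- c("b11", "b01", "b10", "b00")

#' Model variants
#'
#' Named reduced forms of the dynamic-criterion model, obtained by freezing
#' parameters: `no_shift` (all shifts zero: a static criterion), `no_decay`
#' (decay rate `a = 0`: purely additive shifts, `c1` is only the initial
#' criterion), `no_memory` (`a = 1`: the criterion is fully reset each trial
#' to `c1` plus the shift for the previous outcome), and `full`.
#'
#' @format Character vector of the four variant names.
#' @export
VARIANTS <- c("full", "no_shift", "no_decay", "no_memory")

#' Construct a dynamic-criterion parameter set
#'
#' The model is governed by eight parameters: the internal noise standard
#' deviation `sigma`; the criterion decay rate `a` toward the resting
#' criterion `c1`; four signed criterion shifts `b11`, `b01`, `b10`, `b00`
#' applied after a hit, miss, false alarm and correct rejection respectively;
#' and the lapse probability `lam`. All criterion-scale quantities (`sigma`,
#' `c1`, shifts) are in dB above the reference level at which detection is at
#' chance. An optional zero-mean Gaussian jitter with standard deviation
#' `shift_noise_sd` can be added to every criterion update (used in the
#' stationary-distribution exemplars; keep it 0 for fitting).
#'
#' @param sigma internal noise standard deviation, dB; must be > 0.
#' @param a decay rate in `[0, 1]`; `a = 1` erases all criterion memory,
#'   `a = 0` makes shifts purely additive.
#' @param c1 resting (and initial) criterion, dB.
#' @param b11,b01,b10,b00 criterion shifts after hit / miss / false alarm /
#'   correct rejection, dB (signed).
#' @param lam lapse probability in `[0, 1]`.
#' @param shift_noise_sd standard deviation of Gaussian noise added to each
#'   criterion update, dB; default 0.
#' @param variant one of [VARIANTS]; stored as a tag and *not* enforced here
#'   (see [constrain_variant()]).
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(sigma = 1, a = 0, c1 = 0, b01 = -1, b10 = 1)
#' response_probability(0.5, 1, p)
#' @export
model_params <- function(sigma, a = 0, c1 = 0,
                         b11 = 0, b01 = 0, b10 = 0, b00 = 0,
                         lam = 0, shift_noise_sd = 0, variant = "full") {
  p <- list(sigma = sigma, a = a, c1 = c1,
            b11 = b11, b01 = b01, b10 = b10, b00 = b00,
            lam = lam, shift_noise_sd = shift_noise_sd,
            variant = match.arg(variant, VARIANTS))
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' @param p a `model_params` object.
#' @return `p`, invisibly; errors if any invariant fails.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  num <- unlist(p[c("sigma", "a", "c1", .SHIFT_NAMES, "lam", "shift_noise_sd")])
  if (!all(is.finite(num)))
    stop("all model parameters must be finite numbers")
  if (p$sigma <= 0) stop("sigma must be > 0")
  if (p$a < 0 || p$a > 1) stop("a must lie in [0, 1]")
  if (p$lam < 0 || p$lam > 1) stop("lam must lie in [0, 1]")
  if (p$shift_noise_sd < 0) stop("shift_noise_sd must be >= 0")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> variant: %s\n", x$variant))
  cat(sprintf("  sigma = %.4g  a = %.4g  c1 = %.4g  lam = %.4g\n",
              x$sigma, x$a, x$c1, x$lam))
  cat(sprintf("  shifts (hit, miss, FA, CR): %.4g, %.4g, %.4g, %.4g\n",
              x$b11, x$b01, x$b10, x$b00))
  if (x$shift_noise_sd > 0)
    cat(sprintf("  shift noise sd = %.4g\n", x$shift_noise_sd))
  invisible(x)
}

#' Shift vector in canonical outcome order
#'
#' @param p a `model_params` object.
#' @return Numeric vector `c(b11, b01, b10, b00)`, named by [OUTCOMES].
#' @export
shift_vector <- function(p) {
  b <- c(p$b11, p$b01, p$b10, p$b00)
  names(b) <- OUTCOMES
  b
}

#' Apply a model-variant constraint to a parameter set
#'
#' Returns a copy of `p` with the parameters frozen by the named variant set
#' to their constrained values: `no_shift` zeroes all four shifts, `no_decay`
#' sets `a = 0`, `no_memory` sets `a = 1`. Idempotent; `full` is a no-op.
#'
#' @param p a `model_params` object.
#' @param variant one of [VARIANTS].
#' @return A `model_params` object tagged with `variant`.
#' @export
constrain_variant <- function(p, variant) {
  variant <- match.arg(variant, VARIANTS)
  q <- p
  if (variant == "no_shift") q[.SHIFT_NAMES] <- list(0, 0, 0, 0)
  if (variant == "no_decay") q$a <- 0
  if (variant == "no_memory") q$a <- 1
  q$variant <- variant
  validate_params(q)
}

#' Names of parameters a variant holds fixed
#'
#' @param variant one of [VARIANTS].
#' @return Character vector of frozen parameter names (possibly empty).
#' @export
variant_frozen <- function(variant) {
  switch(match.arg(variant, VARIANTS),
         full = character(0),
         no_shift = .SHIFT_NAMES,
         no_decay = "a",
         no_memory = "a")
}

#' Serialise / deserialise parameter sets as JSON
#'
#' Parameter sets serialise to a flat JSON object carrying the eight model
#' parameters, `shift_noise_sd` and the variant tag.
#'
#' @param p a `model_params` object.
#' @param path file path; for `params_from_json` either a path or a JSON
#'   string.
#' @return `params_to_json` returns the path invisibly; `params_from_json`
#'   returns a `model_params` object.
#' @export
params_to_json <- function(p, path) {
  validate_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(model_params, x[c("sigma", "a", "c1", .SHIFT_NAMES,
                            "lam", "shift_noise_sd", "variant")])
}
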