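# Semi-analytical engine: discretise the criterion axis, build the
# outcome-driven transition kernel, solve for stationary criterion
# distributions (including the composed kernel for alternating blocks), and
# derive predicted summary statistics from them.

#' A uniform grid over the criterion axis
#'
#' @param lo,hi axis bounds, dB.
#' @param step grid spacing, dB.
#' @return An object of class `criterion_grid` with `centers`, `lo`, `hi`,
#'   `step`, `n`.
#' @export
criterion_grid <- function(lo, hi, step) {
  if (!(lo < hi) || step <= 0) stop("need lo < hi and step > 0")
  n <- floor((hi - lo) / step + 1e-9) + 1
  structure(list(lo = lo, hi = lo + (n - 1) * step, step = step, n = n,
                 centers = lo + step * (seq_len(n) - 1)),
            class = "criterion_grid")
}

#' Default criterion grid for a parameter set
#'
#' Spans `c1 +/- 8 sigma`, extended to cover every post-shift point
#' `c1 + b_ij +/- 4 sigma`, with spacing `sigma / 40`. This covers the
#' criterion mass reachable under geometric decay while keeping kernels
#' below roughly 2000 x 2000.
#'
#' @param params a [model_params()] object.
#' @param step_div grid step is `sigma / step_div`.
#' @return A [criterion_grid()].
#' @export
default_grid <- function(params, step_div = 40) {
  b <- shift_vector(params)
  lo <- min(params$c1 - 8 * params$sigma, params$c1 + b - 4 * params$sigma)
  hi <- max(params$c1 + 8 * params$sigma, params$c1 + b + 4 * params$sigma)
  step <- params$sigma / step_div
  # keep c1 exactly on the grid so degenerate (shift-free) chains resolve
  lo <- params$c1 - ceiling((params$c1 - lo) / step) * step
  criterion_grid(lo, hi, step)
}

#' Stimulus statistics governing a transition kernel
#'
#' @param levels signal levels, dB above reference (uniform mixture on
#'   signal trials).
#' @param p_signal probability of a signal trial.
#' @param label optional context label (e.g. `"easy"`).
#' @return An object of class `stimulus_context`.
#' @export
stimulus_context <- function(levels, p_signal = 0.5, label = NULL) {
  if (length(levels) < 1 || any(levels < 0)) stop("levels must be >= 0")
  if (p_signal < 0 || p_signal > 1) stop("p_signal must lie in [0, 1]")
  structure(list(levels = as.numeric(levels), p_signal = p_signal,
                 label = label), class = "stimulus_context")
}

# outcome probabilities at each criterion value (rows: grid, cols: OUTCOMES)
outcome_probabilities <- function(centers, params, context) {
  py_sig <- rowMeans(vapply(context$levels, function(mu)
    response_probability(centers, mu, params), numeric(length(centers))))
  py_noise <- response_probability(centers, 0, params)
  ps <- context$p_signal
  cbind(hit = ps * py_sig, miss = ps * (1 - py_sig),
        false_alarm = (1 - ps) * py_noise,
        correct_rejection = (1 - ps) * (1 - py_noise))
}

# triplets depositing unit mass from each source j at destination dest[j],
# by linear interpolation (shift_noise_sd == 0) or by Gaussian cell masses.
deposit_triplets <- function(dest, grid, noise_sd) {
  n <- grid$n
  j <- seq_len(n)
  if (noise_sd <= 0) {
    idx <- (dest - grid$lo) / grid$step  # 0-based fractional cell
    i0 <- floor(idx + 1e-12)
    w1 <- idx - i0
    tri <- rbind(data.frame(i = i0, j = j, x = 1 - w1),
                 data.frame(i = i0 + 1, j = j, x = w1))
  } else {
    # Gaussian jitter around an on-grid destination: cell masses from the
    # normal CDF, with out-of-range tails absorbed into the boundary cells
    # (the boundary is absorbing; only shift-driven escapes count as
    # leakage, and a destination itself off the grid is dropped entirely)
    w <- max(1L, ceiling(6 * noise_sd / grid$step))
    near <- round((dest - grid$lo) / grid$step)
    on_grid <- dest >= grid$lo - 1e-12 & dest <= grid$hi + 1e-12
    tri <- do.call(rbind, lapply(-w:w, function(o) {
      i <- near + o
      edge_lo <- grid$lo + (i - 0.5) * grid$step
      edge_hi <- edge_lo + grid$step
      lo_cdf <- ifelse(i <= 0, 0, stats::pnorm(edge_lo, dest, noise_sd))
      hi_cdf <- ifelse(i >= n - 1, 1, stats::pnorm(edge_hi, dest, noise_sd))
      data.frame(i = pmin(pmax(i, 0), n - 1), j = j,
                 x = (hi_cdf - lo_cdf) * on_grid)
    }))
  }
  tri[tri$x > 0 & tri$i >= 0 & tri$i <= n - 1, ]
}

#' Build the criterion transition kernel
#'
#' Constructs the column-stochastic kernel `M` on a criterion grid: from
#' each source criterion the four outcome probabilities are computed from
#' the stimulus mixture and [response_probability()]; each outcome maps to
#' the deterministic destination `c + a (c1 - c) + b_ij`, deposited with
#' two-point linear interpolation (so off-grid shifts stay unbiased in
#' mean), convolved with the shift noise when `shift_noise_sd > 0`. Columns
#' are truncated at the grid boundary and renormalised; if any column loses
#' more than `max_leakage` of its mass before renormalisation the
#' configuration is deemed to escape the grid and an error is raised (this
#' is how unstable configurations, e.g. ones reinforcing correct decisions,
#' typically announce themselves).
#'
#' @param params a [model_params()] object.
#' @param context a [stimulus_context()].
#' @param grid a [criterion_grid()]; default [default_grid()].
#' @param max_leakage maximum tolerated per-column pre-renormalisation loss.
#' @return An object of class `transition_kernel`: `grid`, `M` (sparse,
#'   column-stochastic), `branches` (one sparse matrix per outcome, summing
#'   to `M` before renormalisation scaling), `params`, `context`,
#'   `max_col_leakage`.
#' @export
build_kernel <- function(params, context, grid = default_grid(params),
                         max_leakage = 0.01) {
  validate_params(params)
  centers <- grid$centers
  n <- grid$n
  probs <- outcome_probabilities(centers, params, context)
  b <- shift_vector(params)
  branches <- lapply(seq_along(OUTCOMES), function(k) {
    dest <- centers + params$a * (params$c1 - centers) + b[k]
    tri <- deposit_triplets(dest, grid, params$shift_noise_sd)
    tri$x <- tri$x * probs[tri$j, k]
    Matrix::sparseMatrix(i = tri$i + 1, j = tri$j, x = tri$x,
                         dims = c(n, n))
  })
  M <- Reduce(`+`, branches)
  colsum <- Matrix::colSums(M)
  leak <- 1 - colsum
  if (max(leak) > max_leakage)
    stop(sprintf(paste0("criterion mass escapes the grid (max column ",
                        "leakage %.3g > %.3g); enlarge the grid or expect ",
                        "an unstable configuration"),
                 max(leak), max_leakage))
  scale <- Matrix::Diagonal(x = 1 / colsum)
  branches <- lapply(branches, function(B) B %*% scale)
  structure(list(grid = grid, M = M %*% scale, branches = branches,
                 params = params, context = context,
                 max_col_leakage = max(leak)),
            class = "transition_kernel")
}

#' Stationary criterion distribution of a kernel
#'
#' Solves `f = M f` by power iteration from a uniform start. Deterministic;
#' errors if the iteration does not reach the stationarity tolerance within
#' the cap (a symptom of an unstable configuration).
#'
#' @param kernel a [build_kernel()] result.
#' @param tol L1 step-change tolerance.
#' @param max_iter iteration cap.
#' @param label optional label stored on the result.
#' @return An object of class `criterion_distribution`: `grid`, `mass`
#'   (sums to 1), `label`, `residual` (`||M f - f||_1`), `iterations`.
#' @export
stationary_distribution <- function(kernel, tol = 1e-12, max_iter = 1e5,
                                    label = NULL) {
  M <- kernel$M
  f <- rep(1 / kernel$grid$n, kernel$grid$n)
  for (it in seq_len(max_iter)) {
    f_new <- as.numeric(M %*% f)
    f_new <- f_new / sum(f_new)
    delta <- sum(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  residual <- sum(abs(as.numeric(M %*% f) - f))
  if (residual >= 1e-9)
    stop(sprintf(paste0("power iteration did not reach stationarity ",
                        "(residual %.3g after %d iterations); the ",
                        "configuration may be unstable"), residual, it))
  structure(list(grid = kernel$grid, mass = f, label = label,
                 residual = residual, iterations = it),
            class = "criterion_distribution")
}

#' Mean and standard deviation of a criterion distribution
#'
#' @param dist a `criterion_distribution`.
#' @return Named vector with `mean` and `sd`, dB.
#' @export
distribution_moments <- function(dist) {
  m <- sum(dist$grid$centers * dist$mass)
  v <- sum((dist$grid$centers - m)^2 * dist$mass)
  c(mean = m, sd = sqrt(v))
}

#' Per-position criterion distributions for a repeating block cycle
#'
#' For sessions whose stimulus statistics repeat over a cycle of blocks
#' (easy, hard, easy, ... in the alternating paradigm), the criterion at the
#' first trial of the cycle is the fixed point of the composed kernel
#' `M_last^L_last ... M_first^L_first`; the remaining `sum(L) - 1` positions
#' follow by applying the position-appropriate kernel. Any repeating cycle
#' of kernels is supported (e.g. an ascending/descending level sweep).
#'
#' @param kernels either a list of [build_kernel()] objects sharing one
#'   grid, or a single kernel (paired with `kernel_hard`).
#' @param kernel_hard optional second kernel for the common two-block case.
#' @param L trials per block: one integer (shared) or one per kernel.
#' @param tol L1 tolerance on the cycle fixed point.
#' @param max_cycles cycle-iteration cap.
#' @return An object of class `blocked_solution`: `grid`, `dists` (list of
#'   mass vectors, one per cycle position), `kernels`, `kernel_index`
#'   (which kernel governs each position's context), `positions`.
#' @export
blocked_stationary <- function(kernels, kernel_hard = NULL, L = 8L,
                               tol = 1e-12, max_cycles = 1e4) {
  if (inherits(kernels, "transition_kernel"))
    kernels <- if (is.null(kernel_hard)) list(kernels)
               else list(kernels, kernel_hard)
  L <- rep_len(as.integer(L), length(kernels))
  grid <- kernels[[1]]$grid
  for (k in kernels)
    if (!identical(k$grid$centers, grid$centers))
      stop("all kernels must share one grid")
  kernel_index <- rep(seq_along(kernels), times = L)
  P <- sum(L)
  cycle <- function(f) {
    for (idx in kernel_index) {
      f <- as.numeric(kernels[[idx]]$M %*% f)
      f <- f / sum(f)
    }
    f
  }
  f <- rep(1 / grid$n, grid$n)
  for (it in seq_len(max_cycles)) {
    f_new <- cycle(f)
    delta <- sum(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= 1e-9)
    stop(sprintf("block cycle did not reach its fixed point (L1 change %.3g)",
                 delta))
  dists <- vector("list", P)
  dists[[1]] <- f
  for (p in seq_len(P - 1)) {
    f <- as.numeric(kernels[[kernel_index[p]]]$M %*% f)
    f <- f / sum(f)
    dists[[p + 1]] <- f
  }
  structure(list(grid = grid, dists = dists, kernels = kernels,
                 kernel_index = kernel_index, positions = seq_len(P)),
            class = "blocked_solution")
}

# expected yes-probabilities under a criterion mass vector
expected_rates <- function(mass, kernel) {
  centers <- kernel$grid$centers
  params <- kernel$params
  py_sig <- rowMeans(vapply(kernel$context$levels, function(mu)
    response_probability(centers, mu, params), numeric(length(centers))))
  py_noise <- response_probability(centers, 0, params)
  c(p_hit = sum(mass * py_sig), p_fa = sum(mass * py_noise))
}

#' Model-predicted summary statistics from criterion distributions
#'
#' Computes, from a stationary solution, the same tables the empirical
#' analyses produce: per-position hit/false-alarm probabilities (the
#' expectation of [response_probability()] over the criterion distribution)
#' and ROC markers conditioned on the previous trial's outcome, derived from
#' the stationary joint law of (outcome at `n`, criterion at `n + 1`).
#'
#' @param solution a [blocked_stationary()] result, or a single
#'   `criterion_distribution` (then `kernel` must be given).
#' @param kernel the kernel matching a single stationary distribution.
#' @return A list with `block` (a `block_summary`-schema data frame; `NA`
#'   counts) and `roc` (a `conditional_roc`-schema data frame).
#' @export
predicted_summaries <- function(solution, kernel = NULL) {
  if (inherits(solution, "criterion_distribution")) {
    if (is.null(kernel)) stop("a kernel is required with a plain distribution")
    solution <- list(grid = solution$grid, dists = list(solution$mass),
                     kernels = list(kernel), kernel_index = 1L,
                     positions = 1L)
    class(solution) <- "blocked_solution"
  }
  ki <- solution$kernel_index
  P <- length(solution$positions)
  rates <- t(vapply(seq_len(P), function(p)
    expected_rates(solution$dists[[p]], solution$kernels[[ki[p]]]),
    numeric(2)))
  labels <- vapply(seq_along(solution$kernels), function(i)
    solution$kernels[[i]]$context$label %||% sprintf("context%d", i),
    character(1))
  ps <- solution$kernels[[1]]$context$p_signal
  block <- data.frame(position = seq_len(P), difficulty = labels[ki],
                      p_hit = rates[, 1], n_signal = NA_integer_,
                      p_fa = rates[, 2], n_noise = NA_integer_,
                      p_correct = ps * rates[, 1] + (1 - ps) * (1 - rates[, 2]),
                      p_yes = ps * rates[, 1] + (1 - ps) * rates[, 2],
                      n = NA_integer_)
  class(block) <- c("block_summary", "data.frame")
  attr(block, "L") <- P / max(1L, length(solution$kernels))
  # conditional markers: joint law of (outcome at n, criterion at n+1),
  # positions weighted equally around the cycle
  acc <- list()
  for (lab in unique(labels)) acc[[lab]] <- list(
    joint = replicate(4, numeric(solution$grid$n), simplify = FALSE),
    uncond = numeric(solution$grid$n), n_pos = 0)
  for (p in seq_len(P)) {
    nxt <- if (p == P) 1L else p + 1L
    lab <- labels[ki[nxt]]
    acc[[lab]]$uncond <- acc[[lab]]$uncond + solution$dists[[nxt]]
    acc[[lab]]$n_pos <- acc[[lab]]$n_pos + 1
    Bs <- solution$kernels[[ki[p]]]$branches
    for (k in 1:4)
      acc[[lab]]$joint[[k]] <- acc[[lab]]$joint[[k]] +
        as.numeric(Bs[[k]] %*% solution$dists[[p]])
  }
  rows <- list()
  for (lab in names(acc)) {
    a <- acc[[lab]]
    kern <- solution$kernels[[match(lab, labels)]]
    un <- expected_rates(a$uncond / a$n_pos, kern)
    rows[[length(rows) + 1]] <- data.frame(
      difficulty = lab, condition = "all", p_fa = un[["p_fa"]],
      p_hit = un[["p_hit"]], weight = 1)
    for (k in 1:4) {
      mass <- a$joint[[k]]
      w <- sum(mass)
      r <- if (w > 0) expected_rates(mass / w, kern) else c(NaN, NaN)
      rows[[length(rows) + 1]] <- data.frame(
        difficulty = lab, condition = OUTCOMES[k], p_fa = r[["p_fa"]],
        p_hit = r[["p_hit"]], weight = w / a$n_pos)
    }
  }
  roc <- do.call(rbind, rows)
  rownames(roc) <- NULL
  class(roc) <- c("conditional_roc", "data.frame")
  list(block = block, roc = roc)
}

#' Total-variation distance between a simulated trace and a stationary law
#'
#' Bins a simulated criterion trace and the analytic stationary distribution
#' on a common histogram and returns half the L1 distance between the two
#' probability vectors. The default bin width of 1 dB matches the scale of
#' the criterion steps in the exemplar configurations; with additive
#' (decay-free) shift rules and small shift noise, the criterion's position
#' modulo the shift lattice mixes on the slow time scale
#' `~ 1 / shift_noise_sd^2` trials, so sub-step bins would measure that
#' sampling mode rather than solver accuracy (see the package vignette).
#' Trace values beyond the grid are clamped to its ends.
#'
#' @param trace numeric vector of simulated criterion values (burn-in
#'   already removed).
#' @param dist a `criterion_distribution`.
#' @param bin_width histogram bin width, dB.
#' @return The total-variation distance, in `[0, 1]`.
#' @export
tv_distance <- function(trace, dist, bin_width = 1) {
  g <- dist$grid
  breaks <- seq(g$lo - g$step / 2, g$hi + g$step / 2 + bin_width,
                by = bin_width)
  hs <- graphics::hist(pmin(pmax(trace, g$lo), g$hi),
                       breaks = c(-Inf, breaks, Inf), plot = FALSE)$counts
  hs <- hs / sum(hs)
  bin_of <- findInterval(g$centers, breaks) + 1
  an <- tapply(dist$mass, factor(bin_of, levels = seq_along(hs)), sum)
  an[is.na(an)] <- 0
  0.5 * sum(abs(hs - an))
}

#' Exemplar parameter configurations for the stationary-distribution gallery
#'
#' The five identically-distributed-trial exemplars used to illustrate the
#' Markov solution (unit internal noise, signal probability 0.5, shift
#' noise 0.01): (i) unit shifts opposing errors; (ii) unit shifts opposing
#' correct decisions; (iii) error-driven shifts larger for misses;
#' (iv) decay toward a resting criterion of 1 with larger shifts for false
#' alarms; (v) as (i) with a two-level signal mixture.
#'
#' @param panel one of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"v"`.
#' @return A list with `params` ([model_params()]) and `context`
#'   ([stimulus_context()]).
#' @export
exemplar_config <- function(panel = c("i", "ii", "iii", "iv", "v")) {
  panel <- match.arg(panel)
  base <- list(sigma = 1, a = 0, c1 = 0.5, shift_noise_sd = 0.01)
  spec <- switch(panel,
    i = list(b01 = -1, b10 = 1, mu = 1),
    ii = list(b00 = -1, b11 = 1, mu = 1),
    iii = list(b01 = -2, b10 = 1, mu = 1),
    iv = list(b01 = -1, b10 = 2, a = 0.1, c1 = 1, mu = 1),
    v = list(b01 = -1, b10 = 1, mu = c(1, 2)))
  mu <- spec$mu
  spec$mu <- NULL
  params <- do.call(model_params, utils::modifyList(base, spec))
  list(params = params, context = stimulus_context(mu, 0.5, panel))
}
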