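test_that("kernels are column-stochastic with degenerate limits", {
  p <- model_params(sigma = 1, a = 0, c1 = 0.5)
  k <- build_kernel(p, stimulus_context(1, 0.5))
  expect_lt(max(abs(Matrix::colSums(k$M) - 1)), 1e-10)
  # a = 0, no shifts, no noise: the identity kernel
  expect_equal(as.matrix(k$M), diag(k$grid$n), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a = 1: every column supported on the <= 4 destinations c1 + b_ij
  p1 <- model_params(sigma = 1, a = 1, c1 = 0.4, b11 = 0.5, b01 = -0.75,
                     b10 = 0.25)
  k1 <- build_kernel(p1, stimulus_context(1, 0.5))
  dests <- sort(unique(round((p1$c1 + shift_vector(p1) - k1$grid$lo) /
                               k1$grid$step))) + 1
  occupied <- which(Matrix::rowSums(k1$M) > 0)
  expect_true(all(occupied %in% dests))
})

test_that("error-driven kernel columns match a direct construction", {
  # unit shifts opposing errors, no noise: each column holds p_miss one
  # shift down, p_fa one shift up, and the rest at its own point
  p <- model_params(sigma = 1, a = 0, c1 = 0.5, b01 = -1, b10 = 1)
  ctx <- stimulus_context(1, 0.5)
  k <- build_kernel(p, ctx)
  g <- k$grid
  steps_per_unit <- round(1 / g$step)
  c_test <- c(10, 300, 500)
  for (j in c_test) {
    cc <- g$centers[j]
    p_yes_sig <- response_probability(cc, 1, p)
    p_yes_noise <- response_probability(cc, 0, p)
    expected <- numeric(g$n)
    expected[j - steps_per_unit] <- 0.5 * (1 - p_yes_sig)        # miss
    expected[j + steps_per_unit] <- 0.5 * p_yes_noise            # FA
    expected[j] <- 0.5 * p_yes_sig + 0.5 * (1 - p_yes_noise)     # correct
    expect_equal(as.numeric(k$M[, j]), expected, tolerance = 1e-12)
  }
})

test_that("stationary solutions reproduce the exemplar phenomenology", {
  cf1 <- exemplar_config("i")
  f1 <- stationary_distribution(build_kernel(cf1$params, cf1$context))
  expect_lt(f1$residual, 1e-9)
  m1 <- distribution_moments(f1)
  # symmetric about the minimum-error criterion (0.5 for equal priors,
  # unit-variance signals at 0 and 1)
  expect_equal(m1[["mean"]], 0.5, tolerance = 1e-6)
  cf2 <- exemplar_config("ii")
  f2 <- stationary_distribution(build_kernel(cf2$params, cf2$context))
  expect_gt(distribution_moments(f2)[["sd"]], m1[["sd"]])
  # shifts larger for misses skew the distribution liberal (downwards)
  cf3 <- exemplar_config("iii")
  f3 <- stationary_distribution(build_kernel(cf3$params, cf3$context))
  expect_lt(distribution_moments(f3)[["mean"]], 0.5)
})

test_that("halving the grid step moves stationary means by < 1%", {
  cf <- exemplar_config("iv")
  for (div in c(40, 80)) {
    f <- stationary_distribution(
      build_kernel(cf$params, cf$context,
                   default_grid(cf$params, step_div = div)))
    assign(paste0("m", div), distribution_moments(f)[["mean"]])
  }
  expect_lt(abs(m80 - m40) / abs(m40), 0.01)
})

test_that("the a = 1 chain equals the enumerated 4-state solution", {
  p <- model_params(sigma = 1, a = 1, c1 = 0.4, b11 = 0.5, b01 = -0.75,
                    b10 = 0.25, b00 = 0, lam = 0.1)
  ctx <- stimulus_context(1.2, 0.5)
  f <- stationary_distribution(build_kernel(p, ctx))
  # oracle: explicit 4x4 outcome chain solved exactly
  cs <- p$c1 + shift_vector(p)
  P <- vapply(cs, function(cc) {
    py_s <- response_probability(cc, 1.2, p)
    py_n <- response_probability(cc, 0, p)
    c(0.5 * py_s, 0.5 * (1 - py_s), 0.5 * py_n, 0.5 * (1 - py_n))
  }, numeric(4))
  pi4 <- Re(eigen(P)$vectors[, 1])
  pi4 <- pi4 / sum(pi4)
  idx <- round((cs - f$grid$lo) / f$grid$step) + 1
  expect_lt(max(abs(f$mass[idx] - pi4)), 1e-8)
  expect_lt(abs(sum(f$mass[idx]) - 1), 1e-10)
})

test_that("blocked solutions degenerate and compose correctly", {
  cf <- exemplar_config("i")
  k <- build_kernel(cf$params, cf$context)
  f <- stationary_distribution(k)
  # identical kernels: all positions equal the simple stationary solution
  sol <- blocked_stationary(k, k, L = 4L)
  for (d in sol$dists) expect_equal(d, f$mass, tolerance = 1e-7)
  # L = 1: fixed point of the explicit two-step composition
  ke <- build_kernel(cf$params, stimulus_context(c(3, 4), 0.5, "easy"))
  kh <- build_kernel(cf$params, stimulus_context(c(1, 2), 0.5, "hard"))
  sol1 <- blocked_stationary(ke, kh, L = 1L)
  # brute-force the two-step map: position 1 sees the easy kernel applied,
  # then the hard kernel, returning to position 1
  f_brute <- rep(1 / k$grid$n, k$grid$n)
  for (i in 1:20000) {
    f_new <- as.numeric(kh$M %*% (ke$M %*% f_brute))
    f_new <- f_new / sum(f_new)
    done <- sum(abs(f_new - f_brute)) < 1e-13
    f_brute <- f_new
    if (done) break
  }
  expect_equal(sol1$dists[[1]], f_brute, tolerance = 1e-8)
  expect_equal(sol1$dists[[2]],
               as.numeric(ke$M %*% sol1$dists[[1]]) /
                 sum(as.numeric(ke$M %*% sol1$dists[[1]])),
               tolerance = 1e-10)
  expect_error(blocked_stationary(
    ke, build_kernel(cf$params, stimulus_context(1, 0.5),
                     default_grid(cf$params, step_div = 20)), L = 2L),
    "share one grid")
})

test_that("the criterion is more conservative during easy blocks", {
  cf <- exemplar_config("i")
  ke <- build_kernel(cf$params, stimulus_context(c(3, 4), 0.5, "easy"))
  kh <- build_kernel(cf$params, stimulus_context(c(1, 2), 0.5, "hard"))
  sol <- blocked_stationary(ke, kh, L = 16L)
  means <- vapply(sol$dists, function(m) sum(m * sol$grid$centers),
                  numeric(1))
  expect_gt(mean(means[1:16]), mean(means[17:32]))
})

test_that("predicted summaries match closed forms and the simulator", {
  # no-shift model: P(FA) = lam/2 + (1 - lam) Phi(-c1 / sigma) exactly
  p0 <- model_params(sigma = 2, a = 0.5, c1 = 1.3, lam = 0.04,
                     variant = "no_shift")
  k0 <- build_kernel(p0, stimulus_context(c(2, 4), 0.5))
  f0 <- stationary_distribution(k0)
  pred0 <- predicted_summaries(f0, kernel = k0)
  expect_lt(abs(pred0$block$p_fa[1] -
                  (p0$lam / 2 + (1 - p0$lam) * pnorm(-p0$c1 / p0$sigma))),
            1e-6)
  # Monte-Carlo oracle: wrapped rates from a large corpus agree with the
  # per-position predictions (4 binomial SDs; the fixed seed makes this a
  # regression bound, slightly inflated for serial correlation)
  su <- f1_setup()
  pred <- f1_solution()$pred
  sessions <- simulate_corpus(su$params, su$design, 250L, seed = 500L)
  w <- wrap_block_positions(pool_trials_test(sessions), 8)
  tol_hit <- 4 * sqrt(0.25 / w$n_signal)
  tol_fa <- 4 * sqrt(0.25 / w$n_noise)
  expect_true(all(abs(w$p_hit - pred$block$p_hit) < tol_hit))
  expect_true(all(abs(w$p_fa - pred$block$p_fa) < tol_fa))
})

test_that("predicted conditional markers are displaced after all outcomes", {
  roc <- f1_solution()$pred$roc
  for (dd in c("easy", "hard")) {
    un <- roc[roc$difficulty == dd & roc$condition == "all", ]
    cond <- roc[roc$difficulty == dd & roc$condition != "all", ]
    disp <- sqrt((cond$p_fa - un$p_fa)^2 + (cond$p_hit - un$p_hit)^2)
    expect_true(all(disp > 0.005))  # including after correct outcomes
  }
})
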