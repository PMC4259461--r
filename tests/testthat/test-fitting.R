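test_that("log_likelihood matches hand-computable cases", {
  # pure lapse: every trial contributes log(1/2)
  s <- f1_small()[[1]]
  p_lapse <- model_params(sigma = 1, lam = 1)
  expect_equal(as.numeric(log_likelihood(s, p_lapse)),
               nrow(s) * log(0.5))
  # single no-signal trial, "no", criterion at the no-signal mean
  one <- data.frame(session_id = "s", trial_index = 1L,
                    block_index = NA, position_in_block = NA,
                    difficulty = NA, h = 0L, mu_db = 0, d = 0L,
                    is_correction = FALSE,
                    outcome = "correct_rejection")
  expect_equal(as.numeric(log_likelihood(one, model_params(sigma = 1))),
               log(0.5))
  expect_error(log_likelihood(s, model_params(sigma = 1,
                                              shift_noise_sd = 0.01)),
               "shift_noise_sd")
})

test_that("likelihood is invariant to session order", {
  ss <- f1_small()[1:3]
  p <- reference_params("f1_blocks8")
  expect_equal(as.numeric(log_likelihood(ss, p)),
               as.numeric(log_likelihood(rev(ss), p)))
  expect_equal(as.numeric(log_likelihood(ss, p)),
               sum(vapply(ss, function(s)
                 as.numeric(log_likelihood(s, p)), numeric(1))))
})

test_that("ground truth beats random unit-magnitude perturbations", {
  ss <- f1_corpus()[1:20]
  truth <- reference_params("f1_blocks8")
  ll0 <- as.numeric(log_likelihood(ss, truth))
  set.seed(99)
  nm <- c("sigma", "a", "c1", "b11", "b01", "b10", "b00", "lam")
  for (i in 1:100) {
    delta <- stats::rnorm(8)
    delta <- delta / sqrt(sum(delta^2)) * stats::runif(1, 1, 3)
    cand <- unlist(unclass(truth)[nm]) + delta
    cand["sigma"] <- max(cand["sigma"], 0.3)
    cand["a"] <- min(max(cand["a"], 0), 1)
    cand["lam"] <- min(max(cand["lam"], 0.001), 0.999)
    p <- do.call(model_params, as.list(cand))
    expect_lt(as.numeric(log_likelihood(ss, p)), ll0)
  }
})

test_that("analytic gradients agree with central finite differences", {
  pts <- list(
    model_params(sigma = 5, a = 0.6, c1 = 1, b11 = 2, b01 = -3, b10 = 1,
                 b00 = 0.5, lam = 0.08),
    reference_params("f1_blocks8"),
    model_params(sigma = 8, a = 0.3, c1 = -1, b11 = -1, b01 = 2,
                 b10 = -0.5, b00 = 1.5, lam = 0.15))
  fixtures <- list(f1_small()[[1]],
                   pool_trials_test(f1_small()[2:3]))
  for (tr in fixtures) for (p in pts) {
    ga <- ll_gradient(tr, p)
    gf <- ll_gradient_fd(tr, p)
    expect_lt(max(abs(ga - gf) / pmax(abs(gf), 1e-6)), 1e-4)
  }
  # corrections excluded from the terms but not the recursion
  pct <- model_params(sigma = 3, a = 0.5, c1 = 1, b01 = -2, b10 = 1,
                      lam = 0.1)
  dct <- session_design("random_with_corrections", all_levels = c(2, 5),
                        max_trials = 150L)
  sct <- apply_correction_policy(dct, pct, seed = 41)
  for (inc in c(TRUE, FALSE)) {
    ga <- ll_gradient(sct, pct, include_corrections = inc)
    gf <- ll_gradient_fd(sct, pct, include_corrections = inc)
    expect_lt(max(abs(ga - gf) / pmax(abs(gf), 1e-6)), 1e-4)
  }
})

test_that("gradients are well-behaved at symmetric points", {
  # all-shift-zero parameters: shift gradients defined, not NaN
  s <- f1_small()[[1]]
  p0 <- model_params(sigma = 6, a = 0.5, c1 = 2, lam = 0.05)
  g <- ll_gradient(s, p0)
  expect_true(all(is.finite(g)))
  # score identity: on data generated at lam = 0.5 the lapse gradient has
  # zero expectation at the generating parameters (Monte-Carlo check)
  p_half <- model_params(sigma = 3, c1 = 1.5, lam = 0.5)
  gl <- vapply(1:40, function(i) {
    n <- 200
    sched <- data.frame(h = rep(c(1, 0), n / 2), mu = rep(c(3, 0), n / 2))
    tr <- simulate_session(sched, p_half, seed = 8000 + i)
    ll_gradient(tr, p_half)[["lam"]]
  }, numeric(1))
  expect_lt(abs(mean(gl)), 3 * stats::sd(gl) / sqrt(length(gl)))
})

test_that("fit_sga honours variants and is seed-deterministic", {
  ss <- f1_small()
  short <- data.frame(iters = c(20L, 40L, 40L), eta = c(0.1, 0.01, 0.001),
                      lam_free = c(FALSE, TRUE, TRUE))
  f_ns <- fit_sga(ss, "no_shift", seed = 3, schedule = short)
  expect_identical(unname(shift_vector(f_ns$params)), rep(0, 4))
  expect_equal(length(f_ns$trace), 100L)
  f_nm <- fit_sga(ss, "no_memory", seed = 3, schedule = short)
  expect_equal(f_nm$params$a, 1)
  again <- fit_sga(ss, "no_shift", seed = 3, schedule = short)
  expect_identical(f_ns$params, again$params)
})

test_that("recovery bias shrinks with corpus size", {
  # ~2,500-trial vs ~25,000-trial corpora over 10 seeds (abbreviated
  # annealing schedule to keep the run fast; same shape as the default)
  su <- f1_setup()
  short <- data.frame(iters = c(50L, 200L, 200L),
                      eta = c(0.1, 0.01, 0.001),
                      lam_free = c(FALSE, TRUE, TRUE))
  errs <- vapply(1:10, function(seed) {
    small <- simulate_corpus(su$params, su$design, 21L,
                             seed = 40000L + 100L * seed)
    big <- simulate_corpus(su$params, su$design, 209L,
                           seed = 60000L + 300L * seed)
    f_small <- fit_sga(small, "full", seed = seed, schedule = short)
    f_big <- fit_sga(big, "full", seed = seed, schedule = short)
    c(abs(f_small$params$sigma - su$params$sigma),
      abs(f_big$params$sigma - su$params$sigma))
  }, numeric(2))
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})

test_that("the coarse grid enumerates 6^5 cell centres", {
  cands <- grid_candidates(grid_spec())
  expect_equal(nrow(cands), 7776L)
  expect_equal(sort(unique(cands$sigma)),
               3 + (1:6 - 0.5) * 1.5)
  expect_equal(unname(grid_fine_spacing(grid_spec())),
               c(20 / 36, 0.25))
  expect_error(grid_spec(shift_points = 1), "at least 2")
})

test_that("the grid fit recovers an in-grid candidate exactly", {
  sp <- grid_spec(shift_points = 3, sigma_points = 3, refine_levels = 0)
  truth <- data.frame(b11 = 0, b01 = -20 / 3, b10 = 20 / 3, b00 = 0,
                      sigma = 4.5)
  markers <- critdyn:::predict_roc_markers(
    truth, easy_levels = c(8, 10), hard_levels = c(3, 5), L = 8,
    lam = 0.05)
  fit <- fit_grid(markers, easy_levels = c(8, 10), hard_levels = c(3, 5),
                  L = 8, spec = sp, lam = 0.05)
  expect_equal(fit$params$b01, -20 / 3)
  expect_equal(fit$params$b10, 20 / 3)
  expect_equal(fit$params$sigma, 4.5)
  expect_equal(fit$params$a, 0)
  expect_lt(fit$distance, 1e-10)
  expect_equal(fit$n_evaluated, 243L)
  # exhaustiveness: the returned distance is <= every coarse candidate's
  expect_true(all(fit$distance <= fit$distances + 1e-15))
  expect_error(fit_grid(within(markers, p_fa[1] <- NaN),
                        easy_levels = c(8, 10), hard_levels = c(3, 5),
                        L = 8, spec = sp),
               "defined")
})
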