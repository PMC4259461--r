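test_that("pc_max matches the unbiased-observer closed form", {
  expect_equal(pc_max(0.3, 0.3), 0.5)
  # z-scores +/-1 give d' = 2, PC = Phi(1)
  expect_equal(pc_max(0.8413447, 0.1586553), 0.8413447, tolerance = 1e-6)
  # z = 0 - (-2), PC = Phi(1)
  expect_equal(pc_max(0.5, 0.02275013), 0.8413447, tolerance = 1e-6)
  # clamping replaces 0/1 by 1/(2N)
  expect_equal(pc_max(1, 0.2, n_signal = 50),
               pc_max(1 - 1 / 100, 0.2))
  expect_error(pc_max(0, 0.5), "trial count")
})

test_that("pc_max is symmetric and monotone", {
  set.seed(1)
  h <- runif(50, 0.01, 0.99)
  f <- runif(50, 0.01, 0.99)
  expect_equal(pc_max(h, f) + pc_max(f, h), rep(1, 50))
  expect_true(all(diff(pc_max(seq(0.1, 0.9, 0.1), 0.2)) > 0))
  expect_true(all(diff(pc_max(0.8, seq(0.1, 0.9, 0.1))) < 0))
})

test_that("fit_sigmoid recovers exact parameters and the reference level", {
  levels <- seq(10, 50, by = 4)
  pts <- data.frame(level = levels,
                    pc = psychometric_sigmoid(levels, 30, 6, 0.1))
  fit <- fit_sigmoid(pts)
  expect_equal(fit$mid, 30, tolerance = 1e-3)
  expect_equal(fit$slope, 6, tolerance = 1e-3)
  expect_equal(fit$lapse_psy, 0.1, tolerance = 1e-3)
  expect_equal(fit$db_ref, fit$mid + fit$slope * qnorm(0.05))
  # lapse-free data: asymptote recovered at 1
  pts0 <- data.frame(level = levels,
                     pc = psychometric_sigmoid(levels, 30, 6, 0))
  expect_equal(1 - fit_sigmoid(pts0)$lapse_psy, 1, tolerance = 1e-3)
  expect_error(fit_sigmoid(data.frame(level = levels,
                                      pc = rep(0.5, length(levels)))),
               "flat")
  expect_error(fit_sigmoid(data.frame(level = c(1, 2, 3), pc = c(.5, .6, .7))),
               "4 distinct")
})

test_that("wrap_block_positions pools by session position modulo 2L", {
  # a single 16-trial session: every cycle position holds exactly one trial
  su <- f1_setup()
  d16 <- session_design("alternating_blocks", block_length = 8L,
                        easy_levels = su$levels$easy,
                        hard_levels = su$levels$hard, max_trials = 16L)
  one <- simulate_session(make_block_schedule(d16, seed = 3), su$params,
                          seed = 4)
  w1 <- wrap_block_positions(one, 8)
  expect_true(all(w1$n == 1L))
  expect_true(all(is.nan(w1$p_hit) | w1$n_signal > 0))
  # a 120-trial session: hard position 9 pools trials 9, 25, ..., 105
  s120 <- f1_small()[[1]]
  w <- wrap_block_positions(s120, 8)
  expect_equal(w$n[9], 7L)
  expect_identical(w$difficulty, rep(c("easy", "hard"), each = 8))
  manual <- s120[((s120$trial_index - 1) %% 16) + 1 == 9 & s120$h == 1, ]
  expect_equal(w$p_hit[9], mean(manual$d))
})

test_that("wrapping two sessions equals count-weighted pooling", {
  ss <- f1_small()[1:2]
  w12 <- wrap_block_positions(ss, 8)
  w1 <- wrap_block_positions(ss[[1]], 8)
  w2 <- wrap_block_positions(ss[[2]], 8)
  pooled_hit <- (w1$p_hit * w1$n_signal + w2$p_hit * w2$n_signal) /
    (w1$n_signal + w2$n_signal)
  expect_equal(w12$p_hit, pooled_hit)
})

test_that("shared-decay exponential regression recovers B", {
  mk <- function(y_inf, y0, B, L) y_inf + (y0 - y_inf) * exp(-B * (0:(L - 1)))
  build <- function(noise_sd, seed) {
    set.seed(seed)
    bs <- data.frame(
      position = 1:16, difficulty = rep(c("easy", "hard"), each = 8),
      p_hit = c(mk(0.9, 0.6, 1.14, 8), mk(0.55, 0.8, 1.14, 8)) +
        rnorm(16, 0, noise_sd),
      n_signal = 100L,
      p_fa = c(mk(0.15, 0.3, 1.14, 8), mk(0.3, 0.12, 1.14, 8)) +
        rnorm(16, 0, noise_sd),
      n_noise = 100L, p_correct = NA, p_yes = NA, n = 200L)
    structure(bs, class = c("block_summary", "data.frame"), L = 8L)
  }
  ef <- attr(fit_block_exponentials(build(0.01, 3)), "exp_fit")
  expect_lt(abs(ef$B - 1.14), 0.1)
  # exact curves: B recovered exactly; 1/B consistent with ~0.90 trials
  ef0 <- attr(fit_block_exponentials(build(0, 1)), "exp_fit")
  expect_equal(ef0$B, 1.14, tolerance = 1e-4)
  expect_lt(abs(ef0$time_constant - 0.90), 0.05)
  # derived curves follow from the hit/FA fits at p_signal = 0.5
  expect_equal(ef0$fitted$yes, 0.5 * ef0$fitted$hit + 0.5 * ef0$fitted$fa)
  expect_equal(ef0$fitted$correct,
               0.5 * ef0$fitted$hit + 0.5 * (1 - ef0$fitted$fa))
})

test_that("flat curves are flagged with B = 0", {
  bs <- data.frame(position = 1:16,
                   difficulty = rep(c("easy", "hard"), each = 8),
                   p_hit = rep(0.7, 16), n_signal = 100L,
                   p_fa = rep(0.2, 16), n_noise = 100L,
                   p_correct = NA, p_yes = NA, n = 200L)
  bs <- structure(bs, class = c("block_summary", "data.frame"), L = 8L)
  ef <- attr(fit_block_exponentials(bs), "exp_fit")
  expect_true(ef$flat)
  expect_equal(ef$B, 0)
  bs$p_hit[3] <- NaN
  expect_error(fit_block_exponentials(bs), "defined")
})

test_that("conditional_roc conditions on the previous trial's outcome", {
  # deterministic alternating hit, FA, hit, FA, ...: trials preceded by a
  # hit are exactly the even-indexed ones
  n <- 20
  tr <- data.frame(session_id = "s", trial_index = 1:n,
                   block_index = 1L, position_in_block = 1L,
                   difficulty = "easy",
                   h = rep(c(1, 0), n / 2), mu_db = rep(c(5, 0), n / 2),
                   d = 1L, is_correction = FALSE)
  tr$outcome <- classify_outcome(tr$h, tr$d)
  roc <- conditional_roc(structure(tr, class = c("trial_log", "data.frame")))
  after_hit <- roc[roc$condition == "hit", ]
  # successors of hits are all no-signal "yes" trials: FA rate 1, no signal
  # trials in the conditioned set
  expect_equal(after_hit$p_fa, 1)
  expect_equal(after_hit$n_noise, sum(seq(2, n) %% 2 == 0))
  expect_equal(after_hit$n_signal, 0)
  after_fa <- roc[roc$condition == "false_alarm", ]
  expect_equal(after_fa$p_hit, 1)
  expect_equal(after_fa$n_noise, 0)
})

test_that("conditioned marker counts and rates pool to the unconditional", {
  roc <- conditional_roc(f1_small())
  for (dd in unique(roc$difficulty)) {
    un <- roc[roc$difficulty == dd & roc$condition == "all", ]
    cond <- roc[roc$difficulty == dd & roc$condition != "all", ]
    expect_equal(sum(cond$n_signal), un$n_signal)
    expect_equal(sum(cond$n_noise), un$n_noise)
    expect_equal(sum(cond$p_hit * cond$n_signal) / un$n_signal, un$p_hit)
    expect_equal(sum(cond$p_fa * cond$n_noise) / un$n_noise, un$p_fa)
  }
})

test_that("subject-1 data show liberal-after-miss, conservative-after-hit", {
  roc <- conditional_roc(f1_corpus())
  for (dd in c("easy", "hard")) {
    cond <- roc[roc$difficulty == dd & roc$condition != "all", ]
    expect_identical(cond$condition[which.max(cond$p_fa)], "miss")
    expect_identical(cond$condition[which.min(cond$p_fa)], "hit")
  }
})
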