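# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# subject-1 ground truth, level sets and blocked design
f1_setup <- function() cached("f1_setup", function() {
  params <- reference_params("f1_blocks8")
  ls <- select_levels_from_sigmoid(fixture_psychometric(params))
  design <- session_design("alternating_blocks", block_length = 8L,
                           easy_levels = ls$easy, hard_levels = ls$hard,
                           max_trials = 120L)
  list(params = params, levels = ls, design = design)
})

# the full-size (~6,500-trial) blocked corpus used for recovery tests
f1_corpus <- function() cached("f1_corpus", function() {
  s <- f1_setup()
  simulate_corpus(s$params, s$design, n_sessions = 54L, seed = 100L)
})

# a small blocked corpus for cheap structural tests
f1_small <- function() cached("f1_small", function() {
  s <- f1_setup()
  simulate_corpus(s$params, s$design, n_sessions = 6L, seed = 300L)
})

# blocked Markov solution and predictions at the ground-truth parameters
f1_solution <- function() cached("f1_solution", function() {
  s <- f1_setup()
  ke <- build_kernel(s$params, stimulus_context(s$levels$easy, 0.5, "easy"))
  kh <- build_kernel(s$params, stimulus_context(s$levels$hard, 0.5, "hard"))
  sol <- blocked_stationary(ke, kh, L = 8L)
  list(solution = sol, pred = predicted_summaries(sol))
})

# simulate one long identically-distributed session for an exemplar panel
exemplar_trace <- function(panel, n = 1e5, seed = 1, burn_in = 1000) {
  cf <- exemplar_config(panel)
  sched <- with_seed_helper(seed, {
    h <- stats::rbinom(n, 1, cf$context$p_signal)
    lv <- cf$context$levels
    mu <- ifelse(h == 1, lv[sample.int(length(lv), n, replace = TRUE)], 0)
    data.frame(h = h, mu = mu)
  })
  ses <- simulate_session(sched, cf$params, seed = seed + 5000L)
  attr(ses, "criterion_trace")[-seq_len(burn_in)]
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  code
}

# rbind a list of trial logs (test-side mirror of the internal pooler)
pool_trials_test <- function(x) {
  if (inherits(x, "data.frame")) return(as.data.frame(x))
  do.call(rbind, lapply(x, as.data.frame))
}
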