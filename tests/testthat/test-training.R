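# Training protocols: batch equivalence, memorisation, retrieval,
# alternating dual-sequence training, reproducibility.

test_that("the compiled training loop equals composed single steps", {
  set.seed(71)
  for (case in 1:5) {
    n <- sample(2:5, 1)
    s <- random_structure(n, 1, 6)
    p <- random_parameters(s)
    ada <- adagrad_state(s)
    X <- matrix(rbinom(20 * n, 1, 0.4), 20, n)
    stR <- init_state(s); pR <- p; adaR <- ada; llR <- numeric(20)
    for (t in 1:20) {
      r <- train_step(X[t, ], stR, pR, adaR)
      stR <- r$state; pR <- r$params; adaR <- r$ada; llR[t] <- r$loglik
    }
    out <- train_sequence(X, init_state(s), p, ada, n_reps = 1L)
    expect_equal(out$params$bias, pR$bias, tolerance = 1e-12)
    expect_equal(out$params$ltp, pR$ltp, tolerance = 1e-12)
    expect_equal(out$params$ltd, pR$ltd, tolerance = 1e-12)
    expect_equal(out$state$alpha, stR$alpha, tolerance = 1e-12)
    expect_equal(out$state$gamma, stR$gamma, tolerance = 1e-12)
    expect_identical(out$state$hist, stR$hist)
    expect_equal(out$ada$ltd_a, adaR$ltd_a, tolerance = 1e-12)
    expect_equal(out$loglik, sum(llR), tolerance = 1e-10)
  }
})

test_that("a constant-ones one-neuron target is memorised quickly", {
  s <- dybm_structure(1, delays = 2)
  set.seed(72)
  res <- train_until_memorized(pattern_sequence(matrix(1L, 1, 1), period = 1),
                               s, max_periods = 100)
  expect_true(res$converged)
  expect_lte(res$periods_used, 100)
  g <- generate_deterministic(res$state, res$params, 5)
  expect_true(all(g$sequence$values == 1L))
})

test_that("a target the fresh model already generates converges at the first check", {
  s <- dybm_structure(2, delays = 3)
  p <- dybm_parameters(s, bias = c(5, -5))   # generates (1, 0) forever
  target <- pattern_sequence(matrix(c(1L, 0L), 1), period = 1)
  res <- train_until_memorized(target, s, params = p, max_periods = 100)
  expect_true(res$converged)
  expect_identical(res$periods_used, 0L)
})

test_that("budget exhaustion reports converged = FALSE without error", {
  set.seed(73)
  res <- train_until_memorized(render_text("SCI"), random_structure(7),
                               max_periods = 20)
  expect_false(res$converged)
  expect_identical(res$periods_used, 20L)
  expect_error(train_until_memorized(
    pattern_sequence(matrix(0L, 2, 1)), dybm_structure(1)), "period")
})

test_that("cue retrieval replays a memorised constant pattern", {
  s <- dybm_structure(2, delays = 2)
  zero <- dybm_parameters(s)
  cue <- matrix(c(1L, 0L), 1)
  expect_true(all(retrieve_with_cue(zero, s, cue, 6)$values == 0L))
  set.seed(74)
  target <- pattern_sequence(matrix(c(1L, 0L), 1), period = 1)
  res <- train_until_memorized(target, s, max_periods = 200)
  expect_true(res$converged)
  got <- retrieve_with_cue(res$params, s, target$values, 6)
  expect_true(all(got$values[, 1] == 1L) && all(got$values[, 2] == 0L))
  expect_true(cue_retrieves(res$params, s, target$values, target))
  expect_error(retrieve_with_cue(zero, s, matrix(integer(0), 0, 2), 5),
               "non-empty")
})

test_that("alternating training with identical sequences ends in one iteration", {
  set.seed(75)
  seq_a <- render_text("SC")
  cue <- pattern_sequence(seq_a$values[1:10, ])
  s <- random_structure(7)
  res <- train_alternating(seq_a, seq_a, cue, cue, s,
                           max_iterations = 50,
                           max_periods_per_iteration = 50000)
  expect_true(res$converged)
  expect_identical(res$iterations_used, 1L)
})

test_that("a small dual-sequence pair is stored and cued apart", {
  # 3-neuron toy pair, period 4; cues span two periods because at this
  # tiny period the trace transient of a shorter cue is still large
  a <- pattern_sequence(matrix(c(1,0,0, 0,1,0, 0,0,1, 1,1,0),
                               4, 3, byrow = TRUE), period = 4)
  b <- mirror_sequence(a)
  cue_a <- pattern_sequence(a$values[rep(1:4, 2), ])
  cue_b <- pattern_sequence(b$values[rep(1:4, 2), ])
  set.seed(76)
  s <- random_structure(3, 1, 5)
  res <- train_alternating(a, b, cue_a, cue_b, s,
                           max_iterations = 20000,
                           max_periods_per_iteration = 300000)
  expect_true(res$converged)
  expect_true(cue_retrieves(res$params, s, cue_a, a))
  expect_true(cue_retrieves(res$params, s, cue_b, b))
  expect_identical(length(res$periods_per_iteration), res$iterations_used)
})

test_that("fits are reproducible bit-for-bit from the seed", {
  target <- render_text("SC")
  f1 <- dybm(target, max_periods = 300, seed = 9)
  f2 <- dybm(target, max_periods = 300, seed = 9)
  expect_identical(f1$structure$delays, f2$structure$delays)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$periods_used, f2$periods_used)
  expect_identical(simulate(f1)$values, simulate(f2)$values)
  f3 <- dybm(target, max_periods = 300, seed = 10)
  expect_false(identical(f3$structure$delays, f1$structure$delays))
})
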