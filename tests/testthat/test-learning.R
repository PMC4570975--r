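# Exact online learning rule: gradients, AdaGrad, single training steps.

test_that("expectation is the conditional spike probability at tau = 1", {
  s <- dybm_structure(2)
  st <- init_state(s)
  expect_equal(expectation(1, st, dybm_parameters(s)), 0.5)
  expect_equal(expectation(1, st, dybm_parameters(s, bias = c(1, 0))),
               exp(1) / (1 + exp(1)))
  set.seed(41)
  inst <- random_instance()
  for (j in 1:3)
    expect_equal(expectation(j, inst$state, inst$params),
                 spike_probability(j, inst$state, inst$params, tau = 1))
})

test_that("gradient components have the expected structure", {
  s <- dybm_structure(2, delays = 3)
  zero <- dybm_parameters(s)
  st <- init_state(s)                  # alpha = 0: LTP gradient vanishes
  g <- compute_gradients(c(1, 1), st, zero)
  expect_equal(g$d_bias, c(0.5, 0.5))  # x - <X> with <X> = 0.5
  expect_true(all(g$d_ltp == 0))
  expect_true(all(g$d_ltd_a == 0) && all(g$d_ltd_b == 0))
  g0 <- compute_gradients(c(0, 0), st, zero)
  expect_equal(g0$d_bias, c(-0.5, -0.5))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  for (case in 1:20) {
    inst <- random_instance()
    x <- rbinom(3, 1, 0.5)
    g <- compute_gradients(x, inst$state, inst$params)
    fd <- fd_gradients(x, inst$state, inst$params)
    expect_lt(max_rel_err(g$d_bias, fd$d_bias), 1e-5)
    expect_lt(max_rel_err(g$d_ltp, fd$d_ltp), 1e-5)
    expect_lt(max_rel_err(g$d_ltd_a + g$d_ltd_b, fd$d_ltd), 1e-5)
  }
})

test_that("AdaGrad steps follow the per-parameter rate formula", {
  s <- dybm_structure(1, delays = 1)
  p <- dybm_parameters(s)
  ada <- adagrad_state(s, eta0 = 1, epsilon = 1e-12)
  mk <- function(gb) {
    g <- compute_gradients(1, init_state(s), p)
    g$d_bias <- gb; g$d_ltp[] <- 0; g$d_ltd_a[] <- 0; g$d_ltd_b[] <- 0
    g
  }
  u1 <- apply_update(p, mk(3), ada)
  u2 <- apply_update(u1$params, mk(4), u1$ada)
  # literal transcription: step_m = eta0 * g_m / sqrt(eps + sum_{m'<=m} g^2)
  expect_equal(u1$params$bias, 3 / sqrt(1e-12 + 9))
  expect_equal(u2$params$bias,
               3 / sqrt(1e-12 + 9) + 4 / sqrt(1e-12 + 9 + 16))
  expect_equal(u2$ada$bias, 25)
  # zero gradient: nothing moves, nothing accrues
  u3 <- apply_update(u2$params, mk(0), u2$ada)
  expect_identical(u3$params$bias, u2$params$bias)
  expect_identical(u3$ada$bias, u2$ada$bias)
})

test_that("AdaGrad accumulators are non-decreasing and LTD accumulates per component", {
  set.seed(43)
  inst <- random_instance()
  ada <- adagrad_state(inst$structure)
  p <- inst$params
  st <- inst$state
  prev <- ada
  for (step in 1:100) {
    x <- rbinom(3, 1, 0.5)
    r <- train_step(x, st, p, ada)
    p <- r$params; ada <- r$ada; st <- r$state
    for (f in c("bias", "ltp", "ltd_a", "ltd_b"))
      expect_true(all(ada[[f]] >= prev[[f]]))
    prev <- ada
  }
  # the two LTD components accumulated different histories
  expect_gt(max(abs(ada$ltd_a - ada$ltd_b)), 0)
})

test_that("a small fixed-rate step never decreases the presented likelihood", {
  set.seed(44)
  for (case in 1:100) {
    inst <- random_instance(n = sample(2:4, 1))
    n <- inst$structure$n_neurons
    x <- rbinom(n, 1, 0.5)
    before <- log_likelihood_step(x, inst$state, inst$params)
    r <- train_step(x, inst$state, inst$params, ada = NULL, rate = 1e-4)
    after <- log_likelihood_step(x, inst$state, r$params)
    expect_gt(after, before)
  }
})

test_that("train_step composes gradients, update and state advance", {
  set.seed(45)
  inst <- random_instance()
  ada <- adagrad_state(inst$structure)
  x <- c(1, 0, 1)
  g <- compute_gradients(x, inst$state, inst$params)
  upd <- apply_update(inst$params, g, ada)
  r <- train_step(x, inst$state, inst$params, ada)
  expect_identical(r$params, upd$params)
  expect_identical(r$ada, upd$ada)
  expect_identical(r$state, advance_state(inst$state, x))
  expect_identical(r$loglik, g$loglik)
})

test_that("training on silence drives the spiking probability down", {
  s <- dybm_structure(2, delays = 2)
  p <- dybm_parameters(s)
  ada <- adagrad_state(s)
  st <- init_state(s)
  for (t in 1:200) {
    r <- train_step(c(0, 0), st, p, ada)
    p <- r$params; ada <- r$ada; st <- r$state
  }
  expect_true(all(p$bias < 0))
  expect_true(all(spike_probabilities(st, p) < 0.5))
  g <- generate_deterministic(st, p, 10)
  expect_true(all(g$sequence$values == 0L))
})

test_that("gradient components are local to their synapse", {
  # with zero parameters the expectations are 0.5 whatever the traces, so
  # perturbing unrelated traces must leave a component untouched
  s <- dybm_structure(3, delays = 4)
  zero <- dybm_parameters(s)
  set.seed(47)
  st <- init_state(s)
  for (t in 1:8) st <- advance_state(st, rbinom(3, 1, 0.5))
  x <- c(1, 0, 1)
  g <- compute_gradients(x, st, zero)
  st2 <- st
  st2$alpha[2, , ] <- st2$alpha[2, , ] + 5   # other pre-synaptic neurons
  st2$hist[3, ] <- 1 - st2$hist[3, ]         # other queues
  st2$gamma[2, ] <- st2$gamma[2, ] + 5       # other neural traces
  g2 <- compute_gradients(x, st2, zero)
  expect_identical(g2$d_ltp[1, 1, ], g$d_ltp[1, 1, ])
  expect_identical(g2$d_ltd_a[1, 1, ], g$d_ltd_a[1, 1, ])
  expect_identical(g2$d_ltd_b[1, 1, ], g$d_ltd_b[1, 1, ])
  expect_identical(g2$d_bias, g$d_bias)
})
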