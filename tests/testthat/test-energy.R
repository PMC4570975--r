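# Energy, conditional spike probability, log-likelihood and generation.

test_that("energy vanishes for zero parameters and for a silent neuron", {
  set.seed(31)
  inst <- random_instance()
  zero <- dybm_parameters(inst$structure)
  for (j in 1:3) {
    expect_identical(energy_neuron(j, 0, inst$state, zero), 0)
    expect_identical(energy_neuron(j, 1, inst$state, zero), 0)
    # every term carries the factor x_j
    expect_identical(energy_neuron(j, 0, inst$state, inst$params), 0)
  }
})

test_that("energy matches a literal term-by-term transcription", {
  set.seed(32)
  for (case in 1:10) {
    inst <- random_instance()
    for (j in 1:3)
      expect_lt(abs(energy_neuron(j, 1, inst$state, inst$params) -
                      oracle_energy_neuron(j, 1, inst$state, inst$params)),
                1e-12)
    x <- rbinom(3, 1, 0.5)
    expect_lt(abs(energy_total(x, inst$state, inst$params) -
                    sum(vapply(1:3, function(j)
                      energy_neuron(j, x[j], inst$state, inst$params),
                      numeric(1)))), 1e-12)
  }
  # single neuron: total energy is the per-neuron energy
  set.seed(33)
  i1 <- random_instance(n = 1)
  expect_equal(energy_total(1, i1$state, i1$params),
               energy_neuron(1, 1, i1$state, i1$params))
})

test_that("spike probabilities normalise and match the closed form", {
  s <- dybm_structure(2)
  st <- init_state(s)
  zero <- dybm_parameters(s)
  expect_equal(spike_probability(1, st, zero), 0.5)
  p1 <- dybm_parameters(s, bias = c(1, 0))
  expect_equal(spike_probability(1, st, p1, tau = 1), exp(1) / (1 + exp(1)))
  # P(spike) + P(silent) = 1 exactly, over random states
  set.seed(34)
  for (case in 1:20) {
    inst <- random_instance()
    pr <- spike_probabilities(inst$state, inst$params)
    e1 <- vapply(1:3, function(j)
      energy_neuron(j, 1, inst$state, inst$params), numeric(1))
    q <- exp(-e1) / (1 + exp(-e1))
    expect_lt(max(abs(pr + (1 - pr) - 1)), 1e-12)
    expect_lt(max(abs(pr - q)), 1e-12)
  }
  # numerically stable at extreme energies
  pbig <- dybm_parameters(s, bias = c(1e4, -1e4))
  pr <- spike_probabilities(st, pbig)
  expect_identical(pr, c(1, 0))
  expect_error(spike_probabilities(st, zero, tau = 0), "tau")
})

test_that("one-step log-likelihood sums per-neuron log-probabilities", {
  s7 <- dybm_structure(7)
  zero7 <- dybm_parameters(s7)
  st7 <- init_state(s7)
  for (x in list(rep(0, 7), rep(1, 7), c(1, 0, 1, 0, 1, 0, 1)))
    expect_equal(log_likelihood_step(x, st7, zero7), -7 * log(2))
  set.seed(35)
  for (case in 1:10) {
    inst <- random_instance()
    x <- rbinom(3, 1, 0.5)
    pr <- spike_probabilities(inst$state, inst$params)
    expect_lt(abs(log_likelihood_step(x, inst$state, inst$params) -
                    sum(log(ifelse(x == 1, pr, 1 - pr)))), 1e-12)
    expect_lte(log_likelihood_step(x, inst$state, inst$params), 0)
  }
  s1 <- dybm_structure(1)
  expect_equal(log_likelihood_step(1, init_state(s1),
                                   dybm_parameters(s1, bias = 1)),
               log(exp(1) / (1 + exp(1))))
  expect_error(log_likelihood_step(c(0, 2, 0), init_state(dybm_structure(3)),
                                   dybm_parameters(dybm_structure(3))),
               "0 or 1")
})

test_that("deterministic generation thresholds strictly at probability 0.5", {
  s <- dybm_structure(3, delays = 2)
  zero <- dybm_parameters(s)
  g <- generate_deterministic(init_state(s), zero, 10)
  expect_true(all(g$sequence$values == 0L))      # ties emit 0
  pbias <- dybm_parameters(s, bias = c(10, -10, 10))
  g2 <- generate_deterministic(init_state(s), pbias, 8)
  expect_true(all(g2$sequence$values[, c(1, 3)] == 1L))
  expect_true(all(g2$sequence$values[, 2] == 0L))
  # two runs from equal state and parameters are identical
  set.seed(36)
  inst <- random_instance()
  ga <- generate_deterministic(inst$state, inst$params, 30)
  gb <- generate_deterministic(inst$state, inst$params, 30)
  expect_identical(ga$sequence$values, gb$sequence$values)
})

test_that("finite-temperature sampling has the model's spike frequencies", {
  s <- dybm_structure(2)
  st <- init_state(s)
  zero <- dybm_parameters(s)
  set.seed(37)
  draws <- replicate(10000, sample_step(st, zero))
  expect_lt(max(abs(rowMeans(draws) - 0.5)), 0.02)
  p1 <- dybm_parameters(s, bias = c(1, 1))
  target <- exp(1) / (1 + exp(1))
  se <- sqrt(target * (1 - target) / 10000)
  draws2 <- replicate(10000, sample_step(st, p1))
  expect_lt(max(abs(rowMeans(draws2) - target)), 3 * se)
  set.seed(99); a <- sample_step(st, p1)
  set.seed(99); b <- sample_step(st, p1)
  expect_identical(a, b)
})
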