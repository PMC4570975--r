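# Independent oracles: literal transcriptions of the defining sums and a
# finite-difference gradient, kept free of the package's vectorised or
# compiled code paths so they can arbitrate it.

# Trace values after presenting history X (T x N) to a fresh state, from
# the defining geometric sums:
#   gamma[j, l]    = sum_{s<=T} mu_l^(T+1-s) X[s, j]
#   alpha[i, j, k] = sum_{s<=T+1-d} lambda_k^(T+2-d-s) X[s, i]
#                    (spikes that have traversed the delay-d queue; the
#                     spike emitted at s arrives at s+d-1 advances later and
#                     the most recent arrival carries weight lambda^1)
#   beta[i, j, l]  = sum_{p=1}^{d-1} mu_l^(d-p) X[T+1-p, i]
#                    (spikes still queued; weight mu^(steps to arrival))
oracle_traces <- function(structure, X) {
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  T_ <- nrow(X)
  gam <- matrix(0, n, L)
  for (j in seq_len(n))
    for (l in seq_len(L))
      for (s in seq_len(T_))
        gam[j, l] <- gam[j, l] + structure$neural_decay[l]^(T_ + 1 - s) * X[s, j]
  alp <- array(0, c(n, n, K))
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(K)) {
        d <- structure$delays[i, j]
        if (T_ + 1 - d >= 1)
          for (s in seq_len(T_ + 1 - d))
            alp[i, j, k] <- alp[i, j, k] +
              structure$synaptic_decay[k]^(T_ + 2 - d - s) * X[s, i]
      }
  bet <- array(0, c(n, n, L))
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (l in seq_len(L)) {
        d <- structure$delays[i, j]
        if (d > 1)
          for (p in seq_len(d - 1))
            if (T_ + 1 - p >= 1)
              bet[i, j, l] <- bet[i, j, l] +
                structure$neural_decay[l]^(d - p) * X[T_ + 1 - p, i]
      }
  list(alpha = alp, gamma = gam, beta = bet)
}

# Literal term-by-term energy of neuron j: bias term, LTP term over arrived
# spikes, LTD term over queued spikes, and the reverse-direction LTD term.
oracle_energy_neuron <- function(j, x_j, state, params) {
  s <- state$structure
  n <- s$n_neurons
  e <- -params$bias[j] * x_j
  for (i in seq_len(n))
    for (k in seq_along(s$synaptic_decay))
      e <- e - params$ltp[i, j, k] * state$alpha[i, j, k] * x_j
  for (i in seq_len(n))
    for (l in seq_along(s$neural_decay))
      e <- e + params$ltd[i, j, l] * compute_beta(state, i, j, l) * x_j
  for (i in seq_len(n))
    for (l in seq_along(s$neural_decay))
      e <- e + params$ltd[j, i, l] * state$gamma[i, l] * x_j
  e
}

# Central finite differences of the one-step log-likelihood with respect to
# every parameter; returns the same shapes as compute_gradients.
fd_gradients <- function(x_t, state, params, h = 1e-5) {
  ll <- function(p) log_likelihood_step(x_t, state, p, tau = 1)
  n <- length(params$bias)
  d_bias <- numeric(n)
  for (q in seq_len(n)) {
    pp <- params; pp$bias[q] <- pp$bias[q] + h
    pm <- params; pm$bias[q] <- pm$bias[q] - h
    d_bias[q] <- (ll(pp) - ll(pm)) / (2 * h)
  }
  d_ltp <- array(0, dim(params$ltp))
  for (q in seq_along(params$ltp)) {
    pp <- params; pp$ltp[q] <- pp$ltp[q] + h
    pm <- params; pm$ltp[q] <- pm$ltp[q] - h
    d_ltp[q] <- (ll(pp) - ll(pm)) / (2 * h)
  }
  d_ltd <- array(0, dim(params$ltd))
  for (q in seq_along(params$ltd)) {
    pp <- params; pp$ltd[q] <- pp$ltd[q] + h
    pm <- params; pm$ltd[q] <- pm$ltd[q] - h
    d_ltd[q] <- (ll(pp) - ll(pm)) / (2 * h)
  }
  list(d_bias = d_bias, d_ltp = d_ltp, d_ltd = d_ltd)
}

# A small random model instance with a warmed-up state, for property tests.
random_instance <- function(n = 3, K = 2, L = 2, T_hist = 12,
                            delay_high = 5) {
  s <- random_structure(n, 1, delay_high,
                        synaptic_decay = sort(runif(K, 0.1, 0.9)),
                        neural_decay = sort(runif(L, 0.1, 0.9)))
  p <- random_parameters(s, 0, 0.3)
  st <- init_state(s)
  X <- matrix(rbinom(T_hist * n, 1, 0.5), T_hist, n)
  for (t in seq_len(T_hist)) st <- advance_state(st, X[t, ])
  list(structure = s, params = p, state = st, history = X)
}

# maximum relative error with an absolute floor for near-zero entries
max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}
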