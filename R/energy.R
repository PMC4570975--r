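#' Per-neuron energy of a candidate value
#'
#' The DyBM assigns each neuron `j` at the current step an energy that is
#' linear in its candidate value `x_j`,
#' \deqn{E_j(x_j) = -x_j \Big( b_j + \sum_{i,k} u_{i,j,k}\,\alpha_{i,j,k}
#'   - \sum_{i,l} v_{i,j,l}\,\beta_{i,j,l}
#'   - \sum_{i,l} v_{j,i,l}\,\gamma_{i,l} \Big),}
#' where the four terms are, in order: the bias (a large positive bias makes
#' spiking likely), long-term potentiation driven by spikes that have already
#' arrived (synaptic traces `alpha`), long-term depression driven by spikes
#' still in transit in the FIFO queue (`beta`), and a second depression term
#' in which `j` acts as the pre-synaptic partner and the post-synaptic
#' neuron's own recent activity (`gamma`) discourages `j` from spiking now.
#' Every term carries the factor `x_j`, so `E_j(0) = 0`.
#'
#' @param j Neuron index.
#' @param x_j Candidate value, 0 or 1.
#' @param state A `"dybm_state"`.
#' @param params A [dybm_parameters()].
#' @return Scalar energy.
#' @export
energy_neuron <- function(j, x_j, state, params) {
  stopifnot(x_j %in% c(0, 1))
  -x_j * energy_gap(state, params)[j]
}

# b_j + sum_k u.alpha - sum_l v.beta - sum_l v'.gamma for every neuron;
# equals E_j(0) - E_j(1), the log-odds of spiking at tau = 1.
energy_gap <- function(state, params) {
  s <- state$structure
  n <- s$n_neurons
  bet <- beta_tensor(state)
  ltp <- apply(params$ltp * state$alpha, 2L, sum)
  ltd_queue <- apply(params$ltd * bet, 2L, sum)
  # reverse term: for neuron j, sum over i, l of v[j, i, l] * gamma[i, l]
  ltd_rev <- vapply(seq_len(n), function(j)
    sum(params$ltd[j, , , drop = FALSE] *
          array(state$gamma, c(1L, n, ncol(state$gamma)))), numeric(1))
  params$bias + ltp - ltd_queue - ltd_rev
}

#' Total energy of a full spike vector
#'
#' The energy of the network decomposes over neurons:
#' `E(x) = sum_j energy_neuron(j, x[j], state, params)`.
#'
#' @param x Length-`N` binary vector.
#' @inheritParams energy_neuron
#' @return Scalar energy.
#' @export
energy_total <- function(x, state, params) {
  n <- state$structure$n_neurons
  if (length(x) != n) stop("'x' must have length n_neurons")
  stopifnot(all(x %in% c(0, 1)))
  -sum(as.numeric(x) * energy_gap(state, params))
}

#' Conditional spike probability of one neuron
#'
#' Given the history summarised in `state`, the neurons are conditionally
#' independent and neuron `j` spikes with probability
#' \deqn{P(x_j = 1) = \frac{e^{-E_j(1)/\tau}}{e^{-E_j(0)/\tau} + e^{-E_j(1)/\tau}},}
#' evaluated in logistic form (numerically stable for `|E|/tau` up to at
#' least `1e4`).  `tau` is the temperature; the deterministic limit
#' `tau -> 0` is provided by [generate_deterministic()] rather than here.
#'
#' @inheritParams energy_neuron
#' @param tau Temperature, strictly positive.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' s <- dybm_structure(1)
#' spike_probability(1, init_state(s), dybm_parameters(s, bias = 1))
spike_probability <- function(j, state, params, tau = 1) {
  spike_probabilities(state, params, tau)[j]
}

#' Conditional spike probabilities of all neurons
#'
#' @inheritParams spike_probability
#' @return Length-`N` numeric vector of probabilities.
#' @export
spike_probabilities <- function(state, params, tau = 1) {
  if (tau <= 0) stop("'tau' must be > 0; use generate_deterministic() for the deterministic limit")
  stats::plogis(energy_gap(state, params) / tau)
}

#' One-step log-likelihood of an observed spike vector
#'
#' `sum_j log P(x_t[j] | history)` at temperature `tau`; always `<= 0`.
#' The state is not advanced.
#'
#' @param x_t Length-`N` binary vector.
#' @inheritParams spike_probability
#' @return Scalar log-likelihood.
#' @export
log_likelihood_step <- function(x_t, state, params, tau = 1) {
  n <- state$structure$n_neurons
  x_t <- as.numeric(x_t)
  if (length(x_t) != n) stop("'x_t' must have length n_neurons")
  if (!all(x_t %in% c(0, 1))) stop("'x_t' entries must be 0 or 1")
  if (tau <= 0) stop("'tau' must be > 0")
  d <- energy_gap(state, params) / tau
  # log P(1) = -log1p(exp(-d)); log P(0) = -log1p(exp(d)); stable via plogis
  sum(stats::plogis(ifelse(x_t == 1, d, -d), log.p = TRUE))
}

#' Deterministic closed-loop generation
#'
#' Runs the model as a generator in the zero-temperature limit: at each step
#' every neuron emits 1 iff its spike probability (at `tau = 1`) is strictly
#' greater than 0.5 (ties emit 0), the emitted vector is fed back through
#' [advance_state()], and the next step proceeds from the updated traces and
#' queues.  Fully deterministic.
#'
#' @param state A `"dybm_state"` to generate from (e.g. the live state after
#'   training, or a zeroed state after presenting a cue).
#' @param params A [dybm_parameters()].
#' @param n_steps Number of steps to generate (`>= 0`).
#' @return A list with `sequence` (a [pattern_sequence()] of `n_steps` rows)
#'   and `state` (the state after generation).
#' @export
generate_deterministic <- function(state, params, n_steps) {
  stopifnot(n_steps >= 0)
  out <- .Call(`_dybm_cpp_generate`, pack_model(state$structure, params),
               pack_state(state), as.integer(n_steps))
  list(sequence = pattern_sequence(out$x),
       state = unpack_state(out$state, state$structure))
}

#' Sample one spike vector at finite temperature
#'
#' Draws each neuron independently with its conditional probability at
#' temperature `tau`, using R's random number generator.  The state is not
#' advanced; compose with [advance_state()] to run the model forward.
#'
#' @inheritParams spike_probability
#' @return Length-`N` integer vector in `{0, 1}`.
#' @export
sample_step <- function(state, params, tau = 1) {
  p <- spike_probabilities(state, params, tau)
  as.integer(stats::runif(length(p)) < p)
}
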