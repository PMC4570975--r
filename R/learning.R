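#' Per-parameter AdaGrad accumulators
#'
#' The online learning rule uses AdaGrad: each scalar parameter keeps the
#' running sum of its squared gradients, and an update with gradient `g`
#' moves the parameter by `eta0 * g / sqrt(epsilon + accumulated squares)`,
#' the accumulator including `g` itself — so every individual step is
#' bounded by `eta0` and parameters whose gradients stay large receive
#' proportionally smaller rates as training progresses.  The two
#' long-term-depression gradient components keep independent accumulators
#' and are applied sequentially, each with its own rate.
#'
#' @param structure A [dybm_structure()].
#' @param eta0 Base learning rate (default 1).
#' @param epsilon Non-negative guard added under the square root.
#' @return An object of class `"dybm_adagrad"` with accumulators `bias`,
#'   `ltp`, `ltd_a`, `ltd_b` and settings `eta0`, `epsilon`.
#' @export
adagrad_state <- function(structure, eta0 = 1, epsilon = 1e-12) {
  stopifnot(eta0 > 0, epsilon >= 0)
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  structure(
    list(bias = numeric(n),
         ltp = array(0, c(n, n, K)),
         ltd_a = array(0, c(n, n, L)),
         ltd_b = array(0, c(n, n, L)),
         eta0 = eta0, epsilon = epsilon),
    class = "dybm_adagrad")
}

#' Expected value of a neuron at the current step
#'
#' The expectation of the binary value neuron `j` generates given the
#' history, i.e. its conditional spike probability at training temperature
#' `tau = 1`.  This is the homeostatic baseline subtracted in every
#' gradient component.
#'
#' @inheritParams spike_probability
#' @return Probability in `[0, 1]`.
#' @export
expectation <- function(j, state, params) {
  spike_probability(j, state, params, tau = 1)
}

#' Exact gradients of the one-step log-likelihood
#'
#' For a presented spike vector `x_t` and the pre-presentation state (traces
#' and queues reflecting the history strictly before `t`), the gradient of
#' `log P(x_t | history)` at `tau = 1` with respect to each parameter is
#' local and exact:
#' \itemize{
#'   \item bias: `x_t[j] - <X_j>`
#'   \item LTP weight `u[i,j,k]`: `(x_t[j] - <X_j>) * alpha[i,j,k]`
#'   \item LTD, queued-spike component: `(<X_j> - x_t[j]) * beta[i,j,l]`
#'   \item LTD, reverse component: `(<X_i> - x_t[i]) * gamma[j,l]`
#' }
#' where `<X_j>` is [expectation()].  The two LTD components sum to the
#' derivative with respect to `v[i,j,l]`.  Each update thus increases the
#' likelihood of what was observed relative to what was expected —
#' potentiation when the post-synaptic neuron fires above expectation after
#' arrived spikes, depression tied to spikes still in transit and to the
#' post-synaptic neuron's own recent firing (homeostatic STDP).
#'
#' @param x_t Length-`N` binary vector presented at the current step.
#' @param state Pre-presentation `"dybm_state"`.
#' @param params A [dybm_parameters()].
#' @return A list of class `"dybm_gradients"` with components `d_bias`,
#'   `d_ltp`, `d_ltd_a`, `d_ltd_b` (shaped like their parameters) and
#'   `loglik`, the one-step log-likelihood at `x_t`.
#' @export
compute_gradients <- function(x_t, state, params) {
  s <- state$structure
  n <- s$n_neurons
  x_t <- as.numeric(x_t)
  if (length(x_t) != n) stop("'x_t' must have length n_neurons")
  if (!all(x_t %in% c(0, 1))) stop("'x_t' entries must be 0 or 1")
  p <- spike_probabilities(state, params, tau = 1)
  resid <- x_t - p                       # observed minus expected
  bet <- beta_tensor(state)
  L <- length(s$neural_decay)
  K <- length(s$synaptic_decay)
  d_ltp <- state$alpha * rep(resid, each = n)          # alpha[i,j,k]*resid[j]
  d_ltd_a <- bet * rep(-resid, each = n)               # beta[i,j,l]*(p-x)[j]
  # gamma[j,l] * (p - x)[i]: dims i, j, l
  d_ltd_b <- outer(-resid, state$gamma)                # n x n x L
  structure(
    list(d_bias = resid,
         d_ltp = array(d_ltp, c(n, n, K)),
         d_ltd_a = array(d_ltd_a, c(n, n, L)),
         d_ltd_b = array(d_ltd_b, c(n, n, L)),
         loglik = log_likelihood_step(x_t, state, params, tau = 1)),
    class = "dybm_gradients")
}

# one AdaGrad move: add g^2 to the accumulator, step by
# eta0 * g / sqrt(eps + accum); a zero gradient moves and accrues nothing
adagrad_move <- function(param, accum, g, eta0, epsilon) {
  accum <- accum + g^2
  step <- ifelse(accum > 0, eta0 * g / sqrt(accum + epsilon), 0)
  list(param = param + step, accum = accum)
}

#' Apply one gradient update
#'
#' Moves every parameter by its per-parameter AdaGrad rate times its
#' gradient component; the squared gradient enters the accumulator as part
#' of the same update, so each scalar step is at most `eta0` in magnitude.
#' The two LTD components are applied sequentially with their own rates and
#' accumulators.  With `ada = NULL` a plain fixed-rate ascent step of size
#' `rate` is taken instead.
#'
#' @param params A [dybm_parameters()].
#' @param grads A [compute_gradients()] report.
#' @param ada An [adagrad_state()], or `NULL` for plain gradient ascent.
#' @param rate Fixed step size used when `ada` is `NULL`.
#' @return A list with updated `params` and `ada`.
#' @export
apply_update <- function(params, grads, ada, rate = 1) {
  if (is.null(ada)) {
    params$bias <- params$bias + rate * grads$d_bias
    params$ltp <- params$ltp + rate * grads$d_ltp
    params$ltd <- params$ltd + rate * (grads$d_ltd_a + grads$d_ltd_b)
    return(list(params = params, ada = NULL))
  }
  e0 <- ada$eta0; eps <- ada$epsilon
  m <- adagrad_move(params$bias, ada$bias, grads$d_bias, e0, eps)
  params$bias <- m$param; ada$bias <- m$accum
  m <- adagrad_move(params$ltp, ada$ltp, grads$d_ltp, e0, eps)
  params$ltp <- m$param; ada$ltp <- m$accum
  m <- adagrad_move(params$ltd, ada$ltd_a, grads$d_ltd_a, e0, eps)
  params$ltd <- m$param; ada$ltd_a <- m$accum
  m <- adagrad_move(params$ltd, ada$ltd_b, grads$d_ltd_b, e0, eps)
  params$ltd <- m$param; ada$ltd_b <- m$accum
  list(params = params, ada = ada)
}

#' One online training step
#'
#' Presents `x_t`: computes all gradient components from the pre-update
#' parameters and pre-advance state (simultaneously), applies the update,
#' and only then advances the state with `x_t`.  Returns the one-step
#' log-likelihood of `x_t` under the pre-update model for monitoring.
#'
#' @inheritParams compute_gradients
#' @inheritParams apply_update
#' @return A list with `params`, `ada`, `state`, `loglik`.
#' @export
train_step <- function(x_t, state, params, ada, rate = 1) {
  g <- compute_gradients(x_t, state, params)
  upd <- apply_update(params, g, ada, rate)
  list(params = upd$params, ada = upd$ada,
       state = advance_state(state, x_t), loglik = g$loglik)
}
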