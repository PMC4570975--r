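#' Initialise the dynamic state of a DyBM
#'
#' The dynamic state consists of the FIFO queue contents of every synapse,
#' the synaptic eligibility traces `alpha[i, j, k]`, the neural eligibility
#' traces `gamma[j, l]` and a clock.  A fresh state is all-zero, which is
#' equivalent to having presented a blank (all-zero) sequence for a
#' sufficiently long time.
#'
#' Because every queue leaving pre-synaptic neuron `i` carries the same
#' recent values of that neuron, the queues are stored as one shared history
#' buffer per neuron, `hist[i, p] = x_i` at `p` steps in the past,
#' `p = 1, ..., max(d) - 1`; the queue of synapse `(i, j)` is the first
#' `d[i, j] - 1` entries of row `i` (tail to head).  Use [queue_contents()]
#' to read an individual queue.
#'
#' @param structure A [dybm_structure()].
#' @return An object of class `"dybm_state"`: a list with elements
#'   `structure`, `hist`, `alpha`, `gamma`, `clock`.
#' @export
#' @examples
#' st <- init_state(dybm_structure(2, delays = 5))
#' queue_contents(st, 1, 2)   # four zeros
init_state <- function(structure) {
  stopifnot(inherits(structure, "dybm_structure"))
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  dm1 <- max(structure$delays) - 1L
  structure(
    list(structure = structure,
         hist = matrix(0, n, dm1),
         alpha = array(0, c(n, n, K)),
         gamma = matrix(0, n, L),
         clock = 0L),
    class = "dybm_state")
}

#' @export
print.dybm_state <- function(x, ...) {
  cat(sprintf("DyBM state at clock %d: %d spikes in transit, |alpha| max %.3g, |gamma| max %.3g\n",
              x$clock, sum(x$hist), max(abs(x$alpha)), max(abs(x$gamma))))
  invisible(x)
}

#' Read the FIFO queue of one synapse
#'
#' @param state A [init_state()] object.
#' @param i,j Pre- and post-synaptic neuron indices.
#' @return Numeric vector of length `d[i, j] - 1`, ordered tail (most recent
#'   pre-synaptic value) to head (the value about to arrive at `j`).  Empty
#'   when `d[i, j] = 1`.
#' @export
queue_contents <- function(state, i, j) {
  d <- state$structure$delays[i, j]
  if (d == 1L) return(numeric(0))
  state$hist[i, seq_len(d - 1L)]
}

#' Queued-spike trace beta of one synapse
#'
#' `beta[i, j, l]` summarises the spikes of pre-synaptic neuron `i` that are
#' still travelling inside the FIFO queue towards `j`: a spike emitted `p`
#' steps ago (`p = 1` is the tail, `p = d - 1` the head) will arrive at `j`
#' in `d - p` steps and contributes with weight `mu_l^(d - p)`, so spikes
#' closer to the head — about to arrive — weigh more.  It is zero iff the
#' queue holds no spikes, and is computed on demand rather than stored.
#'
#' @inheritParams queue_contents
#' @param l Index of the neural decay rate `mu_l`.
#' @return Non-negative scalar.
#' @seealso [beta_tensor()] for all synapses at once.
#' @export
compute_beta <- function(state, i, j, l) {
  s <- state$structure
  n <- s$n_neurons
  if (i < 1L || i > n || j < 1L || j > n || l < 1L ||
      l > length(s$neural_decay))
    stop("index out of range")
  q <- queue_contents(state, i, j)
  if (length(q) == 0L) return(0)
  d <- s$delays[i, j]
  sum(s$neural_decay[l]^(d - seq_along(q)) * q)
}

#' All queued-spike traces as an `N x N x L` array
#'
#' @inheritParams queue_contents
#' @return Array `beta` with `beta[i, j, l] ==` [compute_beta()]`(state, i, j, l)`.
#' @export
beta_tensor <- function(state) {
  s <- state$structure
  n <- s$n_neurons
  L <- length(s$neural_decay)
  b <- array(0, c(n, n, L))
  for (l in seq_len(L))
    for (j in seq_len(n))
      for (i in seq_len(n))
        b[i, j, l] <- compute_beta(state, i, j, l)
  b
}

#' Advance the dynamic state by one time step
#'
#' Given the spike vector `x_t` observed (or generated) at the current time,
#' the state is advanced so that its traces summarise the history including
#' `x_t`: each neural trace is updated as `gamma <- mu_l * (gamma + x_t[j])`;
#' each synaptic trace receives the value arriving at the synapse this step
#' (the queue head, i.e. the pre-synaptic value from `d[i, j] - 1` steps ago,
#' or `x_t[i]` itself when `d[i, j] = 1`) via
#' `alpha <- lambda_k * (alpha + arriving)`; then every queue pops its head
#' and pushes `x_t[i]` at the tail, and the clock increments.  These
#' recursions keep the stored traces exactly equal to their defining
#' geometric sums over the full history.
#'
#' The state is a value: the modified state is returned and the input is
#' left untouched.
#'
#' @param state A `"dybm_state"`.
#' @param x_t Length-`N` vector with entries in `{0, 1}`.
#' @return The advanced `"dybm_state"`.
#' @export
advance_state <- function(state, x_t) {
  s <- state$structure
  n <- s$n_neurons
  x_t <- as.numeric(x_t)
  if (length(x_t) != n) stop("'x_t' must have length n_neurons")
  if (!all(x_t %in% c(0, 1))) stop("'x_t' entries must be 0 or 1")
  d <- s$delays
  dm1 <- ncol(state$hist)
  # value arriving at each synapse this step (queue head; x_t itself if d=1)
  arriving <- matrix(0, n, n)
  if (dm1 > 0L) {
    sel <- d > 1L
    idx <- cbind(row(d)[sel], d[sel] - 1L)
    arriving[sel] <- state$hist[idx]
  }
  arriving[d == 1L] <- x_t[row(d)[d == 1L]]
  for (k in seq_along(s$synaptic_decay))
    state$alpha[, , k] <- s$synaptic_decay[k] *
      (state$alpha[, , k, drop = TRUE] + arriving)
  if (dm1 > 0L) {
    if (dm1 > 1L) state$hist[, 2:dm1] <- state$hist[, 1:(dm1 - 1L)]
    state$hist[, 1L] <- x_t
  }
  state$gamma <- t(s$neural_decay * (t(state$gamma) + rep(x_t, each = length(s$neural_decay))))
  state$clock <- state$clock + 1L
  state
}

#' Advance a state through a whole sequence (no learning)
#'
#' Presents each row of `x` in turn with [advance_state()], optionally
#' recording the per-step log-likelihood before each advance.  This is the
#' operation used to present a cue, or to score a sequence.
#'
#' @param state A `"dybm_state"`.
#' @param x A binary `T x N` matrix (or [pattern_sequence()]).
#' @param params A [dybm_parameters()]; only needed when `loglik = TRUE`.
#' @param loglik If `TRUE`, also return the per-step log-likelihood at
#'   temperature 1.
#' @return When `loglik = FALSE`, the advanced state.  Otherwise a list with
#'   `state` and `loglik` (length-`T` numeric).
#' @export
advance_sequence <- function(state, x, params = NULL, loglik = FALSE) {
  x <- unclass_sequence(x, state$structure$n_neurons)
  if (!loglik) {
    out <- .Call(`_dybm_cpp_advance_seq`, pack_model(state$structure, params),
                 pack_state(state), x, FALSE)
    return(unpack_state(out$state, state$structure))
  }
  stopifnot(inherits(params, "dybm_parameters"))
  out <- .Call(`_dybm_cpp_advance_seq`, pack_model(state$structure, params),
               pack_state(state), x, TRUE)
  list(state = unpack_state(out$state, state$structure),
       loglik = out$loglik)
}
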