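#' Define the fixed architecture of a dynamic Boltzmann machine
#'
#' A dynamic Boltzmann machine (DyBM) is a network of `N` binary stochastic
#' neurons in which every ordered pair of neurons (including self-pairs) is
#' joined by a synapse with an integer conduction delay `d[i, j] >= 1`,
#' realised as a FIFO queue of length `d[i, j] - 1`.  Each neuron keeps `L`
#' neural eligibility traces (decay rates `mu`) summarising its own spiking
#' history, and each synapse keeps `K` synaptic eligibility traces (decay
#' rates `lambda`) summarising the spikes that have already traversed the
#' queue.  The structure is fixed before learning and never changes.
#'
#' @param n_neurons Number of neurons `N` (positive integer).
#' @param delays Either a single integer (used for every ordered pair) or an
#'   `N x N` integer matrix of conduction delays; `delays[i, j]` is the delay
#'   from pre-synaptic neuron `i` to post-synaptic neuron `j`.  All entries
#'   must be `>= 1`.
#' @param synaptic_decay Numeric vector `lambda` of length `K >= 1`, each in
#'   `[0, 1)`.
#' @param neural_decay Numeric vector `mu` of length `L >= 1`, each in
#'   `[0, 1)`.
#' @param temperature Non-negative default temperature `tau`; `0` denotes the
#'   deterministic (thresholding) limit used for closed-loop generation.
#'
#' @return An object of class `"dybm_structure"`: a list with elements
#'   `n_neurons`, `delays`, `synaptic_decay`, `neural_decay`, `temperature`.
#' @seealso [random_structure()] for the delay-sampling constructor used in
#'   the experiments, [init_state()], [dybm()].
#' @export
#' @examples
#' s <- dybm_structure(3, delays = 2)
#' s$delays
dybm_structure <- function(n_neurons, delays = 1L,
                           synaptic_decay = c(0.25, 0.5, 0.75),
                           neural_decay = c(0.25, 0.5, 0.75),
                           temperature = 1) {
  n_neurons <- as.integer(n_neurons)
  stopifnot(length(n_neurons) == 1L, n_neurons >= 1L)
  if (length(delays) == 1L)
    delays <- matrix(as.integer(delays), n_neurons, n_neurons)
  delays <- matrix(as.integer(delays), n_neurons, n_neurons)
  if (any(is.na(delays)) || any(delays < 1L))
    stop("all conduction delays must be integers >= 1")
  synaptic_decay <- as.numeric(synaptic_decay)
  neural_decay <- as.numeric(neural_decay)
  if (length(synaptic_decay) < 1L || any(synaptic_decay < 0) ||
      any(synaptic_decay >= 1))
    stop("'synaptic_decay' must have length >= 1 with entries in [0, 1)")
  if (length(neural_decay) < 1L || any(neural_decay < 0) ||
      any(neural_decay >= 1))
    stop("'neural_decay' must have length >= 1 with entries in [0, 1)")
  stopifnot(length(temperature) == 1L, temperature >= 0)
  structure(
    list(n_neurons = n_neurons, delays = delays,
         synaptic_decay = synaptic_decay, neural_decay = neural_decay,
         temperature = as.numeric(temperature)),
    class = "dybm_structure")
}

#' @export
print.dybm_structure <- function(x, ...) {
  cat(sprintf("DyBM structure: %d neurons, %d synapses (dense incl. self)\n",
              x$n_neurons, x$n_neurons^2))
  cat(sprintf("  conduction delays: %d..%d\n", min(x$delays), max(x$delays)))
  cat(sprintf("  synaptic decay lambda (K=%d): %s\n",
              length(x$synaptic_decay),
              paste(format(x$synaptic_decay), collapse = ", ")))
  cat(sprintf("  neural decay mu (L=%d): %s\n", length(x$neural_decay),
              paste(format(x$neural_decay), collapse = ", ")))
  invisible(x)
}

#' Construct or validate a set of learnable DyBM parameters
#'
#' The learnable parameters are the per-neuron bias `b[j]`, the LTP
#' (long-term potentiation) weights `u[i, j, k]` (one per synapse and
#' synaptic decay rate) and the LTD (long-term depression) weights
#' `v[i, j, l]` (one per synapse and neural decay rate).
#'
#' @param structure A [dybm_structure()].
#' @param bias Length-`N` numeric vector; default all zero.
#' @param ltp `N x N x K` numeric array; default all zero.
#' @param ltd `N x N x L` numeric array; default all zero.
#' @return An object of class `"dybm_parameters"`: a list with elements
#'   `bias`, `ltp`, `ltd`.
#' @seealso [random_parameters()] for the normal initialisation used before
#'   training.
#' @export
dybm_parameters <- function(structure, bias = NULL, ltp = NULL, ltd = NULL) {
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  if (is.null(bias)) bias <- numeric(n)
  if (is.null(ltp)) ltp <- array(0, c(n, n, K))
  if (is.null(ltd)) ltd <- array(0, c(n, n, L))
  bias <- as.numeric(bias)
  ltp <- array(as.numeric(ltp), c(n, n, K))
  ltd <- array(as.numeric(ltd), c(n, n, L))
  if (length(bias) != n)
    stop("'bias' must have length n_neurons")
  if (!all(is.finite(bias), is.finite(ltp), is.finite(ltd)))
    stop("all parameters must be finite")
  structure(list(bias = bias, ltp = ltp, ltd = ltd),
            class = "dybm_parameters")
}

#' @export
print.dybm_parameters <- function(x, ...) {
  cat(sprintf(
    "DyBM parameters: %d biases, %d LTP weights, %d LTD weights\n",
    length(x$bias), length(x$ltp), length(x$ltd)))
  cat(sprintf("  |b| in [%.3g, %.3g], |u| max %.3g, |v| max %.3g\n",
              min(abs(x$bias)), max(abs(x$bias)),
              max(abs(x$ltp)), max(abs(x$ltd))))
  invisible(x)
}

n_parameters <- function(structure) {
  n <- structure$n_neurons
  n + n * n * length(structure$synaptic_decay) +
    n * n * length(structure$neural_decay)
}
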