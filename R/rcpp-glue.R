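# Converters between the R-level S3 objects and the flat lists the C++
# training kernels take.  Kept internal; the C++ side never sees classes.

pack_model <- function(structure, params = NULL) {
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  if (is.null(params)) params <- dybm_parameters(structure)
  list(n = n, K = K, L = L,
       delays = structure$delays,
       lambda = structure$synaptic_decay,
       mu = structure$neural_decay,
       b = params$bias, u = params$ltp, v = params$ltd)
}

pack_state <- function(state) {
  list(hist = state$hist, alpha = state$alpha, gamma = state$gamma,
       clock = state$clock)
}

unpack_state <- function(lst, structure) {
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  structure(
    list(structure = structure,
         hist = matrix(as.numeric(lst$hist), n, max(structure$delays) - 1L),
         alpha = array(as.numeric(lst$alpha), c(n, n, K)),
         gamma = matrix(as.numeric(lst$gamma), n, L),
         clock = as.integer(lst$clock)),
    class = "dybm_state")
}

unpack_params <- function(lst, structure) {
  dybm_parameters(structure, bias = lst$b, ltp = lst$u, ltd = lst$v)
}

pack_ada <- function(ada) {
  list(ab = ada$bias, au = ada$ltp, ava = ada$ltd_a, avb = ada$ltd_b,
       eta0 = ada$eta0, eps = ada$epsilon)
}

unpack_ada <- function(lst, structure, eta0, epsilon) {
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  structure(
    list(bias = as.numeric(lst$ab),
         ltp = array(as.numeric(lst$au), c(n, n, K)),
         ltd_a = array(as.numeric(lst$ava), c(n, n, L)),
         ltd_b = array(as.numeric(lst$avb), c(n, n, L)),
         eta0 = eta0, epsilon = epsilon),
    class = "dybm_adagrad")
}

# strip a pattern_sequence down to a checked integer matrix
unclass_sequence <- function(x, n_neurons = NULL) {
  if (inherits(x, "pattern_sequence")) x <- x$values
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("sequence entries must be 0 or 1")
  if (!is.null(n_neurons) && ncol(x) != n_neurons)
    stop(sprintf("sequence has %d columns but the model has %d neurons",
                 ncol(x), n_neurons))
  storage.mode(x) <- "integer"
  x
}
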