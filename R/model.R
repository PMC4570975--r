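#' Fit a dynamic Boltzmann machine to a periodic binary sequence
#'
#' Trains a DyBM online to memorise `x`: one period of the sequence is
#' presented per training period, each spike vector triggering an exact
#' gradient update of the bias, LTP and LTD weights (AdaGrad step sizes,
#' training temperature 1), and the eligibility traces and FIFO queues are
#' advanced with every presented vector.  At period 0 and after every
#' `check_every` periods the live state is cloned and the model generates
#' two periods deterministically; training stops at the first bit-exact
#' reproduction of the target, or when `max_periods` is exhausted.
#'
#' Conduction delays are sampled uniformly from `delay_range` and initial
#' parameters from Normal(0, `init_sd`), using sub-seeds derived from
#' `seed` (see [seed_streams()]), so a fit is fully reproducible.
#'
#' @param x A periodic [pattern_sequence()] (e.g. from [render_text()]), or
#'   a binary `T x N` matrix whose full length is taken as the period.
#' @param max_periods Training budget (default 130000).
#' @param check_every Periods between convergence checks (default 10).
#' @param delay_range Inclusive integer bounds for the uniform conduction
#'   delays (default `c(1, 9)`).
#' @param synaptic_decay,neural_decay Trace decay rates (defaults
#'   `c(0.25, 0.5, 0.75)` each).
#' @param init_sd Standard deviation of the normal parameter
#'   initialisation (default 0.1).
#' @param eta0 AdaGrad base learning rate (default 1).
#' @param seed Integer seed; default 1.
#' @param structure Optionally a ready-made [dybm_structure()] (then
#'   `delay_range` and the decay arguments are ignored).
#' @param params Optionally ready-made initial [dybm_parameters()].
#' @return An object of class `"dybm"`: a list with elements `structure`,
#'   `params`, `state` (live state at the end of training), `adagrad`,
#'   `target` (the training sequence), `loglik` (summed log-likelihood per
#'   presented period), `periods_used`, `converged`, `seed`, `call`.
#' @seealso [predict.dybm()], [simulate.dybm()], [nll_profile()],
#'   [train_alternating()] for storing two sequences.
#' @export
#' @examples
#' # memorise a short two-letter sequence (a few seconds)
#' fit <- dybm(render_text("SC"), max_periods = 20000, seed = 1)
#' fit$converged
dybm <- function(x, max_periods = 130000L, check_every = 10L,
                 delay_range = c(1L, 9L),
                 synaptic_decay = c(0.25, 0.5, 0.75),
                 neural_decay = c(0.25, 0.5, 0.75),
                 init_sd = 0.1, eta0 = 1, seed = 1L,
                 structure = NULL, params = NULL) {
  cl <- match.call()
  if (!inherits(x, "pattern_sequence"))
    x <- pattern_sequence(x, period = nrow(as.matrix(x)))
  if (is.null(x$period)) x$period <- nrow(x$values)
  n <- ncol(x$values)
  seeds <- seed_streams(seed)
  if (is.null(structure)) {
    set.seed(seeds[["delays"]])
    structure <- random_structure(n, delay_range[1], delay_range[2],
                                  synaptic_decay, neural_decay)
  }
  if (is.null(params)) {
    set.seed(seeds[["params"]])
    params <- random_parameters(structure, 0, init_sd)
  }
  ada <- adagrad_state(structure, eta0 = eta0)
  fit <- train_until_memorized(x, structure, params, ada,
                               max_periods = max_periods,
                               check_every = check_every)
  structure(
    list(structure = structure, params = fit$params, state = fit$state,
         adagrad = fit$ada, target = x, loglik = fit$loglik,
         periods_used = fit$periods_used, converged = fit$converged,
         seed = as.integer(seed), call = cl),
    class = "dybm")
}

#' @export
print.dybm <- function(x, ...) {
  cat("Dynamic Boltzmann machine\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  s <- x$structure
  cat(sprintf("  %d neurons, delays %d..%d, K=%d, L=%d (%d learnable parameters)\n",
              s$n_neurons, min(s$delays), max(s$delays),
              length(s$synaptic_decay), length(s$neural_decay),
              n_parameters(s)))
  if (!is.null(x$converged))
    cat(sprintf("  %s after %d training periods\n",
                if (isTRUE(x$converged)) "memorised target" else
                  "NOT converged (budget exhausted)",
                x$periods_used))
  invisible(x)
}

#' @export
summary.dybm <- function(object, ...) {
  out <- list(model = object,
              final_loglik = if (length(object$loglik))
                utils::tail(object$loglik, 1L) else NA_real_,
              bias_range = range(object$params$bias),
              ltp_range = range(object$params$ltp),
              ltd_range = range(object$params$ltd))
  class(out) <- "summary.dybm"
  out
}

#' @export
print.summary.dybm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  last presented period log-likelihood: %.4f\n",
              x$final_loglik))
  cat(sprintf("  bias in [%.3f, %.3f], LTP in [%.3f, %.3f], LTD in [%.3f, %.3f]\n",
              x$bias_range[1], x$bias_range[2], x$ltp_range[1],
              x$ltp_range[2], x$ltd_range[1], x$ltd_range[2]))
  invisible(x)
}

#' @export
coef.dybm <- function(object, ...) {
  list(bias = object$params$bias, ltp = object$params$ltp,
       ltd = object$params$ltd)
}

#' @export
logLik.dybm <- function(object, ...) {
  # log-likelihood of one period of the target, scored from a clone of the
  # live training state (the protocol under which the model was monitored)
  prof <- nll_profile(object$params, object$structure, object$target,
                      object$state)
  val <- -sum(prof$nll)
  attr(val, "df") <- n_parameters(object$structure)
  attr(val, "nobs") <- nrow(object$target$values)
  class(val) <- "logLik"
  val
}

#' Predict spike probabilities or anomaly scores for a sequence
#'
#' Presents `newdata` step by step (no learning) and returns either the
#' conditional spike probability of every neuron before each step, or the
#' per-step negative log-likelihood (the anomaly score of [nll_profile()]).
#'
#' @param object A fitted [dybm()].
#' @param newdata Binary `T x N` matrix or [pattern_sequence()]; default
#'   the training target.
#' @param type `"prob"` for a `T x N` matrix of probabilities, `"nll"` for
#'   an [nll_profile()].
#' @param from Start from a zeroed state (`"zero"`, default) or a clone of
#'   the live post-training state (`"live"`).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.dybm <- function(object, newdata = NULL,
                         type = c("prob", "nll"),
                         from = c("zero", "live"), ...) {
  type <- match.arg(type)
  from <- match.arg(from)
  if (is.null(newdata)) newdata <- object$target
  xm <- unclass_sequence(newdata, object$structure$n_neurons)
  st <- if (from == "live") object$state else init_state(object$structure)
  if (type == "nll")
    return(nll_profile(object$params, object$structure, xm, st))
  probs <- matrix(NA_real_, nrow(xm), ncol(xm))
  for (t in seq_len(nrow(xm))) {
    probs[t, ] <- spike_probabilities(st, object$params, tau = 1)
    st <- advance_state(st, xm[t, ])
  }
  probs
}

#' Generate sequences from a fitted DyBM
#'
#' Deterministic closed-loop generation (the zero-temperature limit) or
#' finite-temperature sampling.  With a `cue`, the traces and queues are
#' zeroed, the cue is presented, and only the continuation is returned —
#' associative retrieval.  Without a cue, generation starts from a clone of
#' the live post-training state (`from = "live"`, the memorisation
#' protocol) or from a zeroed state.
#'
#' @param object A fitted [dybm()].
#' @param nsim Number of sequences (only meaningful for stochastic
#'   generation; deterministic runs return a single sequence).
#' @param seed Optional integer seed for stochastic generation.
#' @param n_steps Steps to generate; default two periods of the target.
#' @param cue Optional cue sequence.
#' @param from `"live"` (default) or `"zero"` starting state when no cue is
#'   given.
#' @param tau Temperature: `0` (default) for deterministic thresholding,
#'   `> 0` for sampling.
#' @param ... Unused.
#' @return A [pattern_sequence()], or a list of them when `nsim > 1` and
#'   `tau > 0`.
#' @export
simulate.dybm <- function(object, nsim = 1, seed = NULL, n_steps = NULL,
                          cue = NULL, from = c("live", "zero"), tau = 0,
                          ...) {
  from <- match.arg(from)
  if (is.null(n_steps))
    n_steps <- 2L * (if (!is.null(object$target$period))
      object$target$period else nrow(object$target$values))
  if (!is.null(cue)) {
    cm <- unclass_sequence(cue, object$structure$n_neurons)
    st <- advance_sequence(init_state(object$structure), cm)
  } else {
    st <- if (from == "live") object$state else init_state(object$structure)
  }
  if (tau == 0)
    return(generate_deterministic(st, object$params, n_steps)$sequence)
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(nsim), function(s) {
    sti <- st
    out <- matrix(0L, n_steps, object$structure$n_neurons)
    for (t in seq_len(n_steps)) {
      out[t, ] <- sample_step(sti, object$params, tau)
      sti <- advance_state(sti, out[t, ])
    }
    pattern_sequence(out)
  })
  if (nsim == 1L) sims[[1]] else sims
}

#' @export
fitted.dybm <- function(object, ...) {
  predict(object, type = "prob", from = "live")
}

#' @export
residuals.dybm <- function(object, ...) {
  unclass_sequence(object$target) - fitted(object)
}

#' Plot training progress or an anomaly profile
#'
#' `type = "training"` plots the per-period negative log-likelihood of the
#' presented target over training periods (log x-axis); `type = "sequence"`
#' draws the target and a two-period deterministic generation from the live
#' state as stacked bitmaps.
#'
#' @param x A fitted [dybm()].
#' @param type `"training"` or `"sequence"`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.dybm <- function(x, type = c("training", "sequence"), ...) {
  type <- match.arg(type)
  if (type == "training") {
    if (!length(x$loglik)) {
      warning("no training trace recorded")
      return(invisible(x))
    }
    graphics::plot(seq_along(x$loglik), -x$loglik, type = "l", log = "x",
                   xlab = "training period",
                   ylab = "NLL of presented period", ...)
    return(invisible(x))
  }
  gen <- simulate(x)
  tgt <- x$target$values
  img <- rbind(t(tgt[rep(seq_len(nrow(tgt)), length.out = nrow(gen$values)), ]),
               matrix(0L, 1L, nrow(gen$values)),
               t(gen$values))
  graphics::image(seq_len(ncol(img)), seq_len(nrow(img)),
                  t(img[rev(seq_len(nrow(img))), ]),
                  col = c("white", "black"), axes = FALSE,
                  xlab = "time step", ylab = "target / generated", ...)
  invisible(x)
}
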