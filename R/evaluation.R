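#' Per-step negative log-likelihood profile of a sequence
#'
#' Scores each spike vector of `seq` under the model without learning: at
#' each step the negative log-likelihood `-log P(x_t | history)` is
#' recorded at temperature 1, and the traces and queues are then advanced
#' with `x_t` before the next step is scored.  A high value flags a pattern
#' the model finds surprising given what preceded it — the anomaly score.
#'
#' The caller chooses the starting state: the live post-training state
#' (as in the anomaly experiment, where the scored sequence continues the
#' training stream) or a zeroed state.
#'
#' @param params A [dybm_parameters()].
#' @param structure A [dybm_structure()].
#' @param seq Non-empty binary `T x N` matrix or [pattern_sequence()].
#' @param initial_state Optional `"dybm_state"`; default [init_state()].
#' @return An object of class `"nll_profile"`: a data frame with columns
#'   `step` (the time indices scored, continuing `initial_state$clock`) and
#'   `nll` (non-negative reals).  The final state is attached as attribute
#'   `"state"`.
#' @export
nll_profile <- function(params, structure, seq, initial_state = NULL) {
  xm <- unclass_sequence(seq, structure$n_neurons)
  if (nrow(xm) == 0L) stop("'seq' must be non-empty")
  if (is.null(initial_state)) initial_state <- init_state(structure)
  out <- advance_sequence(initial_state, xm, params, loglik = TRUE)
  prof <- data.frame(step = initial_state$clock + seq_len(nrow(xm)),
                     nll = -out$loglik)
  class(prof) <- c("nll_profile", "data.frame")
  attr(prof, "state") <- out$state
  prof
}

#' @export
print.nll_profile <- function(x, ...) {
  cat(sprintf("NLL profile over %d steps: median %.4g, max %.4g at step %d\n",
              nrow(x), stats::median(x$nll), max(x$nll),
              x$step[which.max(x$nll)]))
  invisible(x)
}

#' @export
plot.nll_profile <- function(x, ...) {
  graphics::plot(x$step, x$nll, type = "h", xlab = "time step",
                 ylab = "negative log-likelihood", ...)
  invisible(x)
}
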