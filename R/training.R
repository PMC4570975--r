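#' Train online on repeated presentations of a sequence
#'
#' Presents the rows of `x` in order, `n_reps` times, performing one
#' [train_step()] per row (gradients from pre-update parameters, then
#' AdaGrad update, then state advance).  The heavy loop runs in compiled
#' code; it is step-for-step equivalent to composing [train_step()].
#'
#' @param x Binary `T x N` matrix or [pattern_sequence()].
#' @param state Live `"dybm_state"` (training continues from it).
#' @param params A [dybm_parameters()].
#' @param ada An [adagrad_state()].
#' @param n_reps Number of complete presentations of `x`.
#' @return A list with `params`, `ada`, `state` and `loglik`, the summed
#'   log-likelihood of each presentation (length `n_reps`).
#' @export
train_sequence <- function(x, state, params, ada, n_reps = 1L) {
  xm <- unclass_sequence(x, state$structure$n_neurons)
  out <- .Call(`_dybm_cpp_train_seq`, pack_model(state$structure, params),
               pack_state(state), pack_ada(ada), xm, as.integer(n_reps))
  finish_training(out, state$structure, ada)
}

finish_training <- function(out, structure, ada) {
  res <- list(params = unpack_params(out$model, structure),
              ada = unpack_ada(out$ada, structure, ada$eta0, ada$epsilon),
              state = unpack_state(out$state, structure))
  extra <- setdiff(names(out), c("model", "ada", "state"))
  c(res, out[extra])
}

#' Memorise a periodic sequence by online training
#'
#' Repeatedly presents one period of the target per training period.  At
#' period 0 and after every `check_every` periods, the live state is cloned
#' and the model generates `2 * period` steps deterministically
#' (closed-loop, [generate_deterministic()]); training stops as soon as the
#' generation reproduces two consecutive periods of the target bit for bit,
#' aligned to the phase following the last presented step.  The eligibility
#' traces and queues are not refreshed for the check — the training history
#' itself serves as the cue, as in the memorisation experiment.
#'
#' @param target A periodic [pattern_sequence()] (its `period` must be set
#'   and is presented once per training period).
#' @param structure A [dybm_structure()].
#' @param params,ada Optional initial parameters / AdaGrad state; defaults
#'   are Normal(0, 0.1) parameters (drawn with the current RNG) and fresh
#'   accumulators with `eta0 = 1`.
#' @param max_periods Training budget; exhausting it returns
#'   `converged = FALSE` rather than an error.
#' @param check_every Periods between convergence checks.
#' @return A list with `params`, `ada`, `state` (live, as left by training),
#'   `periods_used`, `converged`, and `loglik` (summed log-likelihood of
#'   each presented period).
#' @export
train_until_memorized <- function(target, structure, params = NULL,
                                  ada = NULL, max_periods = 130000L,
                                  check_every = 10L) {
  stopifnot(inherits(target, "pattern_sequence"))
  if (is.null(target$period)) stop("'target' must have a period")
  xm <- unclass_sequence(target, structure$n_neurons)
  if (nrow(xm) != target$period)
    xm <- xm[seq_len(target$period), , drop = FALSE]
  if (is.null(params)) params <- random_parameters(structure)
  if (is.null(ada)) ada <- adagrad_state(structure)
  out <- .Call(`_dybm_cpp_train_until_memorized`,
               pack_model(structure, params),
               pack_state(init_state(structure)), pack_ada(ada), xm,
               as.integer(max_periods), as.integer(check_every))
  finish_training(out, structure, ada)
}

#' Retrieve a stored sequence from a cue
#'
#' Zeroes the dynamic state (equivalent to a long blank presentation),
#' presents the cue step by step without learning, then generates
#' `n_steps` deterministically and returns only the generated continuation.
#'
#' @param params A [dybm_parameters()].
#' @param structure A [dybm_structure()].
#' @param cue Non-empty binary matrix or [pattern_sequence()].
#' @param n_steps Steps to generate after the cue.
#' @return A [pattern_sequence()] of `n_steps` rows.
#' @export
retrieve_with_cue <- function(params, structure, cue, n_steps) {
  cm <- unclass_sequence(cue, structure$n_neurons)
  if (nrow(cm) == 0L) stop("'cue' must be non-empty")
  st <- advance_sequence(init_state(structure), cm)
  generate_deterministic(st, params, n_steps)$sequence
}

#' Alternating training of two sequences with cue-based stopping
#'
#' Stores two periodic sequences in one model.  Iteration 1 trains on
#' `seq_a` (the "forward" sequence), iteration 2 on `seq_b`, and so on
#' alternately.  Within an iteration, training periods of the scheduled
#' sequence are presented until its cue-based retrieval succeeds: the
#' retrieval check zeroes the traces and queues, presents the cue, generates
#' one period deterministically, and requires an exact bit match with the
#' period of the target that follows the cue.  The check runs before the
#' first period of the iteration and after every `check_every` periods.
#' The whole procedure terminates when, at the end of an iteration, both
#' cues retrieve their sequences — i.e. learning the most recent sequence no
#' longer erases the other — or when a budget runs out.
#'
#' @param seq_a,seq_b Periodic [pattern_sequence()]s over the same neurons.
#' @param cue_a,cue_b Non-empty cues; each must be a prefix of (one period
#'   of) its sequence.
#' @param structure A [dybm_structure()].
#' @param params,ada As in [train_until_memorized()].
#' @param max_iterations Iteration budget.
#' @param max_periods_per_iteration Period budget within one iteration;
#'   exhausting it ends the run with `converged = FALSE`.
#' @param check_every Periods between retrieval checks.
#' @return A list with `params`, `ada`, `state`, `periods_per_iteration`
#'   (integer vector, the relearning-speed curve), `iterations_used`, and
#'   `converged`.
#' @export
train_alternating <- function(seq_a, seq_b, cue_a, cue_b, structure,
                              params = NULL, ada = NULL,
                              max_iterations = 1000L,
                              max_periods_per_iteration = 200000L,
                              check_every = 10L) {
  a <- unclass_sequence(seq_a, structure$n_neurons)
  b <- unclass_sequence(seq_b, structure$n_neurons)
  ca <- unclass_sequence(cue_a, structure$n_neurons)
  cb <- unclass_sequence(cue_b, structure$n_neurons)
  if (nrow(ca) == 0L || nrow(cb) == 0L) stop("cues must be non-empty")
  pa <- if (!is.null(seq_a$period)) seq_a$period else nrow(a)
  pb <- if (!is.null(seq_b$period)) seq_b$period else nrow(b)
  a <- a[seq_len(pa), , drop = FALSE]
  b <- b[seq_len(pb), , drop = FALSE]
  if (is.null(params)) params <- random_parameters(structure)
  if (is.null(ada)) ada <- adagrad_state(structure)
  out <- .Call(`_dybm_cpp_train_alternating`,
               pack_model(structure, params),
               pack_state(init_state(structure)), pack_ada(ada),
               a, b, ca, cb, as.integer(max_iterations),
               as.integer(max_periods_per_iteration),
               as.integer(check_every))
  finish_training(out, structure, ada)
}

#' Check cue-based retrieval of a periodic target
#'
#' Zero state, present `cue`, generate one period, compare bit-for-bit with
#' the continuation of `target` after the cue (the target is treated as
#' periodic, so a cue of any prefix length is allowed).
#'
#' @inheritParams retrieve_with_cue
#' @param target Periodic [pattern_sequence()] the cue should retrieve.
#' @return Logical: `TRUE` iff retrieval is exact over one full period.
#' @export
cue_retrieves <- function(params, structure, cue, target) {
  tm <- unclass_sequence(target, structure$n_neurons)
  p <- if (!is.null(target$period)) target$period else nrow(tm)
  tm <- tm[seq_len(p), , drop = FALSE]
  cm <- unclass_sequence(cue, structure$n_neurons)
  gen <- retrieve_with_cue(params, structure, cm, p)
  expect <- tm[(nrow(cm) + seq_len(p) - 1L) %% p + 1L, , drop = FALSE]
  mismatch_count(gen, expect) == 0L
}
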