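#' Read and write plain-text spike sequences
#'
#' The `.seq.txt` format has one line per time step of `N` characters from
#' `{0, 1}` with no separators, optionally preceded by a header line
#' `#N=<n> period=<p>`.
#'
#' @param path File path.
#' @return `read_sequence()` returns a [pattern_sequence()].
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  period <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    h <- lines[1]
    m <- regmatches(h, regexec("period=([0-9]+)", h))[[1]]
    if (length(m) == 2L) period <- as.integer(m[2])
    lines <- lines[-1]
  }
  lines <- lines[nchar(lines) > 0]
  if (!length(lines))
    return(pattern_sequence(matrix(integer(0), 0L, 0L)))
  if (length(unique(nchar(lines))) != 1L)
    stop("all sequence lines must have equal length")
  vals <- do.call(rbind, lapply(strsplit(lines, ""), function(r) {
    if (!all(r %in% c("0", "1"))) stop("sequence characters must be 0 or 1")
    as.integer(r)
  }))
  pattern_sequence(vals, period = period)
}

#' @rdname read_sequence
#' @param seq A [pattern_sequence()] or binary matrix.
#' @param header Whether to write the `#N= period=` header line.
#' @export
write_sequence <- function(seq, path, header = TRUE) {
  p <- if (inherits(seq, "pattern_sequence")) seq$period else NULL
  v <- unclass_sequence(seq)
  lines <- apply(v, 1L, paste, collapse = "")
  if (header)
    lines <- c(sprintf("#N=%d%s", ncol(v),
                       if (is.null(p)) "" else sprintf(" period=%d", p)),
               lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write text bitmaps
#'
#' The `.bmp.txt` format is an image: `R` lines of equal length over
#' `{0, 1}` (or `{., #}`), rows being neurons top to bottom and columns
#' time steps.  Reading transposes into a [pattern_sequence()].
#'
#' @param path File path.
#' @return `read_bitmap()` returns a [pattern_sequence()] whose period is
#'   the number of columns of the image.
#' @export
read_bitmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nchar(lines) > 0]
  if (length(unique(nchar(lines))) != 1L)
    stop("all bitmap rows must have equal length")
  img <- do.call(rbind, lapply(strsplit(lines, ""), function(r) {
    if (!all(r %in% c("0", "1", ".", "#")))
      stop("bitmap cells must be 0/1 or ./#")
    as.integer(r %in% c("1", "#"))
  }))
  pattern_sequence(t(img), period = ncol(img))
}

#' @rdname read_bitmap
#' @param seq A [pattern_sequence()] or binary matrix.
#' @param chars Two characters used for off/on cells.
#' @export
write_bitmap <- function(seq, path, chars = c(".", "#")) {
  v <- t(unclass_sequence(seq))       # neurons as rows
  writeLines(apply(v, 1L, function(r)
    paste(chars[r + 1L], collapse = "")), path)
  invisible(path)
}

#' Save and restore a model checkpoint
#'
#' Checkpoints are JSON text holding the structure (neuron count, delays,
#' decay rates), the learnable parameters, and optionally the dynamic state
#' (queues, traces, clock), the AdaGrad accumulators and the seed used.
#' Numbers are written at full precision so a round trip is bit-exact.
#'
#' @param model A fitted [dybm()] object, or a list with at least elements
#'   `structure` and `params` (elements `state`, `adagrad`, `seed`,
#'   `periods_used`, `converged` are saved when present).
#' @param path File path.
#' @export
write_dybm <- function(model, path) {
  s <- model$structure
  obj <- list(
    format = "dybm-checkpoint-1",
    structure = list(n_neurons = s$n_neurons, delays = s$delays,
                     synaptic_decay = s$synaptic_decay,
                     neural_decay = s$neural_decay,
                     temperature = s$temperature),
    parameters = list(bias = model$params$bias,
                      ltp = as.vector(model$params$ltp),
                      ltd = as.vector(model$params$ltd)))
  if (!is.null(model$state))
    obj$state <- list(hist = as.vector(model$state$hist),
                      alpha = as.vector(model$state$alpha),
                      gamma = as.vector(model$state$gamma),
                      clock = model$state$clock)
  if (!is.null(model$adagrad))
    obj$adagrad <- list(bias = as.vector(model$adagrad$bias),
                        ltp = as.vector(model$adagrad$ltp),
                        ltd_a = as.vector(model$adagrad$ltd_a),
                        ltd_b = as.vector(model$adagrad$ltd_b),
                        eta0 = model$adagrad$eta0,
                        epsilon = model$adagrad$epsilon)
  for (f in c("seed", "periods_used", "converged"))
    if (!is.null(model[[f]])) obj[[f]] <- model[[f]]
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dybm
#' @return `read_dybm()` returns a list of class `"dybm"` with elements
#'   `structure`, `params` and, when present in the file, `state`,
#'   `adagrad`, `seed`, `periods_used`, `converged`.
#' @export
read_dybm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dybm-checkpoint-1")
    stop("not a dybm checkpoint file")
  st <- obj$structure
  s <- dybm_structure(st$n_neurons,
                      delays = matrix(st$delays, st$n_neurons, st$n_neurons),
                      synaptic_decay = st$synaptic_decay,
                      neural_decay = st$neural_decay,
                      temperature = st$temperature)
  model <- list(structure = s,
                params = unpack_params(
                  list(b = obj$parameters$bias, u = obj$parameters$ltp,
                       v = obj$parameters$ltd), s))
  if (!is.null(obj$state))
    model$state <- unpack_state(
      list(hist = obj$state$hist, alpha = obj$state$alpha,
           gamma = obj$state$gamma, clock = obj$state$clock), s)
  if (!is.null(obj$adagrad))
    model$adagrad <- unpack_ada(
      list(ab = obj$adagrad$bias, au = obj$adagrad$ltp,
           ava = obj$adagrad$ltd_a, avb = obj$adagrad$ltd_b),
      s, obj$adagrad$eta0, obj$adagrad$epsilon)
  for (f in c("seed", "periods_used", "converged"))
    if (!is.null(obj[[f]])) model[[f]] <- obj[[f]]
  class(model) <- "dybm"
  model
}
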