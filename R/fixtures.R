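#' The packaged 5x7 glyph font
#'
#' Loads the block font shipped with the package (letters S, C, I, E, N; 7
#' rows by 5 columns each, no inter-letter spacing, so "SCIENCE" occupies
#' exactly 7 x 35 cells).  The glyphs are fixture data, not code: every
#' bit-level target in the package is defined relative to this file.  The
#' letter "I" is left-right symmetric, so the mirror image of "I" is "I"
#' itself — a property the dual-sequence retrieval experiment relies on.
#'
#' @param path Optional path to an alternative font file in the same format
#'   (record = character line followed by seven lines of five `#`/`.` cells).
#' @return Named list of 7x5 binary matrices, class `"dybm_font"`.
#' @export
#' @examples
#' f <- dybm_font()
#' names(f)
dybm_font <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "font5x7.txt", package = "dybm",
                        mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]   # comment lines
  lines <- lines[nchar(trimws(lines)) > 0]
  glyphs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ch <- trimws(lines[i])
    if (nchar(ch) != 1L)
      stop(sprintf("malformed font file near line: '%s'", lines[i]))
    rows <- lines[(i + 1L):(i + 7L)]
    if (any(nchar(rows) != 5L)) stop("glyph rows must be 5 cells wide")
    g <- t(vapply(strsplit(rows, ""), function(r)
      as.integer(r %in% c("#", "1")), integer(5)))
    glyphs[[ch]] <- g
    i <- i + 8L
  }
  structure(glyphs, class = "dybm_font")
}

#' Render text as a spike-pattern sequence
#'
#' Concatenates the glyph bitmaps of `text` left to right and reads the
#' result column-wise: column `t` of the image becomes the spike vector at
#' time `t`, with the top row mapping to neuron 1.  The period of the
#' resulting sequence is its total number of columns, so `"SCIENCE"` yields
#' a 35-step sequence over 7 neurons.
#'
#' @param text Character string; every character must be in the font.
#' @param font A [dybm_font()].
#' @return A [pattern_sequence()] with `period` set to the number of steps.
#' @export
#' @examples
#' dim(render_text("SCIENCE"))
render_text <- function(text, font = dybm_font()) {
  chars <- strsplit(text, "")[[1]]
  missing <- setdiff(chars, names(font))
  if (length(missing))
    stop(sprintf("characters not in font: %s",
                 paste(unique(missing), collapse = ", ")))
  if (length(chars) == 0L)
    return(pattern_sequence(matrix(integer(0), 0L, 7L)))
  img <- do.call(cbind, font[chars])            # 7 rows x 5*len columns
  pattern_sequence(t(img), period = ncol(img))
}

#' Time-reverse a pattern sequence
#'
#' Reverses the order of the spike vectors (the columns of the bitmap);
#' the neuron order is unchanged.  Applying it twice recovers the input.
#'
#' @param seq A [pattern_sequence()] or binary matrix.
#' @return A [pattern_sequence()].
#' @export
mirror_sequence <- function(seq) {
  p <- if (inherits(seq, "pattern_sequence")) seq$period else NULL
  v <- unclass_sequence(seq)
  pattern_sequence(v[rev(seq_len(nrow(v))), , drop = FALSE], period = p)
}

#' The anomalous "SCIENSESCIENCE" sequence
#'
#' Renders the 70-column sequence "SCIENSESCIENCE": two copies of
#' "SCIENCE" in which the second "C" of the first copy (columns 26-30) is
#' replaced by "S".  Presented to a model trained on "SCIENCE", the
#' replaced glyph is the anomaly the negative log-likelihood profile should
#' flag.
#'
#' @param font A [dybm_font()].
#' @return A [pattern_sequence()] of 70 steps over 7 neurons.
#' @export
make_anomalous_science <- function(font = dybm_font()) {
  render_text("SCIENSESCIENCE", font)
}

#' Sample a model structure with uniform conduction delays
#'
#' All `N^2` ordered neuron pairs (self-pairs included) are connected, each
#' with a conduction delay drawn independently and uniformly from the
#' integers `delay_low..delay_high` (default 1..9).  Three synaptic and
#' three neural eligibility traces per connection, with decay rates 0.25,
#' 0.5 and 0.75, unless overridden.
#'
#' @param n_neurons Number of neurons.
#' @param delay_low,delay_high Inclusive integer delay bounds.
#' @param synaptic_decay,neural_decay Decay-rate vectors, as in
#'   [dybm_structure()].
#' @return A [dybm_structure()].
#' @export
random_structure <- function(n_neurons, delay_low = 1L, delay_high = 9L,
                             synaptic_decay = c(0.25, 0.5, 0.75),
                             neural_decay = c(0.25, 0.5, 0.75)) {
  stopifnot(delay_low >= 1L, delay_low <= delay_high)
  d <- matrix(sample(delay_low:delay_high, n_neurons^2, replace = TRUE),
              n_neurons, n_neurons)
  dybm_structure(n_neurons, delays = d, synaptic_decay = synaptic_decay,
                 neural_decay = neural_decay)
}

#' Sample initial learnable parameters
#'
#' Every bias and weight is drawn independently from a normal distribution,
#' by default mean 0 and standard deviation 0.1 — the initialisation used
#' before training.
#'
#' @param structure A [dybm_structure()].
#' @param mean,sd Normal parameters (`sd >= 0`).
#' @return A [dybm_parameters()].
#' @export
random_parameters <- function(structure, mean = 0, sd = 0.1) {
  stopifnot(sd >= 0)
  n <- structure$n_neurons
  K <- length(structure$synaptic_decay)
  L <- length(structure$neural_decay)
  dybm_parameters(
    structure,
    bias = stats::rnorm(n, mean, sd),
    ltp = array(stats::rnorm(n * n * K, mean, sd), c(n, n, K)),
    ltd = array(stats::rnorm(n * n * L, mean, sd), c(n, n, L)))
}

#' Random i.i.d. Bernoulli test sequence
#'
#' @param n_neurons,n_steps Shape of the sequence.
#' @param density Spike probability per entry, in `[0, 1]`.
#' @return A [pattern_sequence()].
#' @export
random_sequence <- function(n_neurons, n_steps, density = 0.5) {
  stopifnot(density >= 0, density <= 1)
  pattern_sequence(matrix(
    as.integer(stats::runif(n_steps * n_neurons) < density),
    n_steps, n_neurons))
}

#' Derive named sub-seeds from one master seed
#'
#' Experiments draw three independent kinds of randomness: conduction
#' delays, initial parameters, and (optionally) finite-temperature
#' sampling.  To keep each individually reproducible, one master seed is
#' expanded into named sub-seeds with a fixed congruential scramble; set
#' the relevant sub-seed with `set.seed()` before each draw.
#'
#' @param seed Master integer seed.
#' @return Named integer vector with elements `delays`, `params`,
#'   `sampling`.
#' @export
seed_streams <- function(seed) {
  seed <- as.integer(seed)
  scramble <- function(k) {
    x <- (as.double(seed) * 69069 + 12345 * k + 1) %% 2147483647
    as.integer(x)
  }
  c(delays = scramble(1), params = scramble(2), sampling = scramble(3))
}
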