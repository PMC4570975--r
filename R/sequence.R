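#' Binary spike-pattern sequences
#'
#' A pattern sequence is a `T x N` matrix with entries in `{0, 1}`: row `t`
#' is the spike vector presented (or generated) at time `t`, column `j` is
#' neuron `j`.  For periodic targets the period can be attached; `T` must
#' then be a multiple of it.
#'
#' @param values `T x N` binary matrix (or anything coercible to one).
#' @param period Optional positive integer period.
#' @return An object of class `"pattern_sequence"`: a list with elements
#'   `values` and `period`.
#' @export
#' @examples
#' ps <- pattern_sequence(diag(3), period = 3)
#' print(ps)
pattern_sequence <- function(values, period = NULL) {
  values <- as.matrix(values)
  if (length(values) && !all(values %in% c(0, 1)))
    stop("sequence entries must be 0 or 1")
  storage.mode(values) <- "integer"
  if (!is.null(period)) {
    period <- as.integer(period)
    stopifnot(period >= 1L)
    if (nrow(values) %% period != 0L)
      stop("sequence length must be a multiple of its period")
  }
  structure(list(values = values, period = period),
            class = "pattern_sequence")
}

#' @export
dim.pattern_sequence <- function(x) dim(x$values)

#' @export
print.pattern_sequence <- function(x, ...) {
  cat(sprintf("pattern sequence: %d steps x %d neurons%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$period)) "" else sprintf(" (period %d)", x$period)))
  if (nrow(x$values) > 0L && ncol(x$values) > 0L) {
    bm <- t(x$values)          # neurons as rows, time as columns
    for (r in seq_len(nrow(bm)))
      cat(paste(ifelse(bm[r, ] == 1L, "#", "."), collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Hamming distance between two equally shaped sequences
#'
#' The number of differing bits over all `T x N` positions; 0 iff the
#' sequences are identical.  This is the criterion by which a generated
#' sequence is declared to match its target.
#'
#' @param generated,target Two sequences (matrices or
#'   [pattern_sequence()] objects) of identical shape.
#' @return Non-negative integer count.
#' @export
mismatch_count <- function(generated, target) {
  a <- unclass_sequence(generated)
  b <- unclass_sequence(target)
  if (!identical(dim(a), dim(b))) stop("sequences must have identical shape")
  sum(a != b)
}
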