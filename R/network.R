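# Single-layer feed-forward threshold-neuron network.
#
# Output neuron i receives every input j through a real-valued synaptic
# weight w[i, j]; its internal state is the weighted input sum and its
# binary output is a hard threshold on that sum.  Dynamics are synchronous:
# within a time step all internal states are computed from the same
# pre-update weights.

#' Initialize a synaptic weight matrix with i.i.d. uniform entries
#'
#' @param n_out Number of output neurons (rows).
#' @param n_in Number of input neurons (columns); defaults to `n_out`
#'   (square network).
#' @param low,high Bounds of the uniform initial distribution; default
#'   \[0, 1). A nonnegative start reflects purely excitatory feed-forward
#'   connections.
#' @param seed Optional integer seed; same seed, same matrix.
#' @return An `n_out x n_in` numeric matrix.
#' @export
init_weights <- function(n_out, n_in = n_out, low = 0, high = 1,
                         seed = NULL) {
  stopifnot(n_out >= 1L, n_in >= 1L)
  if (!(low < high)) {
    stop("invalid range: `low` must be strictly less than `high`",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  matrix(stats::runif(n_out * n_in, min = low, max = high), n_out, n_in)
}

#' Internal state of every output neuron for one input frame
#'
#' `s_i = sum_j w[i, j] * x[j]` — the postsynaptic membrane potential of
#' neuron `i` given the binary input frame `x`.
#'
#' @param w Weight matrix, rows = output neurons.
#' @param x Binary input vector of length `ncol(w)`.
#' @return Numeric vector of internal states, one per output neuron.
#' @export
internal_state <- function(w, x) {
  if (ncol(w) != length(x)) {
    stop("dimension mismatch: ncol(w) = ", ncol(w),
         " but length(x) = ", length(x), call. = FALSE)
  }
  as.vector(w %*% as.numeric(x))
}

#' Threshold output function
#'
#' `y_i = 1` iff `s_i - eta >= 0`; the boundary case `s_i == eta` fires.
#'
#' @param s Numeric vector of internal states.
#' @param eta Firing threshold.
#' @return Integer 0/1 vector of outputs.
#' @export
fire <- function(s, eta) {
  as.integer(s - eta >= 0)
}

#' Data-scaled default firing threshold
#'
#' The median of the internal states for the first input frame: about half
#' of the output neurons fire initially, which keeps the winner set
#' nondegenerate at any weight scale.  Computed once at the first frame of a
#' run and then frozen.
#'
#' @param w Weight matrix.
#' @param x First input frame.
#' @return A single threshold value.
#' @export
auto_threshold <- function(w, x) {
  stats::median(internal_state(w, x))
}
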