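# The two synaptic learning rules.
#
# Hebbian rule (HEBLR): if output neuron i fires (s_i >= eta), every synapse
# from an active input (x_j = 1) onto i is potentiated by a fixed increment
# dw; nothing else changes.  Learning is gated by postsynaptic firing.
#
# Spatiotemporal rule (STLR): learning is independent of postsynaptic
# firing.  Each active synapse carries a coincidence coefficient I[i, j]
# measuring how strongly input j arrives together with the other coactive
# inputs converging on neuron i; I is compared against two thresholds
# (theta1 > theta2) in a BCM-like fashion: I >= theta1 potentiates (+dw,
# "enhancement"), I <= theta2 depresses (-dw, "attenuation"), and values in
# between leave the weight unchanged ("invariance").  Weights are not
# clipped at zero, so attenuation can drive them negative.

#' Hebbian rule configuration
#'
#' @param dw Weight increment per potentiation event (> 0).
#' @param eta Firing threshold, or `"auto"` for the data-scaled default
#'   (median internal state at the first frame, then frozen).
#' @return A list of class `hebb_config`.
#' @export
hebb_config <- function(dw = 0.3, eta = "auto") {
  stopifnot(is.numeric(dw), dw > 0)
  structure(list(rule = "heblr", dw = dw, eta = eta), class = "hebb_config")
}

#' STLR configuration
#'
#' @param dw Weight increment/decrement magnitude (> 0).
#' @param theta1,theta2 Upper (LTP) and lower (LTD) thresholds on the
#'   coincidence coefficient, with `theta1 > theta2`; or `"auto"` for
#'   percentile-derived defaults frozen at the first training step (see
#'   [run_experiment()]).
#' @param coincidence_form `"approximate"` (`I = w * x / s`, the operative
#'   form) or `"exact"` (`I = w * x * sum of the other coactive drive`).
#' @param normalized Threshold in the unit-sphere-normalized space
#'   (`I~ = w~ * s~`, the default) or on the raw coincidence coefficient.
#' @param theta_probs Percentiles (lower, upper) used when thresholds are
#'   `"auto"`: thresholds are set to these quantiles of the coincidence
#'   coefficient over active synapses at the first frame.
#' @return A list of class `stlr_config`.
#' @export
stlr_config <- function(dw = 0.3, theta1 = "auto", theta2 = "auto",
                        coincidence_form = c("approximate", "exact"),
                        normalized = TRUE, theta_probs = c(0.4, 0.6)) {
  coincidence_form <- match.arg(coincidence_form)
  stopifnot(is.numeric(dw), dw > 0)
  if (is.numeric(theta1) && is.numeric(theta2) && !(theta1 > theta2)) {
    stop("threshold ordering violation: need theta1 > theta2", call. = FALSE)
  }
  stopifnot(length(theta_probs) == 2L, theta_probs[1] < theta_probs[2])
  structure(list(rule = "stlr", dw = dw, theta1 = theta1, theta2 = theta2,
                 coincidence_form = coincidence_form,
                 normalized = normalized, theta_probs = theta_probs),
            class = "stlr_config")
}

#' One Hebbian update step
#'
#' For every output neuron with `s_i >= eta` and every active input
#' (`x_j = 1`), the weight `w[i, j]` is incremented by `dw`.  All other
#' entries are unchanged; the update never decreases a weight.
#'
#' @param w Weight matrix.
#' @param x Binary input frame.
#' @param dw Increment (> 0).
#' @param eta Firing threshold (numeric).
#' @return The updated weight matrix.
#' @export
heblr_update <- function(w, x, dw, eta) {
  s <- internal_state(w, x)
  firing <- s - eta >= 0
  active <- x == 1
  if (any(firing) && any(active)) {
    w[firing, active] <- w[firing, active] + dw
  }
  w
}

#' Coincidence coefficient matrix for the STLR
#'
#' Entry `[i, j]` measures the cooperative activity meeting input `j` at
#' neuron `i`; it is zero wherever `x[j] == 0`.
#'
#' Forms:
#' * `"exact"`: `I[i,j] = w[i,j] x[j] * (s_i - w[i,j] x[j])`, i.e. the
#'   synaptic drive times the summed drive of all *other* active inputs.
#' * `"approximate"`: `I[i,j] = w[i,j] x[j] / s_i`, valid when the network
#'   is large and input firing is not sparse (`s_i` dominates any single
#'   synapse).  Rows with `s_i == 0` are defined as all-zero and a warning
#'   is issued.
#'
#' With `normalized = TRUE` the unit-sphere projection is used instead:
#' `I~[i,j] = w~[i,j] * s~_i` on active synapses, where `w~` is the
#' row-normalized weight vector and `s~_i` the normalized internal state
#' (see [normalize_vectors()]).  Zero-norm weight rows yield a zero row and
#' a warning.
#'
#' @param w Weight matrix.
#' @param x Binary input frame.
#' @param form `"approximate"` (default) or `"exact"`.
#' @param normalized Use the unit-sphere normalized coefficient.
#' @return Matrix of coincidence coefficients, same shape as `w`.
#' @export
stlr_coincidence <- function(w, x, form = c("approximate", "exact"),
                             normalized = FALSE) {
  form <- match.arg(form)
  if (ncol(w) != length(x)) {
    stop("dimension mismatch: ncol(w) = ", ncol(w),
         " but length(x) = ", length(x), call. = FALSE)
  }
  xa <- as.numeric(x)

  if (normalized) {
    norms <- sqrt(rowSums(w^2))
    bad <- norms == 0
    if (any(bad)) {
      warning("zero-norm weight row(s): normalized coincidence set to 0 for ",
              sum(bad), " neuron(s)")
      norms[bad] <- 1
    }
    w_t <- w / norms
    x_norm <- sqrt(sum(xa^2))
    if (x_norm == 0) return(matrix(0, nrow(w), ncol(w)))
    s_t <- as.vector(w_t %*% (xa / x_norm))
    s_t[bad] <- 0
    ii <- (w_t * s_t) * rep(xa, each = nrow(w))
    return(ii)
  }

  drive <- w * rep(xa, each = nrow(w))   # w[i,j] * x[j]
  s <- as.vector(drive %*% rep(1, ncol(w)))
  if (form == "exact") {
    ii <- drive * (s - drive)
    # inactive synapses contribute zero drive, so ii is already 0 there
    ii[, xa == 0] <- 0
    ii
  } else {
    zero <- s == 0
    if (any(zero)) {
      warning("internal state is 0 for ", sum(zero),
              " neuron(s); approximate coincidence set to 0 on those rows")
      s[zero] <- 1
    }
    ii <- drive / s
    ii[zero, ] <- 0
    ii
  }
}

#' One STLR update step
#'
#' Only synapses from active inputs (`x[j] = 1`) change.  Among those, the
#' coincidence coefficient decides the branch: `I >= theta1` gives `+dw`
#' (enhancement), `I <= theta2` gives `-dw` (attenuation), and values
#' strictly between leave the weight unchanged (invariance).  Weights are
#' not clipped, so repeated attenuation can make them negative.
#'
#' @param w Weight matrix.
#' @param x Binary input frame.
#' @param dw Increment/decrement magnitude (> 0).
#' @param theta1,theta2 Numeric thresholds, `theta1 > theta2`.
#' @param form Coincidence form, see [stlr_coincidence()].
#' @param normalized Threshold the unit-sphere-normalized coefficient
#'   (default) or the raw one.
#' @return The updated weight matrix.
#' @export
stlr_update <- function(w, x, dw, theta1, theta2,
                        form = c("approximate", "exact"),
                        normalized = TRUE) {
  form <- match.arg(form)
  if (!(theta1 > theta2)) {
    stop("threshold ordering violation: need theta1 > theta2", call. = FALSE)
  }
  ii <- stlr_coincidence(w, x, form = form, normalized = normalized)
  active <- rep(x == 1, each = nrow(w))
  dim(active) <- dim(w)
  w + dw * (active & ii >= theta1) - dw * (active & ii <= theta2)
}

#' Unit-sphere normalization of an input frame and one weight row
#'
#' Projects the input vector and a neuron's afferent weight vector onto the
#' unit sphere and returns the normalized internal state, the cosine
#' between them: `x~ = x / ||x||`, `w~ = w_row / ||w_row||`,
#' `s~ = sum_j w~_j x~_j`, with `|s~| <= 1` (and `s~ >= 0` whenever both
#' vectors are nonnegative).
#'
#' @param x Input frame (binary or real), nonzero norm.
#' @param w_row One row of the weight matrix, nonzero norm.
#' @return A list with `x_tilde`, `w_tilde` and `s_tilde`.
#' @export
normalize_vectors <- function(x, w_row) {
  if (length(x) != length(w_row)) {
    stop("dimension mismatch between input frame and weight row",
         call. = FALSE)
  }
  xn <- sqrt(sum(x^2))
  wn <- sqrt(sum(w_row^2))
  if (xn == 0 || wn == 0) {
    stop("normalization undefined for zero-norm vectors", call. = FALSE)
  }
  x_tilde <- x / xn
  w_tilde <- w_row / wn
  list(x_tilde = x_tilde, w_tilde = w_tilde,
       s_tilde = sum(w_tilde * x_tilde))
}

#' Normalized coincidence coefficients for one neuron
#'
#' `I~_j = w~_j * s~`: a straight line through the origin in the
#' (`w~`, `I~`) plane with slope `s~`.  The restriction to active inputs is
#' the caller's responsibility (multiply by `x` or subset).
#'
#' @param w_tilde Row-normalized weight vector (from [normalize_vectors()]).
#' @param s_tilde Normalized internal state of the neuron.
#' @return Numeric vector of normalized coincidence coefficients.
#' @export
normalized_coincidence <- function(w_tilde, s_tilde) {
  w_tilde * s_tilde
}

#' Classify neurons into coincidence regions R1/R2/R3
#'
#' A neuron's normalized internal state `s~` fixes which STLR branches its
#' active synapses can reach: `R1` (`s~ >= theta1`) reaches enhancement,
#' invariance and attenuation; `R2` (`theta1 > s~ > theta2`) only
#' invariance and attenuation; `R3` (`s~ <= theta2`) only attenuation.
#' Boundaries are inclusive towards R1 and R3.
#'
#' @param s_tilde Numeric vector of normalized internal states.
#' @param theta1,theta2 Thresholds, `theta1 > theta2`.
#' @return Character vector of labels `"R1"`, `"R2"`, `"R3"`.
#' @export
classify_regions <- function(s_tilde, theta1, theta2) {
  if (!(theta1 > theta2)) {
    stop("threshold ordering violation: need theta1 > theta2", call. = FALSE)
  }
  ifelse(s_tilde >= theta1, "R1", ifelse(s_tilde <= theta2, "R3", "R2"))
}
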