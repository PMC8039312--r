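# Weight-distribution diagnostics.
#
# The trained network is characterized through the pooled distribution of
# synaptic weights (raw, or after per-neuron unit-sphere normalization),
# the number and location of modes in that distribution, and the per-neuron
# fractions of active synapses falling in each STLR branch
# (enhancement q / invariance r / attenuation p, with q + r + p = 1).

#' Pooled histogram of synaptic weights
#'
#' Pools entries of the weight matrix — raw by default, or after row-wise
#' unit-sphere normalization — and bins them into `n_bins` equal-width
#' bins.  An optional column mask restricts pooling to the synapses that
#' the training sequence could actually touch (those from inputs active at
#' least once); synapses from never-active inputs carry no information
#' about the learning rule and otherwise contribute a large untrained
#' background.
#'
#' @param w Weight matrix (non-empty).
#' @param source `"raw"` (default) or `"normalized"` (pool
#'   `w[i,j] / ||W_i||`).
#' @param n_bins Number of bins (>= 2).
#' @param range Optional length-2 numeric giving the bin range; defaults to
#'   the data range.
#' @param columns Optional logical or integer vector selecting the input
#'   columns to pool over; default all.
#' @return An object of class `weight_distribution`: list with `bin_edges`
#'   (length `n_bins + 1`, strictly increasing), `counts` (length
#'   `n_bins`, summing to the number of pooled weights), `mids` and
#'   `source`.
#' @export
weight_histogram <- function(w, source = c("raw", "normalized"),
                             n_bins = 50L, range = NULL, columns = NULL) {
  source <- match.arg(source)
  if (length(w) == 0L) stop("empty weight matrix", call. = FALSE)
  stopifnot(n_bins >= 2L)
  if (source == "normalized") {
    norms <- sqrt(rowSums(w^2))
    norms[norms == 0] <- 1
    w <- w / norms
  }
  if (!is.null(columns)) w <- w[, columns, drop = FALSE]
  if (length(w) == 0L) stop("no columns selected", call. = FALSE)
  vals <- as.vector(w)
  if (is.null(range)) {
    range <- base::range(vals)
    if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  counts <- tabulate(
    findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE),
    nbins = n_bins
  )
  structure(list(bin_edges = edges, counts = counts,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 source = source),
            class = "weight_distribution")
}

#' @export
print.weight_distribution <- function(x, ...) {
  cat("<weight_distribution> ", length(x$counts), " bins over [",
      signif(x$bin_edges[1], 4), ", ", signif(max(x$bin_edges), 4),
      "], n = ", sum(x$counts), ", source = ", x$source, "\n", sep = "")
  invisible(x)
}

moving_average <- function(v, window) {
  # centered moving average, zero-padded: the empirical density is zero
  # outside the histogram support, so mass at the support boundary tapers
  # rather than being artificially flattened
  n <- length(v)
  half <- window %/% 2L
  padded <- c(rep(0, half), v, rep(0, half))
  vapply(seq_len(n), function(i) mean(padded[i:(i + 2L * half)]),
         numeric(1))
}

peak_prominences <- function(y, peaks) {
  # topographic prominence of each local maximum: height minus the higher
  # of the two valley floors separating it from taller terrain; a side with
  # no samples (peak on the boundary) does not constrain the prominence
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    if (length(left) == 0L) {
      left_base <- -Inf
    } else {
      higher_l <- which(left > h)
      from <- if (length(higher_l)) max(higher_l) + 1L else 1L
      left_base <- if (from > length(left)) h else min(left[from:length(left)])
    }
    right <- if (p < length(y)) y[(p + 1L):length(y)] else numeric(0)
    if (length(right) == 0L) {
      right_base <- -Inf
    } else {
      higher_r <- which(right > h)
      to <- if (length(higher_r)) min(higher_r) - 1L else length(right)
      right_base <- if (to == 0L) h else min(right[seq_len(to)])
    }
    base <- max(left_base, right_base)
    if (!is.finite(base)) h else h - base
  }, numeric(1))
}

#' Count modes of a weight distribution
#'
#' Smooths the histogram counts with a centered moving average (counts are
#' zero outside the histogram support, so boundary mass tapers), finds
#' local maxima (plateaus count once, at their leftmost bin), computes
#' each maximum's topographic prominence, and keeps peaks whose prominence
#' is at least `min_prominence_frac` times the maximum smoothed count.
#' The procedure is deterministic and invariant to rescaling all counts by
#' a positive constant.
#'
#' @param d A `weight_distribution`.
#' @param smooth_window Moving-average window in bins (default 5).
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   maximum smoothed count, in (0, 1). Default 0.1.
#' @return An object of class `mode_report`: list with `n_modes`,
#'   `mode_locations` (bin midpoints, ascending), `prominences`, `heights`
#'   (smoothed), and the parameters used.
#' @export
count_modes <- function(d, smooth_window = 5L, min_prominence_frac = 0.1) {
  stopifnot(inherits(d, "weight_distribution"))
  stopifnot(smooth_window >= 1L,
            min_prominence_frac > 0, min_prominence_frac < 1)
  nb <- length(d$counts)
  if (smooth_window > nb) {
    stop("smoothing window (", smooth_window,
         ") exceeds histogram length (", nb, ")", call. = FALSE)
  }
  sm <- moving_average(as.numeric(d$counts), smooth_window)

  # local maxima; runs of equal values are one candidate at the run start
  cand <- integer(0)
  i <- 1L
  while (i <= nb) {
    j <- i
    while (j < nb && sm[j + 1L] == sm[i]) j <- j + 1L
    left_ok <- i == 1L || sm[i - 1L] < sm[i]
    right_ok <- j == nb || sm[j + 1L] < sm[i]
    if (left_ok && right_ok && sm[i] > 0) cand <- c(cand, i)
    i <- j + 1L
  }
  if (length(cand) == 0L) {
    return(structure(list(n_modes = 0L, mode_locations = numeric(0),
                          prominences = numeric(0), heights = numeric(0),
                          smooth_window = smooth_window,
                          min_prominence_frac = min_prominence_frac),
                     class = "mode_report"))
  }
  prom <- peak_prominences(sm, cand)
  keep <- prom >= min_prominence_frac * max(sm)
  cand <- cand[keep]
  prom <- prom[keep]
  structure(list(n_modes = length(cand),
                 mode_locations = d$mids[cand],
                 prominences = prom,
                 heights = sm[cand],
                 smooth_window = smooth_window,
                 min_prominence_frac = min_prominence_frac),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  cat("<mode_report> ", x$n_modes, " mode(s)", sep = "")
  if (x$n_modes > 0) {
    cat(" at ", paste(signif(x$mode_locations, 3), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' The k most prominent modes of a mode report
#'
#' @param report A `mode_report`.
#' @param k How many modes to return (default 2).
#' @return Locations of the (up to) `k` modes with largest prominence,
#'   in ascending location order.
#' @export
dominant_modes <- function(report, k = 2L) {
  stopifnot(inherits(report, "mode_report"))
  if (report$n_modes == 0L) return(numeric(0))
  ord <- order(report$prominences, decreasing = TRUE)
  sort(report$mode_locations[ord[seq_len(min(k, report$n_modes))]])
}

#' Per-neuron STLR branch fractions (q / r / p)
#'
#' For each output neuron, the fractions of its *active* synapses whose
#' coincidence coefficient falls in the enhancement (`I >= theta1`),
#' invariance (`theta2 < I < theta1`) and attenuation (`I <= theta2`)
#' branches.  The three fractions sum to exactly 1 for every neuron with at
#' least one active synapse; neurons with none get `NA` in all three.
#'
#' @param ii Coincidence matrix (raw or normalized), as from
#'   [stlr_coincidence()].
#' @param x Binary input frame.
#' @param theta1,theta2 Thresholds, `theta1 > theta2`.
#' @return A data.frame with columns `neuron`, `q`, `r`, `p`.
#' @export
subset_fractions <- function(ii, x, theta1, theta2) {
  if (!(theta1 > theta2)) {
    stop("threshold ordering violation: need theta1 > theta2", call. = FALSE)
  }
  if (ncol(ii) != length(x)) {
    stop("dimension mismatch between coincidence matrix and input frame",
         call. = FALSE)
  }
  active <- x == 1
  n_active <- sum(active)
  n_out <- nrow(ii)
  if (n_active == 0L) {
    return(data.frame(neuron = seq_len(n_out), q = NA_real_, r = NA_real_,
                      p = NA_real_))
  }
  ia <- ii[, active, drop = FALSE]
  q <- rowSums(ia >= theta1) / n_active
  p <- rowSums(ia <= theta2) / n_active
  r <- rowSums(ia < theta1 & ia > theta2) / n_active
  data.frame(neuron = seq_len(n_out), q = q, r = r, p = p)
}

#' Predicted per-neuron Hebbian step magnitude
#'
#' The total weight change of neuron `i` in one Hebbian step is the number
#' of potentiated synapses times the increment: `y_i * sum(x) * dw`.  This
#' closed form matches the observed row sum of `heblr_update(w, x) - w`
#' exactly.
#'
#' @param x Binary input frame.
#' @param y Binary output vector.
#' @param dw Increment.
#' @return Numeric vector of per-neuron total weight changes.
#' @export
hebbian_step_magnitude <- function(x, y, dw) {
  if (any(!y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  as.numeric(y) * sum(x) * dw
}

#' Cosine similarity of each weight row to each stored pattern
#'
#' Measures where each neuron's afferent weight vector has moved relative
#' to the pattern set: the matrix of cosines, each neuron's best-matching
#' pattern, and the distribution of those assignments.  Under
#' discrimination-style learning the assignments spread over several
#' patterns; under completion-style learning they concentrate.
#'
#' @param w Weight matrix; rows must have nonzero norm.
#' @param ps A `pattern_set` with `ps$n == ncol(w)`.
#' @return A list with `cosines` (`nrow(w) x k`), `assignment` (index of the
#'   best-matching pattern per neuron, ties to the first) and `table`
#'   (assignment counts per pattern).
#' @export
weight_input_similarity <- function(w, ps) {
  stopifnot(inherits(ps, "pattern_set"))
  if (ncol(w) != ps$n) {
    stop("dimension mismatch: ncol(w) = ", ncol(w), " but patterns have ",
         "length ", ps$n, call. = FALSE)
  }
  wn <- sqrt(rowSums(w^2))
  if (any(wn == 0)) stop("zero-norm weight row", call. = FALSE)
  pn <- sqrt(rowSums(ps$patterns^2))
  cosines <- (w %*% t(ps$patterns)) / outer(wn, pn)
  assignment <- max.col(cosines, ties.method = "first")
  tab <- tabulate(assignment, nbins = ps$k)
  names(tab) <- paste0("A", seq_len(ps$k))
  list(cosines = cosines, assignment = assignment, table = tab)
}

#' Pairwise Hamming distances between output vectors
#'
#' Completion maps similar training sequences to nearly identical outputs
#' (small distances); discrimination maps them to distinct outputs (large
#' distances).
#'
#' @param outputs A list of equal-length binary vectors, or a matrix with
#'   one output vector per row.
#' @return A symmetric integer matrix of pairwise Hamming distances with a
#'   zero diagonal.
#' @export
output_discrimination_matrix <- function(outputs) {
  if (is.list(outputs)) {
    len <- vapply(outputs, length, integer(1))
    if (length(unique(len)) != 1L) {
      stop("output vectors must have equal length", call. = FALSE)
    }
    outputs <- do.call(rbind, outputs)
  }
  m <- nrow(outputs)
  d <- matrix(0L, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (b > a) {
        d[a, b] <- d[b, a] <- hamming_distance(outputs[a, ], outputs[b, ])
      }
    }
  }
  d
}

mean_offdiag <- function(d) {
  m <- nrow(d)
  if (m < 2L) return(NA_real_)
  sum(d) / (m * (m - 1L))
}
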