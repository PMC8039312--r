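# Naive per-element reference implementations, kept deliberately loop-based
# and independent of the vectorized package code paths.

oracle_internal_state <- function(w, x) {
  s <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    acc <- 0
    for (j in seq_len(ncol(w))) acc <- acc + w[i, j] * x[j]
    s[i] <- acc
  }
  s
}

oracle_heblr <- function(w, x, dw, eta) {
  s <- oracle_internal_state(w, x)
  out <- w
  for (i in seq_len(nrow(w))) {
    if (s[i] - eta >= 0) {
      for (j in seq_len(ncol(w))) {
        if (x[j] == 1) out[i, j] <- w[i, j] + dw
      }
    }
  }
  out
}

oracle_coincidence <- function(w, x, form = "approximate",
                               normalized = FALSE) {
  n_out <- nrow(w)
  n_in <- ncol(w)
  ii <- matrix(0, n_out, n_in)
  if (normalized) {
    xn <- sqrt(sum(x^2))
    for (i in seq_len(n_out)) {
      wn <- sqrt(sum(w[i, ]^2))
      st <- 0
      for (j in seq_len(n_in)) st <- st + (w[i, j] / wn) * (x[j] / xn)
      for (j in seq_len(n_in)) {
        if (x[j] == 1) ii[i, j] <- (w[i, j] / wn) * st
      }
    }
    return(ii)
  }
  s <- oracle_internal_state(w, x)
  for (i in seq_len(n_out)) {
    for (j in seq_len(n_in)) {
      if (x[j] == 1) {
        if (form == "exact") {
          other <- 0
          for (m in seq_len(n_in)) {
            if (m != j) other <- other + w[i, m] * x[m]
          }
          ii[i, j] <- w[i, j] * x[j] * other
        } else {
          ii[i, j] <- if (s[i] == 0) 0 else w[i, j] * x[j] / s[i]
        }
      }
    }
  }
  ii
}

oracle_stlr <- function(w, x, dw, theta1, theta2, form = "approximate",
                        normalized = FALSE) {
  ii <- oracle_coincidence(w, x, form, normalized)
  out <- w
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (x[j] == 1) {
        if (ii[i, j] >= theta1) {
          out[i, j] <- w[i, j] + dw
        } else if (ii[i, j] <= theta2) {
          out[i, j] <- w[i, j] - dw
        }
      }
    }
  }
  out
}

random_instance <- function(n_out = 8L, n_in = 8L, p_active = 0.5) {
  list(w = matrix(runif(n_out * n_in, 0.05, 1), n_out, n_in),
       x = rbinom(n_in, 1L, p_active))
}

# histogram fixture from raw values
hist_from_values <- function(vals, n_bins = 50L) {
  weight_histogram(matrix(vals, nrow = 1L), source = "raw", n_bins = n_bins)
}
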