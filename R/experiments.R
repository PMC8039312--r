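# Experiment orchestration: the rule x context training protocol.
#
# One experiment = generate a pattern set, build a training sequence
# (same or different context), initialize uniform weights, resolve the
# data-scaled thresholds at the first frame, apply one learning-rule update
# per frame, and collect weight-distribution diagnostics before and after
# training.  A grid runs the four rule x context conditions with shared
# initial weights and a shared pattern set.

derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

#' Build and validate an experiment configuration
#'
#' Captures the full study condition: network/pattern geometry, learning
#' rule and its parameters, training context, and analysis settings.
#' Thresholds given as `"auto"` are resolved from the data at the first
#' training frame and then frozen (see [run_experiment()]); the resolved
#' values are echoed in the result so a run can be reproduced exactly.
#'
#' @param n Network size (inputs = outputs).
#' @param k Number of spatial patterns in the set.
#' @param hd Pairwise Hamming distance between patterns.
#' @param ones_count Ones per pattern (default `n/2`).
#' @param t_len Number of training frames (one weight update per frame).
#' @param rule `"heblr"` or `"stlr"`.
#' @param context `"same"` (one pattern repeated) or `"different"` (a
#'   sequence of distinct patterns).
#' @param dw Learning increment/decrement magnitude.
#' @param eta Firing threshold, or `"auto"` (median internal state at the
#'   first frame).
#' @param theta1,theta2 STLR thresholds, or `"auto"`
#'   (quantiles `theta_probs` of the coincidence coefficient over active
#'   synapses at the first frame).
#' @param theta_probs Quantile pair (lower, upper) for auto thresholds.
#' @param coincidence_form `"approximate"` or `"exact"`.
#' @param normalized Threshold the unit-sphere normalized coincidence
#'   coefficient (default) or the raw one.
#' @param w_low,w_high Uniform range for initial weights.
#' @param n_bins,smooth_window,min_prominence_frac Histogram and
#'   mode-detection parameters, see [weight_histogram()] and
#'   [count_modes()].
#' @param hist_source `"raw"` (default) or `"normalized"` pooled weights.
#' @param hist_active_only Pool histograms only over synapses from inputs
#'   that are active at least once in the training sequence (default
#'   TRUE); synapses from never-active inputs cannot change under either
#'   rule.
#' @param sequence_mode `"canonical"` (different-context frames are
#'   patterns 1..5 in order) or `"randomized"`.
#' @param same_pattern Which pattern a same-context sequence repeats.
#' @param seed Integer seed; mandatory. Every random choice in the run is
#'   derived from it.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(n = 120L, k = 5L, hd = 10L,
                              ones_count = n %/% 2L, t_len = 5L,
                              rule = c("heblr", "stlr"),
                              context = c("same", "different"),
                              dw = 0.3, eta = "auto",
                              theta1 = "auto", theta2 = "auto",
                              theta_probs = c(0.4, 0.6),
                              coincidence_form = c("approximate", "exact"),
                              normalized = TRUE,
                              w_low = 0, w_high = 1,
                              n_bins = 50L, smooth_window = 5L,
                              min_prominence_frac = 0.1,
                              hist_source = c("raw", "normalized"),
                              hist_active_only = TRUE,
                              sequence_mode = c("canonical", "randomized"),
                              same_pattern = 1L,
                              seed) {
  rule <- match.arg(rule)
  context <- match.arg(context)
  coincidence_form <- match.arg(coincidence_form)
  hist_source <- match.arg(hist_source)
  sequence_mode <- match.arg(sequence_mode)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: experiments never seed from the clock",
         call. = FALSE)
  }
  stopifnot(t_len >= 0L, dw > 0, w_low < w_high)
  if (context == "different" && t_len != 5L) {
    stop("different-context training uses the 5-frame protocol ",
         "(t_len = 5)", call. = FALSE)
  }
  if (is.numeric(theta1) && is.numeric(theta2) && !(theta1 > theta2)) {
    stop("threshold ordering violation: need theta1 > theta2", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), k = as.integer(k), hd = as.integer(hd),
         ones_count = as.integer(ones_count), t_len = as.integer(t_len),
         rule = rule, context = context, dw = dw, eta = eta,
         theta1 = theta1, theta2 = theta2, theta_probs = theta_probs,
         coincidence_form = coincidence_form, normalized = normalized,
         w_low = w_low, w_high = w_high, n_bins = as.integer(n_bins),
         smooth_window = as.integer(smooth_window),
         min_prominence_frac = min_prominence_frac,
         hist_source = hist_source,
         hist_active_only = isTRUE(hist_active_only),
         sequence_mode = sequence_mode,
         same_pattern = as.integer(same_pattern),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

resolve_thresholds <- function(cfg, w0, x1) {
  eta <- if (identical(cfg$eta, "auto")) auto_threshold(w0, x1) else cfg$eta
  theta1 <- cfg$theta1
  theta2 <- cfg$theta2
  if (identical(theta1, "auto") || identical(theta2, "auto")) {
    ii <- stlr_coincidence(w0, x1, form = cfg$coincidence_form,
                           normalized = cfg$normalized)
    vals <- ii[, x1 == 1, drop = FALSE]
    qs <- stats::quantile(vals, probs = cfg$theta_probs, names = FALSE)
    if (identical(theta2, "auto")) theta2 <- qs[1]
    if (identical(theta1, "auto")) theta1 <- qs[2]
  }
  list(eta = eta, theta1 = theta1, theta2 = theta2)
}

#' Run one training experiment
#'
#' Executes the full protocol for one rule x context condition: pattern
#' generation, sequence construction, uniform weight initialization,
#' threshold resolution at the first frame (then frozen), `t_len` learning
#' steps (one per frame), and diagnostics at t = 0 and t = t_len.
#' Deterministic given the config's seed: patterns use `seed`, initial
#' weights `seed + 1`, and randomized sequence draws `seed + 2`.
#'
#' @param cfg An `experiment_config`.
#' @param keep_weights Keep per-step weight snapshots (default FALSE).
#' @return An object of class `experiment_result`: list with the resolved
#'   config (`config`, auto thresholds replaced by their numeric values),
#'   the pattern set, initial/final histograms and mode reports, the
#'   q/r/p trajectory (STLR) or firing-count trajectory (HEBLR), final
#'   per-frame outputs and their pairwise-distance matrix, the final
#'   weight matrix, and optionally the per-step snapshots.
#' @export
run_experiment <- function(cfg, keep_weights = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  ps <- generate_pattern_set(cfg$n, cfg$k, cfg$hd, cfg$ones_count,
                             seed = cfg$seed)
  if (cfg$context == "same") {
    seq_ <- make_same_context_sequence(ps$patterns[cfg$same_pattern, ],
                                       max(cfg$t_len, 1L))
  } else {
    seq_ <- make_different_context_sequence(
      ps, mode = cfg$sequence_mode,
      seed = if (cfg$sequence_mode == "randomized")
               derive_seed(cfg$seed, 2L) else NULL)
  }
  w0 <- init_weights(cfg$n, cfg$n, cfg$w_low, cfg$w_high,
                     seed = derive_seed(cfg$seed, 1L))
  x1 <- seq_$frames[1L, ]
  th <- resolve_thresholds(cfg, w0, x1)

  resolved <- cfg
  resolved$eta <- th$eta
  resolved$theta1 <- th$theta1
  resolved$theta2 <- th$theta2

  active_cols <- if (cfg$hist_active_only) {
    colSums(seq_$frames[seq_len(max(cfg$t_len, 1L)), , drop = FALSE]) > 0
  } else {
    rep(TRUE, cfg$n)
  }
  hist0 <- weight_histogram(w0, source = cfg$hist_source,
                            n_bins = cfg$n_bins, columns = active_cols)
  modes0 <- count_modes(hist0, cfg$smooth_window, cfg$min_prominence_frac)

  w <- w0
  snapshots <- if (keep_weights) list(w0) else NULL
  qrp <- vector("list", cfg$t_len)
  firing <- integer(cfg$t_len)
  for (t in seq_len(cfg$t_len)) {
    x <- seq_$frames[t, ]
    if (cfg$rule == "heblr") {
      firing[t] <- sum(fire(internal_state(w, x), th$eta))
      w <- heblr_update(w, x, cfg$dw, th$eta)
    } else {
      ii <- stlr_coincidence(w, x, form = cfg$coincidence_form,
                             normalized = cfg$normalized)
      qrp[[t]] <- subset_fractions(ii, x, th$theta1, th$theta2)
      w <- stlr_update(w, x, cfg$dw, th$theta1, th$theta2,
                       form = cfg$coincidence_form,
                       normalized = cfg$normalized)
    }
    if (keep_weights) snapshots[[t + 1L]] <- w
  }

  hist1 <- weight_histogram(w, source = cfg$hist_source,
                            n_bins = cfg$n_bins, columns = active_cols)
  modes1 <- count_modes(hist1, cfg$smooth_window, cfg$min_prominence_frac)

  # final outputs: response of the trained network to each training frame
  frames <- if (cfg$t_len > 0) {
    seq_$frames[seq_len(cfg$t_len), , drop = FALSE]
  } else {
    seq_$frames[1L, , drop = FALSE]
  }
  outputs <- t(apply(frames, 1L, function(x) {
    fire(internal_state(w, x), th$eta)
  }))
  disc <- output_discrimination_matrix(outputs)

  qrp_df <- if (cfg$rule == "stlr" && cfg$t_len > 0) {
    do.call(rbind, lapply(seq_along(qrp), function(t) {
      cbind(step = t, qrp[[t]])
    }))
  } else {
    NULL
  }

  structure(
    list(config = resolved, pattern_set = ps, sequence = seq_,
         hist_initial = hist0, modes_initial = modes0,
         hist_final = hist1, modes_final = modes1,
         qrp = qrp_df, firing = if (cfg$rule == "heblr") firing else NULL,
         active_cols = active_cols,
         outputs = outputs, discrimination = disc,
         w_initial = w0, w_final = w,
         snapshots = snapshots),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat("<experiment_result> rule = ", cfg$rule, ", context = ", cfg$context,
      ", t_len = ", cfg$t_len, ", seed = ", cfg$seed, "\n", sep = "")
  cat("  modes: initial ", x$modes_initial$n_modes, ", final ",
      x$modes_final$n_modes, " at [",
      paste(signif(x$modes_final$mode_locations, 3), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Run the rule x context grid
#'
#' Runs the four conditions (heblr/stlr x same/different) from one base
#' configuration.  All four share the pattern set and the initial weight
#' matrix (they use the same seed).  A condition that fails yields a
#' structured error record instead of aborting the others.
#'
#' @param base_cfg An `experiment_config`; its `rule` and `context` fields
#'   are overridden per condition.
#' @param keep_weights Passed to [run_experiment()].
#' @return A named list of class `experiment_grid` with elements
#'   `heblr_same`, `heblr_different`, `stlr_same`, `stlr_different`; each
#'   is an `experiment_result` or a record
#'   `list(error = TRUE, message = ...)`.
#' @export
run_grid <- function(base_cfg, keep_weights = FALSE) {
  stopifnot(inherits(base_cfg, "experiment_config"))
  conditions <- expand.grid(rule = c("heblr", "stlr"),
                            context = c("same", "different"),
                            stringsAsFactors = FALSE)
  out <- vector("list", nrow(conditions))
  names(out) <- paste(conditions$rule, conditions$context, sep = "_")
  for (i in seq_len(nrow(conditions))) {
    cfg <- base_cfg
    cfg$rule <- conditions$rule[i]
    cfg$context <- conditions$context[i]
    out[[i]] <- tryCatch(
      run_experiment(cfg, keep_weights = keep_weights),
      error = function(e) {
        list(error = TRUE, rule = cfg$rule, context = cfg$context,
             message = conditionMessage(e))
      }
    )
  }
  structure(out, class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("<experiment_grid>\n")
  for (nm in names(x)) {
    r <- x[[nm]]
    if (isTRUE(r$error)) {
      cat("  ", nm, ": ERROR - ", r$message, "\n", sep = "")
    } else {
      cat("  ", nm, ": ", r$modes_final$n_modes, " final mode(s)\n",
          sep = "")
    }
  }
  invisible(x)
}

hist_to_df <- function(h) {
  data.frame(bin_lo = h$bin_edges[-length(h$bin_edges)],
             bin_hi = h$bin_edges[-1], mid = h$mids, count = h$counts)
}

summarize_result <- function(res) {
  list(
    config = res$config[setdiff(names(res$config), "theta_probs")],
    theta_probs = res$config$theta_probs,
    modes_initial = list(n_modes = res$modes_initial$n_modes,
                         locations = res$modes_initial$mode_locations),
    modes_final = list(n_modes = res$modes_final$n_modes,
                       locations = res$modes_final$mode_locations,
                       prominences = res$modes_final$prominences),
    qrp_mean = if (!is.null(res$qrp)) {
      lapply(split(res$qrp, res$qrp$step), function(d) {
        list(q = mean(d$q, na.rm = TRUE), r = mean(d$r, na.rm = TRUE),
             p = mean(d$p, na.rm = TRUE))
      })
    } else NULL,
    firing = res$firing,
    mean_output_distance = mean_offdiag(res$discrimination)
  )
}

#' Write a machine-readable experiment report
#'
#' For a single result, writes into `dir`: `summary.json` (resolved config
#' and headline numbers), `histogram_t0.csv` / `histogram_tN.csv`,
#' `modes.json`, `qrp.csv` (STLR), `outputs.txt` and `patterns.txt`.
#' For a grid, writes one subdirectory per condition plus a top-level
#' `grid_summary.json`; failed conditions get an `error.json` record.
#'
#' @param x An `experiment_result` or `experiment_grid`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "experiment_grid")) {
    summaries <- list()
    for (nm in names(x)) {
      r <- x[[nm]]
      sub <- file.path(dir, nm)
      if (isTRUE(r$error)) {
        dir.create(sub, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(r, file.path(sub, "error.json"),
                             auto_unbox = TRUE)
        summaries[[nm]] <- r
      } else {
        write_experiment_report(r, sub)
        summaries[[nm]] <- summarize_result(r)
      }
    }
    jsonlite::write_json(summaries, file.path(dir, "grid_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(dir))
  }
  stopifnot(inherits(x, "experiment_result"))
  jsonlite::write_json(summarize_result(x), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(hist_to_df(x$hist_initial),
                   file.path(dir, "histogram_t0.csv"), row.names = FALSE)
  utils::write.csv(hist_to_df(x$hist_final),
                   file.path(dir, "histogram_tN.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(initial = list(n_modes = x$modes_initial$n_modes,
                        locations = x$modes_initial$mode_locations),
         final = list(n_modes = x$modes_final$n_modes,
                      locations = x$modes_final$mode_locations,
                      prominences = x$modes_final$prominences)),
    file.path(dir, "modes.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(x$qrp)) {
    utils::write.csv(x$qrp, file.path(dir, "qrp.csv"), row.names = FALSE)
  }
  write_binary_matrix(x$outputs, file.path(dir, "outputs.txt"))
  write_binary_matrix(x$pattern_set$patterns, file.path(dir, "patterns.txt"))
  invisible(dir)
}

#' Completion-versus-discrimination experiment
#'
#' Trains, for each rule, five replicate networks with *shared* initial
#' weights on the five same-context sequences (one per pattern), then
#' compares the trained networks' outputs to their own training patterns.
#' Completion-style learning (HEBLR) maps the five similar patterns to
#' nearly identical outputs; discrimination-style learning (STLR) maps
#' them to distinct outputs.  The summary statistic is the mean pairwise
#' output Hamming distance across the five replicates.
#'
#' Outputs are read out with the population-median convention applied to
#' the *trained* state: each network's readout threshold is the median of
#' its final internal states, so half its neurons fire.  This equalizes
#' overall excitability between rules — STLR shifts the whole drive
#' distribution up and down, HEBLR only boosts its winners — making the
#' pairwise distances comparable across rules.
#'
#' @param cfg An `experiment_config` used as template (its `rule`,
#'   `context` and `same_pattern` fields are overridden).
#' @return A list with per-rule mean pairwise output distances
#'   (`mean_distance`), the distance matrices (`matrices`) and the output
#'   vectors (`outputs`).
#' @export
discrimination_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  ps <- generate_pattern_set(cfg$n, cfg$k, cfg$hd, cfg$ones_count,
                             seed = cfg$seed)
  w0 <- init_weights(cfg$n, cfg$n, cfg$w_low, cfg$w_high,
                     seed = derive_seed(cfg$seed, 1L))
  n_rep <- min(5L, ps$k)
  res <- list(mean_distance = c(heblr = NA_real_, stlr = NA_real_),
              matrices = list(), outputs = list())
  for (rule in c("heblr", "stlr")) {
    outputs <- matrix(0L, n_rep, cfg$n)
    for (i in seq_len(n_rep)) {
      x <- ps$patterns[i, ]
      th <- resolve_thresholds(cfg, w0, x)
      w <- w0
      for (t in seq_len(cfg$t_len)) {
        w <- if (rule == "heblr") {
          heblr_update(w, x, cfg$dw, th$eta)
        } else {
          stlr_update(w, x, cfg$dw, th$theta1, th$theta2,
                      form = cfg$coincidence_form,
                      normalized = cfg$normalized)
        }
      }
      s_final <- internal_state(w, x)
      outputs[i, ] <- fire(s_final, stats::median(s_final))
    }
    d <- output_discrimination_matrix(outputs)
    res$mean_distance[rule] <- mean_offdiag(d)
    res$matrices[[rule]] <- d
    res$outputs[[rule]] <- outputs
  }
  res
}
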