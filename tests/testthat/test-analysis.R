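test_that("weight histograms conserve counts and flag degenerate inputs", {
  w <- init_weights(120, seed = 2)
  h <- weight_histogram(w, source = "raw", n_bins = 50)
  expect_equal(sum(h$counts), length(w))
  expect_true(all(diff(h$bin_edges) > 0))

  # uniform initialization: flat histogram, chi-square GOF not rejected
  p <- stats::chisq.test(h$counts)$p.value
  expect_gt(p, 0.01)

  # constant matrix: everything in one bin
  hc <- weight_histogram(matrix(0.3, 10, 10), source = "raw", n_bins = 10)
  expect_equal(sum(hc$counts > 0), 1)

  # column restriction pools only the selected synapses
  hsub <- weight_histogram(w, source = "raw", columns = 1:30)
  expect_equal(sum(hsub$counts), 120 * 30)

  # normalized source pools unit-norm rows
  hn <- weight_histogram(w, source = "normalized")
  expect_equal(sum(hn$counts), length(w))
  expect_true(max(hn$bin_edges) < 1)

  expect_error(weight_histogram(matrix(numeric(0), 0, 0)), "empty")
})

test_that("mode counting recovers the known structure of constructed mixtures", {
  set.seed(5)
  two <- c(rnorm(5000, -2, 0.3), rnorm(5000, 2, 0.3))
  expect_equal(count_modes(hist_from_values(two))$n_modes, 2)

  one <- rnorm(10000, 0, 1)
  expect_equal(count_modes(hist_from_values(one))$n_modes, 1)

  # an exactly flat histogram has a single plateau and no second peak
  flat <- hist_from_values(runif(1000))
  flat$counts <- rep(40L, length(flat$counts))
  expect_lte(count_modes(flat)$n_modes, 1)

  three <- c(rnorm(4000, -3, 0.25), rnorm(4000, 0, 0.25),
             rnorm(4000, 3, 0.25))
  m3 <- count_modes(hist_from_values(three))
  expect_equal(m3$n_modes, 3)
  expect_true(all(diff(m3$mode_locations) > 0))   # sorted ascending
})

test_that("mode counting is invariant to rescaling the counts", {
  set.seed(6)
  vals <- c(rnorm(3000, -1, 0.2), rnorm(3000, 1, 0.2))
  d <- hist_from_values(vals)
  m1 <- count_modes(d)
  d7 <- d
  d7$counts <- d$counts * 7L
  m7 <- count_modes(d7)
  expect_equal(m7$n_modes, m1$n_modes)
  expect_equal(m7$mode_locations, m1$mode_locations)
})

test_that("mode counting validates its smoothing window", {
  d <- hist_from_values(runif(100), n_bins = 10)
  expect_error(count_modes(d, smooth_window = 11), "exceeds")
})

test_that("dominant modes are the most prominent ones, in location order", {
  set.seed(8)
  vals <- c(rnorm(6000, -2, 0.2), rnorm(1500, 0, 0.2), rnorm(6000, 2, 0.2))
  m <- count_modes(hist_from_values(vals))
  expect_equal(m$n_modes, 3)
  dom <- dominant_modes(m, 2)
  expect_equal(length(dom), 2)
  expect_lt(dom[1], -1.5)
  expect_gt(dom[2], 1.5)
})

test_that("branch fractions count the hand-built row and always sum to one", {
  ii <- matrix(c(0.8, 0.5, 0.2, 0), 1, 4)
  sf <- subset_fractions(ii, x = rep(1, 4), theta1 = 0.6, theta2 = 0.3)
  expect_equal(sf$q, 0.25)
  expect_equal(sf$r, 0.25)
  expect_equal(sf$p, 0.5)

  # theta1 below every active coincidence: pure enhancement
  sf2 <- subset_fractions(ii, rep(1, 4), theta1 = -1, theta2 = -2)
  expect_equal(sf2$q, 1)
  expect_equal(sf2$r + sf2$p, 0)

  # no active synapses: flagged as missing
  sf3 <- subset_fractions(ii, rep(0, 4), 0.6, 0.3)
  expect_true(all(is.na(sf3$q)))

  set.seed(91)
  for (rep in 1:10) {
    inst <- random_instance(15, 15)
    if (sum(inst$x) == 0) next
    ii <- stlr_coincidence(inst$w, inst$x, normalized = TRUE)
    sf <- subset_fractions(ii, inst$x, theta1 = 0.1, theta2 = 0.05)
    expect_equal(sf$q + sf$r + sf$p, rep(1, 15), tolerance = 1e-14)
  }
})

test_that("the Hebbian step magnitude identity holds against the update itself", {
  set.seed(95)
  for (rep in 1:10) {
    inst <- random_instance(10, 10)
    eta <- runif(1, 0, 3)
    dw <- 0.25
    y <- fire(internal_state(inst$w, inst$x), eta)
    predicted <- hebbian_step_magnitude(inst$x, y, dw)
    observed <- rowSums(heblr_update(inst$w, inst$x, dw, eta) - inst$w)
    expect_equal(observed, predicted, tolerance = 1e-12)
  }
  expect_equal(hebbian_step_magnitude(c(rep(1, 60), rep(0, 60)), 1, 0.1),
               6.0)
  expect_equal(hebbian_step_magnitude(rep(1, 60), 0, 0.1), 0)
})

test_that("weight-to-pattern similarity identifies matching and neutral rows", {
  ps <- generate_pattern_set(120, 5, 10, 60, seed = 13)
  w <- init_weights(6, 120, seed = 13)
  w[1, ] <- ps$patterns[3, ]          # exact pattern copy
  w[2, ] <- 0.5                        # neutral row: equal cosine to all
  sim <- weight_input_similarity(w, ps)
  expect_equal(sim$assignment[1], 3)
  expect_equal(sim$cosines[1, 3], 1)
  expect_lt(diff(range(sim$cosines[2, ])), 1e-12)
  expect_equal(sum(sim$table), 6)
})

test_that("STLR different-context training spreads weight vectors over patterns", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- experiment_config(rule = "stlr", context = "different",
                             seed = seed)
    res <- run_experiment(cfg)
    sim <- weight_input_similarity(res$w_final, res$pattern_set)
    hits <- hits + (sum(sim$table > 0) >= 2)
  }
  expect_gte(hits, 18)   # discrimination signature in nearly every run
})

test_that("output distance matrices behave at the completion and separation limits", {
  y <- rbinom(30, 1, 0.5)
  d_same <- output_discrimination_matrix(list(y, y, y))
  expect_true(all(d_same == 0))
  d_comp <- output_discrimination_matrix(list(y, 1 - y))
  expect_equal(d_comp[1, 2], 30)
  expect_identical(d_comp, t(d_comp))
  expect_error(output_discrimination_matrix(list(c(1, 0), c(1, 0, 1))),
               "equal length")
})
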