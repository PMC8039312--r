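test_that("Hebbian update potentiates exactly the firing-row active-input synapses", {
  # hand-worked single-row case: s = 0.2 + 0.3 = 0.5 >= eta = 0.4
  w <- matrix(c(0.2, 0.5, 0.3), 1, 3)
  out <- heblr_update(w, c(1, 0, 1), dw = 0.1, eta = 0.4)
  expect_equal(as.vector(out), c(0.3, 0.5, 0.4))

  # threshold above every internal state: nothing happens
  out2 <- heblr_update(w, c(1, 0, 1), dw = 0.1, eta = 10)
  expect_identical(out2, w)

  # no active inputs: nothing happens
  out3 <- heblr_update(w, c(0, 0, 0), dw = 0.1, eta = -1)
  expect_identical(out3, w)
})

test_that("Hebbian weight trajectories are element-wise non-decreasing", {
  set.seed(31)
  w <- init_weights(20, 20)
  x <- rbinom(20, 1, 0.5)
  eta <- auto_threshold(w, x)
  for (t in 1:5) {
    w_next <- heblr_update(w, x, dw = 0.3, eta = eta)
    expect_true(all(w_next >= w))
    w <- w_next
  }
})

test_that("approximate coincidence matches the hand-worked row and sums to one", {
  w <- matrix(c(0.2, 0.5, 0.3), 1, 3)
  ii <- stlr_coincidence(w, c(1, 1, 0), form = "approximate")
  expect_equal(as.vector(ii), c(0.2 / 0.7, 0.5 / 0.7, 0), tolerance = 1e-12)

  # single active input: that synapse carries everything
  ii1 <- stlr_coincidence(w, c(0, 1, 0), form = "approximate")
  expect_equal(as.vector(ii1), c(0, 1, 0))

  # row sums over active synapses are identically 1 when s > 0
  set.seed(17)
  for (rep in 1:10) {
    inst <- random_instance(12, 12)
    if (sum(inst$x) == 0) next
    ii <- stlr_coincidence(inst$w, inst$x, form = "approximate")
    expect_equal(unname(rowSums(ii)), rep(1, 12), tolerance = 1e-12)
  }
})

test_that("coincidence is zero at inactive synapses and handles zero drive", {
  set.seed(23)
  inst <- random_instance(6, 6)
  inst$x <- c(1, 1, 0, 1, 0, 0)
  for (form in c("approximate", "exact")) {
    ii <- stlr_coincidence(inst$w, inst$x, form = form)
    expect_true(all(ii[, inst$x == 0] == 0))
  }
  ii_n <- stlr_coincidence(inst$w, inst$x, normalized = TRUE)
  expect_true(all(ii_n[, inst$x == 0] == 0))
  expect_true(all(abs(ii_n) <= 1 + 1e-12))

  # all-zero weight row with approximate form: defined as zero, warned
  w0 <- inst$w
  w0[2, ] <- 0
  expect_warning(ii0 <- stlr_coincidence(w0, inst$x, form = "approximate"),
                 "internal state is 0")
  expect_true(all(ii0[2, ] == 0))
})

test_that("STLR update applies the three-branch rule on active synapses only", {
  # hand-worked: I = (0.286, 0.714, 0); theta1 = 0.5, theta2 = 0.3
  # -> attenuate j1, enhance j2, leave inactive j3
  w <- matrix(c(0.2, 0.5, 0.3), 1, 3)
  out <- stlr_update(w, c(1, 1, 0), dw = 0.1, theta1 = 0.5, theta2 = 0.3,
                     form = "approximate", normalized = FALSE)
  expect_equal(as.vector(out), c(0.1, 0.6, 0.3))

  # pure invariance band: nothing changes
  out2 <- stlr_update(w, c(1, 1, 0), dw = 0.1, theta1 = 0.99,
                      theta2 = 0.01, form = "approximate",
                      normalized = FALSE)
  expect_identical(out2, w)

  # all-zero input: nothing changes (zero drive is warned about)
  expect_warning(
    out3 <- stlr_update(w, c(0, 0, 0), dw = 0.1, theta1 = 0.5,
                        theta2 = 0.3, normalized = FALSE),
    "internal state is 0")
  expect_identical(out3, w)

  expect_error(stlr_update(w, c(1, 1, 0), 0.1, theta1 = 0.2, theta2 = 0.5),
               "ordering")
})

test_that("synapses from inactive inputs are bit-identical across STLR steps", {
  set.seed(41)
  w <- init_weights(30, 30)
  x <- rbinom(30, 1, 0.5)
  inactive <- x == 0
  ref <- w[, inactive]
  for (t in 1:5) {
    w <- stlr_update(w, x, dw = 0.3, theta1 = 0.08, theta2 = 0.02,
                     normalized = TRUE)
    expect_identical(w[, inactive], ref)
  }
})

test_that("STLR weights may become negative under repeated attenuation", {
  set.seed(43)
  w <- init_weights(10, 10)
  x <- rep(1L, 10)
  # theta2 above the whole coincidence range: everything attenuates
  for (t in 1:5) {
    w <- stlr_update(w, x, dw = 0.3, theta1 = 10, theta2 = 9,
                     normalized = FALSE)
  }
  expect_true(any(w < 0))
})

test_that("vectorized rule updates match the per-synapse loop oracle", {
  set.seed(53)
  for (rep in 1:40) {
    inst <- random_instance(8, 8)
    eta <- runif(1, 0, 4)
    dw <- runif(1, 0.05, 0.5)
    expect_identical(heblr_update(inst$w, inst$x, dw, eta),
                     oracle_heblr(inst$w, inst$x, dw, eta))
    for (form in c("approximate", "exact")) {
      th <- sort(runif(2, 0, if (form == "exact") 2 else 0.5))
      expect_identical(
        stlr_update(inst$w, inst$x, dw, th[2], th[1], form = form,
                    normalized = FALSE),
        oracle_stlr(inst$w, inst$x, dw, th[2], th[1], form = form,
                    normalized = FALSE))
    }
    thn <- sort(runif(2, 0, 0.4))
    expect_identical(
      stlr_update(inst$w, inst$x, dw, thn[2], thn[1], normalized = TRUE),
      oracle_stlr(inst$w, inst$x, dw, thn[2], thn[1], normalized = TRUE))
  }
})

test_that("unit-sphere normalization produces unit vectors and bounded states", {
  set.seed(61)
  x <- rbinom(120, 1, 0.5)
  w_row <- runif(120)
  nv <- normalize_vectors(x, w_row)
  expect_equal(sqrt(sum(nv$x_tilde^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(nv$w_tilde^2)), 1, tolerance = 1e-12)
  expect_true(nv$s_tilde >= 0 && nv$s_tilde <= 1)
  # against a direct dot-product computation
  expect_equal(nv$s_tilde,
               sum((w_row / sqrt(sum(w_row^2))) * (x / sqrt(sum(x^2)))),
               tolerance = 1e-12)

  # parallel vectors give s~ = 1 (Cauchy-Schwarz equality)
  v <- runif(10) + 0.1
  expect_equal(normalize_vectors(v, 3 * v)$s_tilde, 1, tolerance = 1e-12)

  # all-equal weight row with half-active input: s~ = 1/sqrt(2)
  x2 <- c(rep(1, 60), rep(0, 60))
  nv2 <- normalize_vectors(x2, rep(0.4, 120))
  expect_equal(nv2$s_tilde, 1 / sqrt(2), tolerance = 1e-12)

  expect_error(normalize_vectors(rep(0, 5), runif(5)), "zero-norm")
})

test_that("normalized coincidence is a line through the origin with slope s~", {
  w_t <- c(0.1, 0.2, 0.3)
  expect_equal(normalized_coincidence(w_t, 0), c(0, 0, 0))
  expect_equal(normalized_coincidence(w_t, 1), w_t)
  set.seed(71)
  for (rep in 1:10) {
    w_row <- runif(30)
    x <- rbinom(30, 1, 0.5)
    if (sum(x) == 0) next
    nv <- normalize_vectors(x, w_row)
    expect_equal(normalized_coincidence(nv$w_tilde, nv$s_tilde),
                 nv$w_tilde * nv$s_tilde)
  }
})

test_that("neurons are partitioned into R1/R2/R3 with inclusive boundaries", {
  s <- c(0.7, 0.5, 0.2, 0.6, 0.4)
  lab <- classify_regions(s, theta1 = 0.6, theta2 = 0.4)
  expect_identical(lab, c("R1", "R2", "R3", "R1", "R3"))
  expect_true(all(lab %in% c("R1", "R2", "R3")))
  expect_error(classify_regions(s, 0.3, 0.5), "ordering")
})
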