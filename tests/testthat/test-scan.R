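stim_fast <- stim_block(cycles = 1)

test_that("one-parameter scans vanish at the nominal multiplier", {
  for (par in c("kappa_s", "E0", "V0")) {
    sc <- scan_1d(stim_fast, nominal, par, multipliers = c(0.8, 1, 1.2))
    expect_equal(sc$error[sc$multiplier == 1], 0)
    expect_true(all(sc$error >= 0, na.rm = TRUE))
  }
})

test_that("grid points that fault are recorded as missing, not dropped", {
  # E0 * 1.3 = 1.04 leaves the validity domain
  sc <- scan_1d(stim_fast, nominal, "E0", multipliers = c(0.8, 1, 1.3))
  expect_equal(nrow(sc), 3)
  expect_true(is.na(sc$error[sc$multiplier == 1.3]))
  expect_false(anyNA(sc$error[sc$multiplier < 1.3]))
})

test_that("V0 scans are exactly linear and symmetric", {
  sc <- scan_1d(stim_fast, nominal, "V0",
                multipliers = seq(0.6, 1.4, by = 0.1))
  # y linear in V0 means error(m) = 100 |m - 1| exactly
  expect_equal(sc$error, 100 * abs(sc$multiplier - 1), tolerance = 1e-10)
  expect_equal(scan_asymmetry(sc, 0.3), 0, tolerance = 1e-10)
  expect_error(scan_asymmetry(sc, 0.5), "grid")
})

test_that("kappa_s asymmetry is positive: the slow side dominates", {
  sc <- scan_1d(stim_fast, nominal, "kappa_s",
                multipliers = seq(0.6, 1.4, by = 0.1))
  expect_gt(scan_asymmetry(sc, 0.3), 0)
})

test_that("a symmetric synthetic error curve has zero asymmetry", {
  sc <- structure(tibble::tibble(multiplier = seq(0.5, 1.5, 0.1),
                                 error = 100 * (seq(0.5, 1.5, 0.1) - 1)^2),
                  parameter = "synthetic", minimum_multiplier = 1,
                  class = c("bm_scan1d", "tbl_df", "tbl", "data.frame"))
  expect_equal(scan_asymmetry(sc, 0.4), 0, tolerance = 1e-12)
})

test_that("two-parameter scans vanish at (1, 1) and match 1D slices", {
  g <- c(0.8, 1, 1.2)
  sc <- scan_2d(stim_fast, nominal, c("kappa_s", "tau_inv"),
                multipliers1 = g, multipliers2 = g)
  expect_equal(sc$error[sc$m1 == 1 & sc$m2 == 1], 0)
  one_d <- scan_1d(stim_fast, nominal, "kappa_s", multipliers = g)
  slice <- sc$error[sc$m2 == 1]
  expect_equal(slice, one_d$error, tolerance = 1e-12)
})

test_that("cells above the error ceiling are trimmed but kept as rows", {
  g <- c(0.5, 1, 1.5)
  sc <- scan_2d(stim_fast, nominal, c("kappa_f", "epsilon"),
                multipliers1 = g, multipliers2 = g, error_ceiling = 10)
  expect_equal(nrow(sc), 9)
  expect_true(any(sc$trimmed))
  expect_true(all(sc$error <= 10, na.rm = TRUE))
})

test_that("compensation index is 0 for separable and 1 for ridge surfaces", {
  g <- seq(0.5, 1.5, by = 0.05)
  sep <- synthetic_scan2d(g, g, function(a, b) 50 * (a - 1)^2 + 80 * (b - 1)^2)
  expect_equal(compensation_index(sep, 0.3), 0)
  ridge <- synthetic_scan2d(g, g, function(a, b) 100 * (a * b - 1)^2)
  # the ridge attains 0 between grid nodes; bilinear interpolation of the
  # sampled surface recovers the unit index up to its O(h^2) resolution
  expect_equal(compensation_index(ridge, 0.3), 1, tolerance = 0.01)
  expect_error(compensation_index(ridge, 0.7), "coverage")
})

test_that("kappa_s and tau_inv compensate along a ridge on the Balloon surface", {
  g <- seq(0.5, 1.5, by = 0.1)
  sc <- scan_2d(stim_fast, nominal, c("kappa_s", "tau_inv"),
                multipliers1 = g, multipliers2 = g)
  idx <- compensation_index(sc, 0.3)
  expect_gt(idx, 0)
  # brute-force oracle: some joint point on the ring beats both axis errors
  y_nom <- simulate_bold(stim_fast, nominal)$y
  errs <- vapply(seq(0.7, 1.3, by = 0.05), function(b) {
    p <- bm_perturb(bm_perturb(nominal, "kappa_s", 1.3), "tau_inv", b)
    bm_relative_error(simulate_bold(stim_fast, p)$y, y_nom)
  }, numeric(1))
  axis_min <- min(
    bm_relative_error(simulate_bold(stim_fast,
                                    bm_perturb(nominal, "kappa_s", 1.3))$y, y_nom),
    bm_relative_error(simulate_bold(stim_fast,
                                    bm_perturb(nominal, "tau_inv", 1.3))$y, y_nom),
    bm_relative_error(simulate_bold(stim_fast,
                                    bm_perturb(nominal, "tau_inv", 0.7))$y, y_nom))
  expect_lt(min(errs), axis_min)
})

test_that("V0 strongly offsets amplitude-like perturbations", {
  g <- seq(0.5, 1.5, by = 0.1)
  comp <- function(pair) {
    sc <- scan_2d(stim_fast, nominal, pair, multipliers1 = g, multipliers2 = g)
    attr(sc, "compensation_index")
  }
  eps_tau <- comp(c("epsilon", "tau_inv"))
  expect_gt(comp(c("epsilon", "V0")), eps_tau)
  expect_gt(comp(c("kappa_f", "V0")), eps_tau)
  expect_gt(comp(c("alpha_inv", "V0")), eps_tau)
})

test_that("v0_offset finds the exact closed-form rescaling", {
  y_nom <- simulate_bold(stim_fast, nominal)$y
  same <- v0_offset(nominal, stim_fast, nominal, y_nom = y_nom)
  expect_equal(same$v0_scale, 1)
  expect_equal(same$residual_error, 0)

  doubled <- v0_offset(bm_perturb(nominal, "V0", 2), stim_fast, nominal,
                       y_nom = y_nom)
  expect_equal(doubled$v0_scale, 0.5, tolerance = 1e-12)
  expect_equal(doubled$residual_error, 0, tolerance = 1e-9)

  pert <- bm_perturb(nominal, "tau_inv", 1.2)
  off <- v0_offset(pert, stim_fast, nominal, y_nom = y_nom)
  uncomp <- bm_relative_error(simulate_bold(stim_fast, pert)$y, y_nom)
  expect_lt(off$residual_error, uncomp)
})

test_that("v0_offset residual never exceeds the uncompensated error", {
  y_nom <- simulate_bold(stim_fast, nominal)$y
  withr::with_seed(103, {
    for (i in 1:6) {
      par <- sample(setdiff(bm_theta_labels(), "E0"), 1)
      m <- runif(1, 0.7, 1.2)
      pert <- bm_perturb(nominal, par, m)
      off <- v0_offset(pert, stim_fast, nominal, y_nom = y_nom)
      uncomp <- bm_relative_error(simulate_bold(stim_fast, pert)$y, y_nom)
      expect_lte(off$residual_error, uncomp + 1e-9)
    }
  })
})
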