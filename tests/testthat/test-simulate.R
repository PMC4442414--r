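test_that("zero neural efficiency decouples the stimulus entirely", {
  sim <- simulate_bold(short_block(), balloon_params(epsilon = 0))
  expect_equal(max(abs(sim$f - 1)), 0)
  expect_equal(max(abs(sim$y)), 0)
})

test_that("constant stimulation converges to the closed-form steady state", {
  sim <- simulate_bold(constant_stim(1, total_s = 120), nominal)
  ss <- balloon_steady_state(1, nominal)
  final <- unlist(sim[nrow(sim), c("f", "s", "v", "q")])
  expect_lt(max(abs(final - ss)), 1e-3)
  expect_equal(unname(final["f"]), 1.2, tolerance = 1e-4)
})

test_that("block-design BOLD shows static-regime plateaus", {
  stim <- stim_block(cycles = 3)
  sim <- simulate_bold(stim, nominal)
  for (cyc in 1:3) {
    on_end <- cyc * 60
    idx <- sim$time >= on_end - 10 & sim$time < on_end
    plateau <- sim$y[idx]
    expect_lt(sd(plateau) / abs(mean(plateau)), 0.01)
    # plateau level is the u = 1 steady-state BOLD
    expect_equal(mean(plateau),
                 balloon_observe(balloon_steady_state(1, nominal), nominal),
                 tolerance = 1e-3)
  }
})

test_that("adaptive and fixed-step integrators agree on the nominal block run", {
  stim <- stim_block() # full 5-cycle reference design
  y_ad <- simulate_bold(stim, nominal, method = "dopri")$y
  y_rk <- simulate_bold(stim, nominal, method = "rk4")$y
  y_rk2 <- simulate_bold(stim, nominal, method = "rk4", substeps = 2)$y
  expect_lt(rel_l2(y_ad, y_rk), 1e-6)
  expect_lt(rel_l2(y_rk2, y_rk), 1e-6) # grid-refinement convergence
})

test_that("integration matches an independent deSolve oracle", {
  skip_if_not_installed("deSolve")
  stim <- short_block()
  y <- simulate_bold(stim, nominal)$y
  y_oracle <- desolve_bold(stim, nominal)
  expect_lt(rel_l2(y, y_oracle), 1e-6)
})

test_that("integration faults report the offending time", {
  # a huge flow-feedback excursion drives the flow negative
  p <- balloon_params(kappa_f = 2.5)
  bad_init <- c(0.01, -5, 1, 1)
  expect_error(simulate_bold(short_block(), p, initial = bad_init),
               "t = ")
})

test_that("relative error behaves as a scaled L2 distance", {
  y <- c(1, 2, 3)
  expect_equal(bm_relative_error(y, y), 0)
  expect_equal(bm_relative_error(2 * y, y), 100)
  expect_error(bm_relative_error(c(1, 2), y), "length")
  expect_error(bm_relative_error(y, c(0, 0, 0)), "zero")
  sim <- simulate_bold(short_block(), nominal)
  expect_identical(bm_relative_error(sim, sim), 0)
})

test_that("the V0 Jacobian column is the exact linear-response y / V0", {
  stim <- short_block()
  sim <- simulate_bold(stim, nominal)
  J <- bold_jacobian(stim, nominal, subset = "V0")
  expected <- sim$y / 0.02
  expect_lt(rel_l2(J[, "V0"], expected), 1e-10)
})

test_that("central differences converge at second order in the step", {
  stim <- stim_block(5, 5, 1, 1, 0.01)
  J1 <- bold_jacobian(stim, nominal, subset = c("kappa_s", "tau_inv"),
                      rel_step = 2e-3)
  J2 <- bold_jacobian(stim, nominal, subset = c("kappa_s", "tau_inv"),
                      rel_step = 1e-3)
  J4 <- bold_jacobian(stim, nominal, subset = c("kappa_s", "tau_inv"),
                      rel_step = 5e-4)
  # Richardson: error(h) ~ C h^2, so successive differences shrink ~4x
  d12 <- max(abs(J1 - J2)); d24 <- max(abs(J2 - J4))
  expect_lt(d24, d12 / 2.5)
})

test_that("the response to neural efficiency is alive at epsilon = 0", {
  stim <- stim_event(1, onsets = 2, total_s = 20)
  J <- bold_jacobian(stim, balloon_params(epsilon = 0), subset = "epsilon")
  expect_gt(max(abs(J)), 0)
  # the flow subsystem responds linearly in epsilon near zero: compare with
  # a forward simulation at small epsilon
  y_small <- simulate_bold(stim, balloon_params(epsilon = 1e-4))$y
  expect_lt(rel_l2(J[, "epsilon"], y_small / 1e-4), 1e-3)
})
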