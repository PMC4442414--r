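test_that("an additive model splits its variance evenly", {
  pri <- tibble::tibble(parameter = c("x1", "x2"), lower = 0, upper = 1)
  res <- sobol_indices(function(th) th[["x1"]] + th[["x2"]], pri,
                       n_base = 1024, seed = 5, order = 2, n_boot = 200)
  f <- res$first_order
  expect_true(f$ci_low[1] <= 0.5 && 0.5 <= f$ci_high[1])
  expect_true(f$ci_low[2] <= 0.5 && 0.5 <= f$ci_high[2])
  s <- res$second_order
  expect_true(s$ci_low[1] <= 0 && 0 <= s$ci_high[1])
  expect_equal(sum(f$index), 1, tolerance = 0.15)
})

test_that("an unused input gets a null index", {
  pri <- tibble::tibble(parameter = c("x1", "x2"), lower = 0, upper = 1)
  res <- sobol_indices(function(th) th[["x1"]], pri, n_base = 512, seed = 5,
                       order = 1, n_boot = 100)
  f <- res$first_order
  expect_equal(f$index[f$parameter == "x1"], 1, tolerance = 0.1)
  expect_lt(abs(f$index[f$parameter == "x2"]), 0.05)
})

test_that("Ishigami indices match the closed forms within the bootstrap CI", {
  pri <- tibble::tibble(parameter = c("x1", "x2", "x3"),
                        lower = -pi, upper = pi)
  res <- sobol_indices(ishigami_fn, pri, n_base = 4096, seed = 5, order = 2,
                       n_boot = 200)
  an <- ishigami_analytic()
  f <- res$first_order
  expect_true(f$ci_low[1] <= an$S1 && an$S1 <= f$ci_high[1])
  expect_true(f$ci_low[2] <= an$S2 && an$S2 <= f$ci_high[2])
  expect_true(f$ci_low[3] <= an$S3 + 0.02 && an$S3 <= f$ci_high[3])
  s <- res$second_order
  s13 <- s[s$parameter1 == "x1" & s$parameter2 == "x3", ]
  expect_true(s13$ci_low <= an$S13 && an$S13 <= s13$ci_high)
  s12 <- s[s$parameter1 == "x1" & s$parameter2 == "x2", ]
  expect_true(s12$ci_low <= 0.02 && -0.02 <= s12$ci_high)
})

test_that("estimation error decays with the base sample size", {
  pri <- tibble::tibble(parameter = c("x1", "x2"), lower = 0, upper = 1)
  errs <- vapply(c(2^7, 2^9, 2^11), function(n) {
    res <- sobol_indices(function(th) th[["x1"]] + th[["x2"]], pri,
                         n_base = n, seed = 17, order = 1, n_boot = 2)
    max(abs(res$first_order$index - 0.5))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("identical seeds give identical results", {
  pri <- tibble::tibble(parameter = c("x1", "x2"), lower = 0, upper = 1)
  f <- function(th) th[["x1"]]^2 + th[["x2"]]
  a <- sobol_indices(f, pri, n_base = 128, seed = 9, n_boot = 50)
  b <- sobol_indices(f, pri, n_base = 128, seed = 9, n_boot = 50)
  expect_identical(a$first_order, b$first_order)
  expect_identical(a$second_order, b$second_order)
})

test_that("degenerate priors are flagged rather than returned as numbers", {
  pri <- tibble::tibble(parameter = c("x1", "x2"),
                        lower = c(1, 2), upper = c(1 + 1e-12, 2 + 1e-12))
  expect_error(sobol_indices(function(th) th[["x1"]] + th[["x2"]], pri,
                             n_base = 64, seed = 1, n_boot = 10),
               "variance")
  expect_error(sobol_indices(function(th) 1, pri, n_base = 64, seed = 1),
               "variance")
})

test_that("non-finite model values fault unless resampling is enabled", {
  pri <- tibble::tibble(parameter = "x1", lower = 0, upper = 1)
  expect_error(
    sobol_indices(function(th) NA_real_,
                  tibble::tibble(parameter = c("x1", "x2"),
                                 lower = 0, upper = 1),
                  n_base = 64, seed = 1),
    "non-finite")
})

test_that("BOLD scalarizations reduce a series as documented", {
  zero <- tibble::tibble(time = 0:9 / 10, y = rep(0, 10))
  for (mode in c("l2_norm", "peak", "time_average")) {
    expect_equal(bold_scalarize(zero, mode), 0)
  }
  sim <- simulate_bold(short_block(), nominal)
  expect_equal(bold_scalarize(dplyr::mutate(sim, y = 2 * y), "l2_norm"),
               2 * bold_scalarize(sim, "l2_norm"))
  expect_gte(bold_scalarize(sim, "peak"), bold_scalarize(sim, "time_average"))
  expect_equal(bold_scalarize(sim, "sample_at", at = 40),
               sim$y[which.min(abs(sim$time - 40))])
  expect_error(bold_scalarize(sim, "maximum"), "arg")
})

test_that("the Balloon Sobol run is seed-deterministic and sums below one", {
  stim <- stim_block(cycles = 1, te = 0.02)
  a <- balloon_sobol(stim, n_base = 64, seed = 21, order = 1, n_boot = 50)
  b <- balloon_sobol(stim, n_base = 64, seed = 21, order = 1, n_boot = 50)
  expect_identical(a$first_order, b$first_order)
  expect_equal(a$rejections, 0)
  se <- (a$first_order$ci_high - a$first_order$ci_low) / (2 * 1.96)
  expect_lte(sum(a$first_order$index), 1 + 3 * sqrt(sum(se^2)))
})
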