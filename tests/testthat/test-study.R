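test_that("a simulate run writes the full-length trajectory table", {
  out <- withr::local_tempdir()
  cfg <- list(experiment = "simulate",
              stimulus = list(paradigm = "block"), # reference 5-cycle design
              seed = 1, out = out)
  bm_run(cfg)
  tab <- utils::read.table(file.path(out, "trajectory.tsv"), header = TRUE)
  expect_equal(nrow(tab), 30000) # 5 cycles x 60 s / 0.01 s
  expect_named(tab, c("time_s", "f", "s", "v", "q", "y"))
  expect_true(file.exists(file.path(out, "config_echo.json")))
  expect_true(file.exists(file.path(out, "run.log")))
})

test_that("a scan1d run writes the default grid with zero at nominal", {
  out <- withr::local_tempdir()
  cfg <- list(experiment = "scan1d",
              stimulus = list(paradigm = "block", cycles = 1),
              options = list(parameter = "kappa_s"),
              seed = 1, out = out)
  bm_run(cfg)
  tab <- utils::read.table(file.path(out, "scan1d_kappa_s.tsv"), header = TRUE)
  expect_equal(nrow(tab), 41)
  expect_equal(tab$error[abs(tab$multiplier - 1) < 1e-12], 0)
  summ <- jsonlite::read_json(file.path(out, "scan1d_kappa_s_summary.json"))
  expect_equal(summ$minimum_multiplier, 1)
})

test_that("identical configs give byte-identical outputs", {
  cfg <- list(experiment = "scan1d",
              stimulus = list(paradigm = "block", cycles = 1),
              options = list(parameter = "tau_inv",
                             multipliers = c(0.8, 1, 1.2)),
              seed = 7)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  bm_run(cfg, out = out1)
  bm_run(cfg, out = out2)
  f <- "scan1d_tau_inv.tsv"
  expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
})

test_that("the config echo reproduces a run byte-identically", {
  cfg <- list(experiment = "sobol",
              stimulus = list(paradigm = "block", cycles = 1, te = 0.05),
              options = list(n_base = 64, n_boot = 20),
              seed = 3)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  bm_run(cfg, out = out1)
  bm_run(file.path(out1, "config_echo.json"), out = out2)
  f <- "sobol_first_order.tsv"
  expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
})

test_that("schema violations are reported with field paths", {
  expect_error(bm_run(list(experiment = "frobnicate", out = tempdir())),
               "experiment")
  expect_error(bm_run(list(experiment = "simulate",
                           stimulus = list(paradigm = "spiral"),
                           out = tempdir())),
               "stimulus.paradigm")
  expect_error(bm_run(list(experiment = "simulate",
                           stimulus = list(paradigm = "block", bogus = 1),
                           out = tempdir())),
               "stimulus.bogus")
  expect_error(bm_run(list(experiment = "simulate",
                           params = list(kappa_q = 2),
                           out = tempdir())),
               "params.kappa_q")
  expect_error(bm_run(list(experiment = "simulate")), "out")
})

test_that("the full study composes every stage and isolates failures", {
  stim <- stim_block(cycles = 1, te = 0.05)
  st <- bm_full_study(stim, nominal, seed = 2, grid_2d = "reduced",
                      n_base = 64, n_boot = 20)
  expect_s3_class(st, "bm_study")
  expect_length(st$scans1d, 7)
  expect_equal(nrow(st$compensation), 21)
  expect_length(st$failures, 0)
  expect_true(all(st$scan1d_summary$minimum_multiplier > 0))
  expect_equal(sort(unique(c(st$compensation$parameter1,
                             st$compensation$parameter2))),
               sort(bm_theta_labels()))
  expect_length(st$summary$sobol_ranking, 7)
  expect_length(st$summary$pi_ranking, 6)
})
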