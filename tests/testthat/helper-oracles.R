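# Shared fixtures and independent oracles used across the suite.

nominal <- balloon_params()

# short block stimulus for fast tests (full 5-cycle design reserved for the
# acceptance checks)
short_block <- function(cycles = 1, te = 0.01) stim_block(cycles = cycles, te = te)

# constant-stimulus window built from an event covering the whole span
constant_stim <- function(value = 1, total_s = 120, te = 0.01) {
  stim_event(event_s = total_s, onsets = 0, amplitude = value,
             total_s = total_s, te = te)
}

# independent ODE oracle: same equations re-derived in R, integrated with
# deSolve::lsoda phase by phase so the zero-order hold is exact
desolve_bold <- function(stim, params, rtol = 1e-10, atol = 1e-12) {
  th <- bm_theta(params)
  rhs <- function(t, x, parms) {
    f <- x[1]; s <- x[2]; v <- x[3]; q <- x[4]
    u <- parms$u
    list(c(
      s,
      th[["epsilon"]] * u - th[["kappa_s"]] * s - th[["kappa_f"]] * (f - 1),
      th[["tau_inv"]] * (f - v^th[["alpha_inv"]]),
      th[["tau_inv"]] * (f * (1 - (1 - th[["E0"]])^(1 / f)) / th[["E0"]] -
                           v^(th[["alpha_inv"]] - 1) * q)
    ))
  }
  te <- attr(stim, "te")
  n <- nrow(stim)
  states <- matrix(NA_real_, n, 4)
  x <- c(1, 0, 1, 1)
  states[1, ] <- x
  # integrate run-by-run over maximal constant-u stretches so the
  # zero-order hold is exact (u[k] holds on [(k-1) te, k te))
  runs <- rle(stim$u[-n])
  a <- 1L
  for (r in seq_along(runs$lengths)) {
    b <- a + runs$lengths[r] - 1L
    times <- ((a - 1L):b) * te
    sol <- deSolve::lsoda(x, times, rhs, parms = list(u = runs$values[r]),
                          rtol = rtol, atol = atol)
    states[(a + 1L):(b + 1L), ] <- sol[-1, 2:5, drop = FALSE]
    x <- states[b + 1L, ]
    a <- b + 1L
  }
  k <- scanner_constants(th[["E0"]])
  th[["V0"]] * (k[1] * (1 - states[, 4]) +
                  k[2] * (1 - states[, 4] / states[, 3]) +
                  k[3] * (1 - states[, 3]))
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# closed-form Ishigami sensitivity indices
ishigami_fn <- function(th) {
  sin(th[["x1"]]) + 7 * sin(th[["x2"]])^2 + 0.1 * th[["x3"]]^4 * sin(th[["x1"]])
}
ishigami_analytic <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 1 / 2
  list(S1 = V1 / V, S2 = V2 / V, S3 = 0, S12 = 0, S13 = V13 / V, S23 = 0)
}

# random valid parameter set for property-style loops
random_params <- function() {
  balloon_params(
    alpha_inv = runif(1, 2, 8), epsilon = runif(1, 0.1, 1),
    kappa_s = runif(1, 0.5, 2), kappa_f = runif(1, 1, 4),
    tau_inv = runif(1, 0.5, 2), E0 = runif(1, 0.2, 0.9),
    V0 = runif(1, 0.005, 0.1)
  )
}

# hand-built two-parameter scan object for testing compensation_index on
# synthetic error surfaces
synthetic_scan2d <- function(m1, m2, err_fn, ceiling = Inf) {
  E <- outer(m1, m2, Vectorize(err_fn))
  g1 <- rep(m1, times = length(m2))
  g2 <- rep(m2, each = length(m1))
  out <- tibble::tibble(m1 = g1, m2 = g2,
                        error = as.vector(E), trimmed = FALSE)
  structure(out, pair = c("a", "b"), m1 = m1, m2 = m2,
            error_matrix = E, raw_matrix = E, error_ceiling = ceiling,
            class = c("bm_scan2d", class(out)))
}
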