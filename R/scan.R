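#' Default multiplier grids for identifiability scans
#'
#' One-parameter scans use 41 multiplicative points on `[0.2, 1.8]`;
#' two-parameter scans use 21 points on `[0.5, 1.5]` per axis. Grids are
#' clipped to each parameter's validity domain (an `E0` multiplier may not
#' push `E0` to 1 or beyond).
#'
#' @param parameter a label from [bm_theta_labels()].
#' @param nominal a [balloon_params()] object (for domain clipping).
#' @param kind `"1d"` or `"2d"`.
#' @return Numeric vector of positive multipliers containing 1.
#' @export
bm_default_multipliers <- function(parameter, nominal, kind = c("1d", "2d")) {
  kind <- match.arg(kind)
  parameter <- match.arg(parameter, bm_theta_labels())
  m <- if (kind == "1d") seq(0.2, 1.8, by = 0.04) else seq(0.5, 1.5, by = 0.05)
  if (parameter %in% c("E0", "V0")) {
    cap <- 1 / bm_theta(nominal)[parameter]
    m <- m[m * bm_theta(nominal)[parameter] < 1 - 1e-9]
  }
  m
}

#' One-parameter relative-error scan
#'
#' Perturbs a single parameter over a multiplicative grid around its nominal
#' value, re-simulates the BOLD response for every grid point, and records
#' the relative L2 error (percent) against the cached nominal BOLD. Grid
#' points whose simulation faults (e.g. the state leaves the positive
#' domain) are recorded as `NA`, never dropped.
#'
#' @param stimulus a `bm_stimulus`.
#' @param nominal the nominal [balloon_params()].
#' @param parameter label of the scanned parameter (theta convention).
#' @param multipliers positive grid containing 1; default
#'   [bm_default_multipliers()].
#' @param y_nom optional precomputed nominal BOLD (vector or `bm_sim`) to
#'   share across scans.
#' @param ... passed to [simulate_bold()].
#' @return A `bm_scan1d` tibble with columns `multiplier`, `error`;
#'   attributes hold the parameter and the argmin multiplier.
#' @export
scan_1d <- function(stimulus, nominal, parameter, multipliers = NULL,
                    y_nom = NULL, ...) {
  parameter <- match.arg(parameter, bm_theta_labels())
  if (is.null(multipliers)) {
    multipliers <- bm_default_multipliers(parameter, nominal, "1d")
  }
  if (any(multipliers <= 0)) abort("multipliers must be positive")
  if (!any(abs(multipliers - 1) < 1e-12)) abort("grid must contain 1")
  y_nom <- if (is.null(y_nom)) simulate_bold(stimulus, nominal, ...)$y
           else pull_y(y_nom)
  errors <- vapply(multipliers, function(m) {
    tryCatch(
      bm_relative_error(
        simulate_bold(stimulus, bm_perturb(nominal, parameter, m), ...)$y,
        y_nom),
      error = function(e) NA_real_)
  }, numeric(1))
  out <- tibble::tibble(multiplier = multipliers, error = errors)
  structure(out, parameter = parameter,
            minimum_multiplier = multipliers[which.min(errors)],
            class = c("bm_scan1d", class(out)))
}

#' @export
print.bm_scan1d <- function(x, ...) {
  cat(sprintf("<bm_scan1d: %s, %d grid points, argmin at multiplier %g>\n",
              attr(x, "parameter"), nrow(x), attr(x, "minimum_multiplier")))
  NextMethod()
}

#' Asymmetry of a one-parameter error curve
#'
#' `error(1 - delta) - error(1 + delta)`, linearly interpolated between grid
#' points. A positive value means the low side of the nominal value
#' dominates the criterion — the signature of parameters controlling the
#' speed of the transients, where slowing the dynamics hurts the fit more
#' than speeding it up.
#'
#' @param result a `bm_scan1d`.
#' @param delta fractional offset; both `1 - delta` and `1 + delta` must lie
#'   inside the scanned grid.
#' @return Signed percentage.
#' @export
scan_asymmetry <- function(result, delta) {
  stopifnot(inherits(result, "bm_scan1d"))
  rng <- range(result$multiplier)
  if (1 - delta < rng[1] || 1 + delta > rng[2]) {
    abort("delta outside grid coverage")
  }
  ok <- !is.na(result$error)
  e <- approx(result$multiplier[ok], result$error[ok],
              xout = c(1 - delta, 1 + delta))$y
  e[1] - e[2]
}

#' Two-parameter relative-error scan
#'
#' Full cross-product scan of a parameter pair over multiplicative grids,
#' with the remaining parameters fixed at their nominal values. Cells whose
#' error exceeds `error_ceiling` (percent) are trimmed to `NA` — estimation
#' methods would never accept a fit that bad, so the surface is only
#' meaningful below the ceiling. A [compensation_index()] is attached.
#'
#' @param stimulus a `bm_stimulus`.
#' @param nominal the nominal [balloon_params()].
#' @param pair character vector of two parameter labels.
#' @param multipliers1,multipliers2 positive grids containing 1; default
#'   [bm_default_multipliers()] (21 points on `[0.5, 1.5]`).
#' @param error_ceiling trim threshold, percent.
#' @param radius ring radius used for the attached compensation index.
#' @param y_nom optional precomputed nominal BOLD.
#' @param ... passed to [simulate_bold()].
#' @return A `bm_scan2d` tibble in long format (`m1`, `m2`, `error`,
#'   `trimmed`); attributes carry the pair, the error matrix and the
#'   compensation index.
#' @export
scan_2d <- function(stimulus, nominal, pair, multipliers1 = NULL,
                    multipliers2 = NULL, error_ceiling = 30, radius = 0.3,
                    y_nom = NULL, ...) {
  stopifnot(length(pair) == 2)
  pair <- vapply(pair, match.arg, "", choices = bm_theta_labels())
  if (pair[1] == pair[2]) abort("pair must name two distinct parameters")
  m1 <- multipliers1 %||% bm_default_multipliers(pair[1], nominal, "2d")
  m2 <- multipliers2 %||% bm_default_multipliers(pair[2], nominal, "2d")
  for (m in list(m1, m2)) {
    if (any(m <= 0) || !any(abs(m - 1) < 1e-12)) {
      abort("grids must be positive and contain 1")
    }
  }
  y_nom <- if (is.null(y_nom)) simulate_bold(stimulus, nominal, ...)$y
           else pull_y(y_nom)
  E <- matrix(NA_real_, length(m1), length(m2))
  for (i in seq_along(m1)) {
    for (j in seq_along(m2)) {
      E[i, j] <- tryCatch({
        p <- bm_perturb(bm_perturb(nominal, pair[1], m1[i]), pair[2], m2[j])
        bm_relative_error(simulate_bold(stimulus, p, ...)$y, y_nom)
      }, error = function(e) NA_real_)
    }
  }
  trimmed <- !is.na(E) & E > error_ceiling
  E_trim <- E
  E_trim[trimmed] <- NA_real_
  grid_m1 <- rep(m1, times = length(m2))
  grid_m2 <- rep(m2, each = length(m1))
  out <- tibble::tibble(m1 = grid_m1, m2 = grid_m2,
                        error = as.vector(E_trim),
                        trimmed = as.vector(trimmed))
  res <- structure(out, pair = pair, m1 = m1, m2 = m2,
                   error_matrix = E_trim, raw_matrix = E,
                   error_ceiling = error_ceiling,
                   class = c("bm_scan2d", class(out)))
  # clipped grids (E0) may not reach the requested radius; use the largest
  # feasible one so pairs stay comparable instead of undefined
  coverage <- min(1 - min(m1), max(m1) - 1, 1 - min(m2), max(m2) - 1)
  r_eff <- min(radius, coverage)
  attr(res, "compensation_radius") <- r_eff
  attr(res, "compensation_index") <-
    tryCatch(compensation_index(res, r_eff), error = function(e) NA_real_)
  res
}

#' @export
print.bm_scan2d <- function(x, ...) {
  cat(sprintf("<bm_scan2d: (%s, %s), %d x %d grid, compensation index %.3f>\n",
              attr(x, "pair")[1], attr(x, "pair")[2],
              length(attr(x, "m1")), length(attr(x, "m2")),
              attr(x, "compensation_index")))
  NextMethod()
}

# bilinear interpolation on the scan grid; NA cells propagate
interp2 <- function(xg, yg, Z, x, y) {
  i <- findInterval(x, xg, all.inside = TRUE)
  j <- findInterval(y, yg, all.inside = TRUE)
  tx <- (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (y - yg[j]) / (yg[j + 1] - yg[j])
  (1 - tx) * (1 - ty) * Z[cbind(i, j)] +
    tx * (1 - ty) * Z[cbind(i + 1, j)] +
    (1 - tx) * ty * Z[cbind(i, j + 1)] +
    tx * ty * Z[cbind(i + 1, j + 1)]
}

#' Compensation index of a two-parameter error surface
#'
#' Quantifies how much a joint change of the pair can offset what either
#' parameter does alone. On the square ring
#' `max(|m1 - 1|, |m2 - 1|) = radius` the surface minimum is compared with
#' the smaller of the two axis-aligned errors at the same radius:
#' \deqn{1 - \min_{ring} C \; / \; \min_{axes} C,}
#' clamped to `[0, 1]`. A separable surface scores 0 (the ring minimum sits
#' on an axis); an exact compensation ridge through the ring scores 1.
#'
#' @param result a `bm_scan2d`.
#' @param radius ring radius as a fraction of the nominal value; must be
#'   inside both grids.
#' @param n_ring interpolation points per ring side.
#' @return Scalar in `[0, 1]`.
#' @export
compensation_index <- function(result, radius = 0.3, n_ring = 201) {
  stopifnot(inherits(result, "bm_scan2d"))
  m1 <- attr(result, "m1"); m2 <- attr(result, "m2")
  Z <- attr(result, "error_matrix")
  if (1 - radius < min(m1) || 1 + radius > max(m1) ||
      1 - radius < min(m2) || 1 + radius > max(m2)) {
    abort("radius outside grid coverage")
  }
  tt <- seq(-radius, radius, length.out = n_ring)
  ring <- rbind(
    cbind(1 - radius, 1 + tt), cbind(1 + radius, 1 + tt),
    cbind(1 + tt, 1 - radius), cbind(1 + tt, 1 + radius)
  )
  vals <- interp2(m1, m2, Z, ring[, 1], ring[, 2])
  if (all(is.na(vals))) abort("boundary set empty after trimming")
  ring_min <- min(vals, na.rm = TRUE)
  axis_vals <- interp2(m1, m2, Z,
                       c(1 - radius, 1 + radius, 1, 1),
                       c(1, 1, 1 - radius, 1 + radius))
  # a trimmed axis point had error above the ceiling, so the ceiling is a
  # conservative lower bound for the denominator when all four are trimmed
  denom <- if (all(is.na(axis_vals))) attr(result, "error_ceiling")
           else min(axis_vals, na.rm = TRUE)
  if (denom <= 0) return(0)
  min(max(1 - ring_min / denom, 0), 1)
}

#' Optimal V0 offset of a perturbation
#'
#' The BOLD output is exactly linear in `V0`, so the best V0 rescaling of a
#' perturbed model against the nominal BOLD has the closed form
#' `c* = <y_pert, y_nom> / ||y_pert||^2`; the residual is the relative error
#' after that rescaling. A small residual means the perturbation is almost
#' entirely absorbable by `V0` — the practical-identifiability trap for the
#' resting blood volume fraction.
#'
#' @param perturbed a perturbed [balloon_params()].
#' @param stimulus a `bm_stimulus`.
#' @param nominal the nominal [balloon_params()].
#' @param y_nom optional precomputed nominal BOLD.
#' @param ... passed to [simulate_bold()].
#' @return A one-row tibble with `v0_scale` (the optimal multiplier on the
#'   perturbed output, equivalently on its `V0`) and `residual_error`
#'   (percent).
#' @export
v0_offset <- function(perturbed, stimulus, nominal, y_nom = NULL, ...) {
  stopifnot(inherits(perturbed, "balloon_params"),
            inherits(nominal, "balloon_params"))
  y_nom <- if (is.null(y_nom)) simulate_bold(stimulus, nominal, ...)$y
           else pull_y(y_nom)
  y_pert <- simulate_bold(stimulus, perturbed, ...)$y
  np <- sum(y_pert^2)
  if (np == 0) abort("perturbed BOLD has zero norm")
  cstar <- sum(y_pert * y_nom) / np
  tibble::tibble(v0_scale = cstar,
                 residual_error = bm_relative_error(cstar * y_pert, y_nom))
}

#' @export
tidy.bm_scan1d <- function(x, ...) {
  tibble::tibble(parameter = attr(x, "parameter"),
                 multiplier = x$multiplier, error = x$error)
}

#' @export
glance.bm_scan1d <- function(x, ...) {
  tibble::tibble(
    parameter = attr(x, "parameter"),
    n_grid = nrow(x),
    n_missing = sum(is.na(x$error)),
    minimum_multiplier = attr(x, "minimum_multiplier"),
    max_error = max(x$error, na.rm = TRUE)
  )
}

#' @export
tidy.bm_scan2d <- function(x, ...) {
  tibble::tibble(parameter1 = attr(x, "pair")[1],
                 parameter2 = attr(x, "pair")[2],
                 m1 = x$m1, m2 = x$m2, error = x$error, trimmed = x$trimmed)
}

#' @export
glance.bm_scan2d <- function(x, ...) {
  tibble::tibble(
    parameter1 = attr(x, "pair")[1],
    parameter2 = attr(x, "pair")[2],
    n_grid = nrow(x),
    n_trimmed = sum(x$trimmed, na.rm = TRUE),
    compensation_index = attr(x, "compensation_index")
  )
}

#' Plot a one-parameter error curve
#' @param object a `bm_scan1d`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bm_scan1d <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$multiplier, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = sprintf("%s multiplier", attr(object, "parameter")),
                  y = "relative BOLD error (%)")
}

#' Plot a two-parameter error surface
#' @param object a `bm_scan2d`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bm_scan2d <- function(object, ...) {
  pr <- attr(object, "pair")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$m1, y = .data$m2, fill = .data$error)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = sprintf("%s multiplier", pr[1]),
                  y = sprintf("%s multiplier", pr[2]),
                  fill = "error (%)")
}
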