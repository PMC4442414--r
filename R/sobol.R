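#' Independent uniform priors around the nominal parameters
#'
#' The default prior for the variance-based analysis: each parameter uniform
#' on `nominal * (1 - width), nominal * (1 + width)`, independent, clipped to
#' the parameter's validity domain (`E0`, `V0` stay below 1).
#'
#' @param params a [balloon_params()] object (centres).
#' @param width half-width as a fraction of the nominal value (default 0.2).
#' @param subset parameter labels to include.
#' @return A `bm_priors` tibble with columns `parameter`, `lower`, `upper`.
#' @export
bm_uniform_priors <- function(params, width = 0.2,
                              subset = bm_theta_labels()) {
  subset <- match.arg(subset, bm_theta_labels(), several.ok = TRUE)
  theta <- bm_theta(params)[subset]
  lower <- theta * (1 - width)
  upper <- theta * (1 + width)
  frac <- subset %in% c("E0", "V0")
  upper[frac] <- pmin(upper[frac], 1 - 1e-6)
  out <- tibble::tibble(parameter = subset, lower = unname(lower),
                        upper = unname(upper))
  validate_priors(out)
  structure(out, class = c("bm_priors", class(out)))
}

validate_priors <- function(priors) {
  stopifnot(is.data.frame(priors),
            all(c("parameter", "lower", "upper") %in% names(priors)))
  if (any(!is.finite(priors$lower)) || any(!is.finite(priors$upper)) ||
      any(priors$lower >= priors$upper)) {
    abort("prior bounds must be finite with lower < upper")
  }
  invisible(priors)
}

draw_prior_rows <- function(priors, n) {
  k <- nrow(priors)
  m <- matrix(runif(n * k), n, k)
  m <- sweep(m, 2, priors$upper - priors$lower, "*")
  m <- sweep(m, 2, priors$lower, "+")
  colnames(m) <- priors$parameter
  m
}

#' First- and second-order Sobol indices by Monte Carlo
#'
#' Variance-based sensitivity of a scalar model output to independent
#' uniform inputs: the first-order index
#' `S_i = Var(E(Y | X_i)) / Var(Y)` and the second-order index
#' `S_ij = (Var(E(Y | X_i, X_j)) - V_i - V_j) / Var(Y)`.
#' Estimation uses the paired-matrix (Saltelli) scheme: two base sample
#' matrices A and B plus the column-swapped hybrids, with
#' `V_i` from the correlation estimator `mean(f(B) * (f(A_B^i) - f(A)))` and
#' the closed pair variance from `mean(f(B_A^i) * f(A_B^j)) - f0^2`.
#' Index uncertainty comes from a row bootstrap of the stored evaluations.
#'
#' @param model function taking one numeric parameter vector (named by the
#'   prior parameters) and returning a finite scalar. `NA` returns are
#'   treated as faults.
#' @param priors a data frame with `parameter`, `lower`, `upper` (see
#'   [bm_uniform_priors()]).
#' @param n_base base sample count n (>= 64); the model is evaluated
#'   `n * (2k + 2)` times for k parameters at order 2, `n * (k + 2)` at
#'   order 1.
#' @param seed integer seed; identical inputs give identical results.
#' @param order 1 (first-order only) or 2 (adds all pairs).
#' @param n_boot bootstrap replicates for the confidence intervals.
#' @param resample_faults if `TRUE`, rows of the design on which the model
#'   faults (returns `NA`) are redrawn from the priors and re-evaluated;
#'   if `FALSE` (default) a fault aborts.
#' @return A `bm_sobol` object: list with tibbles `first_order` and (order 2)
#'   `second_order` (`index`, `ci_low`, `ci_high` columns), the total
#'   variance, `n_base`, and the rejection count.
#' @examples
#' pri <- tibble::tibble(parameter = c("x1", "x2"), lower = 0, upper = 1)
#' sobol_indices(function(th) th["x1"] + th["x2"], pri,
#'               n_base = 128, seed = 1, order = 1, n_boot = 50)
#' @export
sobol_indices <- function(model, priors, n_base, seed, order = 2,
                          n_boot = 200, resample_faults = FALSE) {
  validate_priors(priors)
  if (n_base < 64) abort("n_base must be at least 64")
  if (!order %in% c(1, 2)) abort("order must be 1 or 2")
  k <- nrow(priors)
  labs <- priors$parameter
  n <- as.integer(n_base)

  withr::local_seed(as.integer(seed))
  A <- draw_prior_rows(priors, n)
  B <- draw_prior_rows(priors, n)

  eval_rows <- function(M) apply(M, 1, function(r) {
    val <- model(setNames(r, labs))
    if (length(val) != 1) abort("model must return a scalar")
    as.numeric(val)
  })

  evaluate_design <- function(A, B) {
    m <- nrow(A)
    out <- list(fA = eval_rows(A), fB = eval_rows(B),
                fAB = matrix(NA_real_, m, k))
    for (i in seq_len(k)) {
      ABi <- A; ABi[, i] <- B[, i]
      out$fAB[, i] <- eval_rows(ABi)
    }
    if (order == 2) {
      out$fBA <- matrix(NA_real_, m, k)
      for (i in seq_len(k)) {
        BAi <- B; BAi[, i] <- A[, i]
        out$fBA[, i] <- eval_rows(BAi)
      }
    }
    out
  }

  ev <- evaluate_design(A, B)
  bad_row <- function(ev) {
    bad <- !is.finite(ev$fA) | !is.finite(ev$fB) |
      rowSums(!is.finite(ev$fAB)) > 0
    if (order == 2) bad <- bad | rowSums(!is.finite(ev$fBA)) > 0
    bad
  }
  rejections <- 0L
  rounds <- 0L
  while (any(bad <- bad_row(ev))) {
    if (!resample_faults) abort("model returned non-finite values")
    if ((rounds <- rounds + 1L) > 100L) {
      abort("too many rejection-resampling rounds; priors may be invalid")
    }
    rejections <- rejections + sum(bad)
    idx <- which(bad)
    A[idx, ] <- draw_prior_rows(priors, length(idx))
    B[idx, ] <- draw_prior_rows(priors, length(idx))
    sub <- evaluate_design(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
    # splice re-evaluated rows back in
    ev$fA[idx] <- sub$fA; ev$fB[idx] <- sub$fB
    ev$fAB[idx, ] <- sub$fAB
    if (order == 2) ev$fBA[idx, ] <- sub$fBA
  }

  estimate <- function(rows) {
    fA <- ev$fA[rows]; fB <- ev$fB[rows]
    fAB <- ev$fAB[rows, , drop = FALSE]
    V <- var(c(fA, fB))
    f0sq <- mean(fA * fB)
    Vi <- vapply(seq_len(k), function(i) mean(fB * (fAB[, i] - fA)),
                 numeric(1))
    Si <- Vi / V
    out <- list(V = V, Si = Si)
    if (order == 2) {
      fBA <- ev$fBA[rows, , drop = FALSE]
      pairs <- combn(k, 2)
      Sij <- apply(pairs, 2, function(p) {
        Vij <- mean(fBA[, p[1]] * fAB[, p[2]]) - f0sq
        (Vij - Vi[p[1]] - Vi[p[2]]) / V
      })
      out$Sij <- Sij
      out$pairs <- pairs
    }
    out
  }

  point <- estimate(seq_len(n))
  if (!is.finite(point$V) || point$V <= 1e-14 * max(mean(c(ev$fA, ev$fB))^2, 1e-300)) {
    abort("output variance is (near) zero under the given priors; indices undefined")
  }
  boot_S <- matrix(NA_real_, n_boot, k)
  boot_Sij <- if (order == 2) matrix(NA_real_, n_boot, ncol(point$pairs))
  for (b in seq_len(n_boot)) {
    est <- estimate(sample.int(n, n, replace = TRUE))
    boot_S[b, ] <- est$Si
    if (order == 2) boot_Sij[b, ] <- est$Sij
  }
  ci <- function(mat) {
    t(apply(mat, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  }
  ci1 <- ci(boot_S)
  first <- tibble::tibble(parameter = labs, index = point$Si,
                          ci_low = ci1[, 1], ci_high = ci1[, 2])
  second <- NULL
  if (order == 2) {
    ci2 <- ci(boot_Sij)
    second <- tibble::tibble(
      parameter1 = labs[point$pairs[1, ]],
      parameter2 = labs[point$pairs[2, ]],
      index = point$Sij, ci_low = ci2[, 1], ci_high = ci2[, 2])
  }
  half_ci <- (first$ci_high - first$ci_low) / 2
  if (any(first$index < -half_ci - 0.05 | first$index > 1 + half_ci + 0.05)) {
    warn("some first-order indices fall outside [0, 1] beyond their CI")
  }
  structure(list(first_order = first, second_order = second,
                 total_variance = point$V, n_base = n, order = order,
                 n_boot = n_boot, seed = as.integer(seed),
                 rejections = rejections),
            class = "bm_sobol")
}

#' @export
print.bm_sobol <- function(x, ...) {
  cat(sprintf("<bm_sobol: %d parameters, n_base = %d, Var(Y) = %.4g>\n",
              nrow(x$first_order), x$n_base, x$total_variance))
  print(x$first_order)
  invisible(x)
}

#' @export
tidy.bm_sobol <- function(x, ...) {
  first <- dplyr::mutate(x$first_order, order = 1L, parameter2 = NA_character_)
  first <- dplyr::rename(first, parameter1 = "parameter")
  out <- first
  if (!is.null(x$second_order)) {
    out <- dplyr::bind_rows(first, dplyr::mutate(x$second_order, order = 2L))
  }
  dplyr::select(out, "order", "parameter1", "parameter2", "index",
                "ci_low", "ci_high")
}

#' @export
glance.bm_sobol <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x$first_order),
    n_base = x$n_base,
    total_variance = x$total_variance,
    sum_first_order = sum(x$first_order$index),
    rejections = x$rejections,
    top = x$first_order$parameter[which.max(x$first_order$index)],
    bottom = x$first_order$parameter[which.min(x$first_order$index)]
  )
}

#' Plot first-order Sobol indices with bootstrap intervals
#' @param object a `bm_sobol` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bm_sobol <- function(object, ...) {
  df <- object$first_order
  df$parameter <- stats::reorder(df$parameter, df$index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$index)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "first-order Sobol index")
}

#' Scalarize a BOLD series
#'
#' The variance decomposition needs a scalar output; the BOLD response is a
#' time series. Supported reductions: `l2_norm` (default, coherent with the
#' grid-scan criterion's norm), `peak` (max), `time_average` (mean),
#' `sample_at` (value at the grid time nearest `at`).
#'
#' @param data a data frame with a `y` column (e.g. a [simulate_bold()]
#'   result), or a numeric vector.
#' @param mode one of `"l2_norm"`, `"peak"`, `"time_average"`, `"sample_at"`.
#' @param at time in seconds (for `sample_at`).
#' @return A finite scalar.
#' @export
bold_scalarize <- function(data, mode = c("l2_norm", "peak", "time_average",
                                          "sample_at"), at = NULL) {
  mode <- match.arg(mode)
  y <- pull_y(data)
  switch(mode,
    l2_norm = sqrt(sum(y^2)),
    peak = max(y),
    time_average = mean(y),
    sample_at = {
      if (is.null(at)) abort("mode 'sample_at' needs an 'at' time")
      if (!is.data.frame(data) || !"time" %in% names(data)) {
        abort("mode 'sample_at' needs a data frame with a 'time' column")
      }
      y[which.min(abs(data$time - at))]
    })
}

#' Sobol sensitivity of the Balloon BOLD response
#'
#' Composes [simulate_bold()] with [bold_scalarize()] into the scalar model
#' for [sobol_indices()], under uniform priors on the seven Balloon
#' parameters. Scanner constants track every sampled `E0` automatically
#' (they are derived, never stored). Sampled parameter vectors on which the
#' integration faults are rejection-resampled and counted.
#'
#' @param stimulus a `bm_stimulus`.
#' @param priors a priors table; default `bm_uniform_priors(nominal)`
#'   (independent uniform +/-20%).
#' @param n_base base Monte Carlo sample count.
#' @param seed integer seed.
#' @param mode scalarization mode, see [bold_scalarize()].
#' @param at time for `sample_at` scalarization.
#' @param nominal centre of the default priors.
#' @param order,n_boot as in [sobol_indices()].
#' @param ... passed to [simulate_bold()].
#' @return A `bm_sobol` object with scalarizer metadata attached.
#' @export
balloon_sobol <- function(stimulus, priors = NULL, n_base = 256, seed = 1,
                          mode = "l2_norm", at = NULL,
                          nominal = bm_nominal_params(), order = 2,
                          n_boot = 200, ...) {
  priors <- priors %||% bm_uniform_priors(nominal)
  dots <- list(...)
  model <- function(theta) {
    full <- bm_theta(nominal)
    full[names(theta)] <- theta
    tryCatch({
      sim <- do.call(simulate_bold,
                     c(list(stimulus, bm_from_theta(full)), dots))
      bold_scalarize(sim, mode = mode, at = at)
    }, error = function(e) NA_real_)
  }
  res <- sobol_indices(model, priors, n_base = n_base, seed = seed,
                       order = order, n_boot = n_boot,
                       resample_faults = TRUE)
  res$scalarizer <- mode
  res$paradigm <- attr(stimulus, "paradigm") %||% "custom"
  res
}
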