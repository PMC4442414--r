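#' Balloon model parameters
#'
#' Constructs the seven-parameter vector of the Balloon hemodynamic model in
#' the reciprocal (theta) convention: Grubb's stiffness exponent and the
#' venous transit time are stored as their inverses (`alpha_inv = 1/alpha`,
#' `tau_inv = 1/tau`), which is the parameterization the identifiability
#' scans operate in. The scanner observation constants k1, k2, k3 are never
#' stored: they are derived from the current `E0` on every evaluation
#' (k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2, the 1.5 T values).
#'
#' @param alpha_inv reciprocal Grubb exponent (dimensionless, > 0).
#' @param epsilon neural efficiency, the gain from stimulus to the
#'   flow-inducing signal (>= 0; zero decouples the stimulus).
#' @param kappa_s signal-decay rate (1/s, > 0).
#' @param kappa_f flow-feedback (autoregulation) rate (1/s^2, > 0).
#' @param tau_inv reciprocal venous transit time (1/s, > 0).
#' @param E0 resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting venous blood volume fraction, in (0, 1).
#'
#' @return An object of class `balloon_params`: a named list of the seven
#'   values plus derived physical accessors via [bm_physical()].
#' @examples
#' p <- balloon_params() # Friston-2000 nominal values
#' bm_theta(p)
#' bm_physical(p)
#' @export
balloon_params <- function(alpha_inv = 5, epsilon = 0.5, kappa_s = 1.25,
                           kappa_f = 2.5, tau_inv = 1, E0 = 0.8, V0 = 0.02) {
  p <- list(
    alpha_inv = as.numeric(alpha_inv), epsilon = as.numeric(epsilon),
    kappa_s = as.numeric(kappa_s), kappa_f = as.numeric(kappa_f),
    tau_inv = as.numeric(tau_inv), E0 = as.numeric(E0), V0 = as.numeric(V0)
  )
  validate_balloon_params(p)
  structure(p, class = "balloon_params")
}

#' @export
print.balloon_params <- function(x, ...) {
  cat("<balloon_params>\n")
  print(tibble::as_tibble(unclass(x)[bm_theta_labels()]))
  invisible(x)
}

validate_balloon_params <- function(p) {
  vals <- unlist(p[bm_theta_labels()])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("all Balloon parameters must be finite")
  }
  strict <- setdiff(bm_theta_labels(), "epsilon")
  if (any(vals[strict] <= 0)) {
    abort("alpha_inv, kappa_s, kappa_f, tau_inv, E0, V0 must be strictly positive")
  }
  if (p$epsilon < 0) abort("epsilon must be non-negative")
  if (p$E0 >= 1) abort("E0 must lie strictly inside (0, 1)")
  if (p$V0 >= 1) abort("V0 must lie strictly inside (0, 1)")
  invisible(p)
}

#' Theta-convention labels in canonical order
#'
#' Order follows the reciprocal parameterization theta1..theta7:
#' `alpha_inv, epsilon, kappa_s, kappa_f, tau_inv, E0, V0`.
#' @return Character vector of length 7.
#' @export
bm_theta_labels <- function() {
  c("alpha_inv", "epsilon", "kappa_s", "kappa_f", "tau_inv", "E0", "V0")
}

#' Extract the theta vector of a parameter set
#'
#' @param params a [balloon_params()] object.
#' @return Named numeric vector of length 7 in [bm_theta_labels()] order.
#' @export
bm_theta <- function(params) {
  stopifnot(inherits(params, "balloon_params"))
  unlist(unclass(params)[bm_theta_labels()])
}

#' Convert a theta vector back to a parameter object
#'
#' @param theta named or positional numeric vector of length 7 in
#'   [bm_theta_labels()] order.
#' @return A [balloon_params()] object.
#' @export
bm_from_theta <- function(theta) {
  stopifnot(length(theta) == 7)
  do.call(balloon_params, as.list(setNames(as.numeric(theta), bm_theta_labels())))
}

#' Physical-convention view of a parameter set
#'
#' Returns the same model in the physical convention (alpha and tau instead
#' of their reciprocals), convenient for reporting.
#' @param params a [balloon_params()] object.
#' @return Named numeric vector: alpha, epsilon, kappa_s, kappa_f, tau, E0, V0.
#' @export
bm_physical <- function(params) {
  stopifnot(inherits(params, "balloon_params"))
  c(alpha = 1 / params$alpha_inv, epsilon = params$epsilon,
    kappa_s = params$kappa_s, kappa_f = params$kappa_f,
    tau = 1 / params$tau_inv, E0 = params$E0, V0 = params$V0)
}

#' Nominal Balloon parameterization (packaged fixture)
#'
#' Reads the packaged JSON fixture holding the Friston-2000 nominal values
#' (theta = 5, 0.5, 1.25, 2.5, 1, 0.8, 0.02).
#' @return A [balloon_params()] object.
#' @export
bm_nominal_params <- function() {
  path <- system.file("extdata", "nominal_parameters.json",
                      package = "balloonid", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- unlist(cfg$theta)[paste0("theta", 1:7)]
  bm_from_theta(theta)
}

#' Scanner observation constants
#'
#' The BOLD observation coefficients at 1.5 T as functions of the resting
#' oxygen extraction fraction: k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2. k1 and k3
#' track E0, so they are recomputed rather than stored.
#'
#' @param E0 resting oxygen extraction fraction, in (0, 1).
#' @return Named numeric vector `c(k1, k2, k3)`.
#' @examples
#' scanner_constants(0.8) # k1 = 5.6, k2 = 2, k3 = 1.4
#' @export
scanner_constants <- function(E0) {
  if (!is.numeric(E0) || length(E0) != 1 || !is.finite(E0) ||
      E0 <= 0 || E0 >= 1) {
    abort("E0 must be a single number strictly inside (0, 1)")
  }
  c(k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2)
}

#' Perturb parameters multiplicatively
#'
#' Scales one parameter of a set by a multiplier, in theta convention, and
#' revalidates (so e.g. an E0 multiplier pushing E0 past 1 faults).
#' @param params a [balloon_params()] object.
#' @param parameter a label from [bm_theta_labels()].
#' @param multiplier positive scale factor.
#' @return A new [balloon_params()] object.
#' @export
bm_perturb <- function(params, parameter, multiplier) {
  parameter <- match.arg(parameter, bm_theta_labels())
  theta <- bm_theta(params)
  theta[parameter] <- theta[parameter] * multiplier
  bm_from_theta(theta)
}
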