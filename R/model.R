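#' Balloon model state derivatives
#'
#' Right-hand side of the four-state Balloon model. State order is
#' `(f, s, v, q)`: normalized blood flow, flow-inducing signal, normalized
#' venous volume, normalized deoxyhemoglobin content. The dynamics are
#' \deqn{\dot f = s, \quad \dot s = \epsilon u - \kappa_s s - \kappa_f (f - 1),}
#' \deqn{\dot v = \tau^{-1} (f - v^{1/\alpha}), \quad
#'       \dot q = \tau^{-1}\left(f \frac{1 - (1 - E_0)^{1/f}}{E_0}
#'                 - v^{1/\alpha - 1} q\right).}
#' `f`, `v`, `q` must be strictly positive: the fractional powers are
#' undefined otherwise and a violation is treated as a fault, never clipped.
#'
#' @param state numeric length-4 vector `(f, s, v, q)`.
#' @param u scalar stimulus value.
#' @param params a [balloon_params()] object.
#' @return Numeric length-4 vector of derivatives in state order.
#' @examples
#' balloon_rhs(rest_state(), u = 1, balloon_params())
#' @export
balloon_rhs <- function(state, u, params) {
  state <- check_state(state)
  if (!is.numeric(u) || length(u) != 1 || !is.finite(u)) {
    abort("u must be a single finite number")
  }
  stopifnot(inherits(params, "balloon_params"))
  as.numeric(balloon_rhs_cpp(state, u, bm_theta(params)))
}

#' BOLD observation equation
#'
#' Maps a hemodynamic state to the BOLD signal change:
#' \deqn{y = V_0 \left(k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)\right)}
#' with scanner constants from [scanner_constants()]. The output is exactly
#' linear in `V0` and vanishes at rest (`q = v = 1`).
#'
#' @inheritParams balloon_rhs
#' @return Scalar BOLD value (dimensionless signal change).
#' @export
balloon_observe <- function(state, params) {
  state <- check_state(state)
  stopifnot(inherits(params, "balloon_params"))
  as.numeric(balloon_observe_cpp(matrix(state, nrow = 1), bm_theta(params)))
}

#' The resting state
#'
#' Baseline-normalized rest: `(f, s, v, q) = (1, 0, 1, 1)`.
#' @return Named numeric length-4 vector.
#' @export
rest_state <- function() c(f = 1, s = 0, v = 1, q = 1)

#' Closed-form equilibrium under constant stimulus
#'
#' For constant input u the flow subsystem settles at
#' `f* = 1 + epsilon u / kappa_f`, and the balloon subsystem at
#' `v* = f*^alpha`, `q* = f* (1 - (1 - E0)^(1/f*)) / (E0 v*^(1/alpha - 1))`.
#' Used as an analytic oracle for the integrators.
#'
#' @param u constant stimulus value.
#' @param params a [balloon_params()] object.
#' @return Named numeric length-4 state vector at which [balloon_rhs()]
#'   vanishes.
#' @examples
#' balloon_steady_state(1, balloon_params()) # f* = 1.2 at nominal values
#' @export
balloon_steady_state <- function(u, params) {
  stopifnot(inherits(params, "balloon_params"))
  if (!is.numeric(u) || length(u) != 1 || !is.finite(u)) {
    abort("u must be a single finite number")
  }
  fs <- 1 + params$epsilon * u / params$kappa_f
  if (fs <= 0) abort("constant stimulus drives steady-state flow non-positive")
  alpha <- 1 / params$alpha_inv
  vs <- fs^alpha
  qs <- fs * (1 - (1 - params$E0)^(1 / fs)) / (params$E0 * vs^(params$alpha_inv - 1))
  c(f = fs, s = 0, v = vs, q = qs)
}

check_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 4 || any(!is.finite(state))) {
    abort("state must be a finite length-4 vector (f, s, v, q)")
  }
  if (state[1] <= 0 || state[3] <= 0 || state[4] <= 0) {
    abort("f, v and q must be strictly positive (model domain fault)")
  }
  state
}
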