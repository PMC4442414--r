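#' Jacobian projection index
#'
#' The local sensitivity measure for one parameter: the squared norm of the
#' component of its Jacobian column `J_i` orthogonal to the column space of
#' the other columns `J_-i`,
#' \deqn{\pi_i = J_i^T (I - J_{-i} J_{-i}^{+}) J_i,}
#' with the pseudoinverse taken by singular value decomposition. A value of
#' zero means a small change in the parameter can be completely offset by a
#' combination of the others; the maximum `||J_i||^2` means no offset at all.
#'
#' @param J_i numeric vector over time samples.
#' @param J_minus_i numeric matrix with `length(J_i)` rows: the Jacobian
#'   columns of the remaining parameters.
#' @param svd_tol singular-value cutoff for the pseudoinverse; default
#'   `max(dim) * eps * sigma_max` (standard pseudoinverse practice).
#' @return Non-negative scalar `pi_i`.
#' @examples
#' projection_index(c(1, 1, 0), matrix(c(1, 0, 0), ncol = 1)) # 1
#' @export
projection_index <- function(J_i, J_minus_i, svd_tol = NULL) {
  J_i <- as.numeric(J_i)
  J_minus_i <- as.matrix(J_minus_i)
  if (any(!is.finite(J_i)) || any(!is.finite(J_minus_i))) {
    abort("Jacobian entries must be finite")
  }
  if (length(J_i) != nrow(J_minus_i)) {
    abort("J_i length must equal the row count of J_minus_i")
  }
  sv <- svd(J_minus_i)
  if (is.null(svd_tol)) {
    svd_tol <- max(dim(J_minus_i)) * .Machine$double.eps * max(sv$d, 0)
  }
  keep <- sv$d > svd_tol
  resid <- if (any(keep)) {
    U <- sv$u[, keep, drop = FALSE]
    J_i - U %*% crossprod(U, J_i)
  } else {
    J_i
  }
  max(sum(resid^2), 0)
}

#' Local identifiability of the Balloon parameters
#'
#' Builds the BOLD trajectory Jacobian under a stimulus and computes the
#' projection index for every parameter in `subset`. The default subset is
#' the six dynamical/observation parameters excluding `V0`, the set the
#' local-identifiability literature scans; `V0` can be opted in. A normalized
#' index `pi / ||J_i||^2` in `[0, 1]` is reported alongside the raw value so
#' parameters of very different scales can be ranked.
#'
#' @param stimulus a `bm_stimulus`.
#' @param params a [balloon_params()] object.
#' @param subset parameter labels (>= 2 of [bm_theta_labels()]).
#' @param rel_step finite-difference step for [bold_jacobian()].
#' @param svd_tol pseudoinverse cutoff, as in [projection_index()].
#' @param ... passed to [simulate_bold()] via [bold_jacobian()].
#' @return A `bm_local` object: tibble with columns `parameter`, `pi`,
#'   `pi_normalized`, `jac_norm_sq`; attributes carry the Jacobian rank and
#'   the cutoff used.
#' @export
local_sensitivity <- function(stimulus, params,
                              subset = setdiff(bm_theta_labels(), "V0"),
                              rel_step = 1e-4, svd_tol = NULL, ...) {
  subset <- match.arg(subset, bm_theta_labels(), several.ok = TRUE)
  if (length(subset) < 2) abort("subset must contain at least two parameters")
  J <- bold_jacobian(stimulus, params, subset = subset, rel_step = rel_step, ...)
  sv_full <- svd(J, nu = 0, nv = 0)$d
  tol_full <- max(dim(J)) * .Machine$double.eps * max(sv_full)
  pis <- vapply(seq_along(subset), function(i) {
    projection_index(J[, i], J[, -i, drop = FALSE], svd_tol = svd_tol)
  }, numeric(1))
  norms <- colSums(J^2)
  out <- tibble::tibble(
    parameter = subset,
    pi = pis,
    pi_normalized = ifelse(norms > 0, pis / norms, NA_real_),
    jac_norm_sq = unname(norms)
  )
  structure(out,
            jacobian_rank = sum(sv_full > tol_full),
            svd_tolerance = svd_tol %||% "max(dim)*eps*sigma_max",
            rel_step = rel_step,
            class = c("bm_local", class(out)))
}

#' @export
print.bm_local <- function(x, ...) {
  cat(sprintf("<bm_local: Jacobian rank %d over %d parameters>\n",
              attr(x, "jacobian_rank"), nrow(x)))
  NextMethod()
}

#' @export
tidy.bm_local <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.bm_local <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    jacobian_rank = attr(x, "jacobian_rank"),
    best = x$parameter[which.max(x$pi_normalized)],
    worst = x$parameter[which.min(x$pi_normalized)]
  )
}

#' Plot normalized projection indices
#' @param object a `bm_local` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bm_local <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- stats::reorder(df$parameter, df$pi_normalized)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                   y = .data$pi_normalized)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized projection index")
}
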