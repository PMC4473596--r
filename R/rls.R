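#' Initialise the RLS inverse-correlation matrix
#'
#' `P(0) = I / alpha`, where `alpha` is the (reconfigurable) learning-rate
#' parameter: small `alpha` learns fast but risks divergence, large
#' `alpha` converges slowly.
#'
#' @param N matrix dimension (network size).
#' @param alpha learning-rate parameter, > 0.
#' @return The `N x N` matrix `I / alpha`.
#' @export
init_P <- function(N, alpha = 1) {
  check_scalar(N, "N"); check_scalar(alpha, "alpha")
  if (N < 1) stop_invalid("N must be >= 1")
  if (alpha <= 0) mf_stop("alpha must be positive", "memforce_invalid_input")
  diag(1 / alpha, as.integer(N))
}

#' Rank-one RLS update of the inverse-correlation matrix
#'
#' `P' = P - (P r)(P r)^T / (1 + r^T P r)`. Applied cumulatively over a
#' rate history this keeps `P` equal to the direct inverse
#' `(alpha I + sum_s r_s r_s^T)^{-1}` (Sherman-Morrison), and preserves
#' symmetry and positive definiteness.
#'
#' @param P symmetric positive-definite `N x N` matrix.
#' @param r rate vector of length `N`.
#' @return The updated matrix `P'`.
#' @export
update_P <- function(P, r) {
  r <- as.numeric(r)
  Pr <- as.vector(P %*% r)
  den <- 1 + sum(r * Pr)
  if (!is.finite(den) || den <= 0)
    mf_stop(sprintf("RLS denominator %.3g <= 0: P lost positive definiteness", den),
            "memforce_numerical_error")
  P - tcrossprod(Pr) / den
}

#' Output error signal
#'
#' `e(t) = z(t) - f(t)`, elementwise over readout channels.
#'
#' @param z readout vector.
#' @param f target vector of the same length.
#' @return The error vector.
#' @export
compute_error <- function(z, f) {
  if (length(z) != length(f))
    stop_invalid("z and f must have the same length")
  as.numeric(z) - as.numeric(f)
}

#' RLS weight increment for one trained row
#'
#' `delta_w = -e * (P r)`: the same increment is applied to every trained
#' internal row of `W_NN` (with the row's error in partition/feedback
#' modes) and to the readout row with that readout's error.
#'
#' @param P inverse-correlation matrix.
#' @param r rate vector.
#' @param e_scalar scalar error driving this row.
#' @return Increment vector of length `N`.
#' @export
weight_increment <- function(P, r, e_scalar) {
  check_scalar(e_scalar, "e_scalar")
  -e_scalar * as.vector(P %*% as.numeric(r))
}
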