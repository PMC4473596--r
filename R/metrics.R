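#' Normalised root-mean-square error
#'
#' `RMSE(z, f) / sd(f)`, computed per channel for matrix inputs (columns =
#' channels) and averaged unless `per_channel = TRUE`. A constant target
#' has no scale and raises an error.
#'
#' @param z produced output (vector or `n x k` matrix).
#' @param f target of the same shape.
#' @param per_channel if `TRUE`, return the per-channel vector.
#' @return Scalar NRMSE (or per-channel vector).
#' @export
nrmse <- function(z, f, per_channel = FALSE) {
  z <- as.matrix(z); f <- as.matrix(f)
  if (!all(dim(z) == dim(f))) stop_invalid("z and f must have the same shape")
  s <- apply(f, 2, sd)
  if (any(s == 0))
    mf_stop("constant target channel: NRMSE normalisation undefined",
            "memforce_invalid_input")
  v <- sqrt(colMeans((z - f)^2)) / s
  if (per_channel) v else mean(v)
}

#' Phase-aligned NRMSE
#'
#' Minimum of [nrmse()] over circular time shifts of the output by up to
#' one period, per channel: the metric a periodic pattern generator is
#' judged by when a constant phase offset between output and target is
#' acceptable. Cross-correlations are evaluated with the FFT
#' (`O(n log n)` per channel).
#'
#' @param z produced output (vector or `n x k` matrix).
#' @param f target of the same shape.
#' @param period_steps number of shifts to search (one period of the
#'   pattern on the grid); capped at the signal length.
#' @param per_channel if `TRUE`, return the per-channel vector (each
#'   channel aligned independently).
#' @return Scalar (mean over channels) or per-channel vector.
#' @export
phase_aligned_nrmse <- function(z, f, period_steps, per_channel = FALSE) {
  z <- as.matrix(z); f <- as.matrix(f)
  if (!all(dim(z) == dim(f))) stop_invalid("z and f must have the same shape")
  n <- nrow(z)
  period_steps <- min(as.integer(period_steps), n)
  if (period_steps < 1) stop_invalid("period_steps must be >= 1")
  s <- apply(f, 2, sd)
  if (any(s == 0))
    mf_stop("constant target channel: NRMSE normalisation undefined",
            "memforce_invalid_input")
  out <- numeric(ncol(z))
  for (j in seq_len(ncol(z))) {
    zz <- z[, j]; ff <- f[, j]
    # circular cross-correlation sum_t z[(t - k) mod n] * f[t] for all k
    cc <- Re(fft(fft(ff) * Conj(fft(zz)), inverse = TRUE)) / n
    ks <- seq_len(period_steps)    # shifts 0 .. period_steps - 1
    sse <- sum(zz^2) + sum(ff^2) - 2 * cc[ks]
    out[j] <- sqrt(max(0, min(sse)) / n) / s[j]
  }
  if (per_channel) out else mean(out)
}

# direct (loop) evaluation, kept as the slow reference for the FFT path
phase_aligned_nrmse_direct <- function(z, f, period_steps) {
  z <- as.numeric(z); f <- as.numeric(f)
  n <- length(z)
  best <- Inf
  for (k in seq_len(min(period_steps, n)) - 1) {
    zs <- if (k == 0) z else c(z[(n - k + 1):n], z[1:(n - k)])
    best <- min(best, sqrt(mean((zs - f)^2)) / sd(f))
  }
  best
}
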