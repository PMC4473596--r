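#' Parameters of the recurrent firing-rate network
#'
#' The network follows the classical leaky firing-rate equations: membrane
#' potentials `x` (length `N`) obey
#' `tau dx/dt = -x + g W_NN r + W_NI I(t)` with rates r = tanh(x) and a
#' linear readout `z = W_ZN r`. The gain `g` sets the dynamic regime:
#' below 1 activity decays (echo regime), above roughly 1 the autonomous
#' network is chaotic, the substrate exploited by FORCE learning.
#'
#' @param N neuron count (>= 2).
#' @param g dimensionless synaptic gain; default 1.5 (chaotic regime).
#' @param tau membrane time constant, seconds.
#' @param dt Euler integration step, seconds (`0 < dt <= tau`). Forward
#'   Euler mirrors the difference-equation (accumulator) form used by
#'   digital neuron hardware.
#' @param p_conn internal connection probability (1 = full).
#' @param n_in external input channels (0 = autonomous).
#' @param n_out readout channels.
#' @return A list of class `"network_params"`.
#' @export
network_params <- function(N = 500, g = 1.5, tau = 0.01, dt = 0.001,
                           p_conn = 1, n_in = 0, n_out = 1) {
  for (nm in c("N", "g", "tau", "dt", "p_conn", "n_in", "n_out"))
    check_scalar(get(nm), nm)
  if (N < 2) stop_invalid("N must be at least 2")
  if (g <= 0) stop_invalid("g must be positive")
  if (dt <= 0 || dt > tau) stop_invalid("need 0 < dt <= tau")
  if (p_conn <= 0 || p_conn > 1) stop_invalid("p_conn must lie in (0, 1]")
  if (n_in < 0) stop_invalid("n_in must be >= 0")
  if (n_out < 1) stop_invalid("n_out must be >= 1")
  structure(list(N = as.integer(N), g = g, tau = tau, dt = dt,
                 p_conn = p_conn, n_in = as.integer(n_in),
                 n_out = as.integer(n_out)),
            class = "network_params")
}

#' Initialise network weights and state
#'
#' Internal weights `W_NN` are i.i.d. Gaussian with variance
#' `1 / (p_conn * N)`, zeroed outside a fixed Bernoulli(`p_conn`) mask
#' (the mask never changes afterwards: pruned synapses stay absent through
#' training). Input weights `W_NI` are uniform on `[-1, 1]`; readout
#' weights `W_ZN` Gaussian with standard deviation `1/sqrt(N)`; the initial
#' membrane potential is small Gaussian noise (s.d. 0.5) with
#' r = tanh(x). Uses R's current RNG stream; set the seed first for
#' reproducibility.
#'
#' @param params a [network_params()].
#' @return A list of class `"rate_network"` with elements `params`,
#'   `weights` (`W_NN`, `W_NI`, `W_ZN`, `mask`) and `state`
#'   (`x`, `r`, `t`).
#' @export
init_network <- function(params) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  mask <- if (params$p_conn < 1)
    matrix(runif(N * N) < params$p_conn, N, N) * 1 else matrix(1, N, N)
  W_NN <- matrix(rnorm(N * N, sd = 1 / sqrt(params$p_conn * N)), N, N) * mask
  W_NI <- if (params$n_in > 0)
    matrix(runif(N * params$n_in, -1, 1), N, params$n_in)
  else matrix(0, N, 0)
  W_ZN <- matrix(rnorm(params$n_out * N, sd = 1 / sqrt(N)), params$n_out, N)
  x <- rnorm(N, sd = 0.5)
  structure(list(
    params = params,
    weights = list(W_NN = W_NN, W_NI = W_NI, W_ZN = W_ZN, mask = mask),
    state = list(x = x, r = tanh(x), t = 0)),
    class = "rate_network")
}

#' One forward-Euler step of the rate dynamics
#'
#' Reference (pure R) single-step update:
#' `x <- x + (dt/tau) * (-x + g * W_NN %*% r + W_NI %*% input)`, after
#' which r and t are refreshed (r = tanh(x), t = t + dt).
#'
#' @param state list with `x`, `r`, `t` (as in a `"rate_network"`).
#' @param weights list with `W_NN`, `W_NI` (as in a `"rate_network"`).
#' @param params a [network_params()].
#' @param input external input vector of length `n_in` (ignored when
#'   `n_in = 0`).
#' @return The updated state list.
#' @export
step_network <- function(state, weights, params, input = numeric(0)) {
  drive <- params$g * as.vector(weights$W_NN %*% state$r)
  if (params$n_in > 0) {
    if (length(input) != params$n_in)
      stop_invalid("input length must equal n_in")
    drive <- drive + as.vector(weights$W_NI %*% input)
  }
  x <- state$x + (params$dt / params$tau) * (-state$x + drive)
  if (!all(is.finite(x)))
    mf_stop("network state diverged (non-finite membrane potential)",
            "memforce_divergence")
  list(x = x, r = tanh(x), t = state$t + params$dt)
}

#' Linear readout
#'
#' @param state list with rate vector `r`.
#' @param weights list with readout matrix `W_ZN`.
#' @return Readout vector `z = W_ZN r`, length `n_out`.
#' @export
readout <- function(state, weights) {
  as.vector(weights$W_ZN %*% state$r)
}

#' Free-run the network and record its trajectory
#'
#' Iterates [step_network()] `n_steps` times (compiled loop), recording
#' time, readout and optionally the full rate vector at every step.
#'
#' @param net a `"rate_network"` (or a list with `params`, `weights`,
#'   `state`).
#' @param n_steps number of Euler steps; alternatively give `T_total`
#'   (seconds, a multiple of `dt`).
#' @param inputs either `NULL` (no input), a vector of length `n_in`
#'   (held constant), or an `n_steps x n_in` matrix.
#' @param T_total duration in seconds (used when `n_steps` is missing).
#' @param record_r if `TRUE`, also return the `n_steps x N` rate matrix.
#' @return List with `t` (times), `z` (`n_steps x n_out` readout matrix),
#'   optionally `r`, and `net` (the advanced network).
#' @export
run_network <- function(net, n_steps = NULL, inputs = NULL, T_total = NULL,
                        record_r = FALSE) {
  p <- net$params
  if (is.null(n_steps)) {
    if (is.null(T_total)) stop_invalid("give n_steps or T_total")
    n_steps <- round(T_total / p$dt)
    if (abs(n_steps * p$dt - T_total) > 1e-9 * max(1, T_total))
      stop_invalid("T_total must be a multiple of dt")
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop_invalid("n_steps must be >= 0")
  if (n_steps == 0) {
    return(list(t = numeric(0),
                z = matrix(0, 0, p$n_out),
                net = net))
  }
  I <- expand_inputs(inputs, n_steps, p$n_in)
  res <- run_network_cpp(net$weights$W_NN, net$weights$W_NI,
                         net$weights$W_ZN, net$state$x,
                         p$g, p$dt / p$tau, I, n_steps, record_r)
  net$state <- list(x = as.vector(res$x), r = tanh(as.vector(res$x)),
                    t = net$state$t + n_steps * p$dt)
  out <- list(t = net$state$t - p$dt * (n_steps:1) + p$dt, z = res$z,
              net = net)
  if (record_r) out$r <- res$r
  out
}

expand_inputs <- function(inputs, n_steps, n_in) {
  if (n_in == 0) return(matrix(0, n_steps, 0))
  if (is.null(inputs)) return(matrix(0, n_steps, n_in))
  if (is.matrix(inputs)) {
    if (nrow(inputs) != n_steps || ncol(inputs) != n_in)
      stop_invalid("inputs matrix must be n_steps x n_in")
    return(inputs)
  }
  if (length(inputs) != n_in)
    stop_invalid("constant input must have length n_in")
  matrix(rep(as.numeric(inputs), each = n_steps), n_steps, n_in)
}
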