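#' Behavioural iron-oxide memristor state
#'
#' A single two-terminal resistive device whose conductance `G` is bounded in
#' `[G_min, G_max]` and moves only under programming pulses whose amplitude
#' exceeds the threshold `V_th`. A supra-threshold positive pulse potentiates
#' the device by a fixed fraction `eta_pot` of the remaining headroom
#' (`G <- G + eta_pot * (G_max - G)`); a negative pulse depresses it by
#' `eta_dep` of the distance to the floor. This bounded-geometric ("soft
#' saturation") update reproduces the measured LTP/LTD staircases of FeOx
#' devices, where a 15-pulse train traverses most of the conductance window
#' with per-pulse steps that shrink near the rails. Fine tuning uses a
#' differential pulse pair (one potentiating + one depressing pulse of
#' unequal effect) whose net action is a fixed resistance step
#' `delta_R_pair`.
#'
#' Defaults follow the measured device: conductance window 1.5--4.5 mS
#' (resistance ratio 3), write pulses of |1.6| V with a programming
#' threshold between the 0.1 V read voltage and the write voltage, and a
#' minimum differential-pair resistance step of 0.6 ohm, i.e. a relative
#' precision of about 0.27% at the low-resistance state.
#'
#' @param G initial conductance in siemens.
#' @param G_min,G_max conductance bounds in siemens, `0 < G_min < G_max`.
#' @param eta_pot,eta_dep per-pulse potentiation/depression rates in (0, 1).
#' @param V_th programming threshold magnitude in volts.
#' @param delta_R_pair net resistance step of one differential pulse pair,
#'   in ohms.
#' @return An object of class `"memristor"`.
#' @examples
#' m <- memristor(3e-3)
#' m <- apply_pulse(m, pulse_spec(1.6))
#' read_current(m, 0.1)
#' @export
memristor <- function(G = 3e-3, G_min = 1.5e-3, G_max = 4.5e-3,
                      eta_pot = 0.18, eta_dep = 0.18,
                      V_th = 0.8, delta_R_pair = 0.6) {
  for (nm in c("G", "G_min", "G_max", "eta_pot", "eta_dep", "V_th",
               "delta_R_pair"))
    check_scalar(get(nm), nm)
  if (G_min <= 0 || G_max <= G_min)
    stop_invalid("need 0 < G_min < G_max")
  if (eta_pot <= 0 || eta_pot >= 1 || eta_dep <= 0 || eta_dep >= 1)
    stop_invalid("eta_pot and eta_dep must lie in (0, 1)")
  if (V_th <= 0) stop_invalid("V_th must be positive")
  if (delta_R_pair <= 0) stop_invalid("delta_R_pair must be positive")
  structure(
    list(G = min(max(G, G_min), G_max), G_min = G_min, G_max = G_max,
         eta_pot = eta_pot, eta_dep = eta_dep, V_th = V_th,
         delta_R_pair = delta_R_pair),
    class = "memristor")
}

#' @export
print.memristor <- function(x, ...) {
  cat(sprintf(
    "<memristor> G = %.4g mS in [%.4g, %.4g] mS, eta = (%.3g, %.3g), V_th = %.3g V\n",
    x$G * 1e3, x$G_min * 1e3, x$G_max * 1e3, x$eta_pot, x$eta_dep, x$V_th))
  invisible(x)
}

#' Programming pulse specification
#'
#' @param amplitude signed pulse amplitude in volts.
#' @param width pulse width in seconds (carried for bookkeeping; the
#'   behavioural update depends on the amplitude sign and threshold only,
#'   as devices are programmed with fixed-width pulses).
#' @return An object of class `"pulse_spec"`.
#' @export
pulse_spec <- function(amplitude, width = 10e-6) {
  check_scalar(amplitude, "amplitude")
  check_scalar(width, "width")
  if (width <= 0) stop_invalid("pulse width must be positive")
  structure(list(amplitude = amplitude, width = width), class = "pulse_spec")
}

#' Apply one programming pulse to a memristor
#'
#' Sub-threshold pulses (`|amplitude| < V_th`) leave the conductance
#' bit-identical. A supra-threshold positive pulse moves `G` up by
#' `eta_pot * (G_max - G)`; a negative pulse moves it down by
#' `eta_dep * (G - G_min)`. The result is clamped to `[G_min, G_max]`.
#'
#' @param state a [memristor()].
#' @param pulse a [pulse_spec()].
#' @return The updated `"memristor"`.
#' @export
apply_pulse <- function(state, pulse) {
  stopifnot(inherits(state, "memristor"))
  if (!inherits(pulse, "pulse_spec")) pulse <- do.call(pulse_spec, as.list(pulse))
  a <- pulse$amplitude
  if (abs(a) < state$V_th) return(state)
  g <- state$G
  g <- if (a > 0) g + state$eta_pot * (state$G_max - g)
       else       g - state$eta_dep * (g - state$G_min)
  state$G <- min(max(g, state$G_min), state$G_max)
  state
}

#' Apply one differential pulse pair (fine programming step)
#'
#' A pair of opposite-polarity pulses whose net effect is a fixed change of
#' the device *resistance* by `delta_R_pair` ohms: `direction = +1` is net
#' potentiation (resistance decreases), `direction = -1` net depression.
#' Conversion back to conductance is exact (`G' = 1 / (1/G -+ delta_R)`)
#' and the result is clamped to the conductance window.
#'
#' @param state a [memristor()].
#' @param direction `+1` (potentiate) or `-1` (depress).
#' @return The updated `"memristor"`.
#' @export
apply_pulse_pair <- function(state, direction) {
  stopifnot(inherits(state, "memristor"))
  check_scalar(direction, "direction")
  if (!direction %in% c(-1, 1))
    stop_invalid("direction must be +1 or -1")
  r_new <- 1 / state$G - direction * state$delta_R_pair
  g <- if (r_new <= 0) state$G_max else 1 / r_new
  state$G <- min(max(g, state$G_min), state$G_max)
  state
}

#' Non-disturbing read of a memristor
#'
#' Returns the Ohmic current `G * v_read`. Reading never modifies the
#' device; a read voltage at or above the programming threshold is a
#' protocol violation and raises a `memforce_read_disturb` error.
#'
#' @param state a [memristor()].
#' @param v_read read voltage in volts, `|v_read| < V_th`.
#' @return Current in amperes.
#' @export
read_current <- function(state, v_read = 0.1) {
  stopifnot(inherits(state, "memristor"))
  check_scalar(v_read, "v_read")
  if (abs(v_read) >= state$V_th)
    mf_stop(sprintf("read voltage %.3g V would disturb the device (V_th = %.3g V)",
                    v_read, state$V_th),
            "memforce_read_disturb")
  state$G * v_read
}

#' Calibrate pulse-response rates from a measured LTP/LTD staircase
#'
#' Fits the bounded-geometric update model to a measured conductance
#' staircase: a potentiation ramp followed by a depression ramp (as produced
#' by consecutive +/- pulse trains with reads in between). Under the model,
#' each potentiation step satisfies `dG_k = eta_pot * (G_max - G_k)`, so
#' `eta_pot` is estimated by least squares through the origin of the
#' increments on the remaining headroom (and symmetrically for
#' `eta_dep` on `G_k - G_min`).
#'
#' @param pulse_trace a data frame (or matrix) with columns `pulse_index`
#'   and `conductance_S`, or a path to a CSV file with those columns.
#' @param G_min,G_max conductance bounds of the device under test, siemens.
#' @return A list with elements `eta_pot` and `eta_dep`, both in (0, 1).
#' @examples
#' # a bundled synthetic staircase (15 LTP + 15 LTD pulses, 0.5% noise)
#' trace <- system.file("extdata", "ltp_ltd_staircase_synthetic.csv",
#'                      package = "memforce")
#' calibrate_from_trace(trace)
#' @importFrom stats optimize
#' @export
calibrate_from_trace <- function(pulse_trace, G_min = 1.5e-3, G_max = 4.5e-3) {
  if (is.character(pulse_trace)) pulse_trace <- read.csv(pulse_trace)
  tr <- as.data.frame(pulse_trace)
  if (!all(c("pulse_index", "conductance_S") %in% names(tr))) {
    if (ncol(tr) >= 2) names(tr)[1:2] <- c("pulse_index", "conductance_S")
    else mf_stop("trace needs columns pulse_index, conductance_S",
                 "memforce_calibration_error")
  }
  tr <- tr[order(tr$pulse_index), , drop = FALSE]
  g <- tr$conductance_S
  if (length(g) < 5 || !all(is.finite(g)))
    mf_stop("trace too short or non-finite", "memforce_calibration_error")
  span <- diff(range(g))
  if (span < 1e-3 * (G_max - G_min))
    mf_stop("trace shows no conductance modulation", "memforce_calibration_error")
  peak <- which.max(g)
  pot <- g[seq_len(peak)]
  dep <- g[peak:length(g)]
  # Under the geometric model the headroom decays as A (1 - eta)^k; fit
  # (A, eta) by least squares on the conductances themselves (noise on the
  # measured G is additive on that scale), profiling out the linear A.
  fit_rate <- function(headroom) {
    k <- seq_along(headroom) - 1
    if (length(k) < 3) return(NA_real_)
    sse <- function(eta) {
      b <- (1 - eta)^k
      a <- sum(headroom * b) / sum(b^2)
      sum((headroom - a * b)^2)
    }
    optimize(sse, c(1e-4, 1 - 1e-4), tol = 1e-10)$minimum
  }
  if (length(pot) < 3 || sum(diff(pot)) <= 0)
    mf_stop("need >= 2 monotone potentiation increments", "memforce_calibration_error")
  if (length(dep) < 3 || sum(diff(dep)) >= 0)
    mf_stop("need >= 2 monotone depression increments", "memforce_calibration_error")
  eta_pot <- fit_rate(G_max - pot)
  eta_dep <- fit_rate(dep - G_min)
  if (!is.finite(eta_pot) || !is.finite(eta_dep) ||
      eta_pot <= 0 || eta_pot >= 1 || eta_dep <= 0 || eta_dep >= 1)
    mf_stop("calibration produced rates outside (0, 1)", "memforce_calibration_error")
  list(eta_pot = eta_pot, eta_dep = eta_dep)
}

#' Simulate an LTP/LTD pulse-train measurement
#'
#' Convenience generator for calibration fixtures: applies `n_pulses`
#' potentiating then `n_pulses` depressing supra-threshold pulses to a
#' device, reading the conductance after each, optionally with
#' multiplicative read noise.
#'
#' @param state a [memristor()]; the staircase starts from its `G`.
#' @param n_pulses pulses per polarity (the measurement protocol uses 15).
#' @param amplitude write amplitude in volts.
#' @param noise_sd multiplicative Gaussian noise s.d. on each read (0 = none).
#' @return Data frame with columns `pulse_index`, `conductance_S`.
#' @export
pulse_train_trace <- function(state, n_pulses = 15, amplitude = 1.6,
                              noise_sd = 0) {
  stopifnot(inherits(state, "memristor"))
  g <- numeric(2 * n_pulses + 1)
  g[1] <- state$G
  for (k in seq_len(n_pulses)) {
    state <- apply_pulse(state, pulse_spec(amplitude))
    g[k + 1] <- state$G
  }
  for (k in seq_len(n_pulses)) {
    state <- apply_pulse(state, pulse_spec(-amplitude))
    g[n_pulses + k + 1] <- state$G
  }
  if (noise_sd > 0) g <- g * (1 + rnorm(length(g), 0, noise_sd))
  data.frame(pulse_index = seq_along(g) - 1L, conductance_S = g)
}
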