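#' Differential two-memristor synapse
#'
#' A signed synaptic weight realised by two memristors (conductances `G_1`,
#' `G_2`) feeding an inverting amplifier with feedback resistance `R_f`:
#' the effective weight is `w = -R_f * (G_1 - G_2)`. With the default
#' device window of 1.5--4.5 mS and `R_f = 330` ohm the weight spans
#' `[-0.99, +0.99]` even though the device resistance ratio is only 3.
#'
#' @param G1,G2 initial conductances of the two devices, siemens.
#' @param R_f amplifier feedback resistance, ohms.
#' @param ... further device parameters passed to [memristor()] (shared by
#'   both devices).
#' @return An object of class `"diff_synapse"` with fields `m1`, `m2`, `R_f`.
#' @examples
#' s <- diff_synapse(4.5e-3, 1.5e-3)
#' synapse_weight(s)      # -0.99
#' joint_conductance(s)   # +3 mS
#' @export
diff_synapse <- function(G1 = 3e-3, G2 = 3e-3, R_f = 330, ...) {
  check_scalar(R_f, "R_f")
  if (R_f <= 0) stop_invalid("R_f must be positive")
  s <- structure(
    list(m1 = memristor(G1, ...), m2 = memristor(G2, ...), R_f = R_f),
    class = "diff_synapse")
  s
}

#' @export
print.diff_synapse <- function(x, ...) {
  cat(sprintf("<diff_synapse> G1 = %.4g mS, G2 = %.4g mS, R_f = %g ohm, w = %.4f\n",
              x$m1$G * 1e3, x$m2$G * 1e3, x$R_f, synapse_weight(x)))
  invisible(x)
}

#' Effective synaptic weight of a differential synapse
#'
#' @param s a [diff_synapse()].
#' @return The dimensionless weight `-R_f * (G_1 - G_2)`.
#' @export
synapse_weight <- function(s) {
  stopifnot(inherits(s, "diff_synapse"))
  -s$R_f * (s$m1$G - s$m2$G)
}

#' Joint conductance of a differential synapse
#'
#' @param s a [diff_synapse()].
#' @return `G_1 - G_2` in siemens, always within `[-(G_max - G_min),
#'   +(G_max - G_min)]`.
#' @export
joint_conductance <- function(s) {
  stopifnot(inherits(s, "diff_synapse"))
  s$m1$G - s$m2$G
}

#' Weight range representable by a differential synapse
#' @param s a [diff_synapse()].
#' @return Scalar: `R_f * (G_max - G_min)`, the maximum `|w|`.
#' @export
weight_range <- function(s) {
  stopifnot(inherits(s, "diff_synapse"))
  s$R_f * (s$m1$G_max - s$m1$G_min)
}

#' Choose which device to modulate (four-case programming scheme)
#'
#' To increase the weight `w = -R_f (G_1 - G_2)` one may depress device 1
#' or potentiate device 2; to decrease it, potentiate device 1 or depress
#' device 2. Exactly one device changes per modulation stage. The rule
#' picks the device with the larger conductance headroom in the required
#' direction; on a tie device 2 is modulated (fixed, documented tie-break).
#'
#' @param s a [diff_synapse()].
#' @param delta_w_sign `+1` to increase the weight, `-1` to decrease it.
#' @return A list with `device` (`"m1"` or `"m2"`) and `direction`
#'   (`+1` potentiate, `-1` depress).
#' @export
plan_update <- function(s, delta_w_sign) {
  stopifnot(inherits(s, "diff_synapse"))
  check_scalar(delta_w_sign, "delta_w_sign")
  if (!delta_w_sign %in% c(-1, 1))
    stop_invalid("delta_w_sign must be +1 or -1")
  if (delta_w_sign > 0) {
    h1 <- s$m1$G - s$m1$G_min       # depress m1
    h2 <- s$m2$G_max - s$m2$G       # potentiate m2
    dir1 <- -1; dir2 <- +1
  } else {
    h1 <- s$m1$G_max - s$m1$G       # potentiate m1
    h2 <- s$m2$G - s$m2$G_min       # depress m2
    dir1 <- +1; dir2 <- -1
  }
  if (h1 <= 0 && h2 <= 0)
    mf_stop("no conductance headroom in the requested direction",
            "memforce_no_headroom")
  if (h2 >= h1) list(device = "m2", direction = dir2)
  else          list(device = "m1", direction = dir1)
}

#' Closed-loop programming of a synapse to a target weight
#'
#' Write-verify loop implementing the two-speed modulation protocol: while
#' the weight error exceeds `coarse_frac` of the full weight range, full
#' supra-threshold pulses (bounded-geometric steps) are applied to the
#' device chosen by [plan_update()]; inside the band, differential pulse
#' pairs (fixed 0.6-ohm resistance steps by default) step the weight toward
#' the target for as long as a step still reduces the error. Each
#' iteration modulates exactly one device (one modulation stage). The loop
#' stops within `tol` of the full weight range of the target, typically
#' within half a fine step.
#'
#' @param s a [diff_synapse()].
#' @param w_target target weight; must satisfy `|w_target| <= weight_range(s)`.
#' @param tol relative tolerance as a fraction of the full weight range
#'   (2 * weight_range); default 0.003, the device's achievable precision.
#' @param coarse_frac coarse/fine switchover band as a fraction of the full
#'   weight range.
#' @param write_amplitude amplitude of coarse programming pulses, volts.
#' @param max_iter safety bound on modulation stages.
#' @return The programmed `"diff_synapse"`, with attributes
#'   `pulses_coarse` and `pulses_fine` (counts used by this call).
#' @export
program_to_target <- function(s, w_target, tol = 0.003, coarse_frac = 0.05,
                              write_amplitude = 1.6, max_iter = 10000L) {
  stopifnot(inherits(s, "diff_synapse"))
  check_scalar(w_target, "w_target")
  wmax <- weight_range(s)
  full_range <- 2 * wmax
  if (abs(w_target) > wmax + 1e-12)
    mf_stop(sprintf("target weight %.4f outside representable range [%.4f, %.4f]",
                    w_target, -wmax, wmax),
            "memforce_invalid_target")
  tol_abs <- tol * full_range
  band <- coarse_frac * full_range
  n_coarse <- 0L; n_fine <- 0L
  gmin <- s$m1$G_min; gmax <- s$m1$G_max
  # below half the smallest representable fine step no pulse can improve
  if (abs(w_target - synapse_weight(s)) <
      0.5 * s$R_f * gmin^2 * s$m1$delta_R_pair) {
    attr(s, "pulses_coarse") <- 0L
    attr(s, "pulses_fine") <- 0L
    return(s)
  }
  # refresh: with both devices in the high-conductance half, erase toward
  # the floor and re-program (the array is isolated during modulation, so
  # the transient excursion is unseen); the pair then sits at the
  # high-resistance end where the differential step is finest
  if (s$m1$G > gmin + 0.4 * (gmax - gmin) &&
      s$m2$G > gmin + 0.4 * (gmax - gmin)) {
    guard <- 0L
    while (s$m1$G > gmin + 1e-8 && guard < 400L) {
      s$m1 <- apply_pulse(s$m1, pulse_spec(-write_amplitude))
      n_coarse <- n_coarse + 1L; guard <- guard + 1L
    }
    guard <- 0L
    while (s$m2$G > gmin + 1e-8 && guard < 400L) {
      s$m2 <- apply_pulse(s$m2, pulse_spec(-write_amplitude))
      n_coarse <- n_coarse + 1L; guard <- guard + 1L
    }
  }
  for (it in seq_len(max_iter)) {
    err <- w_target - synapse_weight(s)
    if (abs(err) <= 1e-15) break
    if (abs(err) > band) {
      plan <- plan_update(s, sign(err))
      pulse <- pulse_spec(plan$direction * write_amplitude)
      if (plan$device == "m1") s$m1 <- apply_pulse(s$m1, pulse)
      else                     s$m2 <- apply_pulse(s$m2, pulse)
      n_coarse <- n_coarse + 1L
    } else {
      plan <- tryCatch(plan_update(s, sign(err)), error = function(e) NULL)
      if (is.null(plan)) break
      s2 <- s
      if (plan$device == "m1") s2$m1 <- apply_pulse_pair(s2$m1, plan$direction)
      else                     s2$m2 <- apply_pulse_pair(s2$m2, plan$direction)
      if (abs(w_target - synapse_weight(s2)) < abs(err) - 1e-18) {
        s <- s2
        n_fine <- n_fine + 1L
      } else {
        # the planned device's step overshoots; the complementary device
        # (different conductance state, so a different step size) may
        # still improve -- one more modulation stage on it
        s3 <- s
        if (plan$device == "m1")
          s3$m2 <- apply_pulse_pair(s3$m2, if (err > 0) +1 else -1)
        else
          s3$m1 <- apply_pulse_pair(s3$m1, if (err > 0) -1 else +1)
        if (abs(w_target - synapse_weight(s3)) < abs(err) - 1e-18) {
          s <- s3
          n_fine <- n_fine + 1L
        } else {
          # composition: same-polarity pairs on both devices (two stages)
          # net to the *difference* of their fine steps, much finer than
          # either single step
          spp <- s
          spp$m1 <- apply_pulse_pair(spp$m1, +1)
          spp$m2 <- apply_pulse_pair(spp$m2, +1)
          sdd <- s
          sdd$m1 <- apply_pulse_pair(sdd$m1, -1)
          sdd$m2 <- apply_pulse_pair(sdd$m2, -1)
          if (abs(w_target - synapse_weight(spp)) < abs(err) - 1e-18) {
            s <- spp
            n_fine <- n_fine + 2L
          } else if (abs(w_target - synapse_weight(sdd)) < abs(err) - 1e-18) {
            s <- sdd
            n_fine <- n_fine + 2L
          } else break
        }
      }
    }
    if (it == max_iter)
      mf_stop("programming did not converge within max_iter stages",
              "memforce_programming_failure")
  }
  if (abs(w_target - synapse_weight(s)) > tol_abs)
    mf_stop(sprintf("programmed weight %.5f misses target %.5f beyond tolerance",
                    synapse_weight(s), w_target),
            "memforce_programming_failure")
  attr(s, "pulses_coarse") <- n_coarse
  attr(s, "pulses_fine") <- n_fine
  s
}
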