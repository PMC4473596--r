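#' Target patterns
#'
#' A `"pattern"` couples a uniform time grid `t` with a target matrix `f`
#' (`n_steps x n_out`), optional static control inputs (`n_steps x n_in`,
#' constant within labelled segments) and, when defined, the fundamental
#' period in seconds. Generators are pure functions of their parameters
#' and R's RNG state.
#'
#' @name pattern
#' @keywords internal
NULL

new_pattern <- function(t, f, controls = NULL, period = NULL,
                        label = "pattern", segments = NULL) {
  f <- as.matrix(f)
  structure(list(t = t, f = f, controls = controls, period = period,
                 label = label, segments = segments),
            class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat(sprintf("<pattern> '%s': %d steps x %d channel(s), dt = %g s%s\n",
              x$label, nrow(x$f), ncol(x$f), x$t[2] - x$t[1],
              if (!is.null(x$period)) sprintf(", period = %g s", x$period) else ""))
  invisible(x)
}

#' Single sinusoid target
#'
#' `f(t) = amplitude * sin(2 pi frequency t + phase)` on a uniform grid.
#'
#' @param amplitude peak amplitude.
#' @param frequency_Hz frequency in hertz (> 0).
#' @param phase phase offset in radians.
#' @param dt grid spacing in seconds.
#' @param n_steps number of samples.
#' @return A `"pattern"` with one channel.
#' @export
sinusoid <- function(amplitude = 1, frequency_Hz = 1, phase = 0,
                     dt = 0.001, n_steps = 1000) {
  check_scalar(amplitude, "amplitude"); check_scalar(frequency_Hz, "frequency_Hz")
  if (frequency_Hz <= 0 || dt <= 0) stop_invalid("frequency and dt must be positive")
  t <- (seq_len(n_steps) - 1) * dt
  new_pattern(t, amplitude * sin(2 * pi * frequency_Hz * t + phase),
              period = 1 / frequency_Hz, label = "sinusoid")
}

#' Composite-of-sinusoids target
#'
#' Pointwise sum of component sinusoids. The default fixture is the
#' four-harmonic composite (5, 10, 15, 20 Hz with amplitudes 1, 0.5, 0.25,
#' 0.125; fundamental period 0.2 s, i.e. 20 membrane time constants at the
#' default tau, the regime in which a rate network holds a learned limit
#' cycle robustly). The recorded period is the least common period of the
#' component frequencies when they are commensurate (`NULL` otherwise).
#'
#' @param components a data frame or matrix with columns `amplitude`,
#'   `frequency_Hz`, `phase` (phase optional, default 0); one row per
#'   component.
#' @inheritParams sinusoid
#' @return A `"pattern"` with one channel.
#' @export
composite_sinusoids <- function(components = data.frame(
                                  amplitude = c(1, 0.5, 0.25, 0.125),
                                  frequency_Hz = c(5, 10, 15, 20)),
                                dt = 0.001, n_steps = 1000) {
  cmp <- as.data.frame(components)
  if (nrow(cmp) < 1) stop_invalid("need at least one component")
  if (is.null(cmp$phase)) cmp$phase <- 0
  if (any(cmp$frequency_Hz <= 0)) stop_invalid("frequencies must be positive")
  t <- (seq_len(n_steps) - 1) * dt
  f <- rep(0, n_steps)
  for (i in seq_len(nrow(cmp)))
    f <- f + cmp$amplitude[i] *
      sin(2 * pi * cmp$frequency_Hz[i] * t + cmp$phase[i])
  per <- rational_period(cmp$frequency_Hz)
  new_pattern(t, f, period = per, label = "composite")
}

rational_period <- function(freqs, tol = 1e-9) {
  # least common period of frequencies assumed rational with small
  # denominators; returns NULL when no common period <= 1e3 s is found
  for (k in 1:1000) {
    per <- k / min(freqs)
    if (all(abs(per * freqs - round(per * freqs)) < tol)) return(per)
  }
  NULL
}

#' Dual-pattern task with static control inputs
#'
#' Builds the two-attractor learning task: training segments of patterns A
#' and B alternate (`a, b, a, b, ...`), each tagged with its own fixed
#' random static control vector held constant for the whole segment. The
#' default targets are two composites of the same two frequencies with
#' swapped amplitude ratios: A = 1.0 sin(2 pi f1 t) + 0.5 sin(2 pi f2 t),
#' B = 0.5 sin(2 pi f1 t) + 1.0 sin(2 pi f2 t), `f1 = 5` Hz, `f2 = 10` Hz
#' (common period 0.2 s, 20 membrane time constants at the default tau).
#' Control vectors are drawn uniform on `[-1, 1]` and redrawn until they
#' are at least unit distance apart.
#'
#' @param pattern_a,pattern_b single-channel `"pattern"`s with equal `dt`;
#'   defaults as above.
#' @param control_dim dimension of the static control vectors.
#' @param segment_steps steps per training segment (default: two periods
#'   of pattern A).
#' @param n_cycles number of A+B segment pairs.
#' @return A list: `pattern` (the interleaved training `"pattern"` with
#'   `controls` and `segments`), `control_a`, `control_b`, and the two
#'   source patterns (recycled per segment).
#' @export
dual_pattern_task <- function(pattern_a = NULL, pattern_b = NULL,
                              control_dim = 10, segment_steps = NULL,
                              n_cycles = 8) {
  if (is.null(pattern_a))
    pattern_a <- composite_sinusoids(data.frame(
      amplitude = c(1, 0.5), frequency_Hz = c(5, 10)), n_steps = 200)
  if (is.null(pattern_b))
    pattern_b <- composite_sinusoids(data.frame(
      amplitude = c(0.5, 1), frequency_Hz = c(5, 10)), n_steps = 200)
  dta <- pattern_a$t[2] - pattern_a$t[1]
  dtb <- pattern_b$t[2] - pattern_b$t[1]
  if (abs(dta - dtb) > 1e-12) stop_invalid("patterns must share the same dt")
  if (is.null(segment_steps)) {
    per <- if (!is.null(pattern_a$period)) pattern_a$period else
      nrow(pattern_a$f) * dta
    segment_steps <- round(2 * per / dta)
  }
  repeat {
    ca <- runif(control_dim, -1, 1)
    cbv <- runif(control_dim, -1, 1)
    if (sqrt(sum((ca - cbv)^2)) >= 1) break
  }
  recycle <- function(p, n) p$f[((seq_len(n) - 1) %% nrow(p$f)) + 1, 1]
  fa <- recycle(pattern_a, segment_steps)
  fb <- recycle(pattern_b, segment_steps)
  f <- numeric(0); ctrl <- NULL; seg <- character(0)
  for (k in seq_len(n_cycles)) {
    f <- c(f, fa, fb)
    seg <- c(seg, rep("a", segment_steps), rep("b", segment_steps))
  }
  ctrl <- matrix(NA_real_, length(f), control_dim)
  ctrl[seg == "a", ] <- matrix(ca, sum(seg == "a"), control_dim, byrow = TRUE)
  ctrl[seg == "b", ] <- matrix(cbv, sum(seg == "b"), control_dim, byrow = TRUE)
  t <- (seq_along(f) - 1) * dta
  list(pattern = new_pattern(t, f, controls = ctrl,
                             period = pattern_a$period,
                             label = "dual", segments = seg),
       control_a = ca, control_b = cbv,
       pattern_a = pattern_a, pattern_b = pattern_b)
}

#' Synthetic multi-joint motor trajectory
#'
#' Generates a smooth, bounded stand-in for a multi-joint motion-capture
#' take (62 joint-angle channels, > 1000 frames): each channel is a random
#' low-order Fourier series (up to `n_harmonics` harmonics of the common
#' base frequency `1 / (n_frames dt)`, so the trajectory is periodic on the
#' grid) plus a channel-specific multiple of a shared smooth "jump"
#' envelope (a Gaussian bump mid-take emulating the crouch-extend-land
#' excursion). Channel amplitudes are scaled to order-one joint-angle
#' ranges (angles normalised, not degrees).
#'
#' @param n_joints number of channels (62 matches a full joint set).
#' @param n_frames frames (> 1000 for the full-scale task).
#' @param dt frame spacing in seconds.
#' @param n_harmonics maximum harmonic order per channel.
#' @return A `"pattern"` with `n_joints` channels and period
#'   `n_frames * dt`.
#' @export
synthetic_motor <- function(n_joints = 62, n_frames = 1200, dt = 0.001,
                            n_harmonics = 5) {
  if (n_joints < 1 || n_frames < 2) stop_invalid("invalid n_joints/n_frames")
  t <- (seq_len(n_frames) - 1) * dt
  f0 <- 1 / (n_frames * dt)
  phase01 <- t * f0                      # 0 .. <1 through the take
  env <- exp(-((phase01 - 0.5) / 0.15)^2) # shared jump envelope
  env <- env - mean(env)
  f <- matrix(0, n_frames, n_joints)
  for (j in seq_len(n_joints)) {
    amps <- rnorm(n_harmonics, 0, 0.5 / seq_len(n_harmonics))
    phs <- runif(n_harmonics, 0, 2 * pi)
    ch <- rep(0, n_frames)
    for (h in seq_len(n_harmonics))
      ch <- ch + amps[h] * sin(2 * pi * h * f0 * t + phs[h])
    f[, j] <- ch + rnorm(1, 0, 0.3) * env
  }
  new_pattern(t, f, period = n_frames * dt, label = "synthetic_motor")
}

#' Read a CMU-style AMC joint-angle file
#'
#' Parses the text motion-capture dialect: optional `#` comment and `:`
#' option lines, then repeated frame blocks of a bare frame number followed
#' by `bonename v1 v2 ...` lines. Channels are concatenated in file order
#' (`bone.1`, `bone.2`, ...), one row per frame.
#'
#' @param path path to the AMC file.
#' @param dt frame spacing in seconds (CMU captures are 120 fps).
#' @return A `"pattern"` whose columns are named joint-angle channels.
#' @examples
#' # a bundled 12-frame synthetic jump with a 62-channel bone layout
#' amc <- system.file("extdata", "jump_synthetic.amc", package = "memforce")
#' dim(read_amc(amc)$f)
#' @export
read_amc <- function(path, dt = 1 / 120) {
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- !(lines == "" | startsWith(lines, "#") | startsWith(lines, ":"))
  lines <- lines[keep]
  if (length(lines) == 0)
    mf_stop("empty AMC file (no frame blocks)", "memforce_parse_error")
  is_frame <- grepl("^[0-9]+$", lines)
  if (!is_frame[1])
    mf_stop(sprintf("line 1: expected a frame number, got '%s'", lines[1]),
            "memforce_parse_error")
  frames <- list(); chan_names <- NULL; cur <- NULL; cur_names <- character(0)
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(chan_names)) chan_names <<- cur_names
    else if (!identical(chan_names, cur_names))
      mf_stop("inconsistent bone/channel layout across frames",
              "memforce_parse_error")
    frames[[length(frames) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    if (is_frame[i]) {
      flush()
      cur <- numeric(0); cur_names <- character(0)
    } else {
      toks <- strsplit(lines[i], "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[-1]))
      if (length(vals) == 0 || any(is.na(vals)))
        mf_stop(sprintf("line %d: malformed bone line '%s'", i, lines[i]),
                "memforce_parse_error")
      cur <- c(cur, vals)
      cur_names <- c(cur_names,
                     paste0(toks[1], ".", seq_along(vals)))
    }
  }
  flush()
  if (length(frames) == 0)
    mf_stop("no frames parsed", "memforce_parse_error")
  f <- do.call(rbind, frames)
  colnames(f) <- chan_names
  new_pattern((seq_len(nrow(f)) - 1) * dt, f, label = "amc")
}

#' Write a pattern to AMC text format
#'
#' Inverse of [read_amc()] for patterns with channel names of the form
#' `bone.k`; unnamed channels are written under a single `chan` bone.
#'
#' @param pattern a `"pattern"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_amc <- function(pattern, path) {
  f <- pattern$f
  nms <- colnames(f)
  if (is.null(nms)) nms <- rep("chan", ncol(f))
  else nms <- sub("\\.[0-9]+$", "", nms)
  bones <- rle(nms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#!OML:ASF generated", ":FULLY-SPECIFIED", ":DEGREES"), con)
  for (fr in seq_len(nrow(f))) {
    writeLines(as.character(fr), con)
    off <- 0
    for (b in seq_along(bones$values)) {
      k <- bones$lengths[b]
      writeLines(paste(c(bones$values[b],
                         sprintf("%.17g", f[fr, off + seq_len(k)])),
                       collapse = " "), con)
      off <- off + k
    }
  }
  invisible(path)
}

#' Export a pattern (or reproduced trajectory) as CSV
#'
#' @param pattern a `"pattern"`, or a list with `t` and `z`/`f` matrices.
#' @param file output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_pattern_csv <- function(pattern, file) {
  f <- if (!is.null(pattern$f)) pattern$f else pattern$z
  f <- as.matrix(f)
  colnames(f) <- paste0("f_", seq_len(ncol(f)))
  out <- data.frame(t = pattern$t, f)
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}
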