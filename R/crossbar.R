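#' Memristive crossbar of differential synapses
#'
#' A rows x cols array of differential two-memristor synapses (rows index
#' postsynaptic neurons, columns presynaptic sources) stored as two
#' conductance matrices `G1`, `G2` plus shared device parameters. The
#' crossbar operates in two mutually exclusive stages: `"processing"`
#' (signal transduction through small non-disturbing read voltages; weights
#' may be read but not programmed) and `"modulation"` (the array is
#' isolated from the neurons and synapses are reprogrammed; within one
#' modulation stage at most one memristor per synapse changes). Programming
#' one synapse never perturbs any other (half-select discipline).
#'
#' @param nrow,ncol array dimensions.
#' @param G1,G2 optional initial conductance matrices (siemens); default
#'   both devices at mid-window, i.e. all weights 0.
#' @param R_f amplifier feedback resistance, ohms.
#' @param stage initial stage, `"processing"` or `"modulation"`.
#' @param ... device parameters passed to [memristor()] (shared by all
#'   devices).
#' @return An object of class `"crossbar"`.
#' @export
crossbar <- function(nrow, ncol, G1 = NULL, G2 = NULL, R_f = 330,
                     stage = c("processing", "modulation"), ...) {
  stage <- match.arg(stage)
  proto <- memristor(...)
  mid <- (proto$G_min + proto$G_max) / 2
  if (is.null(G1)) G1 <- matrix(mid, nrow, ncol)
  if (is.null(G2)) G2 <- matrix(mid, nrow, ncol)
  G1 <- as.matrix(G1); G2 <- as.matrix(G2)
  if (!all(dim(G1) == c(nrow, ncol)) || !all(dim(G2) == c(nrow, ncol)))
    stop_invalid("G1/G2 dimensions must match nrow x ncol")
  if (any(G1 < proto$G_min - 1e-15) || any(G1 > proto$G_max + 1e-15) ||
      any(G2 < proto$G_min - 1e-15) || any(G2 > proto$G_max + 1e-15))
    stop_invalid("initial conductances outside the device window")
  structure(
    list(G1 = G1, G2 = G2, R_f = R_f, device = proto, stage = stage),
    class = "crossbar")
}

#' @export
print.crossbar <- function(x, ...) {
  cat(sprintf("<crossbar> %d x %d differential synapses, R_f = %g ohm, stage = %s\n",
              nrow(x$G1), ncol(x$G1), x$R_f, x$stage))
  invisible(x)
}

#' Switch the operating stage of a crossbar
#' @param cb a [crossbar()].
#' @param stage `"processing"` or `"modulation"`.
#' @return The crossbar with the new stage.
#' @export
set_stage <- function(cb, stage = c("processing", "modulation")) {
  stopifnot(inherits(cb, "crossbar"))
  cb$stage <- match.arg(stage)
  cb
}

#' Weight matrix realised by a crossbar
#' @param cb a [crossbar()].
#' @return Matrix of weights `-R_f * (G1 - G2)`.
#' @export
weight_matrix <- function(cb) {
  stopifnot(inherits(cb, "crossbar"))
  -cb$R_f * (cb$G1 - cb$G2)
}

#' Build a crossbar realising a given weight matrix
#'
#' Maps each target weight to a conductance pair. The default `"low"`
#' bias is the canonical high-resistance realisation — the passive device
#' sits at `G_min` and only the active one carries the difference
#' (`G1 = G_min + max(gd, 0)`, `G2 = G_min + max(-gd, 0)` with
#' `gd = -w / R_f`) — which minimises read power and gives the finest
#' differential-pair steps. `"mid"` splits symmetrically around the
#' window centre. Both are exact for any representable weight.
#'
#' @param W target weight matrix, entries within the representable range.
#' @param R_f feedback resistance, ohms.
#' @param bias `"low"` (canonical, default) or `"mid"`.
#' @param ... device parameters passed to [memristor()].
#' @return A `"crossbar"` in processing stage whose [weight_matrix()]
#'   equals `W`.
#' @export
crossbar_from_weights <- function(W, R_f = 330, bias = c("low", "mid"), ...) {
  W <- as.matrix(W)
  bias <- match.arg(bias)
  proto <- memristor(...)
  wmax <- R_f * (proto$G_max - proto$G_min)
  if (any(abs(W) > wmax + 1e-12))
    mf_stop("weights outside the representable crossbar range",
            "memforce_invalid_target")
  gd <- -W / R_f                      # G1 - G2
  if (bias == "low") {
    G1 <- proto$G_min + pmax(gd, 0)
    G2 <- proto$G_min + pmax(-gd, 0)
  } else {
    mid <- (proto$G_min + proto$G_max) / 2
    G1 <- mid + gd / 2
    G2 <- mid - gd / 2
  }
  crossbar(nrow(W), ncol(W), G1 = G1, G2 = G2, R_f = R_f, ...)
}

#' Program a whole crossbar to a target weight matrix
#'
#' Runs the closed-loop coarse/fine programming of [program_to_target()]
#' independently on every synapse (half-select: programming one cell never
#' touches any other). Requires the crossbar to be in modulation stage.
#'
#' @param cb a [crossbar()] in `"modulation"` stage.
#' @param W_target target weight matrix, same shape as the crossbar.
#' @param tol relative tolerance (fraction of the full weight range).
#' @param coarse_frac coarse/fine switchover band (fraction of full range).
#' @return The programmed crossbar, with attributes `pulses_coarse` and
#'   `pulses_fine` (total counts).
#' @export
write_weight_matrix <- function(cb, W_target, tol = 0.003, coarse_frac = 0.05) {
  stopifnot(inherits(cb, "crossbar"))
  if (cb$stage != "modulation")
    mf_stop("crossbar must be in modulation stage to be programmed",
            "memforce_stage_error")
  W_target <- as.matrix(W_target)
  if (!all(dim(W_target) == dim(cb$G1)))
    stop_invalid("W_target shape must match the crossbar")
  d <- cb$device
  res <- program_matrix_cpp(cb$G1, cb$G2, W_target, cb$R_f,
                            d$G_min, d$G_max, d$eta_pot, d$eta_dep,
                            d$delta_R_pair, tol, coarse_frac, 10000L)
  if (res$failed >= 0) {
    ij <- arrayInd(res$failed + 1L, dim(cb$G1))
    mf_stop(sprintf("programming failed at synapse (%d, %d)", ij[1], ij[2]),
            "memforce_programming_failure")
  }
  cb$G1 <- res$G1; cb$G2 <- res$G2
  attr(cb, "pulses_coarse") <- res$n_coarse
  attr(cb, "pulses_fine") <- res$n_fine
  cb
}

#' Apply multiplicative weight dispersion (device variation)
#'
#' Models device-to-device and cycle-to-cycle variation by multiplying each
#' trained weight by an independent factor drawn uniformly from
#' `[1 - d, 1 + d]`, then clamping to the representable weight range.
#' Draws use R's current RNG stream; set the seed beforehand for
#' reproducibility.
#'
#' @param W weight matrix (or vector).
#' @param d dispersion fraction in `[0, 1)` (e.g. 0.06 for +/-6%).
#' @param w_max clamp bound on `|w|`; default 0.99, the crossbar range with
#'   the default device window and `R_f = 330` ohm. Use `Inf` for ideal
#'   (unclamped) weights.
#' @param model `"uniform"` (default) or `"gaussian"` (factors
#'   `N(1, (d/sqrt(3))^2)`, matching the uniform variance).
#' @return Perturbed weights, same shape as `W`.
#' @export
apply_dispersion <- function(W, d, w_max = 0.99,
                             model = c("uniform", "gaussian")) {
  model <- match.arg(model)
  check_scalar(d, "d")
  if (d < 0 || d >= 1) stop_invalid("dispersion d must lie in [0, 1)")
  if (d == 0) return(W)
  fac <- if (model == "uniform") runif(length(W), 1 - d, 1 + d)
         else rnorm(length(W), 1, d / sqrt(3))
  out <- W * fac
  out[out > w_max] <- w_max
  out[out < -w_max] <- -w_max
  out
}

#' Export a crossbar snapshot as a data frame
#'
#' @param cb a [crossbar()].
#' @param file optional CSV path; if given, the table is written there.
#' @return Data frame with columns `row`, `col`, `G1_S`, `G2_S`, `weight`
#'   (invisibly when `file` is given).
#' @export
crossbar_snapshot <- function(cb, file = NULL) {
  stopifnot(inherits(cb, "crossbar"))
  idx <- expand.grid(row = seq_len(nrow(cb$G1)), col = seq_len(ncol(cb$G1)))
  out <- data.frame(idx,
                    G1_S = as.vector(cb$G1), G2_S = as.vector(cb$G2),
                    weight = as.vector(weight_matrix(cb)))
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
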