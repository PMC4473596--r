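# FORCE (RLS) training drivers. The per-step reference operations live in
# rls.R / network.R; the production loop runs compiled (RcppArmadillo) and
# is cross-checked against an R-assembled loop in the test suite.

force_config <- function(net, pattern, n_train_steps, alpha, update_every,
                         row_mode, feedback_vec) {
  p <- net$params
  f <- pattern$f
  if (!is.matrix(f)) f <- matrix(f, ncol = 1)
  if (ncol(f) != p$n_out)
    stop_invalid("pattern channel count must equal n_out")
  ctrl <- pattern$controls
  if (is.null(ctrl)) ctrl <- matrix(0, nrow(f), p$n_in)
  if (!is.matrix(ctrl)) ctrl <- matrix(ctrl, ncol = max(1, p$n_in))
  if (p$n_in == 0) ctrl <- matrix(0, nrow(f), 0)
  else if (ncol(ctrl) != p$n_in)
    stop_invalid("control channel count must equal n_in")
  if (nrow(ctrl) != nrow(f))
    stop_invalid("controls must have one row per pattern step")
  if (n_train_steps < 0) stop_invalid("n_train_steps must be >= 0")
  row_mode <- match.arg(row_mode, c("identical", "partition", "feedback"))
  part <- switch(row_mode,
    identical = rep(1L, p$N),
    # contiguous even split of neurons across readout channels
    partition = as.integer(cut(seq_len(p$N), p$n_out, labels = FALSE)),
    feedback = rep(1L, p$N))
  if (row_mode %in% c("feedback", "partition")) {
    # the per-row random scaling is the absorbed-feedback construction;
    # in partition mode it applies within each channel's neuron subset
    if (is.null(feedback_vec)) feedback_vec <- runif(p$N, -1, 1)
    if (length(feedback_vec) != p$N)
      stop_invalid("feedback_vec must have length N")
  } else feedback_vec <- rep(1, p$N)
  list(f = f, ctrl = ctrl, n_steps = as.integer(n_train_steps),
       row_mode = row_mode, part = part, fb = as.numeric(feedback_vec),
       alpha = alpha, update_every = as.integer(update_every))
}

default_tracked <- function(N, n_out, n_tracked = 10) {
  # sample synapses from W_NN and (one or two) from W_ZN, as in the
  # conductance-evolution traces of the online-learning experiment
  n_zn <- min(2L, n_tracked)
  n_nn <- n_tracked - n_zn
  cells <- cbind(0L, sample.int(N, n_nn, replace = TRUE),
                 sample.int(N, n_nn, replace = TRUE))
  zn <- cbind(1L, sample.int(n_out, n_zn, replace = TRUE),
              sample.int(N, n_zn, replace = TRUE))
  rbind(cells, zn)
}

#' Online FORCE training through the memristive crossbar
#'
#' Trains the network to reproduce a target pattern by recursive least
#' squares while every weight lives on the crossbar: each step the array is
#' in processing stage for the Euler update, readout and error; every
#' `update_every` steps the inverse-correlation matrix is updated, the RLS
#' increments `-e P r` computed, the array switched to modulation stage and
#' every affected synapse reprogrammed (coarse pulses plus differential
#' pulse pairs, one device per synapse per stage) to its new target within
#' `tol_program`, then switched back. Internal rows and the readout row(s)
#' are updated simultaneously from the same `P`.
#'
#' @param net a `"rate_network"` from [init_network()].
#' @param pattern a `"pattern"` (see [sinusoid()] and friends); its rows
#'   are recycled if training is longer than the pattern.
#' @param n_train_steps number of training steps.
#' @param cb optional [crossbar()] backing the weights; by default one is
#'   built from the network's initial weights (`R_f = 330` ohm devices).
#' @param alpha RLS learning-rate parameter (`P(0) = I/alpha`).
#' @param update_every steps between RLS/programming updates (default 1:
#'   weights are modified at each time step).
#' @param tol_program relative programming tolerance (fraction of the full
#'   weight range).
#' @param row_mode how internal rows share the error: `"feedback"` (the
#'   default: row `i`'s increment is scaled by a fixed random factor in
#'   `[-1, 1]`, the absorbed-feedback construction that replaces an
#'   explicit readout-feedback pathway and reliably entrains the chaotic
#'   substrate), `"identical"` (every row gets the same increment, driven
#'   by the mean channel error) or `"partition"` (neurons split evenly
#'   across readout channels, each subset driven by its own channel's
#'   error; the choice for multi-joint tasks).
#' @param feedback_vec optional length-`N` row scaling for
#'   `row_mode = "feedback"`.
#' @param n_tracked number of synapses whose joint conductance is traced
#'   (sampled from `W_NN` and `W_ZN`).
#' @param train_internal,train_readout which weight groups are trained.
#' @return A list of class `"force_fit"`: `net` (weights synced from the
#'   crossbar), `cb`, `P`, `traces` (`z`, `e`, `g_joint` matrices),
#'   `pulses` (coarse/fine totals) and bookkeeping fields.
#' @export
train_online <- function(net, pattern, n_train_steps,
                         cb = NULL, alpha = 1, update_every = 1,
                         tol_program = 0.003, row_mode = "feedback",
                         feedback_vec = NULL, n_tracked = 10,
                         train_internal = TRUE, train_readout = TRUE) {
  stopifnot(inherits(net, "rate_network"))
  p <- net$params
  if (is.null(cb)) {
    Wall <- rbind(net$weights$W_NN, net$weights$W_ZN)
    cb <- crossbar_from_weights(clamp_weights(Wall))
  }
  if (nrow(cb$G1) != p$N + p$n_out || ncol(cb$G1) != p$N)
    stop_invalid("crossbar must be (N + n_out) x N: internal rows then readout rows")
  cfg <- force_config(net, pattern, n_train_steps, alpha, update_every,
                      row_mode, feedback_vec)
  W <- weight_matrix(cb)
  net$weights$W_NN <- W[seq_len(p$N), , drop = FALSE] * net$weights$mask
  net$weights$W_ZN <- W[p$N + seq_len(p$n_out), , drop = FALSE]
  tracked <- default_tracked(p$N, p$n_out, n_tracked)
  d <- cb$device
  res <- force_train_cpp(
    net$weights$W_NN, net$weights$W_NI, net$weights$W_ZN,
    net$weights$mask, net$state$x, p$g, p$dt / p$tau,
    cfg$f, cfg$ctrl, cfg$n_steps, cfg$alpha, cfg$update_every,
    cfg$part - 1L, match(cfg$row_mode, c("identical", "partition", "feedback")) - 1L,
    cfg$fb, train_internal, train_readout,
    TRUE, cb$G1, cb$G2, cb$R_f,
    d$G_min, d$G_max, d$eta_pot, d$eta_dep, d$delta_R_pair,
    tol_program, 0.05, tracked)
  net$weights$W_NN <- res$WNN
  net$weights$W_ZN <- res$WZN
  net$state <- list(x = as.vector(res$x), r = tanh(as.vector(res$x)),
                    t = net$state$t + cfg$n_steps * p$dt)
  cb$G1 <- res$G1; cb$G2 <- res$G2
  structure(list(
    net = net, cb = cb, P = res$P, mode = "online",
    traces = list(z = res$Z, e = res$E, g_joint = res$Gjoint,
                  tracked = tracked),
    pulses = list(coarse = res$n_coarse, fine = res$n_fine),
    alpha = alpha, update_every = update_every, row_mode = cfg$row_mode),
    class = "force_fit")
}

#' Offline FORCE training with a single final crossbar write
#'
#' Runs the identical RLS learning loop on ideal continuous weights (no
#' device in the loop), then writes the final weight matrices to a crossbar
#' once at tolerance `tol_program`. The returned fit carries both the
#' continuous network and the quantised (crossbar-backed) copy so their
#' test errors can be compared.
#'
#' @inheritParams train_online
#' @param write_crossbar if `FALSE`, skip the final write (purely ideal
#'   training).
#' @return A `"force_fit"` with `net` (continuous weights), `net_quantized`
#'   and `cb` (after the single write; `NULL` if skipped), `P`, `traces`
#'   and `pulses`.
#' @export
train_offline <- function(net, pattern, n_train_steps,
                          alpha = 1, update_every = 1, tol_program = 0.003,
                          row_mode = "feedback", feedback_vec = NULL,
                          n_tracked = 10, train_internal = TRUE,
                          train_readout = TRUE, write_crossbar = TRUE) {
  stopifnot(inherits(net, "rate_network"))
  p <- net$params
  cfg <- force_config(net, pattern, n_train_steps, alpha, update_every,
                      row_mode, feedback_vec)
  tracked <- default_tracked(p$N, p$n_out, n_tracked)
  res <- force_train_cpp(
    net$weights$W_NN, net$weights$W_NI, net$weights$W_ZN,
    net$weights$mask, net$state$x, p$g, p$dt / p$tau,
    cfg$f, cfg$ctrl, cfg$n_steps, cfg$alpha, cfg$update_every,
    cfg$part - 1L, match(cfg$row_mode, c("identical", "partition", "feedback")) - 1L,
    cfg$fb, train_internal, train_readout,
    FALSE, matrix(0, 0, 0), matrix(0, 0, 0), 330,
    1.5e-3, 4.5e-3, 0.18, 0.18, 0.6, tol_program, 0.05, tracked)
  net$weights$W_NN <- res$WNN
  net$weights$W_ZN <- res$WZN
  net$state <- list(x = as.vector(res$x), r = tanh(as.vector(res$x)),
                    t = net$state$t + cfg$n_steps * p$dt)
  cb <- NULL; net_q <- NULL; pulses <- list(coarse = 0, fine = 0)
  if (write_crossbar) {
    Wall <- clamp_weights(rbind(net$weights$W_NN, net$weights$W_ZN))
    cb <- crossbar_from_weights(matrix(0, nrow(Wall), ncol(Wall)))
    cb <- set_stage(cb, "modulation")
    cb <- write_weight_matrix(cb, Wall, tol = tol_program)
    pulses <- list(coarse = attr(cb, "pulses_coarse"),
                   fine = attr(cb, "pulses_fine"))
    cb <- set_stage(cb, "processing")
    Wq <- weight_matrix(cb)
    net_q <- net
    net_q$weights$W_NN <- Wq[seq_len(p$N), , drop = FALSE] * net$weights$mask
    net_q$weights$W_ZN <- Wq[p$N + seq_len(p$n_out), , drop = FALSE]
  }
  structure(list(
    net = net, net_quantized = net_q, cb = cb, P = res$P, mode = "offline",
    traces = list(z = res$Z, e = res$E, g_joint = res$Gjoint,
                  tracked = tracked),
    pulses = pulses,
    alpha = alpha, update_every = update_every, row_mode = cfg$row_mode),
    class = "force_fit")
}

clamp_weights <- function(W, w_max = 0.99) {
  W[W > w_max] <- w_max
  W[W < -w_max] <- -w_max
  W
}

#' @export
print.force_fit <- function(x, ...) {
  cat(sprintf("<force_fit> %s training, %d steps, row_mode = %s\n",
              x$mode, nrow(x$traces$z), x$row_mode))
  if (nrow(x$traces$e) > 0)
    cat(sprintf("  final |e| (last 100 steps): %.4g\n",
                mean(abs(tail_rows(x$traces$e, 100)))))
  invisible(x)
}

tail_rows <- function(m, k) m[max(1, nrow(m) - k + 1):nrow(m), , drop = FALSE]
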