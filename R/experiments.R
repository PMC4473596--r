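# Experiment drivers: end-to-end training/testing runs, the
# device-variation robustness sweep, and the multi-joint motor task.

default_config <- function() {
  list(
    task = "sinusoid",
    seed = 1L,
    network = list(N = 500, g = 1.5, tau = 0.01, dt = 0.001, p_conn = 1),
    pattern = list(),
    # alpha = 10 damps the RLS gain enough that per-step programming
    # granularity does not dominate online learning; 200 periods is well
    # past convergence for the fixture tasks
    train = list(mode = "online", n_periods_train = 200, n_periods_test = 20,
                 alpha = 10, update_every = 1, tol_program = 0.003,
                 row_mode = "feedback"),
    control_dim = 10,
    success_threshold = 0.5)
}

merge_config <- function(config) {
  cfg <- default_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], config[[nm]])
    else cfg[[nm]] <- config[[nm]]
  }
  # the dual-pattern experiment runs at alpha = 1 unless overridden
  if (identical(cfg$task, "dual") && is.null(config$train$alpha))
    cfg$train$alpha <- 1
  cfg
}

#' Load an experiment configuration from YAML or JSON
#'
#' Missing entries fall back to package defaults (single 10 Hz sinusoid,
#' N = 500, g = 1.5, tau = 10 ms, dt = 1 ms, online training with
#' alpha = 10 — alpha = 1 for the dual task — and updates every step).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  # YAML 1.1 reads a bare `N` key as boolean FALSE; keep y/n/N/Y literal
  keep_yn <- list(
    "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
    "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path, handlers = keep_yn)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(raw)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}

build_task <- function(cfg) {
  dt <- cfg$network$dt
  pat <- cfg$pattern
  switch(cfg$task,
    sinusoid = {
      # fixture: a 10 Hz unit sinusoid, one period per 10 membrane time
      # constants at the default tau
      p <- sinusoid(amplitude = pat$amplitude %||% 1,
                    frequency_Hz = pat$frequency_Hz %||% 10,
                    dt = dt,
                    n_steps = round((1 / (pat$frequency_Hz %||% 10)) / dt))
      list(pattern = p, n_in = 0, controls = NULL)
    },
    composite = {
      comp <- pat$components %||% data.frame(
        amplitude = c(1, 0.5, 0.25, 0.125), frequency_Hz = c(5, 10, 15, 20))
      p <- composite_sinusoids(comp, dt = dt,
                               n_steps = round(rational_period(comp$frequency_Hz) / dt))
      list(pattern = p, n_in = 0, controls = NULL)
    },
    dual = {
      task <- dual_pattern_task(control_dim = cfg$control_dim,
                                n_cycles = pat$n_cycles %||% 8)
      list(pattern = task$pattern, n_in = cfg$control_dim, dual = task)
    },
    stop_invalid(sprintf("unknown task '%s'", cfg$task)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pattern-learning experiment end to end
#'
#' Builds the target pattern, initialises the network (and, for online
#' mode, its backing crossbar), trains by FORCE/RLS, runs a frozen-weight
#' test phase and computes metrics. For the dual task both patterns are
#' tested under their respective static control inputs (one settling
#' period is discarded before scoring each).
#'
#' @param config nested configuration list (see [load_config()]); any
#'   subset of the default entries may be supplied, e.g.
#'   `list(task = "sinusoid", seed = 3)`.
#' @return An `"experiment_report"`: `config`, `seed`, `config_hash`,
#'   `metrics` (train/test NRMSE, phase-aligned test NRMSE, pulse counts,
#'   `success`), `traces` (training `z`/`e`, tracked joint conductances,
#'   test `z` vs `f`) and, for reuse, the fitted system (`fit`, `task`).
#' @export
run_experiment <- function(config = list()) {
  cfg <- merge_config(config)
  set.seed(cfg$seed)
  task <- build_task(cfg)
  per_steps <- round((task$pattern$period %||%
                        (nrow(task$pattern$f) * cfg$network$dt)) / cfg$network$dt)
  params <- network_params(N = cfg$network$N, g = cfg$network$g,
                           tau = cfg$network$tau, dt = cfg$network$dt,
                           p_conn = cfg$network$p_conn,
                           n_in = task$n_in, n_out = ncol(task$pattern$f))
  net <- init_network(params)
  tr <- cfg$train
  n_train <- if (!is.null(tr$n_train_steps)) tr$n_train_steps
             else if (cfg$task == "dual") nrow(task$pattern$f)
             else round(tr$n_periods_train * per_steps)
  n_test <- round(tr$n_periods_test * per_steps)
  fit <- if (identical(tr$mode, "online"))
    train_online(net, task$pattern, n_train, alpha = tr$alpha,
                 update_every = tr$update_every,
                 tol_program = tr$tol_program, row_mode = tr$row_mode)
  else
    train_offline(net, task$pattern, n_train, alpha = tr$alpha,
                  update_every = tr$update_every,
                  tol_program = tr$tol_program, row_mode = tr$row_mode,
                  write_crossbar = identical(tr$mode, "offline"))
  test_net <- if (identical(tr$mode, "offline") &&
                  !is.null(fit$net_quantized)) fit$net_quantized else fit$net
  metrics <- list(); traces <- list(
    train_z = fit$traces$z, train_e = fit$traces$e,
    g_joint = fit$traces$g_joint)
  if (cfg$task == "dual") {
    # discard one settling period after the control input switches, then
    # score two full periods (about the span the pattern is judged over;
    # constant phase offsets are tolerated by the aligned metric)
    res <- test_dual(test_net, task$dual, n_settle = per_steps,
                     n_score = 2 * per_steps)
    metrics$test_nrmse <- res$nrmse
    metrics$test_nrmse_phase_aligned <- res$nrmse_pa
    metrics$success <- all(res$nrmse_pa < cfg$success_threshold)
    traces$test <- res$traces
  } else {
    offset <- n_train %% nrow(task$pattern$f)
    f_test <- recycle_rows(task$pattern$f, n_test, offset)
    out <- run_network(test_net, n_steps = n_test)
    metrics$test_nrmse <- nrmse(out$z, f_test)
    metrics$test_nrmse_phase_aligned <-
      phase_aligned_nrmse(out$z, f_test, per_steps)
    metrics$success <- metrics$test_nrmse_phase_aligned < cfg$success_threshold
    traces$test <- list(t = out$t, z = out$z, f = f_test)
  }
  ne <- nrow(fit$traces$e)
  metrics$train_nrmse_last10 <- if (n_train > 0)
    sqrt(mean(tail_rows(fit$traces$e, max(1, round(ne / 10)))^2)) /
      mean(apply(as.matrix(task$pattern$f), 2, sd)) else NA_real_
  metrics$pulses_coarse <- fit$pulses$coarse
  metrics$pulses_fine <- fit$pulses$fine
  metrics$untrained_baseline <- (n_train == 0)
  structure(list(
    config = cfg, seed = cfg$seed, config_hash = config_hash(cfg),
    metrics = metrics, traces = traces, fit = fit, task = task,
    net_tested = test_net, period_steps = per_steps),
    class = "experiment_report")
}

recycle_rows <- function(f, n, offset = 0) {
  f <- as.matrix(f)
  f[((offset + seq_len(n) - 1) %% nrow(f)) + 1, , drop = FALSE]
}

test_dual <- function(net, dual, n_settle, n_score) {
  score <- function(net, ctrl, pat) {
    settle <- run_network(net, n_steps = n_settle, inputs = ctrl)
    out <- run_network(settle$net, n_steps = n_score, inputs = ctrl)
    f <- recycle_rows(pat$f, n_score)
    per <- round(pat$period / (pat$t[2] - pat$t[1]))
    list(net = out$net,
         nrmse = nrmse(out$z, f),
         pa = phase_aligned_nrmse(out$z, f, per),
         tr = list(t = out$t, z = out$z, f = f))
  }
  a <- score(net, dual$control_a, dual$pattern_a)
  b <- score(a$net, dual$control_b, dual$pattern_b)
  list(nrmse = c(a = a$nrmse, b = b$nrmse),
       nrmse_pa = c(a = a$pa, b = b$pa),
       traces = list(a = a$tr, b = b$tr))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> task = %s, seed = %d, hash = %s\n",
              x$config$task, x$seed, x$config_hash))
  m <- x$metrics
  cat(sprintf("  test NRMSE: %s | phase-aligned: %s | success: %s\n",
              paste(signif(m$test_nrmse, 4), collapse = ", "),
              paste(signif(m$test_nrmse_phase_aligned, 4), collapse = ", "),
              paste(m$success, collapse = ", ")))
  invisible(x)
}

#' Device-variation robustness sweep
#'
#' Perturbs the trained weights of a dual-pattern system with independent
#' multiplicative uniform factors `U(1 - d, 1 + d)` ("weight dispersion")
#' at each level, re-tests both patterns under their control inputs, and
#' scores each trial as a success when its phase-aligned NRMSE is below
#' the threshold. Repeated over `trials` random perturbations per level.
#'
#' @param report an `"experiment_report"` from a dual-task
#'   [run_experiment()].
#' @param levels dispersion fractions to test (default +/-6, 12, 16%).
#' @param trials random perturbation trials per level.
#' @param success_threshold phase-aligned NRMSE below which a pattern
#'   counts as reproduced.
#' @return A list of class `"variation_sweep"`: `table` (one row per
#'   level x trial x pattern: `nrmse_pa`, `success`), `summary` (success
#'   fraction per level and pattern), `levels`, `threshold`.
#' @export
variation_sweep <- function(report, levels = c(0.06, 0.12, 0.16),
                            trials = 10, success_threshold = 0.5) {
  stopifnot(inherits(report, "experiment_report"),
            identical(report$config$task, "dual"))
  net0 <- report$net_tested %||% report$fit$net
  dual <- report$task$dual
  per <- report$period_steps
  w_max <- 0.99
  rows <- list()
  for (d in levels) for (tr in seq_len(trials)) {
    net <- net0
    net$weights$W_NN <- apply_dispersion(net0$weights$W_NN, d, w_max) *
      net0$weights$mask
    net$weights$W_ZN <- apply_dispersion(net0$weights$W_ZN, d, w_max)
    res <- test_dual(net, dual, n_settle = per, n_score = 2 * per)
    rows[[length(rows) + 1L]] <- data.frame(
      level = d, trial = tr, pattern = c("a", "b"),
      nrmse_pa = as.numeric(res$nrmse_pa),
      success = as.numeric(res$nrmse_pa) < success_threshold)
  }
  tab <- do.call(rbind, rows)
  summ <- aggregate(success ~ level + pattern, tab, mean)
  structure(list(table = tab, summary = summ, levels = levels,
                 threshold = success_threshold),
            class = "variation_sweep")
}

#' @export
print.variation_sweep <- function(x, ...) {
  cat("<variation_sweep> success fraction by level and pattern:\n")
  print(x$summary)
  invisible(x)
}

#' Largest/smallest dispersion levels bracketing pattern survival
#'
#' Helper summarising a [variation_sweep()]: the largest tested level at
#' which *both* patterns are reproduced in the majority (> 50%) of trials,
#' and the smallest level at which *neither* pattern is reproduced in the
#' majority of trials. `NA` when no tested level qualifies.
#'
#' @param sweep a `"variation_sweep"`.
#' @return List with `largest_both_ok` and `smallest_both_fail`
#'   (dispersion fractions).
#' @export
dispersion_brackets <- function(sweep) {
  s <- sweep$summary
  both_ok <- both_fail <- logical(0)
  for (d in sweep$levels) {
    fr <- s$success[s$level == d]
    both_ok <- c(both_ok, all(fr > 0.5))
    both_fail <- c(both_fail, all(fr < 0.5))
  }
  list(
    largest_both_ok = if (any(both_ok)) max(sweep$levels[both_ok]) else NA_real_,
    smallest_both_fail = if (any(both_fail)) min(sweep$levels[both_fail]) else NA_real_)
}

#' Multi-joint motor pattern learning
#'
#' Trains a network with one readout per joint channel on a (by default
#' synthetic) multi-joint motor trajectory, using the partitioned update
#' mode: internal neurons are split evenly across the readout channels and
#' each subset's rows are driven by its own channel's error. Reports
#' per-channel and mean phase-aligned NRMSE over a frozen-weight test pass.
#'
#' @param config list; recognised entries: `seed`, `n_joints` (62),
#'   `n_frames` (1200), `network` (`N` = 800, `g`, `tau`, `dt`),
#'   `train` (`alpha`, `update_every`, `n_repeats_train` = 20,
#'   `n_repeats_test` = 2), `pattern` (a ready-made `"pattern"`, e.g. from
#'   [read_amc()], instead of the synthetic default).
#' @return An `"experiment_report"` whose `metrics` carry
#'   `per_channel_nrmse_pa` (one entry per joint), `mean_nrmse_pa`,
#'   `test_nrmse`, and `success` (mean below 0.5).
#' @export
run_motor_experiment <- function(config = list()) {
  # tau = 50 ms keeps the 1.2 s trajectory within ~25 network time
  # constants, the regime in which the learned cycle is held stably
  cfg <- modifyList(list(
    seed = 1L, n_joints = 62, n_frames = 1200,
    network = list(N = 800, g = 1.5, tau = 0.05, dt = 0.001, p_conn = 1),
    train = list(alpha = 1, update_every = 1, n_repeats_train = 40,
                 n_repeats_test = 2),
    pattern = NULL), config)
  set.seed(cfg$seed)
  pat <- cfg$pattern %||%
    synthetic_motor(cfg$n_joints, cfg$n_frames, cfg$network$dt)
  n_frames <- nrow(pat$f)
  params <- network_params(N = cfg$network$N, g = cfg$network$g,
                           tau = cfg$network$tau, dt = cfg$network$dt,
                           p_conn = cfg$network$p_conn,
                           n_in = 0, n_out = ncol(pat$f))
  net <- init_network(params)
  n_train <- cfg$train$n_repeats_train * n_frames
  fit <- train_offline(net, pat, n_train, alpha = cfg$train$alpha,
                       update_every = cfg$train$update_every,
                       row_mode = "partition", write_crossbar = FALSE)
  n_test <- cfg$train$n_repeats_test * n_frames
  out <- run_network(fit$net, n_steps = n_test)
  f_test <- recycle_rows(pat$f, n_test, n_train %% n_frames)
  pc <- phase_aligned_nrmse(out$z, f_test, n_frames, per_channel = TRUE)
  metrics <- list(
    per_channel_nrmse_pa = pc,
    mean_nrmse_pa = mean(pc),
    test_nrmse = nrmse(out$z, f_test),
    success = mean(pc) < 0.5)
  structure(list(
    config = cfg, seed = cfg$seed, config_hash = config_hash(cfg["seed"]),
    metrics = metrics,
    traces = list(test = list(t = out$t, z = out$z, f = f_test)),
    fit = fit, pattern = pat, period_steps = n_frames),
    class = "experiment_report")
}

#' Serialise an experiment report
#'
#' Writes the JSON metrics (with seed and config hash) and CSV trace files
#' (test output vs target; tracked joint-conductance curves when present)
#' into a directory.
#'
#' @param report an `"experiment_report"`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metrics = file.path(dir, "metrics.json"))
  meta <- list(seed = report$seed, config_hash = report$config_hash,
               metrics = report$metrics)
  jsonlite::write_json(meta, paths[["metrics"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tst <- report$traces$test
  dump_zf <- function(tr, path) {
    z <- as.matrix(tr$z); f <- as.matrix(tr$f)
    colnames(z) <- paste0("z_", seq_len(ncol(z)))
    colnames(f) <- paste0("f_", seq_len(ncol(f)))
    write.csv(data.frame(t = tr$t, z, f), path, row.names = FALSE)
  }
  if (!is.null(tst)) {
    if (!is.null(tst$z)) {
      paths["test"] <- file.path(dir, "test_trace.csv")
      dump_zf(tst, paths[["test"]])
    } else for (nm in names(tst)) {
      paths[paste0("test_", nm)] <- file.path(dir, sprintf("test_trace_%s.csv", nm))
      dump_zf(tst[[nm]], paths[[paste0("test_", nm)]])
    }
  }
  gj <- report$traces$g_joint
  if (!is.null(gj) && length(gj)) {
    paths["g_joint"] <- file.path(dir, "joint_conductance.csv")
    gj <- as.matrix(gj)
    colnames(gj) <- paste0("synapse_", seq_len(ncol(gj)))
    write.csv(data.frame(step = seq_len(nrow(gj)), gj),
              paths[["g_joint"]], row.names = FALSE)
  }
  invisible(paths)
}
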