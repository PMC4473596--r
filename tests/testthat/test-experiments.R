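test_that("NRMSE and its phase-aligned variant have the right closed forms", {
  f <- sinusoid(1, 1, n_steps = 1000)$f
  expect_equal(nrmse(f, f), 0)
  # flat output against a unit sinusoid: RMS and sd only differ by the
  # n/(n-1) sample factor
  expect_equal(nrmse(matrix(0, 1000, 1), f), sqrt(999 / 1000),
               tolerance = 1e-12)
  expect_error(nrmse(f, matrix(1, 1000, 1)), class = "memforce_invalid_input")
  # circular shifts are recovered exactly
  for (k in c(1, 137, 500)) {
    n <- nrow(f)
    zs <- f[c((n - k + 1):n, 1:(n - k)), , drop = FALSE]
    expect_lt(phase_aligned_nrmse(zs, f, 1000), 1e-10)
  }
  # an unaligned comparison is hurt by a large shift
  zs <- f[c(501:1000, 1:500), , drop = FALSE]
  expect_gt(nrmse(zs, f), 0.1)
  # FFT evaluation matches the direct shift loop
  set.seed(77)
  z <- cumsum(rnorm(400)); fr <- sin(seq(0, 12, length.out = 400))
  expect_equal(phase_aligned_nrmse(z, fr, 100),
               phase_aligned_nrmse_direct(z, fr, 100), tolerance = 1e-10)
  # per-channel output
  z2 <- cbind(f, 0.5 * f); f2 <- cbind(f, f)
  pc <- nrmse(z2, f2, per_channel = TRUE)
  expect_equal(length(pc), 2)
  expect_equal(pc[1], 0)
})

test_that("configs merge, load from YAML/JSON and hash stably", {
  cfg <- memforce:::merge_config(list(seed = 9, network = list(N = 100)))
  expect_equal(cfg$network$N, 100)
  expect_equal(cfg$network$g, 1.5)        # untouched defaults survive
  expect_equal(cfg$train$alpha, 10)
  y <- tempfile(fileext = ".yaml")
  writeLines(c("task: dual", "seed: 5", "network:", "  N: 120"), y)
  cy <- load_config(y)
  expect_equal(cy$task, "dual"); expect_equal(cy$network$N, 120)
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(task = "sinusoid", seed = 5), j, auto_unbox = TRUE)
  cj <- load_config(j)
  expect_equal(cj$seed, 5)
  expect_identical(memforce:::config_hash(cy), memforce:::config_hash(cy))
  expect_false(identical(memforce:::config_hash(cy),
                         memforce:::config_hash(cj)))
})

test_that("an untrained run is flagged and scores order-one error", {
  rep0 <- run_experiment(list(
    task = "sinusoid", seed = 2,
    network = list(N = 80),
    train = list(n_train_steps = 0, n_periods_test = 2, mode = "offline")))
  expect_true(rep0$metrics$untrained_baseline)
  expect_gt(rep0$metrics$test_nrmse, 0.3)
  expect_true(is.na(rep0$metrics$train_nrmse_last10))
  # reproducible bit-for-bit given (config, seed) in ideal-weight mode
  rep0b <- run_experiment(list(
    task = "sinusoid", seed = 2,
    network = list(N = 80),
    train = list(n_train_steps = 0, n_periods_test = 2, mode = "offline")))
  expect_identical(rep0$metrics, rep0b$metrics)
  expect_identical(rep0$traces$test$z, rep0b$traces$test$z)
})

test_that("a small end-to-end experiment trains, reports and serialises", {
  rep <- run_experiment(list(
    task = "sinusoid", seed = 4,
    network = list(N = 200),
    pattern = list(frequency_Hz = 4),
    train = list(mode = "offline", n_periods_train = 60, n_periods_test = 8)))
  m <- rep$metrics
  expect_lt(m$test_nrmse_phase_aligned, 0.5)
  expect_true(all(is.finite(unlist(m[c("test_nrmse", "train_nrmse_last10")]))))
  expect_gt(m$pulses_fine + m$pulses_coarse, 0)   # the final write happened
  expect_equal(ncol(rep$traces$g_joint), 10)
  expect_true(all(abs(rep$traces$g_joint) <= 3e-3))
  dir <- tempfile()
  paths <- save_report(rep, dir)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[["metrics"]])
  expect_equal(meta$seed, 4)
  expect_true(is.numeric(meta$metrics$test_nrmse))
})

test_that("dispersion bracket summary reads a sweep table correctly", {
  sweep <- structure(list(
    summary = data.frame(
      level = rep(c(0.06, 0.12, 0.16), each = 2),
      pattern = rep(c("a", "b"), 3),
      success = c(0.9, 0.8, 0.9, 0.2, 0.1, 0.0)),
    levels = c(0.06, 0.12, 0.16)), class = "variation_sweep")
  br <- dispersion_brackets(sweep)
  expect_equal(br$largest_both_ok, 0.06)
  expect_equal(br$smallest_both_fail, 0.16)
  # degenerate: nothing qualifies
  sweep$summary$success <- c(0.9, 0.2, 0.9, 0.2, 0.9, 0.2)
  br2 <- dispersion_brackets(sweep)
  expect_true(is.na(br2$largest_both_ok))
  expect_true(is.na(br2$smallest_both_fail))
})

test_that("zero dispersion reproduces the undisturbed test exactly", {
  # tiny dual system only to exercise the sweep plumbing
  rep <- run_experiment(list(
    task = "dual", seed = 11,
    network = list(N = 120),
    pattern = list(n_cycles = 2),
    train = list(mode = "offline", update_every = 2)))
  set.seed(1)
  sw <- variation_sweep(rep, levels = 0, trials = 1)
  expect_equal(sort(as.numeric(sw$table$nrmse_pa)),
               sort(as.numeric(rep$metrics$test_nrmse_phase_aligned)),
               tolerance = 1e-10)
})
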