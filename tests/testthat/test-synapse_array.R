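test_that("differential weight and joint conductance arithmetic", {
  expect_equal(synapse_weight(diff_synapse(3e-3, 3e-3)), 0)
  s <- diff_synapse(1.5e-3, 4.5e-3, R_f = 330)
  expect_equal(synapse_weight(s), +0.99, tolerance = 1e-12)
  expect_equal(synapse_weight(diff_synapse(4.5e-3, 1.5e-3)), -0.99,
               tolerance = 1e-12)
  expect_equal(joint_conductance(diff_synapse(4.5e-3, 1.5e-3)), 3e-3,
               tolerance = 1e-15)
  expect_equal(weight_range(s), 0.99, tolerance = 1e-12)
  # any reachable synapse state stays inside the joint-conductance interval
  set.seed(4)
  for (i in 1:1000) {
    s <- diff_synapse(runif(1, 1.5e-3, 4.5e-3), runif(1, 1.5e-3, 4.5e-3))
    gj <- joint_conductance(s)
    expect_true(gj >= -3e-3 && gj <= 3e-3)
    expect_true(abs(synapse_weight(s)) <= 0.99 + 1e-12)
  }
})

test_that("plan_update implements the four-case scheme with documented tie-break", {
  # enumeration over the quadrants of (G1, G2) headroom:
  # increase w -> depress m1 or potentiate m2, larger headroom wins
  expect_identical(plan_update(diff_synapse(4.4e-3, 3.0e-3), +1),
                   list(device = "m1", direction = -1))
  expect_identical(plan_update(diff_synapse(2.0e-3, 2.0e-3), +1),
                   list(device = "m2", direction = +1))
  # decrease w -> potentiate m1 or depress m2
  expect_identical(plan_update(diff_synapse(2.0e-3, 4.4e-3), -1),
                   list(device = "m2", direction = -1))
  expect_identical(plan_update(diff_synapse(1.6e-3, 2.0e-3), -1),
                   list(device = "m1", direction = +1))
  # exact tie goes to m2 (exactly representable device window)
  tie <- diff_synapse(2, 2, G_min = 1, G_max = 3)
  expect_identical(plan_update(tie, +1), list(device = "m2", direction = +1))
  expect_identical(plan_update(tie, -1), list(device = "m2", direction = -1))
  # saturation forces the other device
  expect_identical(plan_update(diff_synapse(4.5e-3, 4.5e-3), +1),
                   list(device = "m1", direction = -1))
  # weight already at its extreme: no headroom at all
  expect_error(plan_update(diff_synapse(1.5e-3, 4.5e-3), +1),
               class = "memforce_no_headroom")
})

test_that("closed-loop programming reaches targets within tolerance", {
  # already at target: zero pulses, bit-identical conductances
  s <- diff_synapse(3e-3, 3e-3)
  s2 <- program_to_target(s, synapse_weight(s))
  expect_identical(s2$m1$G, s$m1$G)
  expect_identical(attr(s2, "pulses_coarse") + attr(s2, "pulses_fine"), 0L)
  # full-range swing lands within 0.3% of the 1.98 weight range
  s2 <- program_to_target(diff_synapse(3e-3, 3e-3), 0.99, tol = 0.003)
  expect_lte(abs(synapse_weight(s2) - 0.99), 0.003 * 1.98)
  # out-of-range target rejected
  expect_error(program_to_target(diff_synapse(), 2.0),
               class = "memforce_invalid_target")
  # random start/target pairs all converge
  set.seed(9)
  for (i in 1:40) {
    s <- diff_synapse(runif(1, 1.5e-3, 4.5e-3), runif(1, 1.5e-3, 4.5e-3))
    wt <- runif(1, -0.98, 0.98)
    s2 <- program_to_target(s, wt)
    expect_lte(abs(synapse_weight(s2) - wt), 0.003 * 1.98)
  }
})

test_that("compiled matrix programming agrees with the scalar R loop", {
  set.seed(21)
  n <- 6
  G1 <- matrix(runif(n * n, 1.5e-3, 4.5e-3), n, n)
  G2 <- matrix(runif(n * n, 1.5e-3, 4.5e-3), n, n)
  W <- matrix(runif(n * n, -0.95, 0.95), n, n)
  cb <- crossbar(n, n, G1 = G1, G2 = G2, stage = "modulation")
  out <- write_weight_matrix(cb, W)
  for (k in seq_len(n * n)) {
    s <- diff_synapse(G1[k], G2[k])
    s <- program_to_target(s, W[k])
    expect_identical(out$G1[k], s$m1$G)
    expect_identical(out$G2[k], s$m2$G)
  }
})

test_that("crossbar writes respect stage and half-select locality", {
  set.seed(31)
  W <- matrix(runif(100, -0.9, 0.9), 10, 10)
  cb <- crossbar(10, 10)
  expect_error(write_weight_matrix(cb, W), class = "memforce_stage_error")
  cb <- set_stage(cb, "modulation")
  cb2 <- write_weight_matrix(cb, W)
  expect_lte(max(abs(weight_matrix(cb2) - W)), 0.003 * 1.98)
  # writing the current weights again costs zero pulses
  cb3 <- write_weight_matrix(cb2, weight_matrix(cb2))
  expect_equal(attr(cb3, "pulses_coarse") + attr(cb3, "pulses_fine"), 0)
  # half-select: reprogramming a single cell leaves all others bit-identical
  W2 <- weight_matrix(cb2)
  W2[4, 7] <- W2[4, 7] + 0.3
  cb4 <- write_weight_matrix(cb2, W2)
  moved <- abs(cb4$G1 - cb2$G1) + abs(cb4$G2 - cb2$G2) > 0
  expect_identical(which(moved), which(row(W2) == 4 & col(W2) == 7))
})

test_that("weight dispersion is multiplicative, bounded and mean-preserving", {
  W <- matrix(seq(-0.9, 0.9, length.out = 25), 5, 5)
  expect_identical(apply_dispersion(W, 0), W)
  set.seed(5)
  Wp <- apply_dispersion(W, 0.06)
  expect_true(all(abs(Wp / W - 1) <= 0.06 + 1e-12))
  set.seed(6)
  fac <- apply_dispersion(matrix(1, 1e5, 1), 0.1, w_max = Inf)
  expect_equal(mean(fac), 1.0, tolerance = 1e-3)
  expect_error(apply_dispersion(W, 1.2), class = "memforce_invalid_input")
  # clamping to the representable range
  set.seed(7)
  Wc <- apply_dispersion(matrix(0.98, 100, 1), 0.1)
  expect_true(all(Wc <= 0.99))
})

test_that("crossbar snapshots export every synapse", {
  cb <- crossbar_from_weights(matrix(c(-0.5, 0, 0.25, 0.99), 2, 2))
  snap <- crossbar_snapshot(cb)
  expect_equal(nrow(snap), 4)
  expect_equal(snap$weight, c(-0.5, 0, 0.25, 0.99), tolerance = 1e-12)
  expect_equal(-330 * (snap$G1_S - snap$G2_S), snap$weight, tolerance = 1e-12)
  f <- tempfile(fileext = ".csv")
  crossbar_snapshot(cb, f)
  expect_equal(read.csv(f)$weight, snap$weight, tolerance = 1e-9)
})
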