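test_that("P initialisation and the rank-one update match the direct inverse", {
  expect_equal(init_P(2, 4), diag(0.25, 2))
  expect_equal(init_P(3, 1), diag(3))
  expect_error(init_P(2, 0), class = "memforce_invalid_input")
  # scalar case worked by hand: P = 1, r = 1 -> P' = 1 - 1/2 = 0.5
  expect_equal(update_P(matrix(1), 1), matrix(0.5))
  # zero rate leaves P untouched
  P <- init_P(5, 2)
  expect_identical(update_P(P, rep(0, 5)), P)
  # oracle: after k updates P must equal (alpha I + sum r r^T)^{-1}
  set.seed(8)
  N <- 20; alpha <- 1.7
  P <- init_P(N, alpha)
  C <- diag(alpha, N)
  for (k in 1:50) {
    r <- rnorm(N)
    P <- update_P(P, r)
    C <- C + tcrossprod(r)
  }
  expect_lt(max(abs(P - solve(C))), 1e-8)
  # symmetry and positive definiteness survive
  expect_lt(max(abs(P - t(P))), 1e-12)
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("P stays symmetric positive definite over long update histories", {
  set.seed(10)
  N <- 10
  P <- init_P(N, 1)
  for (k in 1:10000) {
    P <- update_P(P, rnorm(N, sd = 0.5))
    if (k %% 2000 == 0) {
      expect_lt(max(abs(P - t(P))), 1e-10)
      expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("error signal and weight increments follow the RLS formulas", {
  expect_equal(compute_error(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(compute_error(0.7, 0.5), 0.2)
  expect_equal(length(compute_error(rnorm(62), rnorm(62))), 62)
  expect_error(compute_error(1:3, 1:2), class = "memforce_invalid_input")
  # increment = -e P r, hand-checked
  P <- diag(2); r <- c(0.2, -0.1)
  expect_equal(weight_increment(P, r, 0.5), c(-0.1, 0.05))
  expect_equal(weight_increment(P, r, 0), c(0, 0))
  # always parallel to P r
  set.seed(2)
  P <- crossprod(matrix(rnorm(9), 3)); r <- rnorm(3)
  w1 <- weight_increment(P, r, 0.3); w2 <- weight_increment(P, r, -1.2)
  expect_equal(w1 / 0.3, w2 / -1.2, tolerance = 1e-12)
})

test_that("the compiled trainer reproduces an R loop built from the primitives", {
  set.seed(33)
  net <- small_net(33, N = 30, g = 1.5)
  fb <- runif(30, -1, 1)
  pat <- sinusoid(1, 2, dt = 0.001, n_steps = 500)
  fit <- train_offline(net, pat, n_train_steps = 300, row_mode = "feedback",
                       feedback_vec = fb, write_crossbar = FALSE)
  ref <- r_force_loop(net, pat, 300, alpha = 1, feedback_vec = fb)
  expect_lt(max(abs(fit$net$weights$W_NN - ref$weights$W_NN)), 1e-8)
  expect_lt(max(abs(fit$net$weights$W_ZN - ref$weights$W_ZN)), 1e-8)
  expect_lt(max(abs(fit$net$state$x - ref$state$x)), 1e-8)
  expect_lt(max(abs(as.vector(fit$traces$z) - ref$z)), 1e-8)
  expect_lt(max(abs(fit$P - ref$P)), 1e-8)
})

test_that("a solved task induces no error and no weight change", {
  set.seed(40)
  net <- small_net(40, N = 25)
  net$weights$W_ZN[] <- 0
  pat <- new_pattern_for_test(rep(0, 100))
  fit <- train_offline(net, pat, n_train_steps = 100, write_crossbar = FALSE)
  expect_true(all(fit$traces$e == 0))
  expect_identical(fit$net$weights$W_ZN, matrix(0, 1, 25))
  # zero training steps leave everything untouched
  fit0 <- train_offline(net, pat, n_train_steps = 0, write_crossbar = FALSE)
  expect_identical(fit0$net$weights$W_NN, net$weights$W_NN)
})

test_that("sparse connectivity masks are preserved through training", {
  set.seed(50)
  net <- small_net(50, N = 60, p_conn = 0.2)
  zero_before <- net$weights$mask == 0
  pat <- sinusoid(1, 2, dt = 0.001, n_steps = 500)
  fit <- train_offline(net, pat, n_train_steps = 400, write_crossbar = FALSE)
  expect_true(all(fit$net$weights$W_NN[zero_before] == 0))
  expect_true(any(fit$net$weights$W_NN[!zero_before] !=
                    net$weights$W_NN[!zero_before]))
})

test_that("online and offline training agree as programming noise vanishes", {
  set.seed(60)
  N <- 30
  net <- small_net(60, N = N)
  fb <- runif(N, -1, 1)
  pat <- sinusoid(0.5, 2, dt = 0.001, n_steps = 500)
  set.seed(61)
  off <- train_offline(net, pat, n_train_steps = 100, feedback_vec = fb,
                       write_crossbar = FALSE)
  # near-ideal devices: 0.05-ohm fine step, tight tolerance
  cb <- crossbar_from_weights(
    clamp_weights(rbind(net$weights$W_NN, net$weights$W_ZN)),
    delta_R_pair = 0.05)
  set.seed(61)
  on <- train_online(net, pat, n_train_steps = 100, cb = cb,
                     feedback_vec = fb, tol_program = 2e-4)
  expect_lt(max(abs(on$net$weights$W_NN - off$net$weights$W_NN)), 5e-3)
  expect_lt(max(abs(on$net$weights$W_ZN - off$net$weights$W_ZN)), 5e-3)
  expect_lt(max(abs(on$traces$z - off$traces$z)), 0.05)
})

test_that("training collapses the output error power by orders of magnitude", {
  # RLS clamps the tracking error from the first update, so the honest
  # convergence contrast is against the untrained network's output error
  for (s in c(42, 7)) {
    set.seed(s)
    net <- init_network(network_params(N = 400, g = 1.5))
    pat <- sinusoid(1, 10, dt = 0.001, n_steps = 100)
    f <- pat$f[rep(1:100, 20), , drop = FALSE]
    base <- run_network(net, n_steps = 2000)$z
    power_untrained <- mean((base - f)^2)
    fit <- train_offline(net, pat, n_train_steps = 10000,
                         write_crossbar = FALSE)
    e <- as.vector(fit$traces$e)
    power_late <- mean(tail(e, 1000)^2)
    expect_gt(power_untrained / power_late, 100)
  }
})
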