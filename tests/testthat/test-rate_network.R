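test_that("initialisation matches the declared distributions and is seeded", {
  set.seed(1)
  net <- init_network(network_params(N = 100))
  expect_equal(dim(net$weights$W_NN), c(100, 100))
  expect_equal(var(as.vector(net$weights$W_NN)), 1 / 100, tolerance = 0.2)
  expect_equal(net$state$r, tanh(net$state$x))
  # sparse: nonzero fraction concentrates around p_conn
  set.seed(2)
  nets <- init_network(network_params(N = 100, p_conn = 0.1))
  frac <- mean(nets$weights$mask)
  expect_lt(abs(frac - 0.1), 0.02)
  expect_true(all(nets$weights$W_NN[nets$weights$mask == 0] == 0))
  # determinism under a fixed seed
  a <- small_net(7); b <- small_net(7)
  expect_identical(a$weights, b$weights)
  expect_identical(a$state, b$state)
})

test_that("single Euler steps follow the leaky dynamics closed forms", {
  p <- network_params(N = 4, tau = 0.01, dt = 0.001)
  W <- list(W_NN = matrix(0, 4, 4), W_NI = matrix(0, 4, 0),
            W_ZN = matrix(0, 1, 4))
  # zero state with no drive is a fixed point
  st <- list(x = rep(0, 4), r = rep(0, 4), t = 0)
  expect_equal(step_network(st, W, p)$x, rep(0, 4))
  # pure leak: x decays by (1 - dt/tau) per step
  st <- list(x = rep(1, 4), r = tanh(rep(1, 4)), t = 0)
  expect_equal(step_network(st, W, p)$x, rep(0.9, 4), tolerance = 1e-12)
  # readout is a linear projection; a one-hot row selects a neuron
  W$W_ZN <- matrix(c(0, 0, 1, 0), 1)
  st <- list(x = c(0.3, -0.2, 0.7, 0.1), r = tanh(c(0.3, -0.2, 0.7, 0.1)), t = 0)
  expect_equal(readout(st, W), tanh(0.7))
  expect_equal(readout(st, list(W_ZN = matrix(0, 1, 4))), 0)
})

test_that("sub-critical networks relax to rest and rates stay bounded", {
  for (s in 1:5) {
    set.seed(s)
    net <- init_network(network_params(N = 80, g = 0.5))
    # gain 0.5 puts the spectral radius of g W_NN safely below 1
    ev <- eigen(0.5 * net$weights$W_NN, only.values = TRUE)$values
    expect_lt(max(Re(ev)), 1)
    n0 <- sqrt(sum(net$state$x^2))
    out10 <- run_network(net, n_steps = 100)       # 10 tau
    expect_lt(sqrt(sum(out10$net$state$x^2)), 5e-3 * n0)
    out20 <- run_network(out10$net, n_steps = 100) # 20 tau
    expect_lt(sqrt(sum(out20$net$state$x^2)), 1e-3 * n0)
  }
  # chaotic regime keeps |r| <= 1 always
  set.seed(3)
  net <- init_network(network_params(N = 100, g = 1.8))
  out <- run_network(net, n_steps = 500, record_r = TRUE)
  expect_true(all(abs(out$r) <= 1))
})

test_that("the compiled runner composes like repeated reference steps", {
  set.seed(12)
  net <- small_net(12, N = 30)
  out <- run_network(net, n_steps = 2)
  st <- net$state
  st <- step_network(st, net$weights, net$params)
  z1 <- readout(st, net$weights)
  st <- step_network(st, net$weights, net$params)
  z2 <- readout(st, net$weights)
  expect_equal(out$net$state$x, st$x, tolerance = 1e-12)
  expect_equal(as.vector(out$z), c(z1, z2), tolerance = 1e-12)
  # zero-length run returns an empty trajectory and leaves the state alone
  out0 <- run_network(net, n_steps = 0)
  expect_equal(nrow(out0$z), 0)
  expect_identical(out0$net$state, net$state)
  # constant input handling matches the reference step
  set.seed(13)
  neti <- small_net(13, N = 20, n_in = 3)
  u <- c(0.5, -1, 0.25)
  outi <- run_network(neti, n_steps = 1, inputs = u)
  sti <- step_network(neti$state, neti$weights, neti$params, u)
  expect_equal(outi$net$state$x, sti$x, tolerance = 1e-12)
})

test_that("halving dt refines the trajectory at first order", {
  errs <- sapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    set.seed(20)
    net <- init_network(network_params(N = 50, g = 0.9, tau = 0.01, dt = dt))
    x_coarse <- run_network(net, n_steps = round(0.1 / dt))$net$state$x
    set.seed(20)
    net2 <- init_network(network_params(N = 50, g = 0.9, tau = 0.01, dt = dt / 2))
    x_fine <- run_network(net2, n_steps = round(0.2 / dt))$net$state$x
    max(abs(x_coarse - x_fine))
  })
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[2], 1.5)   # ~2 for an O(dt) scheme
  expect_lt(errs[1] / errs[2], 3.0)
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(network_params(N = 1), class = "memforce_invalid_input")
  expect_error(network_params(dt = 0.02), class = "memforce_invalid_input")
  expect_error(network_params(p_conn = 0), class = "memforce_invalid_input")
  net <- small_net(1, N = 10, n_in = 2)
  expect_error(run_network(net, 5, inputs = c(1, 2, 3)),
               class = "memforce_invalid_input")
  expect_error(run_network(net, T_total = 0.0015),
               class = "memforce_invalid_input")
})
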