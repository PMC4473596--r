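# Shared fixtures (all generated in code at test time).

small_net <- function(seed, N = 40, g = 1.5, n_in = 0, n_out = 1,
                      p_conn = 1) {
  set.seed(seed)
  init_network(network_params(N = N, g = g, tau = 0.01, dt = 0.001,
                              p_conn = p_conn, n_in = n_in, n_out = n_out))
}

# pure-R FORCE loop assembled from the exported per-step operations;
# the independent reference for the compiled trainer (ideal weights,
# single readout)
r_force_loop <- function(net, pattern, n_steps, alpha = 1,
                         feedback_vec) {
  p <- net$params
  W <- net$weights
  state <- net$state
  P <- init_P(p$N, alpha)
  f <- as.matrix(pattern$f)
  z_trace <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    state <- step_network(state, W, p)
    z <- readout(state, W)
    e <- compute_error(z, f[((t - 1) %% nrow(f)) + 1, ])
    P <- update_P(P, state$r)
    dw <- weight_increment(P, state$r, e)  # -e * P r
    W$W_ZN <- W$W_ZN + matrix(dw, 1)
    W$W_NN <- W$W_NN + outer(feedback_vec, dw)
    z_trace[t] <- z
  }
  list(weights = W, state = state, P = P, z = z_trace)
}

# minimal hand-built pattern (bypasses the generators)
new_pattern_for_test <- function(f, dt = 0.001) {
  f <- as.matrix(f)
  structure(list(t = (seq_len(nrow(f)) - 1) * dt, f = f, controls = NULL,
                 period = NULL, label = "test", segments = NULL),
            class = "pattern")
}
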