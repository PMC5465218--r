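# shared fixtures for the test suite

# the dimensional glucose-lactate set
p_dim <- default_dimensional_params()

# a small, fast parameter set for lattice unit tests: moderate fluxes and
# diffusion so the explicit stepper converges quickly
p_toy <- function(k = 5, c_blood = 1) {
  model_params(
    Y_u = 1, Y_r = 19, e_m = 10, u_max = 1, K_s = 2,
    v_max = 100, K_w = 5, alpha_ab = 100, r_max = 6.48,
    lambda_max = 2, K_E = 20, K_inh = 8, sigma_max = 2, K_tox = 15,
    D_S = 10, D_W = 10, d = 4L, k = k, c_blood = c_blood,
    units = "dimensional"
  )
}

# random valid parameter draws for property tests
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    Y_u <- runif(1, 0.5, 5)
    Y_r <- Y_u + runif(1, 0.5, 20)
    e_m <- runif(1, 1, 50)
    u_m <- e_m / (Y_u + Y_r)
    repeat {
      r_max <- runif(1, u_m, 20 * u_m)
      u_max <- runif(1, 1.1 * u_m, 10 * u_m)
      alpha_ab <- runif(1, 5, 200)
      if (alpha_ab * u_max > r_max) break
    }
    model_params(
      Y_u = Y_u, Y_r = Y_r, e_m = e_m, u_max = u_max,
      K_s = runif(1, 0.5, 5), v_max = runif(1, 10, 200),
      K_w = runif(1, 1, 10), alpha_ab = alpha_ab, r_max = r_max,
      lambda_max = runif(1, 0.5, 4), K_E = runif(1, 5, 50),
      K_inh = runif(1, 2, 20), sigma_max = runif(1, 0.5, 4),
      K_tox = runif(1, 5, 30), D_S = 10, D_W = 10, d = 4L,
      k = runif(1, 0.5, 20), c_blood = runif(1, 0.5, 10)
    )
  })
}
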