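test_that("Michaelis-Menten uptake has the canonical shape", {
  expect_equal(mm_uptake(0, 3, 2), 0)
  expect_equal(mm_uptake(2, 3, 2), 1.5)        # half-saturation at x = K
  expect_equal(mm_uptake(0.5, 1, 2), 0.2)      # 1 * 0.5 / 2.5
  expect_error(mm_uptake(-0.1, 1, 1), "negative")
})

test_that("healthy cells meet maintenance from nutrient alone when saturated", {
  fl <- healthy_fluxes(10 * p_dim$K_s, 0, p_dim)
  expect_equal(fl$u, p_dim$u_m)
  expect_equal(fl$v, 0)
  expect_equal(fl$e, p_dim$e_m)
})

test_that("starving healthy cells top up with waste to exactly e_m when available", {
  fl <- healthy_fluxes(0.5, 1e6, p_dim)
  expect_equal(fl$u, 0.2)                     # u_MM(0.5) = 1 * 0.5 / 2.5
  expect_equal(fl$v, 0.3 * 20 / 19)           # (u_m - u)(1 + Y_u/Y_r)
  expect_equal(fl$e, p_dim$e_m)
  # without waste the deficit remains
  fl0 <- healthy_fluxes(0.5, 0, p_dim)
  expect_equal(fl0$v, 0)
  expect_equal(fl0$e, 1 * 0.2 + 19 * 0.2)     # = 4 < e_m
  expect_lt(fl0$e, p_dim$e_m)
})

test_that("aberrant cells overflow above the respiration cap", {
  fl <- aberrant_fluxes(0.5, p_dim)
  expect_equal(fl$u, 20)                      # 100 * u_MM(0.5)
  expect_equal(fl$v, -13.52)                  # r_max - u
  expect_equal(fl$r, 6.48)
  expect_equal(fl$e, 143.12)                  # 1*20 + 19*6.48
  expect_equal(aberrant_fluxes(0, p_dim)$e, 0)
  # below the cap nothing is excreted
  s_small <- 1e-4
  expect_equal(aberrant_fluxes(s_small, p_dim)$v, 0)
})

test_that("replication rate is zero at maintenance and factorizes at half-saturations", {
  expect_equal(replication_rate(p_dim$e_m, 0, p_dim), 0)
  expect_equal(replication_rate(p_dim$e_m + p_dim$K_E, 0, p_dim),
               p_dim$lambda_max / 2)
  expect_equal(replication_rate(p_dim$e_m + p_dim$K_E, p_dim$K_inh, p_dim),
               p_dim$lambda_max / 4)
  # below maintenance the rate stays zero whatever the denominator does
  expect_equal(replication_rate(0, 0, p_dim), 0)
})

test_that("death rate saturates in the waste level", {
  expect_equal(death_rate(0, p_dim), 0)
  expect_equal(death_rate(p_dim$K_tox, p_dim), p_dim$sigma_max / 2)
  expect_equal(death_rate(3 * p_dim$K_tox, p_dim), 0.75 * p_dim$sigma_max)
})

test_that("flux kernel invariants hold over a dense random (s, w) sample", {
  set.seed(7)
  n <- 1e4
  s <- rexp(n, 1 / 2); w <- rexp(n, 1 / 5)
  th <- substrate_thresholds(p_dim)
  he <- healthy_fluxes(s, w, p_dim)
  ab <- aberrant_fluxes(s, p_dim)
  for (fl in list(he, ab)) {
    expect_equal(fl$r, fl$u + fl$v, tolerance = 1e-12)
    expect_true(all(fl$r >= 0 & fl$r <= p_dim$r_max + 1e-12))
    expect_equal(fl$e, p_dim$Y_u * fl$u + p_dim$Y_r * fl$r, tolerance = 1e-12)
  }
  expect_true(all(he$v >= 0))
  expect_true(all(he$e <= p_dim$e_m + 1e-12))
  expect_true(all(ab$v <= 0))
  # secretion exactly above s_sec; growth-capable energy exactly above s_gr
  expect_equal(ab$v < 0, s > th$s_sec)
  lam <- replication_rate(ab$e, 0, p_dim)
  expect_equal(lam > 0, s > th$s_gr)
  # healthy e_m attained exactly when nutrient or waste suffices
  sat <- mm_uptake(s, p_dim$u_max, p_dim$K_s) >= p_dim$u_m
  topped <- mm_uptake(w, p_dim$v_max, p_dim$K_w) >=
    (p_dim$u_m - he$u) * (1 + p_dim$Y_u / p_dim$Y_r)
  expect_equal(abs(he$e - p_dim$e_m) < 1e-9, sat | topped)
})

test_that("flux kernels are continuous across their branch points", {
  th <- substrate_thresholds(p_dim)
  for (s0 in c(th$s_m, th$s_sec, th$s_gr)) {
    eps <- 1e-9 * max(s0, 1)
    for (fn in list(function(s) healthy_fluxes(s, 3, p_dim)$v,
                    function(s) healthy_fluxes(s, 3, p_dim)$e,
                    function(s) aberrant_fluxes(s, p_dim)$v,
                    function(s) aberrant_fluxes(s, p_dim)$e)) {
      expect_equal(fn(s0 + eps), fn(max(s0 - eps, 0)), tolerance = 1e-6)
    }
  }
})
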