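test_that("mean-field right-hand side honors the logistic and balance structure", {
  p <- default_nondim_params(k = 10, c_blood = 3)
  for (phi in c(0, 1)) {
    d <- mf_rhs(list(phi = phi, s = 1, w = 0.2), p)
    expect_equal(d$dphi, 0)
  }
  # healthy-saturated branch: at s = c - u_m/k >= s_m, ds/dt vanishes at phi = 0
  s_star <- 3 - p$u_m / 10
  expect_gte(s_star, substrate_thresholds(p)$s_m)
  d <- mf_rhs(list(phi = 0, s = s_star, w = 0), p)
  expect_equal(d$ds, 0)
  # full aberrant tissue below the secretion threshold produces no waste
  th <- substrate_thresholds(p)
  d1 <- mf_rhs(list(phi = 1, s = th$s_sec / 2, w = 0), p)
  expect_equal(d1$dw, 0)
})

test_that("QSS concentrations solve the balances and match closed forms", {
  p <- default_nondim_params(k = 10, c_blood = 3)
  cl <- qss_concentrations(0, p)
  expect_equal(cl$s, 3 - p$u_m / 10, tolerance = 1e-9)   # saturated healthy
  expect_equal(cl$w, 0)
  # residuals vanish at any interior phi
  for (phi in c(0.1, 0.5, 0.9)) {
    cl <- qss_concentrations(phi, p)
    d <- mf_rhs(list(phi = phi, s = cl$s, w = cl$w), p)
    expect_lt(abs(d$ds), 1e-7)
    expect_lt(abs(d$dw), 1e-7)
  }
  # no sources at c = 0
  p0 <- default_nondim_params(k = 10, c_blood = 0)
  expect_equal(qss_concentrations(1, p0), list(s = 0, w = 0))
  # k = 0 admits no finite steady state with positive uptake
  pk0 <- default_nondim_params(k = 0, c_blood = 1)
  expect_error(qss_concentrations(0.5, pk0), "k = 0")
  expect_error(qss_concentrations(1.5, p), "\\[0, 1\\]")
})

test_that("a fully aberrant tissue below s_sec reaches a waste-free steady state", {
  p <- default_nondim_params(k = 200, c_blood = 0.02)
  cl <- qss_concentrations(1, p)
  expect_lt(cl$s, substrate_thresholds(p)$s_sec)
  expect_equal(cl$w, 0)
})

test_that("QSS trajectories stay in [0, 1] and respect the sign of the net rate", {
  # deep in the toxicity-suppressed phase the fraction declines
  p <- default_nondim_params(k = 50, c_blood = 7.5)
  tr <- mf_trajectory(0.3, p, t_max = 50)
  expect_true(all(tr$phi >= 0 & tr$phi <= 1))
  expect_lt(tr$phi[nrow(tr)], 0.3)
  expect_true(all(diff(tr$phi) <= 1e-10))
  # an inert environment (no energy, no waste) freezes the fraction
  p0 <- default_nondim_params(k = 10, c_blood = 0)
  tr0 <- mf_trajectory(0.5, p0, t_max = 20)
  expect_equal(tr0$phi, rep(0.5, nrow(tr0)), tolerance = 1e-9)
})

test_that("asymptotic fraction lands on the thresholds' prediction in region III", {
  p <- default_nondim_params()
  # phi_gr >= 1 in the never-secreting phase: full takeover
  pk <- with_environment(p, 2000, 0.0095)
  th <- fraction_thresholds(pk)
  expect_lte(th$phi_sec, 0)
  expect_gte(th$phi_gr, 1)
  af <- asymptotic_fraction(pk)
  expect_true(af$converged)
  expect_equal(af$phi_f, 1)
  # phi_gr < 1: nutrient-limited plateau at phi_gr
  pk2 <- with_environment(p, 2000, 0.008)
  th2 <- fraction_thresholds(pk2)
  expect_lte(th2$phi_sec, 0)
  expect_lt(th2$phi_gr, 1)
  af2 <- asymptotic_fraction(pk2)
  expect_equal(af2$phi_f, th2$phi_gr, tolerance = 1e-4)
  expect_lte(af2$phi_f, min(1, th2$phi_gr) + 1e-4)
  # without nutrient the aberrant fraction cannot grow
  af0 <- asymptotic_fraction(default_nondim_params(k = 10, c_blood = 0))
  expect_lte(af0$phi_f, 1 / 400 + 1e-9)
})

test_that("the QSS reduction matches stiff integration of the full system", {
  p <- default_nondim_params(k = 1000, c_blood = 0.1)
  times <- seq(0, 40, length.out = 201)
  qss <- mf_trajectory(1 / 400, p, times = times)
  full <- mf_trajectory_full(1 / 400, p, times = times)
  expect_lt(max(abs(qss$phi - full$phi)), 0.02)
  expect_equal(qss$phi[length(times)], 1, tolerance = 1e-3)
})
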