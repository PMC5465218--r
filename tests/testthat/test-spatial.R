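test_that("tissue_state builds the initial configuration", {
  st <- tissue_state(5, s = 2, w = 0)
  expect_equal(st$N, 5L)
  expect_equal(sum(st$type), 1L)
  expect_true(st$type[2, 2])                 # floor(5/2) = 2
  expect_equal(aberrant_fraction(st), 1 / 25)
  st2 <- tissue_state(4, aberrant = c(1, 16), s = 1)
  expect_equal(aberrant_fraction(st2), 2 / 16)
})

test_that("the lattice operator vanishes on uniform fields and matches hand evaluation", {
  p <- p_toy(k = 0, c_blood = 8)
  # u_MM(8) = 0.8 >= u_m: healthy cells draw exactly u_m, no diffusion term
  st <- tissue_state(6, aberrant = NULL, s = 8, w = 0)
  rhs <- field_rhs(st, p)
  expect_equal(rhs$ds, matrix(-p$u_m, 6, 6))
  expect_equal(rhs$dw, matrix(0, 6, 6))
  # hand-computed 2 x 2 fixture with coordination d = 2:
  # site (i): ds_i = (D/2) * sum_j (s_j - s_i) over its 2 lattice neighbors
  p2 <- p_toy(k = 0, c_blood = 1)
  p2$d <- 2L
  s0 <- matrix(c(1, 1, 0, 0), 2, 2)   # left column 1, right column 0
  st2 <- tissue_state(2, aberrant = NULL, s = s0, w = 0)
  u0 <- matrix(pmin(s0 / (2 + s0), 0.5), 2, 2)   # healthy Eq-2 uptake
  expect_equal(field_rhs(st2, p2)$ds,
               (p2$D_S / 2) * matrix(c(-1, -1, 1, 1), 2, 2) - u0)
})

test_that("discrete diffusion conserves mass with no uptake and no blood exchange", {
  # all-aberrant tissue at s = 0 takes up nothing and secretes nothing,
  # so the waste field evolves by pure diffusion
  p <- p_toy(k = 0, c_blood = 1)
  set.seed(5)
  w0 <- matrix(rexp(64), 8, 8)
  for (bnd in c("noflux", "periodic")) {
    st <- tissue_state(8, aberrant = matrix(TRUE, 8, 8), s = 0, w = w0,
                       boundary = bnd)
    dt <- 0.1 / (p$D_W + p$k)
    expect_true(all(field_rhs(st, p)$ds == 0))
    for (i in 1:1e4) st$w <- st$w + dt * field_rhs(st, p)$dw
    expect_equal(sum(st$w), sum(w0), tolerance = 1e-9)
    expect_lt(max(st$w) - min(st$w), 1e-6)   # smoothed flat
  }
})

test_that("equilibration reaches the analytic all-healthy fixed point", {
  p <- p_toy(k = 5, c_blood = 8)
  st <- tissue_state(6, aberrant = NULL, s = 8, w = 0)
  for (method in c("stepper", "newton")) {
    eq <- equilibrate_fields(st, p, tol = 1e-10, method = method)
    # u_MM(s*) > u_m, so k(c - s*) = u_m: s* = c - u_m/k uniformly
    expect_equal(eq$s, matrix(8 - 0.5 / 5, 6, 6), tolerance = 1e-8)
    expect_equal(eq$w, matrix(0, 6, 6))
  }
  # idempotence: a fixed point is returned unchanged
  eq <- equilibrate_fields(st, p, tol = 1e-10, method = "newton")
  eq2 <- equilibrate_fields(eq, p, tol = 1e-10, method = "newton")
  expect_equal(eq2$s, eq$s, tolerance = 1e-9)
})

test_that("stepper and Newton agree on a mixed tissue", {
  p <- p_toy(k = 2, c_blood = 3)
  st <- tissue_state(6, aberrant = c(15, 16, 21), s = 3, w = 0)
  tol <- 1e-9
  eq_n <- equilibrate_fields(st, p, tol = tol, method = "newton")
  eq_s <- equilibrate_fields(st, p, tol = tol, method = "stepper")
  # both meet the residual tolerance; fields agree to a small multiple
  expect_lt(max(abs(eq_n$s - eq_s$s)), 10 * tol / p$k)
  expect_lt(max(abs(eq_n$w - eq_s$w)), 10 * tol / p$k)
  rhs <- field_rhs(eq_n, p)
  expect_lt(max(abs(rhs$ds)), tol)
  expect_lt(max(abs(rhs$dw)), tol)
  expect_true(all(eq_n$s >= 0) && all(eq_n$w >= 0))
})

test_that("with no nutrient source the field drains to zero", {
  p <- p_toy(k = 0, c_blood = 1)
  st <- tissue_state(4, aberrant = NULL, s = 0.5, w = 0)
  eq <- equilibrate_fields(st, p, tol = 1e-6, method = "stepper",
                           max_time = 1e4)
  expect_lt(max(eq$s), 1e-4)
})

test_that("non-convergence raises an error carrying the residual", {
  # a time budget far below the relaxation time of the tissue
  p <- p_toy(k = 0.5, c_blood = 5)
  st <- tissue_state(4, aberrant = matrix(TRUE, 4, 4), s = 5, w = 0)
  err <- tryCatch(
    equilibrate_fields(st, p, tol = 1e-12, method = "stepper",
                       max_time = 0.05),
    warburgsim_equilibration_error = function(e) e)
  expect_s3_class(err, "warburgsim_equilibration_error")
  expect_gt(err$residual, 0)
})

test_that("event rates follow cell type, neighborhood and local fields", {
  p <- p_toy(k = 5, c_blood = 8)
  # all healthy: silent tissue
  st <- tissue_state(4, aberrant = NULL, s = 8, w = 0)
  r <- event_rates(st, p)
  expect_true(all(r$lam == 0) && all(r$sig == 0))
  # an aberrant cell walled in by aberrant cells cannot replicate but can die
  st2 <- tissue_state(3, aberrant = matrix(TRUE, 3, 3), s = 8, w = 2)
  r2 <- event_rates(st2, p)
  expect_true(all(r2$lam == 0))
  expect_true(all(r2$sig > 0))
  # a lone aberrant cell in a clean, nutrient-rich spot replicates only
  st3 <- tissue_state(3, aberrant = 5, s = 8, w = 0)
  r3 <- event_rates(st3, p)
  expect_gt(r3$lam[5], 0)
  expect_equal(r3$sig[5], 0)
  expect_equal(sum(r3$lam > 0), 1L)
})

test_that("gillespie events are selected proportionally to their rates", {
  p <- p_toy(k = 5, c_blood = 8)
  st <- tissue_state(3, aberrant = 5, s = 8, w = 0)
  lam <- sig <- matrix(0, 3, 3)
  lam[5] <- 2; sig[5] <- 1
  set.seed(123)
  n <- 1e4
  births <- 0L; wait <- numeric(n)
  for (i in seq_len(n)) {
    step <- gillespie_step(st, p, rates = list(lam = lam, sig = sig))
    births <- births + (step$event$type == "replication")
    wait[i] <- step$event$dt
  }
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(births / n - 2 / 3), 3 * se)
  expect_equal(mean(wait), 1 / 3, tolerance = 0.05)
  # a replication flips exactly one healthy neighbor; a death frees the site
  set.seed(1)
  step <- gillespie_step(st, p, rates = list(lam = lam, sig = sig))
  dphi <- aberrant_fraction(step$state) - aberrant_fraction(st)
  expect_equal(abs(dphi), 1 / 9)
  # absorbing signal when nothing can happen
  none <- gillespie_step(st, p, rates = list(lam = 0 * lam, sig = 0 * sig))
  expect_equal(none$event$type, "none")
})

test_that("simulations are reproducible and phi moves one site at a time", {
  p <- default_nondim_params(k = 1000, c_blood = 0.1)
  tr1 <- run_simulation(p, N = 8, seed = 42, t_max = 200)
  tr2 <- run_simulation(p, N = 8, seed = 42, t_max = 200)
  expect_identical(tr1$record, tr2$record)
  expect_identical(tr1$outcome, tr2$outcome)
  expect_true(all(abs(diff(tr1$record$phi)) %in% c(0, 1 / 64)))
  expect_true(all(diff(tr1$record$t) > 0))
})

test_that("without blood nutrient the aberrant cell is inert", {
  p <- default_nondim_params(k = 10, c_blood = 0)
  tr <- run_simulation(p, N = 6, seed = 1, t_max = 50)
  expect_equal(tr$n_events, 0L)
  expect_equal(tr$outcome, "stalled")
  expect_equal(tr$phi_f, 1 / 36)
  expect_false(tr$ever_secreted)
})

test_that("nutrient-starved low-turnover environments never secrete waste", {
  # deep W-: c far below the secretion threshold once uptake equilibrates
  p <- default_nondim_params(k = 0.5, c_blood = 0.05)
  th <- fraction_thresholds(p)
  expect_lte(th$phi_sec, 0)
  tr <- run_simulation(p, N = 8, seed = 3, t_max = 100)
  expect_false(tr$ever_secreted)
  expect_lte(tr$phi_f, 1 / 64 * 2)
})

test_that("trajectories round-trip to CSV with a JSON sidecar", {
  p <- default_nondim_params(k = 1000, c_blood = 0.1)
  tr <- run_simulation(p, N = 6, seed = 7, t_max = 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$phi, tr$record$phi)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv))
  expect_equal(meta$seed, 7L)
  expect_equal(meta$outcome, tr$outcome)
  expect_equal(meta$params$k, 1000)
})
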