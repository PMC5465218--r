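#' Mean-field (spatially homogeneous) tissue model
#'
#' When metabolite transport is fast enough that every cell senses the same
#' nutrient level `s` and waste level `w`, the tissue state reduces to the
#' triple `(phi, s, w)` with `phi` the aberrant fraction, evolving as
#'
#' * `dphi/dt = (lambda - sigma) * phi * (1 - phi)` — replication and death
#'   at fixed total population, both requiring the vicinity of a healthy
#'   cell (hence the logistic factor);
#' * `ds/dt = -phi * u_ab - (1 - phi) * u_he + k (c - s)`;
#' * `dw/dt = -phi * v_ab - (1 - phi) * v_he - k w` (aberrant `v_ab <= 0`
#'   is a source of waste, healthy `v_he >= 0` a sink, blood a pure sink).
#'
#' `lambda` and `sigma` are the aberrant replication and death rates of
#' [replication_rate()] and [death_rate()] evaluated at the aberrant cell's
#' energy output in `(s, w)`.
#'
#' @param state numeric vector or list with components `phi`, `s`, `w`.
#' @param p a `model_params` object with `k`, `c` set.
#' @return a named list `(dphi, ds, dw)`.
#' @export
mf_rhs <- function(state, p) {
  phi <- state[["phi"]]; s <- state[["s"]]; w <- state[["w"]]
  ab <- aberrant_fluxes(s, p)
  he <- healthy_fluxes(s, w, p)
  lam <- replication_rate(ab$e, w, p)
  sig <- death_rate(w, p)
  list(
    dphi = (lam - sig) * phi * (1 - phi),
    ds = -phi * ab$u - (1 - phi) * he$u + p$k * (p$c - s),
    dw = -phi * ab$v - (1 - phi) * he$v - p$k * w
  )
}

#' Quasi-steady-state metabolite levels at a given aberrant fraction
#'
#' Sets `ds/dt = dw/dt = 0` at fixed `phi` and solves for the tissue
#' nutrient and waste levels. The S balance decouples (uptake depends on
#' `s` only): `k(c - s) = phi*u_ab(s) + (1-phi)*u_he(s)` has a unique root
#' in `[0, c]` because the left side is strictly decreasing and the right
#' side non-decreasing in `s`. Given `s*`, the W balance
#' `-phi*v_ab(s*) = (1-phi)*v_he(s*, w) + k w` likewise has a unique
#' non-negative root. The model is therefore monostable at the
#' concentration level: the piecewise-min structure of the flux kernel
#' creates kinks but no extra roots.
#'
#' @param phi aberrant fraction in `[0, 1]`.
#' @param p a `model_params` object with `k > 0` and `c` set.
#' @param tol root-finding tolerance passed to [stats::uniroot()].
#' @return a named list `(s, w)` with the steady-state levels.
#' @export
qss_concentrations <- function(phi, p, tol = 1e-12) {
  if (is.na(p$k) || is.na(p$c))
    stop("qss_concentrations needs the environment (k, c) set", call. = FALSE)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  if (p$k <= 0)
    stop("no finite quasi-steady state at k = 0 with positive uptake",
         call. = FALSE)
  if (p$c == 0) return(list(s = 0, w = 0))
  uptake <- function(s)
    phi * aberrant_fluxes(s, p)$u + (1 - phi) * healthy_fluxes(s, 0, p)$u
  g <- function(s) p$k * (p$c - s) - uptake(s)
  s_star <- if (g(p$c) >= 0) p$c else
    stats::uniroot(g, c(0, p$c), tol = tol)$root
  source_w <- -phi * aberrant_fluxes(s_star, p)$v
  if (source_w <= 0) return(list(s = s_star, w = 0))
  h <- function(w) source_w - (1 - phi) * healthy_fluxes(s_star, w, p)$v - p$k * w
  w_hi <- source_w / p$k
  w_star <- if (h(w_hi) >= 0) w_hi else
    stats::uniroot(h, c(0, w_hi), tol = tol)$root
  list(s = s_star, w = w_star)
}

# net per-capita growth rate of the aberrant fraction under QSS
qss_growth <- function(phi, p) {
  cl <- qss_concentrations(phi, p)
  ab <- aberrant_fluxes(cl$s, p)
  replication_rate(ab$e, cl$w, p) - death_rate(cl$w, p)
}

#' Integrate the quasi-steady-state-reduced aberrant fraction
#'
#' The QSS reduction leaves `phi` as the only dynamical variable:
#' `dphi/dt = (lambda(phi) - sigma(phi)) * phi * (1 - phi)` with the
#' metabolite levels re-solved from [qss_concentrations()] along the way.
#' Integration uses `deSolve::ode` (lsoda).
#'
#' @param phi0 initial aberrant fraction in `(0, 1)`; the reference value
#'   `1/400` is one cell's worth of a `20 x 20` tissue.
#' @param p a `model_params` object with `k > 0`, `c` set.
#' @param t_max integration horizon (non-dimensional time).
#' @param times optional explicit output times.
#' @param tol relative/absolute integration tolerance.
#' @return a data frame `(t, phi, s, w)`.
#' @export
mf_trajectory <- function(phi0, p, t_max = 1000, times = NULL, tol = 1e-8) {
  stopifnot(phi0 > 0, phi0 < 1)
  if (is.null(times)) times <- seq(0, t_max, length.out = 401L)
  deriv <- function(t, y, parms) {
    phi <- min(max(y[1L], 0), 1)
    list(qss_growth(phi, p) * phi * (1 - phi))
  }
  sol <- deSolve::ode(c(phi = phi0), times, deriv, parms = NULL,
                      method = "lsoda", rtol = tol, atol = tol)
  phi <- pmin(pmax(sol[, "phi"], 0), 1)
  cl <- vapply(phi, function(f) unlist(qss_concentrations(f, p)), numeric(2))
  data.frame(t = sol[, "time"], phi = phi, s = cl[1L, ], w = cl[2L, ])
}

#' Integrate the full three-variable homogeneous model
#'
#' Direct stiff integration of the `(phi, s, w)` system without the QSS
#' reduction; serves as the independent check that metabolite time scales
#' are fast enough for the reduction to hold.
#'
#' @inheritParams mf_trajectory
#' @param s0,w0 initial metabolite levels (defaults: blood level and zero).
#' @return a data frame `(t, phi, s, w)`.
#' @export
mf_trajectory_full <- function(phi0, p, t_max = 1000, times = NULL,
                               s0 = p$c, w0 = 0, tol = 1e-8) {
  stopifnot(phi0 > 0, phi0 < 1)
  if (is.null(times)) times <- seq(0, t_max, length.out = 401L)
  deriv <- function(t, y, parms) {
    st <- list(phi = min(max(y[1L], 0), 1), s = max(y[2L], 0), w = max(y[3L], 0))
    d <- mf_rhs(st, p)
    list(c(d$dphi, d$ds, d$dw))
  }
  sol <- deSolve::ode(c(phi = phi0, s = s0, w = w0), times, deriv,
                      parms = NULL, method = "lsoda", rtol = tol, atol = tol)
  data.frame(t = sol[, "time"], phi = pmin(pmax(sol[, "phi"], 0), 1),
             s = sol[, "s"], w = sol[, "w"])
}

#' Asymptotic aberrant fraction of the homogeneous model
#'
#' Integrates the QSS-reduced dynamics for a long time and reports the
#' final fraction, rounded to the absorbing endpoints 0/1 when within
#' `endpoint_tol`. The result satisfies
#' `phi_f <= min(1, phi_gr)` (`phi_gr` caps the achievable fraction; see
#' [fraction_thresholds()]).
#'
#' @param p a `model_params` object with `k > 0`, `c` set.
#' @param phi0 initial fraction (reference `1/400`).
#' @param t_long integration horizon.
#' @param tol integration tolerance; convergence requires
#'   `|dphi/dt| <= conv_tol` at `t_long`.
#' @param conv_tol convergence tolerance on the final derivative.
#' @param endpoint_tol rounding tolerance to the endpoints.
#' @return a list `(phi_f, converged, dphi_final)`.
#' @export
asymptotic_fraction <- function(p, phi0 = 1 / 400, t_long = 1000,
                                tol = 1e-8, conv_tol = 1e-6,
                                endpoint_tol = 1e-6) {
  times <- c(0, t_long / 2, t_long)
  deriv <- function(t, y, parms) {
    phi <- min(max(y[1L], 0), 1)
    list(qss_growth(phi, p) * phi * (1 - phi))
  }
  sol <- deSolve::ode(c(phi = phi0), times, deriv, parms = NULL,
                      method = "lsoda", rtol = tol, atol = tol)
  phi_f <- min(max(sol[nrow(sol), "phi"], 0), 1)
  dphi <- qss_growth(phi_f, p) * phi_f * (1 - phi_f)
  if (phi_f < endpoint_tol) phi_f <- 0
  if (phi_f > 1 - endpoint_tol) phi_f <- 1
  list(phi_f = phi_f, converged = abs(dphi) <= conv_tol, dphi_final = dphi)
}
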