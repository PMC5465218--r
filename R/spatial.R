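#' Tissue state on the square lattice
#'
#' An `N x N` single layer of cells, each site either healthy or aberrant,
#' with per-site concentration fields of the primary nutrient `s` and the
#' waste `w`. Grids are stored as `N x N` matrices; site `i` in vectorized
#' (column-major) order corresponds to `(row, col) = ((i-1) %% N + 1,
#' (i-1) %/% N + 1)`.
#'
#' @param N lattice side length (`>= 1`).
#' @param aberrant which sites start aberrant: `"center"` (a single cell at
#'   `(floor(N/2), floor(N/2))`, maximally far from the boundary), a vector
#'   of site indices, or a logical `N x N` matrix.
#' @param s,w initial concentration fields: scalars or `N x N` matrices,
#'   `>= 0`. The natural initial condition is `s = c`, `w = 0`.
#' @param t elapsed time.
#' @param boundary `"noflux"` (missing neighbors carry no flux; the natural
#'   choice for a finite tissue patch bathed by blood) or `"periodic"`.
#' @return an object of class `tissue_state` with fields `N`, `type`
#'   (logical matrix, `TRUE` = aberrant), `s`, `w`, `t`, `boundary`.
#' @export
tissue_state <- function(N, aberrant = "center", s = 0, w = 0, t = 0,
                         boundary = c("noflux", "periodic")) {
  boundary <- match.arg(boundary)
  N <- as.integer(N)
  stopifnot(N >= 1L)
  type <- matrix(FALSE, N, N)
  if (identical(aberrant, "center")) {
    ctr <- max(1L, N %/% 2L)
    type[ctr, ctr] <- TRUE
  } else if (is.matrix(aberrant)) {
    stopifnot(identical(dim(aberrant), dim(type)))
    type[] <- as.logical(aberrant)
  } else if (is.numeric(aberrant)) {
    type[as.integer(aberrant)] <- TRUE
  } else if (!is.null(aberrant)) {
    stop("unrecognized 'aberrant' specification", call. = FALSE)
  }
  as_field <- function(x) {
    if (length(x) == 1L) x <- matrix(x, N, N)
    stopifnot(is.matrix(x), identical(dim(x), c(N, N)), all(x >= 0))
    x
  }
  structure(list(N = N, type = type, s = as_field(s), w = as_field(w),
                 t = t, boundary = boundary),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat("tissue_state: ", x$N, "x", x$N, " lattice, phi = ",
      signif(aberrant_fraction(x), 4), ", t = ", signif(x$t, 6),
      ", ", x$boundary, " boundary\n", sep = "")
  cat("mean s = ", signif(mean(x$s), 6), ", mean w = ", signif(mean(x$w), 6),
      "\n", sep = "")
  invisible(x)
}

#' @rdname tissue_state
#' @param state a `tissue_state`.
#' @export
aberrant_fraction <- function(state) mean(state$type)

# ---- lattice operators -----------------------------------------------------

# sum over existing neighbors (zero-padded shifts for no-flux)
nbr_sum <- function(m, periodic = FALSE) {
  n <- nrow(m)
  if (n == 1L && !periodic) return(matrix(0, 1L, ncol(m)))
  if (periodic) {
    up <- m[c(n, seq_len(n - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
    lf <- m[, c(ncol(m), seq_len(ncol(m) - 1L)), drop = FALSE]
    rt <- m[, c(seq_len(ncol(m) - 1L) + 1L, 1L), drop = FALSE]
  } else {
    z_row <- matrix(0, 1L, ncol(m))
    up <- rbind(z_row, m[-n, , drop = FALSE])
    dn <- rbind(m[-1L, , drop = FALSE], z_row)
    z_col <- matrix(0, n, 1L)
    lf <- cbind(z_col, m[, -ncol(m), drop = FALSE])
    rt <- cbind(m[, -1L, drop = FALSE], z_col)
  }
  up + dn + lf + rt
}

# per-site neighbor counts
nbr_count <- function(N, periodic = FALSE) {
  if (periodic) return(matrix(4, N, N))
  nbr_sum(matrix(1, N, N), periodic = FALSE)
}

# neighbor site indices of vectorized site i
site_neighbors <- function(i, N, periodic = FALSE) {
  row <- (i - 1L) %% N + 1L
  col <- (i - 1L) %/% N + 1L
  if (periodic) {
    rows <- c(if (row == 1L) N else row - 1L, if (row == N) 1L else row + 1L, row, row)
    cols <- c(col, col, if (col == 1L) N else col - 1L, if (col == N) 1L else col + 1L)
  } else {
    rows <- c(row - 1L, row + 1L, row, row)
    cols <- c(col, col, col - 1L, col + 1L)
    keep <- rows >= 1L & rows <= N & cols >= 1L & cols <= N
    rows <- rows[keep]; cols <- cols[keep]
  }
  unique((cols - 1L) * N + rows)
}

# sparse adjacency matrix of the lattice (for the Newton field solver)
lattice_adjacency <- function(N, periodic = FALSE) {
  n <- N * N
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- site_neighbors(i, N, periodic)
    ii <- c(ii, rep.int(i, length(nb)))
    jj <- c(jj, nb)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = rep.int(1, length(ii)),
                       dims = c(n, n))
}

# per-site fluxes for the whole grid, dispatched on cell type
grid_fluxes <- function(state, p) {
  he <- healthy_fluxes(state$s, state$w, p)
  ab <- aberrant_fluxes(state$s, p)
  sel <- state$type
  u <- he$u; u[sel] <- ab$u[sel]
  v <- he$v; v[sel] <- ab$v[sel]
  r <- he$r; r[sel] <- ab$r[sel]
  e <- he$e; e[sel] <- ab$e[sel]
  list(u = u, v = v, r = r, e = e)
}

#' Reaction-diffusion right-hand side on the lattice
#'
#' Time derivatives of the concentration fields: neighbor-averaging
#' diffusion `D * ((1/d) * sum_j x_j - (n_i/d) * x_i)` (written in flux form
#' so that missing neighbors carry no flux and total mass is conserved at
#' `k = 0` with uptake disabled), cellular exchange (`-u` for S, `-v` for W;
#' aberrant `v < 0` is a source of waste), and blood exchange (`+k(c - s)`
#' for S; `-k w` for W, the blood being a pure sink for waste). Fluxes are
#' recomputed from the current fields according to each site's type.
#'
#' @param state a `tissue_state`.
#' @param p a `model_params` object with `k`, `c` set.
#' @return a list `(ds, dw, fluxes)` of derivative grids and the per-site
#'   flux grids used.
#' @export
field_rhs <- function(state, p) {
  if (is.na(p$k) || is.na(p$c))
    stop("field_rhs needs the environment (k, c) set", call. = FALSE)
  per <- state$boundary == "periodic"
  cnt <- nbr_count(state$N, per)
  fl <- grid_fluxes(state, p)
  ds <- (p$D_S / p$d) * (nbr_sum(state$s, per) - cnt * state$s) -
    fl$u + p$k * (p$c - state$s)
  dw <- (p$D_W / p$d) * (nbr_sum(state$w, per) - cnt * state$w) -
    fl$v - p$k * state$w
  list(ds = ds, dw = dw, fluxes = fl)
}

# condition for equilibration failure
equilibration_error <- function(residual, msg) {
  structure(class = c("warburgsim_equilibration_error", "error", "condition"),
            list(message = sprintf("%s (residual max-norm %.3g)", msg, residual),
                 call = NULL, residual = residual))
}

# ---- field equilibration ---------------------------------------------------

# semismooth Newton for the S steady state: the S equation decouples from w
# because uptake u depends on s only (both cell types)
newton_field_s <- function(state, p, ctx, tol, maxit = 60L) {
  n <- state$N^2
  ab <- as.vector(state$type)
  x <- pmax(as.vector(state$s), 0)
  Fres <- function(x) {
    mmu <- p$u_max * x / (p$K_s + x)
    u <- pmin(mmu, p$u_m)
    u[ab] <- p$alpha_ab * mmu[ab]
    as.vector(ctx$L_s %*% x) - u + p$k * (p$c - x)
  }
  f <- Fres(x)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) <= tol) return(matrix(x, state$N, state$N))
    slope <- mm_slope(x, p$u_max, p$K_s)
    mmu <- p$u_max * x / (p$K_s + x)
    up <- ifelse(mmu < p$u_m, slope, 0)
    up[ab] <- p$alpha_ab * slope[ab]
    J <- ctx$L_s - Matrix::Diagonal(n, x = up + p$k)
    dx <- tryCatch(as.vector(Matrix::solve(J, -f)), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) return(NULL)
    step <- 1
    repeat {
      xn <- pmax(x + step * dx, 0)
      fn <- Fres(xn)
      if (max(abs(fn)) < max(abs(f)) || step < 1 / 64) break
      step <- step / 2
    }
    if (max(abs(fn)) >= max(abs(f))) return(NULL)  # stalled
    x <- xn; f <- fn
  }
  if (max(abs(f)) <= tol) matrix(x, state$N, state$N) else NULL
}

# Newton for the W steady state given equilibrated s
newton_field_w <- function(state, p, ctx, tol, maxit = 60L) {
  n <- state$N^2
  ab <- as.vector(state$type)
  svec <- as.vector(state$s)
  mmu <- p$u_max * svec / (p$K_s + svec)
  u_he <- pmin(mmu, p$u_m)
  cap <- (p$u_m - u_he) * (1 + p$Y_u / p$Y_r)   # healthy recycling demand
  v_ab <- pmin(0, p$r_max - p$alpha_ab * mmu)   # aberrant secretion (<= 0)
  x <- pmax(as.vector(state$w), 0)
  vfun <- function(x) {
    if (p$knockout) v <- numeric(n)
    else v <- pmax(pmin(p$v_max * x / (p$K_w + x), cap), 0)
    v[ab] <- v_ab[ab]
    v
  }
  Fres <- function(x) as.vector(ctx$L_w %*% x) - vfun(x) - p$k * x
  f <- Fres(x)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) <= tol) return(matrix(x, state$N, state$N))
    if (p$knockout) {
      vp <- numeric(n)
    } else {
      vmm <- p$v_max * x / (p$K_w + x)
      vp <- ifelse(vmm < cap, mm_slope(x, p$v_max, p$K_w), 0)
    }
    vp[ab] <- 0
    J <- ctx$L_w - Matrix::Diagonal(n, x = vp + p$k)
    dx <- tryCatch(as.vector(Matrix::solve(J, -f)), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) return(NULL)
    step <- 1
    repeat {
      xn <- pmax(x + step * dx, 0)
      fn <- Fres(xn)
      if (max(abs(fn)) < max(abs(f)) || step < 1 / 64) break
      step <- step / 2
    }
    if (max(abs(fn)) >= max(abs(f))) return(NULL)
    x <- xn; f <- fn
  }
  if (max(abs(f)) <= tol) matrix(x, state$N, state$N) else NULL
}

# diffusion + blood-exchange operator in sparse form, built once per run
solver_context <- function(N, p, boundary) {
  per <- boundary == "periodic"
  A <- lattice_adjacency(N, per)
  cnt <- as.vector(nbr_count(N, per))
  n <- N * N
  lap <- function(D) (D / p$d) * (A - Matrix::Diagonal(n, x = cnt))
  # blood-exchange and uptake terms enter through the Newton diagonal
  list(A = A, cnt = cnt, L_s = lap(p$D_S), L_w = lap(p$D_W))
}

#' Equilibrate the concentration fields
#'
#' Advances the nutrient and waste fields, with the cell configuration
#' frozen, until the reaction-diffusion right-hand side satisfies
#' `max(|ds/dt|, |dw/dt|) <= tol` — the fast-metabolite quasi-steady state
#' that the event dynamics assumes.
#'
#' Two schemes are available. `"stepper"` (the reference scheme) is adaptive
#' explicit Euler with a stability-bounded step size; it preserves
#' non-negativity by construction. `"newton"` is a direct semismooth Newton
#' solve of the steady-state system, exploiting the fact that the S
#' equation decouples from `w` (uptake depends on `s` only) and the W
#' equation is then solved given `s`; it is much faster and agrees with the
#' stepper to within a small multiple of `tol`. Newton falls back to the
#' stepper if it stalls (e.g. near a branch-point kink of the flux
#' kernel).
#'
#' @param state a `tissue_state`.
#' @param p a `model_params` object with `k`, `c` set.
#' @param tol residual max-norm tolerance (non-dimensional concentration
#'   per time).
#' @param max_time maximal internal integration time for the stepper before
#'   giving up with an error carrying the residual norm.
#' @param method `"stepper"` or `"newton"`.
#' @param ctx internal solver context (precomputed lattice operators);
#'   built automatically when `NULL`.
#' @return the `tissue_state` with equilibrated `s`, `w` (cell types and
#'   elapsed time `t` unchanged).
#' @export
equilibrate_fields <- function(state, p, tol = 1e-8, max_time = 1000,
                               method = c("stepper", "newton"), ctx = NULL) {
  method <- match.arg(method)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (is.null(ctx)) ctx <- solver_context(state$N, p, state$boundary)
  if (method == "newton") {
    s_new <- newton_field_s(state, p, ctx, tol)
    if (!is.null(s_new)) {
      state$s <- s_new
      w_new <- newton_field_w(state, p, ctx, tol)
      if (!is.null(w_new)) {
        state$w <- w_new
        stopifnot(all(state$s >= 0), all(state$w >= 0))
        return(state)
      }
    }
    # fall through to the stepper from the best available iterate
  }
  # adaptive explicit Euler, step bounded by the fastest local rate
  per <- state$boundary == "periodic"
  cnt_max <- max(ctx$cnt)
  rate_s <- p$D_S * cnt_max / p$d + p$k + p$alpha_ab * p$u_max / p$K_s
  rate_w <- p$D_W * cnt_max / p$d + p$k + p$v_max / p$K_w
  dt <- 0.8 / max(rate_s, rate_w)
  t_int <- 0
  repeat {
    rhs <- field_rhs(state, p)
    res <- max(max(abs(rhs$ds)), max(abs(rhs$dw)))
    if (res <= tol) break
    if (t_int >= max_time)
      stop(equilibration_error(res, "field equilibration did not converge"))
    n_sub <- 32L
    for (i in seq_len(n_sub)) {
      state$s <- pmax(state$s + dt * rhs$ds, 0)
      state$w <- pmax(state$w + dt * rhs$dw, 0)
      if (i < n_sub) rhs <- field_rhs(state, p)
    }
    t_int <- t_int + n_sub * dt
  }
  stopifnot(all(state$s >= 0), all(state$w >= 0))
  state
}

#' Replication and death rates of every site
#'
#' Only aberrant cells have stochastic dynamics. An aberrant cell
#' replicates (into the site of a randomly picked healthy neighbor) at the
#' rate of [replication_rate()] evaluated at its local energy output and
#' waste level, provided it has at least one healthy neighbor; it dies (and
#' is replaced by a healthy cell) at the rate of [death_rate()]. Healthy
#' cells have zero rates. Fields are assumed equilibrated.
#'
#' @param state a `tissue_state` with equilibrated fields.
#' @param p a `model_params` object.
#' @return a list of `N x N` matrices `(lam, sig)`.
#' @export
event_rates <- function(state, p) {
  per <- state$boundary == "periodic"
  lam <- sig <- matrix(0, state$N, state$N)
  ab <- state$type
  if (any(ab)) {
    has_healthy_nbr <- nbr_sum(1 - ab, per) > 0
    e_ab <- aberrant_fluxes(state$s, p)$e
    can_rep <- ab & has_healthy_nbr
    lam[can_rep] <- replication_rate(e_ab[can_rep], state$w[can_rep], p)
    sig[ab] <- death_rate(state$w[ab], p)
  }
  list(lam = lam, sig = sig)
}

#' One Gillespie event
#'
#' Samples the waiting time to the next replication or death event from an
#' exponential with the total rate, advances the clock, picks the event in
#' proportion to its rate, and applies it: replication converts a uniformly
#' chosen healthy neighbor of the parent to aberrant; death converts the
#' dying aberrant cell back to healthy. Exactly one site changes type. Uses
#' R's global RNG stream.
#'
#' @param state a `tissue_state` with equilibrated fields.
#' @param p a `model_params` object.
#' @param rates optional precomputed [event_rates()].
#' @return a list `(state, event)`; when no event is possible (total rate
#'   zero) the state is returned unchanged with
#'   `event = list(type = "none")`.
#' @export
gillespie_step <- function(state, p, rates = NULL) {
  if (is.null(rates)) rates <- event_rates(state, p)
  rate_vec <- c(rates$lam, rates$sig)
  R <- sum(rate_vec)
  if (R <= 0) return(list(state = state, event = list(type = "none")))
  dt <- stats::rexp(1L, R)
  n <- state$N^2
  idx <- sample.int(2L * n, 1L, prob = rate_vec)
  per <- state$boundary == "periodic"
  if (idx <= n) {
    nb <- site_neighbors(idx, state$N, per)
    nb <- nb[!state$type[nb]]
    target <- nb[sample.int(length(nb), 1L)]
    state$type[target] <- TRUE
    event <- list(type = "replication", parent = idx, site = target, dt = dt)
  } else {
    site <- idx - n
    state$type[site] <- FALSE
    event <- list(type = "death", site = site, dt = dt)
  }
  state$t <- state$t + dt
  list(state = state, event = event)
}

#' Simulate the spread of the aberrant phenotype on the lattice
#'
#' Full stochastic simulation: starting from the given cell configuration
#' with fields `s = c`, `w = 0`, the metabolite fields are equilibrated
#' (quasi-steady state), the tissue-level observables are recorded, and
#' cell dynamics is advanced to the next replication/death event with the
#' Gillespie algorithm; this alternation repeats until the tissue absorbs
#' at `phi = 0` (healthy) or `phi = 1` (takeover), no event is possible, or
#' `t_max` is reached. Fields are re-equilibrated from scratch before every
#' event; rates are never cached across events.
#'
#' Fully reproducible: the run is a pure function of
#' `(p, N, init, seed, ...)`.
#'
#' @param p a `model_params` object with `k`, `c` set (normally
#'   non-dimensional, from [default_nondim_params()]).
#' @param N lattice side (the reference tissue is `20 x 20`).
#' @param init initial aberrant sites, as in [tissue_state()] (default: a
#'   single central aberrant cell).
#' @param seed integer seed for the run's single RNG stream.
#' @param t_max stop after this time with outcome `"non-absorbed"`.
#' @param at_takeover `"stop"` treats `phi = 1` as absorbing takeover (the
#'   default); `"continue"` keeps simulating (deaths then re-seed healthy
#'   cells while waste persists).
#' @param field_solver equilibration scheme per event, see
#'   [equilibrate_fields()]; the Newton fast path is the simulation default
#'   for tractable replicate ensembles.
#' @param boundary lattice boundary condition.
#' @param tol equilibration residual tolerance.
#' @return an object of class `tissue_trajectory`: list with `record` (data
#'   frame of `t`, `phi`, `s_mean`, `w_mean`, `u_he_mean`, `v_he_mean`,
#'   `n_secreting`, `n_recycling`, one row per event plus the initial row),
#'   `outcome` (`"healthy"`, `"takeover"`, `"stalled"`, `"non-absorbed"`),
#'   `phi_f`, `ever_secreted`, `ever_recycled`, `n_events`, `final_state`,
#'   `params`, `N`, `seed`.
#' @export
run_simulation <- function(p, N = 20, init = "center", seed = 1L,
                           t_max = 1000, at_takeover = c("stop", "continue"),
                           field_solver = c("newton", "stepper"),
                           boundary = c("noflux", "periodic"),
                           tol = 1e-8) {
  at_takeover <- match.arg(at_takeover)
  field_solver <- match.arg(field_solver)
  boundary <- match.arg(boundary)
  validate_params(p)
  if (is.na(p$k) || is.na(p$c))
    stop("run_simulation needs the environment (k, c) set", call. = FALSE)
  set.seed(as.integer(seed))
  state <- tissue_state(N, aberrant = init, s = p$c, w = 0, boundary = boundary)
  ctx <- solver_context(state$N, p, boundary)
  rec <- vector("list", 256L)
  n_rec <- 0L
  ever_sec <- FALSE; ever_rec <- FALSE
  observe <- function(state) {
    fl <- grid_fluxes(state, p)
    he <- !state$type
    n_secreting <- sum(fl$v[state$type] < -1e-12)
    n_recycling <- sum(fl$v[he] > 1e-12)
    ever_sec <<- ever_sec || n_secreting > 0L
    ever_rec <<- ever_rec || n_recycling > 0L
    data.frame(
      t = state$t, phi = aberrant_fraction(state),
      s_mean = mean(state$s), w_mean = mean(state$w),
      u_he_mean = if (any(he)) mean(fl$u[he]) else NA_real_,
      v_he_mean = if (any(he)) mean(fl$v[he]) else NA_real_,
      n_secreting = n_secreting, n_recycling = n_recycling
    )
  }
  equil <- function(state, n_events) {
    tryCatch(
      equilibrate_fields(state, p, tol = tol, method = field_solver, ctx = ctx),
      warburgsim_equilibration_error = function(e) {
        stop("equilibration failed at event ", n_events, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  n_events <- 0L
  state <- equil(state, n_events)
  n_rec <- n_rec + 1L; rec[[n_rec]] <- observe(state)
  outcome <- NULL
  repeat {
    phi <- aberrant_fraction(state)
    if (phi == 0) { outcome <- "healthy"; break }
    if (phi == 1 && at_takeover == "stop") { outcome <- "takeover"; break }
    if (state$t >= t_max) { outcome <- "non-absorbed"; break }
    step <- gillespie_step(state, p)
    if (identical(step$event$type, "none")) {
      outcome <- if (phi == 1) "takeover" else "stalled"
      break
    }
    state <- step$state
    n_events <- n_events + 1L
    state <- equil(state, n_events)
    if (n_rec == length(rec)) rec <- c(rec, vector("list", length(rec)))
    n_rec <- n_rec + 1L; rec[[n_rec]] <- observe(state)
  }
  traj <- structure(list(
    record = do.call(rbind, rec[seq_len(n_rec)]),
    outcome = outcome, phi_f = aberrant_fraction(state),
    ever_secreted = ever_sec, ever_recycled = ever_rec,
    n_events = n_events, final_state = state,
    params = p, N = as.integer(N), seed = as.integer(seed)
  ), class = "tissue_trajectory")
  traj
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  cat("tissue_trajectory: ", x$N, "x", x$N, " lattice, seed ", x$seed,
      ", k = ", signif(x$params$k, 4), ", c = ", signif(x$params$c, 4), "\n",
      sep = "")
  cat(x$n_events, " events, outcome: ", x$outcome,
      " (phi_f = ", signif(x$phi_f, 4), ")",
      if (x$ever_secreted) "; waste secreted" else "; no waste secreted",
      if (x$ever_recycled) "; waste recycled" else "", "\n", sep = "")
  invisible(x)
}

#' Write a trajectory to disk
#'
#' The event record as CSV plus a JSON sidecar with the full parameter set,
#' seed, outcome and package version.
#'
#' @param traj a `tissue_trajectory`.
#' @param csv_path output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path) {
  utils::write.csv(traj$record, csv_path, row.names = FALSE)
  meta <- list(
    params = traj$params[!(names(traj$params) %in% "units")],
    units = traj$params$units,
    N = traj$N, seed = traj$seed, outcome = traj$outcome,
    phi_f = traj$phi_f, n_events = traj$n_events,
    ever_secreted = traj$ever_secreted, ever_recycled = traj$ever_recycled,
    package_version = as.character(utils::packageVersion("warburgsim"))
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", csv_path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}
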