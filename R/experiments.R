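#' Deterministic per-run seed derivation
#'
#' A pure function of the sweep's base seed and the point/replicate
#' indices, so any single grid point's ensemble can be reproduced in
#' isolation and results are independent of scheduling order.
#'
#' @param seed0 integer base seed.
#' @param i_k,i_c 1-based indices into the `k` and `c` grids.
#' @param rep 1-based replicate index.
#' @return an integer seed below `2^31`.
#' @export
derive_seed <- function(seed0, i_k, i_c, rep) {
  as.integer((as.double(seed0) + 1000003 * i_k + 10007 * i_c + rep) %%
               2147483647)
}

#' Phase sweep of the spatial model
#'
#' Runs [run_simulation()] for every `(k, c)` grid point and replicate,
#' with seeds derived by [derive_seed()], and summarizes per point the mean
#' final aberrant fraction, the outcome counts, and the operational waste
#' role: `"W-"` if no replicate ever secreted waste, `"Sh."` if secretion
#' was accompanied by healthy recycling (majority of replicates), `"W+"`
#' if waste was secreted but never recycled.
#'
#' Individual run failures are recorded per point and the sweep continues.
#'
#' @param k_values,c_values environment grids (non-dimensional; the
#'   portraits use `k` logarithmic and `c` linear).
#' @param p a `model_params` object (its `k`, `c` are overwritten per
#'   point).
#' @param N lattice side.
#' @param replicates runs per grid point.
#' @param seed0 base seed.
#' @param ... further arguments to [run_simulation()].
#' @return an object of class `sweep_result`: list with `points` (one row
#'   per grid point: `k`, `c`, `mean_phi_f`, outcome counts, `secreted`,
#'   `recycled`, `waste_role`), `runs` (one row per run: `k`, `c`,
#'   `replicate`, `seed`, `phi_f`, `outcome`, `secreted`, `recycled`,
#'   `error`), `model = "spatial"`, and the knockout flag.
#' @export
phase_sweep_spatial <- function(k_values, c_values, p, N = 20,
                                replicates = 5, seed0 = 1L, ...) {
  stopifnot(replicates >= 1)
  runs <- list(); pts <- list()
  for (i_k in seq_along(k_values)) for (i_c in seq_along(c_values)) {
    pk <- with_environment(p, k_values[i_k], c_values[i_c])
    point_runs <- lapply(seq_len(replicates), function(rep) {
      seed <- derive_seed(seed0, i_k, i_c, rep)
      res <- tryCatch(run_simulation(pk, N = N, seed = seed, ...),
                      error = function(e) e)
      if (inherits(res, "error")) {
        data.frame(k = pk$k, c = pk$c, replicate = rep, seed = seed,
                   phi_f = NA_real_, outcome = "error",
                   secreted = NA, recycled = NA,
                   error = conditionMessage(res))
      } else {
        data.frame(k = pk$k, c = pk$c, replicate = rep, seed = seed,
                   phi_f = res$phi_f, outcome = res$outcome,
                   secreted = res$ever_secreted, recycled = res$ever_recycled,
                   error = NA_character_)
      }
    })
    df <- do.call(rbind, point_runs)
    runs[[length(runs) + 1L]] <- df
    ok <- df[df$outcome != "error", , drop = FALSE]
    role <- if (nrow(ok) == 0L) NA_character_ else {
      n_sec <- sum(ok$secreted); n_rec <- sum(ok$recycled)
      if (n_sec == 0L) "W-"
      else if (n_rec >= max(1L, n_sec %/% 2L)) "Sh."
      else "W+"
    }
    pts[[length(pts) + 1L]] <- data.frame(
      k = pk$k, c = pk$c,
      mean_phi_f = if (nrow(ok)) mean(ok$phi_f) else NA_real_,
      n_takeover = sum(ok$outcome == "takeover"),
      n_healthy = sum(ok$outcome == "healthy"),
      n_other = sum(!(ok$outcome %in% c("takeover", "healthy"))),
      n_error = sum(df$outcome == "error"),
      secreted = any(ok$secreted), recycled = any(ok$recycled),
      waste_role = role
    )
  }
  structure(list(points = do.call(rbind, pts), runs = do.call(rbind, runs),
                 model = "spatial", knockout = p$knockout,
                 N = N, replicates = replicates, seed0 = seed0),
            class = "sweep_result")
}

#' Phase sweep of the mean-field model
#'
#' [asymptotic_fraction()] and [classify_region()] at every `(k, c)` grid
#' point, plus detection of the discontinuous takeover boundary as
#' adjacent-point jumps in `phi_f` along each `c`-scan.
#'
#' @inheritParams phase_sweep_spatial
#' @param phi0 initial aberrant fraction.
#' @param jump_threshold adjacent-point difference in `phi_f` that counts
#'   as a discontinuity.
#' @param ... further arguments to [asymptotic_fraction()].
#' @return a `sweep_result` with `points` (`k`, `c`, `phi_f`, `converged`,
#'   `region`, `coarse_region`) and `boundary` (one row per detected jump:
#'   `k`, `c_lo`, `c_hi`, `delta_phi`).
#' @export
phase_sweep_meanfield <- function(k_values, c_values, p, phi0 = 1 / 400,
                                  jump_threshold = 0.5, ...) {
  pts <- list()
  for (i_k in seq_along(k_values)) for (i_c in seq_along(c_values)) {
    pk <- with_environment(p, k_values[i_k], c_values[i_c])
    af <- tryCatch(asymptotic_fraction(pk, phi0 = phi0, ...),
                   error = function(e) e)
    if (inherits(af, "error")) {
      pts[[length(pts) + 1L]] <- data.frame(
        k = pk$k, c = pk$c, phi_f = NA_real_, converged = FALSE,
        region = NA_character_, coarse_region = NA_character_)
    } else {
      reg <- classify_region(pk, phi_f = af$phi_f)
      pts[[length(pts) + 1L]] <- data.frame(
        k = pk$k, c = pk$c, phi_f = af$phi_f, converged = af$converged,
        region = reg$fine, coarse_region = reg$coarse)
    }
  }
  points <- do.call(rbind, pts)
  boundary <- detect_jumps(points, jump_threshold)
  structure(list(points = points, boundary = boundary, model = "meanfield",
                 knockout = p$knockout, phi0 = phi0, seed0 = NA_integer_),
            class = "sweep_result")
}

# adjacent-point discontinuities of phi_f along c at each fixed k
detect_jumps <- function(points, jump_threshold = 0.5) {
  out <- list()
  for (kv in unique(points$k)) {
    sub <- points[points$k == kv, , drop = FALSE]
    sub <- sub[order(sub$c), , drop = FALSE]
    d <- diff(sub$phi_f)
    hit <- which(abs(d) > jump_threshold)
    for (j in hit)
      out[[length(out) + 1L]] <- data.frame(
        k = kv, c_lo = sub$c[j], c_hi = sub$c[j + 1L], delta_phi = d[j])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(k = numeric(0), c_lo = numeric(0), c_hi = numeric(0),
                  delta_phi = numeric(0))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result (", x$model, " model",
      if (isTRUE(x$knockout)) ", shuttle knocked out" else "", "): ",
      nrow(x$points), " grid points\n", sep = "")
  print(utils::head(x$points, 12L))
  if (nrow(x$points) > 12L) cat("...\n")
  invisible(x)
}

#' Replicate ensemble at one environment: bistability detection
#'
#' Runs the spatial model `replicates` times at a single `(k, c)` and
#' counts the absorbing outcomes. The dynamics is called bistable when both
#' full takeover (`phi_f = 1`) and tissue recovery (`phi_f = 0`) occur
#' among the replicates — the fluctuation-driven coexistence that the
#' homogeneous model cannot show.
#'
#' @param k,c_blood environment (non-dimensional).
#' @param p a `model_params` object.
#' @param N lattice side.
#' @param replicates number of runs (`>= 2`).
#' @param seed0 base seed (runs use `derive_seed(seed0, 1, 1, rep)`).
#' @param ... further arguments to [run_simulation()].
#' @return a list of class `bistability_scan`: outcome `counts`
#'   (takeover / healthy / other), `bistable` flag, mean `phi_f`, and the
#'   per-run data frame.
#' @export
bistability_scan <- function(k, c_blood, p, N = 20, replicates = 20,
                             seed0 = 1L, ...) {
  stopifnot(replicates >= 2)
  sw <- phase_sweep_spatial(k, c_blood, p, N = N, replicates = replicates,
                            seed0 = seed0, ...)
  runs <- sw$runs
  counts <- c(takeover = sum(runs$outcome == "takeover"),
              healthy = sum(runs$outcome == "healthy"),
              other = sum(!(runs$outcome %in% c("takeover", "healthy"))))
  structure(list(k = k, c = c_blood, counts = counts,
                 bistable = counts[["takeover"]] > 0L && counts[["healthy"]] > 0L,
                 mean_phi_f = mean(runs$phi_f, na.rm = TRUE),
                 runs = runs, N = N, seed0 = seed0,
                 knockout = p$knockout),
            class = "bistability_scan")
}

#' @export
print.bistability_scan <- function(x, ...) {
  cat("bistability_scan at k = ", signif(x$k, 4), ", c = ", signif(x$c, 4),
      " (", x$N, "x", x$N, if (isTRUE(x$knockout)) ", knockout" else "",
      ")\n", sep = "")
  print(x$counts)
  cat(if (x$bistable) "bistable: both absorbing outcomes observed\n"
      else "not bistable in this ensemble\n")
  cat("mean phi_f = ", signif(x$mean_phi_f, 4), "\n", sep = "")
  invisible(x)
}

#' Locate the discontinuous takeover edge of the mean-field model
#'
#' Scans `c` at fixed `k` and returns the midpoint of the first
#' adjacent-point jump of `phi_f` larger than `jump_threshold` (the
#' discontinuous transition from a fully aberrant to a healthy tissue).
#' Used to quantify the shuttle-knockout shift of the edge.
#'
#' @param k fixed turn-over rate.
#' @param c_values scan grid in `c` (ascending).
#' @param p a `model_params` object.
#' @param ... passed to [phase_sweep_meanfield()].
#' @inheritParams phase_sweep_meanfield
#' @return a list `(edge_c, delta_phi, sweep)`; `edge_c` is `NA` when no
#'   jump is found.
#' @export
meanfield_edge <- function(k, c_values, p, jump_threshold = 0.5, ...) {
  sw <- phase_sweep_meanfield(k, c_values, p, jump_threshold = jump_threshold,
                              ...)
  b <- sw$boundary
  if (nrow(b) == 0L) return(list(edge_c = NA_real_, delta_phi = NA_real_,
                                 sweep = sw))
  list(edge_c = (b$c_lo[1L] + b$c_hi[1L]) / 2, delta_phi = b$delta_phi[1L],
       sweep = sw)
}
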