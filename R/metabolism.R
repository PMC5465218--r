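#' Michaelis-Menten uptake kinetics
#'
#' `vmax * x / (K + x)`: monotone increasing in `x`, bounded by `vmax`,
#' half-saturated at `x = K`. Vectorized over `x`.
#'
#' @param x substrate concentration(s), `>= 0`.
#' @param vmax maximal uptake flux.
#' @param K Michaelis constant.
#' @return uptake flux(es), same length as `x`.
#' @export
mm_uptake <- function(x, vmax, K) {
  if (any(x < 0)) stop("negative concentration in mm_uptake", call. = FALSE)
  if (vmax <= 0 || K <= 0) stop("vmax and K must be positive", call. = FALSE)
  vmax * x / (K + x)
}

# slope d/dx of mm_uptake, used by the Newton field solver
mm_slope <- function(x, vmax, K) vmax * K / (K + x)^2

#' Optimal flux pattern of a healthy cell
#'
#' Healthy cells target the fixed maintenance energy output `e_m`, using the
#' primary nutrient preferentially. Their S uptake is
#' `u = min(u_MM(s), u_m)` with `u_m = e_m/(Y_u + Y_r)` the smallest uptake
#' meeting `e_m` without recycling. When `u_MM(s) < u_m` they cover the
#' energy deficit by importing waste at
#' `v = min(v_MM(w), (u_m - u)(1 + Y_u/Y_r))` — either as much W as locally
#' available or the minimal amount that restores `e = e_m`. The respired
#' flux is `r = u + v` and the energy output `e = Y_u*u + Y_r*r`, which for
#' healthy cells never exceeds `e_m`.
#'
#' Under a shuttle knockout (`p$knockout`) the recycling flux is forced to
#' zero.
#'
#' All inputs are vectorized elementwise; the computation is stateless (no
#' cross-cell coupling).
#'
#' @param s,w local S and W concentrations (`>= 0`; recycled to a common
#'   length).
#' @param p a `model_params` object.
#' @return a list of class `cell_fluxes` with numeric components `u`
#'   (S uptake), `v` (W uptake, `>= 0`), `r = u + v`, and `e` (energy
#'   output).
#' @export
healthy_fluxes <- function(s, w, p) {
  if (any(s < 0) || any(w < 0))
    stop("negative concentration in healthy_fluxes", call. = FALSE)
  u <- pmin(mm_uptake(s, p$u_max, p$K_s), p$u_m)
  if (p$knockout) {
    v <- 0 * (u + w)  # zeros, recycled to the common shape
  } else {
    need <- (p$u_m - u) * (1 + p$Y_u / p$Y_r)
    v <- pmin(mm_uptake(w, p$v_max, p$K_w), need)
    # Eq-3 min can only go negative through floating noise at the u = u_m
    # branch point; clamp defensively
    v <- pmax(v, 0)
  }
  r <- u + v
  structure(list(u = u, v = v, r = r, e = p$Y_u * u + p$Y_r * r),
            class = "cell_fluxes")
}

#' Optimal flux pattern of an aberrant cell
#'
#' Aberrant cells maximize energy output with dysregulated uptake
#' `u = alpha_ab * u_MM(s)`. The respired flux is capped at `r_max`; any
#' excess precursor is secreted as waste, `v = min(0, r_max - u) <= 0`, so
#' `r = u + v = min(u, r_max)` and `e = Y_u*u + Y_r*r`. Secretion (`v < 0`)
#' occurs exactly when `s` exceeds the secretion threshold `s_sec` (see
#' [substrate_thresholds()]).
#'
#' @param s local S concentration(s), `>= 0`.
#' @param p a `model_params` object.
#' @return a `cell_fluxes` list (`v <= 0` here; waste flux out of the cell).
#' @export
aberrant_fluxes <- function(s, p) {
  if (any(s < 0)) stop("negative concentration in aberrant_fluxes", call. = FALSE)
  u <- p$alpha_ab * mm_uptake(s, p$u_max, p$K_s)
  v <- pmin(0, p$r_max - u)
  r <- u + v
  structure(list(u = u, v = v, r = r, e = p$Y_u * u + p$Y_r * r),
            class = "cell_fluxes")
}

#' Replication rate of an aberrant cell
#'
#' Zero unless the cell's energy output exceeds the maintenance flux `e_m`;
#' above it the rate rises in Monod fashion with the energy surplus
#' (half-saturation `K_E`) and is inhibited by local waste through the
#' factor `K_inh / (K_inh + w)`:
#' `lambda = lambda_max * max(e - e_m, 0)/(max(e - e_m, 0) + K_E) * K_inh/(K_inh + w)`.
#'
#' @param e energy output flux(es), `>= 0`.
#' @param w local W concentration(s), `>= 0`.
#' @param p a `model_params` object.
#' @return replication rate(s) in `[0, lambda_max)`.
#' @export
replication_rate <- function(e, w, p) {
  if (any(e < 0) || any(w < 0))
    stop("negative argument in replication_rate", call. = FALSE)
  de <- pmax(e - p$e_m, 0)
  p$lambda_max * de / (de + p$K_E) * p$K_inh / (p$K_inh + w)
}

#' Death rate of an aberrant cell
#'
#' Waste toxicity: `sigma = sigma_max * w / (K_tox + w)`, increasing in `w`
#' and saturating at `sigma_max`.
#'
#' @param w local W concentration(s), `>= 0`.
#' @param p a `model_params` object.
#' @return death rate(s) in `[0, sigma_max)`.
#' @export
death_rate <- function(w, p) {
  if (any(w < 0)) stop("negative concentration in death_rate", call. = FALSE)
  p$sigma_max * w / (p$K_tox + w)
}
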