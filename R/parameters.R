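#' Model parameter sets
#'
#' All kinetic, yield and toxicity constants of the tissue model, together
#' with the environmental parameters `k` (blood-tissue turn-over rate) and
#' `c` (blood concentration of the primary nutrient S), live in a single
#' `model_params` object. Every other function in the package consumes only
#' this object, so a mixed-units computation is impossible by construction.
#'
#' Two unit systems are supported and tracked through the `units` field:
#'
#' * `"dimensional"`: concentrations in mM, time in days, per-cell fluxes in
#'   pmol/day per cell volume h^3 (h ~ 0.01 mm, see
#'   [cell_spacing_from_density()]).
#' * `"nondimensional"`: concentrations in units of `K_tox`, time in units of
#'   `1/sigma_max`, fluxes in units of `K_tox * sigma_max` (so `K_tox = 1`
#'   and `sigma_max = 1` after conversion).
#'
#' @param Y_u,Y_r dimensionless ATP yields of the S -> P + E and P -> E steps;
#'   `Y_u < Y_r` is required (fermentation yields less than respiration).
#' @param e_m maintenance energy output flux of healthy cells.
#' @param u_max,K_s Michaelis-Menten parameters of healthy S uptake.
#' @param v_max,K_w Michaelis-Menten parameters of W uptake (recycling).
#' @param alpha_ab dimensionless uptake dysregulation factor of aberrant
#'   cells (their S uptake is `alpha_ab * u_MM(s)`).
#' @param r_max cap on the P -> E (respiration-like) flux.
#' @param lambda_max,K_E,K_inh replication-rate parameters: maximal rate,
#'   energy half-saturation, waste inhibition constant.
#' @param sigma_max,K_tox death-rate parameters: maximal rate and waste
#'   toxicity half-saturation.
#' @param D_S,D_W effective lattice diffusion constants (1/time; the
#'   continuum coefficient already divided by the squared cell spacing and
#'   combined with the lattice stencil, so the lattice operator needs no
#'   further geometry input).
#' @param d lattice coordination number (4 for the square lattice).
#' @param k blood-tissue turn-over rate (1/time), `k = 1/tau`; may be `NA`
#'   until an experiment sets it.
#' @param c_blood blood concentration of S; may be `NA` until set.
#' @param knockout logical; `TRUE` disables the waste shuttle by forcing the
#'   healthy waste-uptake flux `v_he = 0` (see [shuttle_knockout()]).
#' @param units `"dimensional"` or `"nondimensional"`.
#'
#' @return An object of class `model_params`: a named list of the above plus
#'   the derived maintenance uptake `u_m = e_m / (Y_u + Y_r)`, the smallest S
#'   uptake at which a healthy cell meets `e_m` without recycling waste.
#' @seealso [default_dimensional_params()], [default_nondim_params()],
#'   [nondimensionalize()]
#' @export
model_params <- function(Y_u, Y_r, e_m, u_max, K_s, v_max, K_w, alpha_ab,
                         r_max, lambda_max, K_E, K_inh, sigma_max, K_tox,
                         D_S, D_W, d = 4L, k = NA_real_, c_blood = NA_real_,
                         knockout = FALSE,
                         units = c("dimensional", "nondimensional")) {
  units <- match.arg(units)
  p <- list(
    Y_u = Y_u, Y_r = Y_r, e_m = e_m, u_max = u_max, K_s = K_s,
    v_max = v_max, K_w = K_w, alpha_ab = alpha_ab, r_max = r_max,
    lambda_max = lambda_max, K_E = K_E, K_inh = K_inh,
    sigma_max = sigma_max, K_tox = K_tox, D_S = D_S, D_W = D_W,
    d = as.integer(d), k = as.numeric(k), c = as.numeric(c_blood),
    u_m = e_m / (Y_u + Y_r),
    knockout = isTRUE(knockout), units = units
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set and stops with a message
#' naming the violated invariant. Called by all constructors; exported so
#' configuration files can be validated after editing.
#'
#' @param p a `model_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  pos <- c("Y_u", "Y_r", "e_m", "u_max", "K_s", "v_max", "K_w", "alpha_ab",
           "r_max", "lambda_max", "K_E", "K_inh", "sigma_max", "K_tox",
           "D_S", "D_W")
  for (nm in pos) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("invalid parameter set: '", nm, "' must be a strictly positive scalar",
           call. = FALSE)
  }
  for (nm in c("k", "c")) {
    val <- p[[nm]]
    if (!is.na(val) && (!is.finite(val) || val < 0))
      stop("invalid parameter set: '", nm, "' must be >= 0 (or NA if unset)",
           call. = FALSE)
  }
  if (!(p$d %in% c(1L, 2L, 3L, 4L)))
    stop("invalid parameter set: coordination number 'd' must be in 1..4",
         call. = FALSE)
  if (p$Y_u >= p$Y_r)
    stop("invalid parameter set: requires Y_u < Y_r ",
         "(yield of direct oxidation below yield of full respiration)",
         call. = FALSE)
  if (abs(p$u_m - p$e_m / (p$Y_u + p$Y_r)) > 1e-12 * p$u_m)
    stop("invalid parameter set: u_m must equal e_m/(Y_u + Y_r)", call. = FALSE)
  if (p$u_m > p$r_max)
    stop("invalid parameter set: requires u_m <= r_max ",
         "(maintenance uptake must fit under the respiration cap)",
         call. = FALSE)
  if (p$u_m >= p$u_max)
    stop("invalid parameter set: requires u_m < u_max ",
         "(healthy cells must be able to reach maintenance uptake)",
         call. = FALSE)
  if (p$u_m >= p$alpha_ab * p$u_max)
    stop("invalid parameter set: requires u_m < alpha_ab * u_max", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tissue metabolism parameter set (", x$units, " units",
      if (x$knockout) ", shuttle knocked out" else "", ")\n", sep = "")
  num <- vapply(x[!(names(x) %in% c("units", "knockout", "d"))], identity,
                numeric(1))
  print(signif(num, 6))
  cat("d =", x$d, "\n")
  invisible(x)
}

#' The dimensional parameter set
#'
#' The glucose-lactate calibration of the model: ATP yields from a coarse
#' glycolysis/respiration split, uptake kinetics from GLUT1-like transport
#' (with glucose-to-lactate stoichiometry folded into `K_s`, `u_max`),
#' lactate recycling via MCT-like transport, growth inhibition and toxicity
#' from in vitro lactate data, and a respiration cap from proteome/
#' mitochondrial limits. Units: mM, day, pmol/day per cell volume.
#'
#' `D_S = D_W` are effective lattice constants; the literature value
#' 0.06 per second is stored converted to per day. The environment `(k, c)`
#' is left unset: experiments must supply it.
#'
#' @param k turn-over rate in 1/day (optional).
#' @param c_blood blood S concentration in mM (optional).
#' @return A `model_params` object in dimensional units.
#' @examples
#' p <- default_dimensional_params()
#' p$u_m  # 0.5 pmol/day/cell: e_m / (Y_u + Y_r) = 10 / 20
#' @export
default_dimensional_params <- function(k = NA_real_, c_blood = NA_real_) {
  model_params(
    Y_u = 1, Y_r = 19,
    e_m = 10,              # pmol ATP/day per cell volume
    u_max = 1, K_s = 2,    # glucose uptake, stoichiometry-rescaled
    v_max = 100, K_w = 5,  # lactate uptake
    alpha_ab = 100,
    r_max = 6.48,          # respiration cap, pmol/day/cell
    lambda_max = 2, K_E = 20, K_inh = 8,
    sigma_max = 2, K_tox = 15,
    D_S = 0.06 * 86400, D_W = 0.06 * 86400,  # 0.06 / sec in 1 / day
    d = 4L, k = k, c_blood = c_blood,
    units = "dimensional"
  )
}

#' Flux-unit conversion for non-dimensionalization
#'
#' The model's per-cell fluxes are in pmol/day per cell volume; the lattice
#' fields are concentrations (mM). Converting one into the other requires a
#' volume scale, fixed by the cell geometry: with cell spacing h = 0.01 mm
#' (areal density 1e4 cells/mm^2), one pmol per cell volume h^3 is
#' 1e-12 mol / 1e-12 L = 1 mol/L = 1000 mM, so 1 pmol/day/h^3 = 1000 mM/day.
#' This is the package default; the methods vignette discusses how the
#' choice positions the phase portrait's features in the `(k, c)` plane.
#'
#' @return a positive scalar (mM per (pmol/day/h^3), times day).
#' @export
flux_conversion_geometric <- function() 1000

#' Non-dimensionalize a parameter set
#'
#' Rescales a dimensional parameter set into the model's natural units:
#' concentrations in units of `K_tox`, time in units of `1/sigma_max`,
#' fluxes in units of `K_tox * sigma_max`. In the output `K_tox = 1` and
#' `sigma_max = 1`. Dimensionless ratios (`Y_u/Y_r`, `alpha_ab`,
#' `K_inh/K_tox`, `lambda_max/sigma_max`, `u_m/r_max`) are unchanged.
#'
#' Applying the function to an already non-dimensional set with
#' `flux_conversion = 1` is the identity.
#'
#' @param p a valid `model_params` object.
#' @param flux_conversion positive scalar converting per-cell flux units
#'   into concentration-per-time units before the `K_tox * sigma_max`
#'   rescaling; see [flux_conversion_geometric()].
#' @return a `model_params` object with `units = "nondimensional"`.
#' @export
nondimensionalize <- function(p, flux_conversion = flux_conversion_geometric()) {
  validate_params(p)
  if (!is.numeric(flux_conversion) || length(flux_conversion) != 1L ||
      !is.finite(flux_conversion) || flux_conversion <= 0)
    stop("'flux_conversion' must be a positive scalar", call. = FALSE)
  conc <- p$K_tox
  rate <- p$sigma_max
  flux <- flux_conversion / (conc * rate)
  model_params(
    Y_u = p$Y_u, Y_r = p$Y_r,
    e_m = p$e_m * flux,
    u_max = p$u_max * flux, K_s = p$K_s / conc,
    v_max = p$v_max * flux, K_w = p$K_w / conc,
    alpha_ab = p$alpha_ab,
    r_max = p$r_max * flux,
    lambda_max = p$lambda_max / rate,
    K_E = p$K_E * flux,
    K_inh = p$K_inh / conc,
    sigma_max = 1, K_tox = 1,
    D_S = p$D_S / rate, D_W = p$D_W / rate,
    d = p$d,
    k = p$k / rate, c_blood = p$c / conc,
    knockout = p$knockout,
    units = "nondimensional"
  )
}

#' The non-dimensional parameter set used by the experiments
#'
#' [default_dimensional_params()] rescaled by [nondimensionalize()] with the
#' calibrated flux conversion, with the environment `(k, c)` given directly
#' in non-dimensional units (time in `1/sigma_max`, concentration in
#' `K_tox`), matching the axes of the phase portraits.
#'
#' @param k non-dimensional turn-over rate.
#' @param c_blood non-dimensional blood nutrient level.
#' @param flux_conversion see [nondimensionalize()].
#' @return a `model_params` object with `units = "nondimensional"`.
#' @examples
#' p <- default_nondim_params(k = 1000, c_blood = 0.1)
#' p$K_tox      # 1 by construction
#' p$lambda_max # 1: lambda_max / sigma_max = 2 / 2
#' @export
default_nondim_params <- function(k = NA_real_, c_blood = NA_real_,
                                  flux_conversion = flux_conversion_geometric()) {
  p <- nondimensionalize(default_dimensional_params(), flux_conversion)
  p$k <- as.numeric(k)
  p$c <- as.numeric(c_blood)
  validate_params(p)
  p
}

#' Set the environmental parameters of an existing set
#'
#' @param p a `model_params` object.
#' @param k,c_blood turn-over rate and blood nutrient level, in `p`'s units.
#' @return the updated `model_params` object.
#' @export
with_environment <- function(p, k, c_blood) {
  validate_params(p)
  p$k <- as.numeric(k)
  p$c <- as.numeric(c_blood)
  validate_params(p)
  p
}

#' Disable the waste shuttle
#'
#' Returns a parameter variant in which healthy cells never import waste
#' (`v_he = 0`, equivalent to `v_max = 0`); aberrant secretion and all other
#' behavior are unchanged. The flag is carried into every simulation output.
#'
#' @param p a `model_params` object.
#' @return `p` with `knockout = TRUE`.
#' @export
shuttle_knockout <- function(p) {
  validate_params(p)
  p$knockout <- TRUE
  p
}

#' Cell spacing implied by an areal cell density
#'
#' Flat-tissue packing at `density` cells per mm^2 puts cells a distance
#' `1/sqrt(density)` apart; the model's reference density of 1e4 cells/mm^2
#' gives h = 0.01 mm.
#'
#' @param density_per_mm2 areal cell density (cells per mm^2).
#' @return cell spacing h in mm.
#' @export
cell_spacing_from_density <- function(density_per_mm2) {
  if (any(density_per_mm2 <= 0)) stop("density must be positive", call. = FALSE)
  1 / sqrt(density_per_mm2)
}

#' Read and write parameter files
#'
#' Plain `key = value` configuration files (one scalar per line, `#`
#' comments allowed). Values round-trip at full double precision; the set is
#' validated on read with errors naming the violated invariant.
#'
#' @param p a `model_params` object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   validated `model_params` object.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  num <- names(p)[vapply(p, is.numeric, logical(1))]
  lines <- c(
    "# warburgsim parameter file",
    sprintf("units = %s", p$units),
    sprintf("knockout = %s", if (p$knockout) "true" else "false"),
    sprintf("%s = %.17g", num, vapply(p[num], as.numeric, numeric(1)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed parameter line: ", lines[bad][1L], call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  if (anyDuplicated(keys))
    stop("duplicate parameter key: ", keys[duplicated(keys)][1L], call. = FALSE)
  val_of <- function(key, default = NULL) {
    if (key %in% keys) vals[match(key, keys)] else default
  }
  need <- function(key) {
    v <- val_of(key)
    if (is.null(v)) stop("missing parameter: '", key, "'", call. = FALSE)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x) && !identical(tolower(v), "na"))
      stop("parameter '", key, "' is not numeric: ", v, call. = FALSE)
    x
  }
  model_params(
    Y_u = need("Y_u"), Y_r = need("Y_r"), e_m = need("e_m"),
    u_max = need("u_max"), K_s = need("K_s"),
    v_max = need("v_max"), K_w = need("K_w"),
    alpha_ab = need("alpha_ab"), r_max = need("r_max"),
    lambda_max = need("lambda_max"), K_E = need("K_E"),
    K_inh = need("K_inh"), sigma_max = need("sigma_max"),
    K_tox = need("K_tox"), D_S = need("D_S"), D_W = need("D_W"),
    d = as.integer(need("d")),
    k = need("k"), c_blood = need("c"),
    knockout = identical(tolower(val_of("knockout", "false")), "true"),
    units = val_of("units", "dimensional")
  )
}
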