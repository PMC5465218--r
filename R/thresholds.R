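#' Substrate thresholds of the tissue model
#'
#' Three critical levels of the tissue nutrient concentration `s` organize
#' the model's behavior:
#'
#' * `s_m = K_s * u_m / (u_max - u_m)`: below it, healthy cells cannot meet
#'   their maintenance energy from S alone and must recycle waste.
#' * `s_sec = K_s * r_max / (alpha_ab * u_max - r_max)`: above it, aberrant
#'   uptake exceeds the respiration cap and waste is secreted.
#' * `s_gr = K_s * u_m / (alpha_ab * u_max - u_m)`: above it, aberrant cells
#'   clear their maintenance energy and can replicate.
#'
#' With `u_m <= r_max` the ordering `s_gr <= s_sec <= s_m` holds, and the
#' window `s_sec < s < s_m` is where aberrant secretion and healthy
#' recycling coexist (the waste shuttle).
#'
#' @param p a `model_params` object (any unit system; outputs are in the
#'   same units).
#' @return a named list `(s_m, s_sec, s_gr)`.
#' @export
substrate_thresholds <- function(p) {
  validate_params(p)
  if (p$alpha_ab * p$u_max <= p$r_max)
    stop("thresholds undefined: requires alpha_ab * u_max > r_max", call. = FALSE)
  list(
    s_m   = p$K_s * p$u_m   / (p$u_max - p$u_m),
    s_sec = p$K_s * p$r_max / (p$alpha_ab * p$u_max - p$r_max),
    s_gr  = p$K_s * p$u_m   / (p$alpha_ab * p$u_max - p$u_m)
  )
}

#' Aberrant-fraction thresholds
#'
#' The duals of [substrate_thresholds()]: for each substrate threshold, the
#' aberrant fraction `phi` whose quasi-steady-state nutrient level equals
#' it. With `m = min(r_max, alpha_ab * u_m)`:
#'
#' * `phi_m  = (k (c - s_m) - u_m) / ((alpha_ab - 1) u_m)`
#' * `phi_sec = (alpha_ab k (c - s_sec) - m) / (alpha_ab r_max - m)`
#' * `phi_gr  = (alpha_ab k (c - s_gr) - u_m) / ((alpha_ab - 1) u_m)`
#'
#' Healthy cells need recycling once `phi > phi_m`, waste is secreted while
#' `phi < phi_sec`, and aberrant growth stops at `phi >= phi_gr` (so
#' `phi_gr` bounds the achievable aberrant fraction). Values may be negative
#' or exceed 1; that is meaningful (e.g. `phi_sec <= 0` marks the phase in
#' which waste is never secreted).
#'
#' @param p a `model_params` object with `k` and `c` set.
#' @return a named list `(phi_m, phi_sec, phi_gr)`.
#' @export
fraction_thresholds <- function(p) {
  s <- substrate_thresholds(p)
  if (is.na(p$k) || is.na(p$c))
    stop("fraction thresholds need the environment (k, c) set", call. = FALSE)
  m <- min(p$r_max, p$alpha_ab * p$u_m)
  list(
    phi_m   = (p$k * (p$c - s$s_m) - p$u_m) / ((p$alpha_ab - 1) * p$u_m),
    phi_sec = (p$alpha_ab * p$k * (p$c - s$s_sec) - m) /
              (p$alpha_ab * p$r_max - m),
    phi_gr  = (p$alpha_ab * p$k * (p$c - s$s_gr) - p$u_m) /
              ((p$alpha_ab - 1) * p$u_m)
  )
}

#' Classify the phase region of an environment
#'
#' Compares the asymptotic aberrant fraction `phi_f` of the homogeneous
#' model with the fraction thresholds:
#'
#' * Region I (`phi_f <= phi_m`): healthy cells never needed recycling;
#'   sustained secretion; growth limited by toxicity. Coarse label `W+`.
#' * Region II (`phi_m < phi_f < phi_sec`): a waste shuttle kicks in and is
#'   sustained. Coarse label `Sh.`
#' * Region III (`phi_f >= phi_sec`): secretion is not sustained; growth
#'   limited by nutrient, `phi_f = min(1, phi_gr)`. Subdivided into IIIa
#'   (`phi_sec > 0`, transient secretion; coarse `Sh.`) and IIIb
#'   (`phi_sec <= 0`, waste never secreted; coarse `W-`).
#'
#' @param p a `model_params` object with `k`, `c` set.
#' @param phi_f asymptotic aberrant fraction, normally from
#'   [asymptotic_fraction()]; if missing it is computed internally with that
#'   function's defaults.
#' @param ... passed to [asymptotic_fraction()] when `phi_f` is missing.
#' @return a list of class `region_label`: `fine` in
#'   `c("I", "II", "IIIa", "IIIb")`, `coarse` in `c("W+", "Sh.", "W-")`,
#'   plus `phi_f` and the thresholds used.
#' @export
classify_region <- function(p, phi_f = NULL, ...) {
  th <- fraction_thresholds(p)
  if (is.null(phi_f)) phi_f <- asymptotic_fraction(p, ...)$phi_f
  fine <-
    if (phi_f <= th$phi_m) "I"
    else if (phi_f < th$phi_sec) "II"
    else if (th$phi_sec > 0) "IIIa"
    else "IIIb"
  coarse <- c(I = "W+", II = "Sh.", IIIa = "Sh.", IIIb = "W-")[[fine]]
  structure(list(fine = fine, coarse = coarse, phi_f = phi_f, thresholds = th),
            class = "region_label")
}

#' @export
print.region_label <- function(x, ...) {
  cat("Region ", x$fine, " (", x$coarse, "), phi_f = ",
      signif(x$phi_f, 4), "\n", sep = "")
  cat("thresholds: phi_m = ", signif(x$thresholds$phi_m, 4),
      ", phi_sec = ", signif(x$thresholds$phi_sec, 4),
      ", phi_gr = ", signif(x$thresholds$phi_gr, 4), "\n", sep = "")
  invisible(x)
}
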