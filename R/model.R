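#' Water-stress function f(H)
#'
#' Piecewise-linear gate in `[0, 1]` applied to vascular growth, evaporation
#' and transpiration: `f = (H - z - h2) / (h1 - h2)`, clamped to 0 where the
#' water table is at or below the root depth (`H <= h2 + z`) and to 1 where
#' it is at or above the stress threshold (`H >= h1 + z`). Continuous in `H`;
#' the kinks use closed intervals (exact equality yields the clamped value).
#'
#' @param H hydraulic-head field (matrix or numeric), metres.
#' @param params [peat_params()].
#' @return dimensionless field in `[0, 1]`, same shape as `H`.
#' @export
#' @examples
#' water_stress(c(0.5, 0.75, 1.0), peat_params()) # 0, 0.5, 1
water_stress <- function(H, params) {
  if (params$h1 == params$h2)
    peat_stop("h1 == h2: water-stress ramp undefined", "peat_invalid_parameter")
  if (!all(is.finite(H)))
    peat_stop("H contains non-finite values", "peat_validation_error")
  f <- (H - params$z - params$h2) / (params$h1 - params$h2)
  pmin(pmax(f, 0), 1)
}

#' Nutrient concentration from availability
#'
#' Converts the areal nutrient stock `N` (g_N m^-2) to the pore-water
#' concentration `N_c` (g_N m^-3) via `N = N_c * H * theta`.
#'
#' @param N nutrient-availability field, g_N m^-2.
#' @param H hydraulic-head field, m (strictly positive).
#' @param params [peat_params()].
#' @return concentration field, g_N m^-3.
#' @export
nutrient_concentration <- function(N, H, params) {
  if (any(!is.finite(H)) || any(H <= 0))
    peat_stop("H must be finite and > 0 everywhere", "peat_domain_error")
  N / (H * params$theta)
}

#' Local (reaction) tendencies of the four fields
#'
#' Evaluates the diffusion- and advection-free part of the model pointwise:
#' vascular growth gated by nutrient concentration and water stress, losses
#' and Sphagnum competition; Sphagnum logistic growth and vascular
#' competition; the local water balance (precipitation, evaporation,
#' transpiration, all over the porosity); and the nutrient budget (input,
#' uptake, death recycling, loss).
#'
#' @param state [field_state()].
#' @param params [peat_params()].
#' @param forcing optional list with effective climate values `p`, `e`, `t_v`
#'   (already scaled by any evapotranspiration factor); defaults to the
#'   values in `params`.
#' @return list of class `peat_tendencies` with `dB_dt`, `dS_dt`, `dH_dt`,
#'   `dN_dt` (field units per year).
#' @export
reaction_terms <- function(state, params, forcing = NULL) {
  validate_state(state)
  forcing <- modifyList(list(p = params$p, e = params$e, t_v = params$t_v),
                        forcing %||% list())
  if (any(unlist(forcing) < 0))
    peat_stop("forcing values must be >= 0", "peat_validation_error")
  B <- state$B; S <- state$S; H <- state$H; N <- state$N
  f <- water_stress(H, params)
  Nc <- nutrient_concentration(N, H, params)
  dB <- params$r_B * Nc * B * f - (params$d + params$b) * B -
    params$c_BS * S - params$k_BS * S * B / (params$H_B + B)
  dS <- params$r_S * S * (1 - S / params$S_max) -
    params$k_SB * S * B / (params$H_S + S)
  dH <- (forcing$p - forcing$e * f - forcing$t_v * f * B) / params$theta
  dN <- params$N_in - params$u * Nc * B * f +
    (params$d * params$u / params$g_conv) * B - params$r * N
  structure(list(dB_dt = dB, dS_dt = dS, dH_dt = dH, dN_dt = dN),
            class = c("peat_tendencies", "list"))
}
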