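#' Model parameters
#'
#' Builds the full parameter set of the peatland reaction-diffusion model.
#' Defaults are the published mean-annual values for a boreal ombrotrophic
#' bog; units are metres, years and grams (`g_B`, `g_S`, `g_N` denote grams
#' of vascular biomass, Sphagnum biomass and nutrient, respectively).
#'
#' Parameters (defaults in parentheses):
#' \describe{
#'   \item{r_B (0.2)}{vascular growth parameter, m^3 g_N^-1 yr^-1}
#'   \item{d (0.1), b (0.2)}{vascular recycling and other-loss rates, yr^-1}
#'   \item{D_B (2)}{vascular biomass diffusion, m^2 yr^-1}
#'   \item{c_BS (0.1), k_BS (0.5)}{Sphagnum inhibition / feedback on vascular
#'     plants, g_B g_S^-1 yr^-1}
#'   \item{H_B (800)}{half-saturation density for vascular plants, g_B m^-2}
#'   \item{r_S (0.2), S_max (800)}{Sphagnum logistic growth rate (yr^-1) and
#'     carrying capacity (g_S m^-2)}
#'   \item{k_SB (0.1), H_S (300)}{vascular feedback on Sphagnum
#'     (g_S g_B^-1 yr^-1) and its half-saturation (g_S m^-2)}
#'   \item{D_S (0.2)}{Sphagnum diffusion, m^2 yr^-1}
#'   \item{p (0.5), e (0.3), t_v (0.005)}{precipitation (m yr^-1), evaporation
#'     parameter (m yr^-1) and transpiration parameter (m^3 g_B^-1 yr^-1) —
#'     the three climate-linked parameters}
#'   \item{k (500)}{hydraulic conductivity, m yr^-1}
#'   \item{theta (0.7)}{soil porosity, dimensionless}
#'   \item{N_in (2.5)}{external nutrient input, g_N m^-2 yr^-1 (control
#'     parameter, studied over 0-5)}
#'   \item{u (0.002), r (0.1)}{nutrient uptake (m^3 g_B^-1 yr^-1) and loss
#'     (yr^-1) parameters}
#'   \item{D_N (10)}{nutrient diffusion, m^2 yr^-1}
#'   \item{h1 (0), h2 (-0.5), z (1)}{water-stress thresholds: pressure head
#'     below which stress occurs, root depth, elevation head (m)}
#'   \item{g_conv (= r_B)}{conversion factor in the death-recycling nutrient
#'     flux (d*u/g_conv)*B, m^3 g_N^-1 yr^-1; not tabulated in the source
#'     model, defaulting to the growth parameter so the recycled flux is the
#'     per-biomass nutrient content u/g_conv times the death rate d}
#' }
#'
#' @param ... named overrides of any default, e.g. `peat_params(N_in = 1.375)`.
#' @return A named list of class `peat_params`.
#' @export
#' @examples
#' p <- peat_params(N_in = 2.5)
#' p$r_B
peat_params <- function(...) {
  defaults <- list(
    r_B = 0.2, d = 0.1, b = 0.2, D_B = 2, c_BS = 0.1, k_BS = 0.5, H_B = 800,
    r_S = 0.2, S_max = 800, k_SB = 0.1, H_S = 300, D_S = 0.2,
    p = 0.5, t_v = 0.005, e = 0.3, k = 500, theta = 0.7,
    N_in = 2.5, u = 0.002, r = 0.1, D_N = 10,
    h1 = 0, h2 = -0.5, z = 1, g_conv = NULL)
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    peat_stop("parameter overrides must be named", "peat_invalid_parameter")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    peat_stop(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")),
              "peat_invalid_parameter")
  pars <- modifyList(defaults, over)
  if (is.null(pars$g_conv)) pars$g_conv <- pars$r_B
  class(pars) <- c("peat_params", "list")
  validate_params(pars)
  pars
}

validate_params <- function(pars) {
  num <- vapply(pars, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    peat_stop("all parameters must be finite scalars", "peat_invalid_parameter")
  nonneg <- c("r_B", "d", "b", "D_B", "c_BS", "k_BS", "r_S", "k_SB", "D_S",
              "p", "t_v", "e", "k", "N_in", "u", "r", "D_N")
  bad <- nonneg[vapply(nonneg, function(nm) pars[[nm]] < 0, logical(1))]
  if (length(bad) > 0)
    peat_stop(paste0("parameter(s) must be >= 0: ", paste(bad, collapse = ", ")),
              "peat_invalid_parameter")
  if (!(pars$theta > 0 && pars$theta <= 1))
    peat_stop("theta must satisfy 0 < theta <= 1", "peat_invalid_parameter")
  if (!(pars$h2 < pars$h1))
    peat_stop("h2 must be strictly less than h1 (else the water-stress ramp is degenerate)",
              "peat_invalid_parameter")
  if (pars$S_max <= 0 || pars$H_B <= 0 || pars$H_S <= 0)
    peat_stop("S_max, H_B and H_S must be > 0", "peat_invalid_parameter")
  if (pars$g_conv <= 0)
    peat_stop("g_conv must be > 0", "peat_invalid_parameter")
  invisible(pars)
}

# flatten to the named numeric vector the C++ core consumes
param_vector <- function(pars) {
  unlist(pars[c("r_B", "d", "b", "D_B", "c_BS", "k_BS", "H_B",
                "r_S", "S_max", "k_SB", "H_S", "D_S",
                "p", "t_v", "e", "k", "theta",
                "N_in", "u", "r", "D_N", "h1", "h2", "z", "g_conv")])
}

#' @export
print.peat_params <- function(x, ...) {
  cat("<peat_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 7), " = ", format(v)), sep = "\n")
  invisible(x)
}
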