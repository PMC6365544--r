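#' Random initial state
#'
#' The published initial condition: a random scattering of spots bearing
#' 200 g m^-2 of biomass, vascular plants and Sphagnum each covering 12.5%
#' of the grid cells (disjoint sets, counted exactly, chosen without
#' replacement), over the plantless equilibrium `H = p/e` and `N = N_in/r`.
#' Spots default to single cells; a blob radius is available for robustness
#' studies.
#'
#' @param grid [sim_grid()].
#' @param params [peat_params()].
#' @param seed integer seed (deterministic output).
#' @param spot_biomass biomass per seeded cell, g m^-2.
#' @param cover fraction of cells seeded per species.
#' @param blob_radius radius in cells of each seeded spot (0 = single cell).
#' @return [field_state()] at `time = 0`.
#' @export
random_initial_state <- function(grid, params, seed,
                                 spot_biomass = 200, cover = 0.125,
                                 blob_radius = 0) {
  ncell <- grid$nx * grid$ny
  nspot <- floor(cover * ncell)
  if (2 * nspot > ncell)
    peat_stop("2 x cover exceeds the grid", "peat_validation_error")
  B <- matrix(0, grid$ny, grid$nx)
  S <- matrix(0, grid$ny, grid$nx)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cells <- sample.int(ncell, 2 * nspot)
  B[cells[seq_len(nspot)]] <- spot_biomass
  S[cells[nspot + seq_len(nspot)]] <- spot_biomass
  if (blob_radius > 0) {
    B <- grow_blobs(B, blob_radius, spot_biomass)
    S <- grow_blobs(S, blob_radius, spot_biomass)
    S[B > 0] <- 0 # vascular seeds take precedence where blobs overlap
  }
  H <- matrix(params$p / params$e, grid$ny, grid$nx)
  N <- matrix(params$N_in / params$r, grid$ny, grid$nx)
  field_state(B, S, H, N, time = 0)
}

grow_blobs <- function(f, radius, value) {
  out <- f
  for (s in -radius:radius) for (t in -radius:radius)
    if (s * s + t * t <= radius * radius)
      out <- pmax(out, shift_y(shift_x(f, s), t))
  out
}

#' Synthetic yearly climate scenario
#'
#' Stand-in for a GCM-derived forcing series: independent yearly draws of
#' precipitation (m yr^-1) and of a dimensionless evapotranspiration
#' (Penman-Monteith) factor multiplying the evaporation and transpiration
#' terms of the water balance. Draws are Gaussian about the stated means,
#' truncated at 0 (precipitation) and at a small positive floor (factor);
#' an optional lag-1 autocorrelation is available (default 0 — the source
#' series' statistics are not published, so defaults are declared, not
#' inferred).
#'
#' @param years number of years.
#' @param mean_precip,sd_precip mean and sd of yearly precipitation, m yr^-1
#'   (defaults 0.8 and 0.1, emulating the boreal scenario's 800 mm/yr mean).
#' @param mean_factor,sd_factor mean and sd of the evapotranspiration factor.
#' @param start_year first calendar year of the series.
#' @param ar1 lag-1 autocorrelation of both series.
#' @param seed integer seed.
#' @return list of class `climate_scenario`: `year`, `precip`, `et_factor`.
#' @export
synthetic_climate <- function(years, mean_precip = 0.8, sd_precip = 0.1,
                              mean_factor = 1, sd_factor = 0,
                              start_year = 1, ar1 = 0, seed = 1) {
  if (sd_precip < 0 || sd_factor < 0)
    peat_stop("standard deviations must be >= 0", "peat_invalid_parameter")
  if (abs(ar1) >= 1)
    peat_stop("ar1 must lie in (-1, 1)", "peat_invalid_parameter")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- function(mu, sigma, floor_at) {
    z <- rnorm(years)
    if (ar1 != 0 && years > 1) {
      for (i in 2:years) z[i] <- ar1 * z[i - 1] + sqrt(1 - ar1^2) * z[i]
    }
    pmax(mu + sigma * z, floor_at)
  }
  sc <- list(year = start_year + seq_len(years) - 1,
             precip = draw(mean_precip, sd_precip, 0),
             et_factor = draw(mean_factor, sd_factor, 1e-6))
  class(sc) <- c("climate_scenario", "list")
  sc
}

#' Constant climate scenario
#'
#' @param years number of years.
#' @param precip constant precipitation, m yr^-1.
#' @param et_factor constant evapotranspiration factor.
#' @param start_year first calendar year.
#' @return [synthetic_climate()]-shaped `climate_scenario`.
#' @export
constant_climate <- function(years, precip, et_factor = 1, start_year = 1) {
  synthetic_climate(years, mean_precip = precip, sd_precip = 0,
                    mean_factor = et_factor, sd_factor = 0,
                    start_year = start_year, seed = 0)
}

#' Impose a drought window on a scenario
#'
#' Replaces precipitation by `drought_precip` for `duration` years starting
#' at `start_year`; evapotranspiration factors are untouched.
#'
#' @param scenario [synthetic_climate()] output.
#' @param start_year first calendar year of the drought.
#' @param duration drought length in years (0 = no change).
#' @param drought_precip precipitation during the drought, m yr^-1
#'   (default 0.05, i.e. 50 mm/yr).
#' @return modified `climate_scenario`.
#' @export
drought_override <- function(scenario, start_year, duration,
                             drought_precip = 0.05) {
  if (duration == 0) return(scenario)
  window <- start_year + seq_len(duration) - 1
  idx <- match(window, scenario$year)
  if (any(is.na(idx)))
    peat_stop("drought window extends beyond the scenario", "peat_validation_error")
  scenario$precip[idx] <- drought_precip
  scenario
}

#' Uncorrelated random binary field
#'
#' Independent per-cell occupation with probability `prob` — the classical
#' two-dimensional uncorrelated site-percolation reference system used to
#' validate the cluster machinery.
#'
#' @param grid [sim_grid()] (only `nx`, `ny` used).
#' @param prob occupation probability in `[0, 1]`.
#' @param seed integer seed.
#' @return [binarize()]-shaped `binary_pattern` (threshold slot 0.5 on the
#'   0/1 field).
#' @export
uncorrelated_binary_field <- function(grid, prob, seed) {
  if (prob < 0 || prob > 1)
    peat_stop("prob must lie in [0, 1]", "peat_invalid_parameter")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mask <- matrix(runif(grid$nx * grid$ny) < prob, grid$ny, grid$nx)
  structure(list(mask = mask, threshold = 0.5, species = NULL),
            class = c("binary_pattern", "list"))
}

#' Power-law mean-cluster-area samples
#'
#' Ground truth for the critical-exponent fitter: points on
#' `A = |p - p_c|^(-gamma)` with optional multiplicative lognormal noise.
#'
#' @param gamma exponent (> 0).
#' @param p_c critical filling factor.
#' @param p ladder of filling factors (must exclude `p_c`).
#' @param noise_sd sd of the lognormal noise on log(A) (0 = exact).
#' @param seed integer seed.
#' @return data.frame with columns `p`, `area`.
#' @export
power_law_cluster_samples <- function(gamma, p_c, p, noise_sd = 0, seed = 1) {
  if (gamma <= 0) peat_stop("gamma must be > 0", "peat_invalid_parameter")
  if (any(p == p_c))
    peat_stop("ladder must exclude p_c", "peat_validation_error")
  area <- abs(p - p_c)^(-gamma)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    area <- area * exp(rnorm(length(p), 0, noise_sd))
  }
  data.frame(p = p, area = area)
}

#' Derive per-run seeds from a master seed
#'
#' Counter-based derivation: `seed_i = (master + i * 1000003) mod (2^31 - 1)`
#' — reproducible, independent-stream seeds for sweeps and replicates,
#' recorded in run manifests.
#'
#' @param master master integer seed.
#' @param n number of seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  as.integer((as.numeric(master) + seq_len(n) * 1000003) %% (2^31 - 1))
}
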