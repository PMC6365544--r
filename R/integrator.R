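#' Periodic 5-point Laplacian
#'
#' Second-order centred Laplacian with wrap-around (toroidal) boundaries.
#' The stencil sums to zero over the grid, so pure diffusion is discretely
#' conservative.
#'
#' @param field numeric matrix (rows = y, columns = x).
#' @param dx cell size, m.
#' @return matrix of the same shape.
#' @export
laplacian_periodic <- function(field, dx) {
  if (!is.matrix(field) || nrow(field) < 4 || ncol(field) < 4)
    peat_stop("field must be a matrix of at least 4 x 4", "peat_validation_error")
  if (!all(is.finite(field)))
    peat_stop("field contains non-finite values", "peat_validation_error")
  (shift_x(field, 1) + shift_x(field, -1) +
     shift_y(field, 1) + shift_y(field, -1) - 4 * field) / dx^2
}

# circular shifts: shift_x(f, 1)[y, x] = f[y, x+1 (wrapped)]
shift_x <- function(f, by) {
  nx <- ncol(f)
  f[, ((seq_len(nx) - 1 + by) %% nx) + 1, drop = FALSE]
}
shift_y <- function(f, by) {
  ny <- nrow(f)
  f[((seq_len(ny) - 1 + by) %% ny) + 1, , drop = FALSE]
}

#' Conservative divergence of a coefficient-weighted gradient flux
#'
#' Computes `div(coef * grad(phi))` in face-flux form on the periodic grid:
#' the flux across each cell face is the arithmetic mean of `coef` on the two
#' adjacent cells times the centred difference of `phi`. Face fluxes
#' telescope, so the grid sum of the result vanishes to rounding — this is
#' what makes the Darcy and nutrient-advection terms exactly conservative on
#' the closed torus.
#'
#' @param coef non-negative coefficient field (e.g. `H` for Darcy flow).
#' @param phi transported potential field.
#' @param dx cell size, m.
#' @return matrix of the same shape.
#' @export
div_grad_flux <- function(coef, phi, dx) {
  if (!is.matrix(coef) || !identical(dim(coef), dim(phi)))
    peat_stop("coef and phi must be matrices of one shape", "peat_validation_error")
  if (any(coef < 0))
    peat_stop("coef must be >= 0", "peat_validation_error")
  face <- function(cs, ps) 0.5 * (coef + cs) * (ps - phi)
  (face(shift_x(coef, 1), shift_x(phi, 1)) +
     face(shift_x(coef, -1), shift_x(phi, -1)) +
     face(shift_y(coef, 1), shift_y(phi, 1)) +
     face(shift_y(coef, -1), shift_y(phi, -1))) / dx^2
}

#' Transport tendencies of the four fields
#'
#' The spatial part of the model: biomass diffusion for `B` and `S`, Darcy
#' groundwater flow `div((k/theta) H grad H)` for `H`, and for `N` the
#' head-weighted nutrient diffusion `div(theta D_N H grad N_c)` plus
#' advection with the groundwater flux `div(k H N_c grad H)`. Each term's
#' grid sum vanishes to rounding.
#'
#' @inheritParams reaction_terms
#' @param grid [sim_grid()].
#' @return list of class `peat_tendencies` with the transport contributions.
#' @export
transport_terms <- function(state, params, grid) {
  validate_state(state)
  dx <- grid$dx
  Nc <- nutrient_concentration(state$N, state$H, params)
  structure(list(
    dB_dt = params$D_B * laplacian_periodic(state$B, dx),
    dS_dt = params$D_S * laplacian_periodic(state$S, dx),
    dH_dt = (params$k / params$theta) * div_grad_flux(state$H, state$H, dx),
    dN_dt = div_grad_flux(params$theta * params$D_N * state$H, Nc, dx) +
      div_grad_flux(params$k * state$H * Nc, state$H, dx)),
    class = c("peat_tendencies", "list"))
}

#' Explicit-Euler stability guard
#'
#' Advisory check of the diffusive stability condition
#' `dt <= safety * dx^2 / (4 * D_max)`, where `D_max` is the largest
#' effective diffusivity among `D_B`, `D_S`, `theta * D_N * max(H)` and
#' `k * max(H) / theta`. [run_simulation()] refuses to start on failure
#' unless overridden.
#'
#' @inheritParams transport_terms
#' @param dt candidate time step, yr.
#' @param safety safety factor in (0, 1].
#' @return list with `pass` (logical), `max_dt` (the bound, `Inf` when all
#'   diffusivities vanish), `D_max`.
#' @export
stability_guard <- function(params, grid, state = NULL, dt, safety = 0.9) {
  maxH <- if (is.null(state)) params$p / params$e else max(state$H)
  D_max <- max(params$D_B, params$D_S,
               params$theta * params$D_N * maxH,
               params$k * maxH / params$theta)
  max_dt <- if (D_max <= 0) Inf else safety * grid$dx^2 / (4 * D_max)
  list(pass = dt <= max_dt, max_dt = max_dt, D_max = D_max)
}

# effective forcing -> scalar triple for the C++ core
forcing_triplet <- function(params, forcing = NULL) {
  forcing <- modifyList(list(p = params$p, e = params$e, t_v = params$t_v),
                        forcing %||% list())
  if (any(unlist(forcing) < 0))
    peat_stop("forcing values must be >= 0", "peat_validation_error")
  forcing
}

#' One explicit Euler step
#'
#' Advances the state by `dt` using reaction plus conservative transport
#' tendencies. After the update `B`, `S`, `N` are clamped at 0 and `H` is
#' floored at `h_floor`; clamp events are counted and attached as attribute
#' `"clamps"`.
#'
#' @inheritParams transport_terms
#' @param forcing optional effective climate list (`p`, `e`, `t_v`).
#' @param dt time step, yr.
#' @param h_floor lower bound kept on `H`, m.
#' @param h_cap optional overflow/runoff ceiling on `H`, m (`NULL` = off).
#' @return new [field_state()] with `time` advanced by `dt` and a
#'   `"clamps"` attribute (named counts).
#' @export
step_euler <- function(state, params, forcing = NULL, grid, dt,
                       h_floor = 1e-6, h_cap = NULL) {
  validate_state(state)
  fo <- forcing_triplet(params, forcing)
  out <- cpp_step(state$B, state$S, state$H, state$N, param_vector(params),
                  fo$p, fo$e, fo$t_v, grid$dx, dt, h_floor,
                  h_cap %||% -1)
  new <- field_state(out$B, out$S, out$H, out$N, time = state$time + dt)
  attr(new, "clamps") <- out$clamps
  new
}

#' Run the full simulation
#'
#' Integrates the model for `config$duration` whole years with explicit
#' Euler steps of `config$dt`, optionally driven by a yearly climate
#' scenario (piecewise-constant precipitation and evapotranspiration factor
#' per calendar year). Emits full-field snapshots every
#' `config$snapshot_interval` years (plus the initial and final states) and
#' a yearly series of spatial means, including the evapotranspiration flux
#' `e*f + t_v*f*B` (scenario-scaled).
#'
#' @param initial [field_state()] to start from.
#' @param params [peat_params()].
#' @param scenario optional [climate_scenario()]; years not covered by the
#'   scenario use `params$p` and factor 1.
#' @param config [sim_config()].
#' @param grid [sim_grid()].
#' @param h_floor lower bound kept on `H`, m.
#' @param h_cap optional overflow/runoff ceiling on `H`, m; its use is
#'   reported via a message (off by default).
#' @param override_stability set `TRUE` to run despite a failing
#'   [stability_guard()].
#' @return list of class `peat_trajectory`: `snapshots` (list of states,
#'   initial first), `yearly` (data.frame: `year`, `mean_B`, `mean_S`,
#'   `mean_H`, `mean_N`, `mean_ET`, `precip`, `et_factor`), `clamps`,
#'   `final` (last state), plus the inputs for provenance.
#' @export
run_simulation <- function(initial, params, scenario = NULL, config, grid,
                           h_floor = 1e-6, h_cap = NULL,
                           override_stability = FALSE) {
  validate_state(initial)
  if (!identical(dim(initial$B), c(grid$ny, grid$nx)))
    peat_stop("initial state shape does not match grid", "peat_validation_error")
  years <- config$duration
  if (years > 0) {
    guard <- stability_guard(params, grid, initial, config$dt,
                             config$stability_safety)
    if (!guard$pass && !override_stability)
      peat_stop(sprintf(
        "dt = %g exceeds the stability bound %.3g yr (D_max = %.3g m^2/yr); reduce dt or set override_stability = TRUE",
        config$dt, guard$max_dt, guard$D_max), "peat_invalid_parameter")
  }
  if (!is.null(h_cap))
    message("H ceiling (overflow cap) active at ", h_cap, " m")

  if (years == 0) {
    return(structure(list(snapshots = list(initial),
                          snapshot_years = initial$time,
                          yearly = empty_yearly(), final = initial,
                          clamps = c(B = 0, S = 0, N = 0, H_floor = 0, H_cap = 0),
                          params = params, grid = grid, config = config,
                          scenario = scenario),
                     class = c("peat_trajectory", "list")))
  }

  t0 <- initial$time
  fv <- scenario_forcing(scenario, params, t0, years)
  steps_per_year <- as.integer(round(1 / config$dt))
  if (abs(steps_per_year * config$dt - 1) > 1e-8)
    peat_stop("dt must divide one year (1/dt integral)", "peat_invalid_parameter")

  out <- cpp_run(initial$B, initial$S, initial$H, initial$N,
                 param_vector(params), fv$precip, fv$et_factor,
                 t0, years, steps_per_year, config$dt, grid$dx,
                 config$snapshot_interval, h_floor, h_cap %||% -1)

  yearly <- as.data.frame(out$yearly)
  names(yearly) <- c("year", "mean_B", "mean_S", "mean_H", "mean_N",
                     "mean_ET", "precip", "et_factor")
  snaps <- c(list(initial),
             lapply(out$snapshots, function(s)
               field_state(s$B, s$S, s$H, s$N, time = s$time)))
  final <- snaps[[length(snaps)]]
  structure(list(snapshots = snaps,
                 snapshot_years = c(t0, t0 + out$snapshot_years),
                 yearly = yearly, final = final, clamps = out$clamps,
                 params = params, grid = grid, config = config,
                 scenario = scenario),
            class = c("peat_trajectory", "list"))
}

empty_yearly <- function() {
  data.frame(year = numeric(0), mean_B = numeric(0), mean_S = numeric(0),
             mean_H = numeric(0), mean_N = numeric(0), mean_ET = numeric(0),
             precip = numeric(0), et_factor = numeric(0))
}

# per-year forcing vectors for years t0+1 .. t0+years
scenario_forcing <- function(scenario, params, t0, years) {
  precip <- rep(params$p, years)
  etf <- rep(1, years)
  if (!is.null(scenario)) {
    yrs <- floor(t0) + seq_len(years)
    idx <- match(yrs, scenario$year)
    hit <- !is.na(idx)
    precip[hit] <- scenario$precip[idx[hit]]
    etf[hit] <- scenario$et_factor[idx[hit]]
  }
  list(precip = precip, et_factor = etf)
}

#' @export
print.peat_trajectory <- function(x, ...) {
  cat(sprintf("<peat_trajectory> %d snapshot(s), %d yearly record(s), t = %g yr\n",
              length(x$snapshots), nrow(x$yearly), x$final$time))
  if (nrow(x$yearly) > 0) {
    tail1 <- x$yearly[nrow(x$yearly), ]
    cat(sprintf("  final means: B = %.2f  S = %.2f  H = %.4f  N = %.4f\n",
                tail1$mean_B, tail1$mean_S, tail1$mean_H, tail1$mean_N))
  }
  invisible(x)
}
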