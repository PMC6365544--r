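#' Simulation grid
#'
#' Cell-centred periodic (toroidal) grid. The published configuration is
#' 128 x 128 cells at 2 m resolution (a 256 m x 256 m bog); the package's
#' scaled profile uses 64 x 64 at 4 m, covering the same physical domain.
#'
#' @param nx,ny number of cells in x and y (>= 4).
#' @param dx isotropic cell size in metres.
#' @return A list of class `peat_grid` with fields `nx`, `ny`, `dx`,
#'   `periodic` (always `TRUE`).
#' @export
sim_grid <- function(nx = 128, ny = nx, dx = 2) {
  if (nx < 4 || ny < 4)
    peat_stop("grid must be at least 4 x 4", "peat_invalid_parameter")
  if (dx <= 0)
    peat_stop("dx must be > 0", "peat_invalid_parameter")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 periodic = TRUE),
            class = c("peat_grid", "list"))
}

#' Simulation configuration
#'
#' @param dt time step in years (published runs use 1e-4; the scaled profile
#'   uses 1e-3, validated by a dt-halving consistency check).
#' @param duration run length in whole years.
#' @param snapshot_interval years between stored full-field snapshots
#'   (the final state is always stored).
#' @param seed optional integer seed recorded with the run.
#' @param stability_safety safety factor in (0, 1] for the explicit-Euler
#'   diffusive stability bound checked by [stability_guard()].
#' @return A list of class `peat_config`.
#' @export
sim_config <- function(dt = 1e-4, duration = 400, snapshot_interval = 50,
                       seed = NULL, stability_safety = 0.9) {
  if (dt <= 0) peat_stop("dt must be > 0", "peat_invalid_parameter")
  if (duration < 0)
    peat_stop("duration must be >= 0", "peat_invalid_parameter")
  if (snapshot_interval < 1)
    peat_stop("snapshot_interval must be >= 1 year", "peat_invalid_parameter")
  if (!(stability_safety > 0 && stability_safety <= 1))
    peat_stop("stability_safety must be in (0, 1]", "peat_invalid_parameter")
  structure(list(dt = dt, duration = as.integer(round(duration)),
                 snapshot_interval = as.integer(round(snapshot_interval)),
                 seed = seed, stability_safety = stability_safety),
            class = c("peat_config", "list"))
}

#' Scaled simulation profile
#'
#' The desk-scale profile used throughout the package's tests and scaled
#' reproductions: a 64 x 64 grid at 4 m resolution (the same 256 m domain as
#' the full-scale configuration, at half resolution) integrated with
#' dt = 1e-3 yr. The coarser dx keeps the explicit scheme inside its
#' diffusive stability bound at the larger step.
#'
#' @param duration run length in years.
#' @param snapshot_interval years between snapshots.
#' @param nx grid size (cells per side).
#' @param dx cell size in metres.
#' @param dt time step in years.
#' @return list with elements `grid` ([sim_grid()]) and `config`
#'   ([sim_config()]).
#' @export
scaled_profile <- function(duration = 400, snapshot_interval = 50,
                           nx = 64, dx = 4, dt = 1e-3) {
  list(grid = sim_grid(nx, nx, dx),
       config = sim_config(dt = dt, duration = duration,
                           snapshot_interval = snapshot_interval))
}

#' Field state
#'
#' The four coupled fields at one instant: vascular biomass `B` (g_B m^-2),
#' Sphagnum biomass `S` (g_S m^-2), hydraulic head `H` (m) and nutrient
#' availability `N` (g_N m^-2), all matrices of one shape (rows = y,
#' columns = x).
#'
#' @param B,S,H,N numeric matrices of identical dimension.
#' @param time simulation time in years.
#' @return A list of class `peat_state`.
#' @export
field_state <- function(B, S, H, N, time = 0) {
  st <- structure(list(B = B, S = S, H = H, N = N, time = time),
                  class = c("peat_state", "list"))
  validate_state(st)
  st
}

validate_state <- function(st) {
  dims <- lapply(st[c("B", "S", "H", "N")], dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    peat_stop("B, S, H, N must be matrices of one shape", "peat_validation_error")
  for (nm in c("B", "S", "H", "N"))
    if (!all(is.finite(st[[nm]])))
      peat_stop(paste0("field ", nm, " contains non-finite values"),
                "peat_validation_error")
  if (any(st$B < 0) || any(st$S < 0) || any(st$N < 0))
    peat_stop("B, S and N must be non-negative", "peat_validation_error")
  if (any(st$H <= 0))
    peat_stop("H must be strictly positive", "peat_validation_error")
  invisible(st)
}

#' @export
print.peat_state <- function(x, ...) {
  cat(sprintf("<peat_state> %d x %d cells at t = %g yr\n",
              nrow(x$B), ncol(x$B), x$time))
  cat(sprintf("  mean B = %.2f  S = %.2f  H = %.4f  N = %.4f\n",
              mean(x$B), mean(x$S), mean(x$H), mean(x$N)))
  invisible(x)
}

#' @export
print.peat_grid <- function(x, ...) {
  cat(sprintf("<peat_grid> %d x %d cells, dx = %g m (%g x %g m, periodic)\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx))
  invisible(x)
}
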