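#' Load a configuration file
#'
#' YAML configuration with up to three blocks — `params` (model parameters,
#' same symbols and units as [peat_params()]), `grid` (`nx`, `ny`, `dx`) and
#' `sim` (`dt`, `duration`, `snapshot_interval`, `seed`,
#' `stability_safety`). Unspecified fields take the published defaults; an
#' empty file yields the full default configuration. Unknown keys are
#' rejected, and invariant violations surface as classed errors.
#'
#' @param path path to a YAML file.
#' @return list of class `peat_configuration` with `params`, `grid`,
#'   `config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    peat_stop(paste0("config file not found: ", path), "peat_config_error")
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    peat_stop(paste0("config parse error: ",
                                     conditionMessage(e)), "peat_config_error"))
  raw <- raw %||% list()
  unknown <- setdiff(names(raw), c("params", "grid", "sim"))
  if (length(unknown) > 0)
    peat_stop(paste0("unknown config block(s): ", paste(unknown, collapse = ", ")),
              "peat_config_error")
  params <- do.call(peat_params, as.list(raw$params %||% list()))
  gl <- raw$grid %||% list()
  bad <- setdiff(names(gl), c("nx", "ny", "dx"))
  if (length(bad) > 0)
    peat_stop(paste0("unknown grid key(s): ", paste(bad, collapse = ", ")),
              "peat_config_error")
  grid <- do.call(sim_grid, gl)
  sl <- raw$sim %||% list()
  bad <- setdiff(names(sl),
                 c("dt", "duration", "snapshot_interval", "seed",
                   "stability_safety"))
  if (length(bad) > 0)
    peat_stop(paste0("unknown sim key(s): ", paste(bad, collapse = ", ")),
              "peat_config_error")
  config <- do.call(sim_config, sl)
  structure(list(params = params, grid = grid, config = config),
            class = c("peat_configuration", "list"))
}

#' Save a configuration file
#'
#' Writes a [load_config()]-compatible YAML file; save-then-load round-trips
#' to identical resolved settings.
#'
#' @param cfg `peat_configuration` (or list with `params`, `grid`, `config`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(list(
    params = unclass(cfg$params),
    grid = cfg$grid[c("nx", "ny", "dx")],
    sim = Filter(Negate(is.null),
                 cfg$config[c("dt", "duration", "snapshot_interval", "seed",
                              "stability_safety")])),
    path)
  invisible(path)
}

fmt <- function(x) sprintf("%.17g", x)

#' Write a field-state snapshot
#'
#' Self-describing plain-text format: a header with grid dimensions, cell
#' size, time and per-field units, then one whitespace-separated block of
#' `ny` rows per field (row = y, column = x, 0-based cell-centred
#' coordinates, row-major). Values are written with 17 significant digits so
#' the round-trip is bit-exact.
#'
#' @param state [field_state()].
#' @param path output path.
#' @param dx cell size recorded in the header, m.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path, dx = NA) {
  validate_state(state)
  units <- c(B = "g_B m-2", S = "g_S m-2", H = "m", N = "g_N m-2")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# peatsim snapshot v1",
               sprintf("ny %d", nrow(state$B)),
               sprintf("nx %d", ncol(state$B)),
               sprintf("dx %s", fmt(dx)),
               sprintf("time %s", fmt(state$time))), con)
  for (nm in c("B", "S", "H", "N")) {
    writeLines(sprintf("field %s units %s", nm, units[[nm]]), con)
    writeLines(apply(state[[nm]], 1, function(r) paste(fmt(r), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a field-state snapshot
#'
#' @param path path written by [write_snapshot()].
#' @return [field_state()] with attribute `"dx"`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5 || lines[1] != "# peatsim snapshot v1")
    peat_stop("not a peatsim snapshot file", "peat_schema_error")
  hdr <- function(i, key) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (parts[1] != key) peat_stop(paste0("expected header key ", key),
                                   "peat_schema_error")
    v <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(v)) peat_stop(paste0("malformed header value for ", key),
                            "peat_schema_error")
    v
  }
  ny <- hdr(2, "ny"); nx <- hdr(3, "nx")
  dx <- hdr(4, "dx"); time <- hdr(5, "time")
  pos <- 6
  fields <- list()
  for (nm in c("B", "S", "H", "N")) {
    if (pos > length(lines) || !startsWith(lines[pos], paste0("field ", nm)))
      peat_stop(paste0("snapshot truncated or malformed at field ", nm),
                "peat_schema_error")
    block <- lines[pos + seq_len(ny)]
    if (length(block) != ny || anyNA(block))
      peat_stop("snapshot truncated", "peat_schema_error")
    vals <- scan(text = block, quiet = TRUE)
    if (length(vals) != ny * nx)
      peat_stop("snapshot field has wrong size", "peat_schema_error")
    fields[[nm]] <- matrix(vals, ny, nx, byrow = TRUE)
    pos <- pos + ny + 1
  }
  st <- field_state(fields$B, fields$S, fields$H, fields$N, time = time)
  attr(st, "dx") <- dx
  st
}

#' Write / read the yearly mean series
#'
#' CSV with header `year, mean_B, mean_S, mean_H, mean_N, mean_ET, precip,
#' et_factor`, written at full precision (17 significant digits) so the
#' round-trip is bit-exact.
#'
#' @param yearly data.frame as produced by [run_simulation()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_yearly_series <- function(yearly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(yearly), collapse = ","), con)
  if (nrow(yearly) > 0)
    writeLines(apply(yearly, 1, function(r) paste(fmt(r), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_yearly_series
#' @export
read_yearly_series <- function(path) {
  need <- c("year", "mean_B", "mean_S", "mean_H", "mean_N", "mean_ET",
            "precip", "et_factor")
  df <- read.csv(path)
  if (!identical(names(df), need))
    peat_stop("yearly series file has unexpected columns", "peat_schema_error")
  df
}

#' Write / read a climate scenario
#'
#' CSV with header `year, precip_m_per_yr, et_factor` at full precision.
#'
#' @param scenario `climate_scenario`.
#' @param path file path.
#' @return `path` (write) or a `climate_scenario` (read).
#' @export
write_scenario <- function(scenario, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("year,precip_m_per_yr,et_factor", con)
  writeLines(paste(fmt(scenario$year), fmt(scenario$precip),
                   fmt(scenario$et_factor), sep = ","), con)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), c("year", "precip_m_per_yr", "et_factor")))
    peat_stop("scenario file has unexpected columns", "peat_schema_error")
  if (any(df$precip_m_per_yr < 0) || any(df$et_factor <= 0))
    peat_stop("scenario violates invariants (precip >= 0, factor > 0)",
              "peat_validation_error")
  structure(list(year = df$year, precip = df$precip_m_per_yr,
                 et_factor = df$et_factor),
            class = c("climate_scenario", "list"))
}

#' Write a run manifest
#'
#' JSON provenance record: resolved configuration, master and derived seeds,
#' package version, timestamps and the output file inventory. A run
#' re-executed from its manifest (same seeds) reproduces all numeric outputs
#' bit-identically.
#'
#' @param path output JSON path.
#' @param cfg `peat_configuration`.
#' @param master_seed master seed.
#' @param derived_seeds derived per-run seeds.
#' @param outputs character vector of output files.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg, master_seed, derived_seeds = integer(0),
                           outputs = character(0),
                           started = Sys.time(), finished = Sys.time()) {
  jsonlite::write_json(list(
    package = "peatsim",
    version = as.character(utils::packageVersion("peatsim")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    derived_seeds = derived_seeds,
    params = unclass(cfg$params),
    grid = cfg$grid[c("nx", "ny", "dx")],
    sim = Filter(Negate(is.null),
                 cfg$config[c("dt", "duration", "snapshot_interval", "seed",
                              "stability_safety")]),
    outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
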