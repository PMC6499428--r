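## Configuration files, run output writers and the manifest.

.known_keys <- list(
  top = c("protocol", "model", "solver", "output"),
  protocol = c("name", "tstar", "cooling", "T_cool", "t_on", "domain",
               "duration"),
  model = c("type", "params", "thermo", "scale"),
  model_params_ms = c("tau_in", "tau_out", "tau_open", "tau_close", "v_gate"),
  model_params_ap = c("k", "a", "mu1", "mu2", "eps0"),
  model_thermo = c("A", "B", "Q", "T_a"),
  model_scale = c("v_rest", "v_peak"),
  solver = c("dt", "dx", "dy", "newton_tol", "newton_max_iter", "linear_tol",
             "scheme", "coupling_mode", "lambda", "joule_source",
             "snapshot_stride_ms", "trace_T", "stop_when_quiescent",
             "quiescence_threshold_mV", "quiescence_hold_ms"),
  output = c("dir", "formats"))

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    sugg <- vapply(unknown, function(k) {
      hit <- agrep(k, allowed, max.distance = 0.3, value = TRUE)
      if (length(hit)) sprintf(" (did you mean '%s'?)", hit[1]) else ""
    }, character(1))
    stop(sprintf("unknown key%s in %s: %s", if (length(unknown) > 1) "s" else "",
                 where,
                 paste0("'", unknown, "'", sugg, collapse = ", ")),
         call. = FALSE)
  }
}

#' Provenance of the default parameter values
#'
#' Flat table of every model constant with its default, unit and the
#' parameter group it belongs to; embedded in every run manifest.
#'
#' @return A data.frame with columns `name`, `value`, `unit`, `source`.
#' @export
param_provenance <- function() {
  rbind(
    data.frame(name = c("tau_in", "tau_out", "tau_open", "tau_close", "v_gate"),
               value = c(0.05, 1, 95, 162, 0.13),
               unit = c("ms", "ms", "ms", "ms", "1"),
               source = "dimensional Mitchell-Schaeffer constants"),
    data.frame(name = c("k", "a", "mu1", "mu2", "eps0"),
               value = c(8, 0.15, 0.2, 0.3, 0.002),
               unit = "1",
               source = "dimensionless Aliev-Panfilov constants"),
    data.frame(name = c("v_rest", "v_peak"),
               value = c(-85, 40), unit = "mV", source = "voltage scaling"),
    data.frame(name = c("chi", "Cm", "Gi_xx", "Gi_yy", "Ge_xx", "Ge_yy"),
               value = c(2000, 1, 3.0, 0.315, 2.0, 1.35),
               unit = c("1/cm", "uF/cm^2", rep("mS/cm", 4)),
               source = "bidomain tissue constants"),
    data.frame(name = c("rho", "cp", "kT", "bc"),
               value = c(1.084e-3, 3676, 5.6e-6, 8e-5),
               unit = c("kg/cm^3", "J/(kg degC)", "J/(ms cm degC)",
                        "J/(ms cm^3 degC)"),
               source = "Pennes bioheat constants"),
    data.frame(name = c("A_ms", "B_ms", "Q_ms", "A_ap", "B_ap", "Q_ap", "T_a"),
               value = c(1, 0.07, 2.4, 1, 0.081, 2.4, 37),
               unit = c("1", "1/degC", "1", "1", "1/degC", "1", "degC"),
               source = "ionic thermal-coupling constants"))
}

#' Load a run configuration file
#'
#' Reads a YAML configuration with sections `protocol`, `model`, `solver` and
#' `output`, validates every key (unknown keys are rejected with a
#' suggestion), and fills in the documented defaults for everything omitted.
#' An empty or protocol-only file yields the full default parameterization.
#'
#' @param path Path to a YAML file.
#' @return An object of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Validate a raw configuration list
#'
#' @param raw Nested list as read from YAML.
#' @return An object of class `"run_config"` with defaults filled in.
#' @export
validate_config <- function(raw) {
  .check_keys(raw, .known_keys$top, "config")
  pr <- raw$protocol %||% list()
  .check_keys(pr, .known_keys$protocol, "protocol")
  mo <- raw$model %||% list()
  .check_keys(mo, .known_keys$model, "model")
  so <- raw$solver %||% list()
  .check_keys(so, .known_keys$solver, "solver")
  ou <- raw$output %||% list()
  .check_keys(ou, .known_keys$output, "output")

  name <- pr$name %||% "planar_q10"
  name <- match.arg(name, c("planar_q10", "single_spiral", "multi_spiral",
                            "domain_size_check"))
  mtype <- mo$type %||% if (name == "planar_q10") "ms" else "ap"
  mtype <- match.arg(mtype, c("ms", "ap"))
  pkeys <- if (mtype == "ms") .known_keys$model_params_ms else .known_keys$model_params_ap
  if (!is.null(mo$params)) .check_keys(mo$params, pkeys, "model$params")
  if (!is.null(mo$thermo)) .check_keys(mo$thermo, .known_keys$model_thermo, "model$thermo")
  if (!is.null(mo$scale)) .check_keys(mo$scale, .known_keys$model_scale, "model$scale")

  cfg <- list(
    protocol = list(name = name,
                    tstar = pr$tstar %||% 37,
                    cooling = pr$cooling %||% "none",
                    T_cool = pr$T_cool %||% 30,
                    t_on = pr$t_on,
                    ## YAML represents mixed int/real sequences as lists
                    domain = if (!is.null(pr$domain)) as.numeric(unlist(pr$domain)),
                    duration = pr$duration),
    model = list(type = mtype,
                 params = mo$params %||% list(),
                 thermo = mo$thermo %||% list(),
                 scale = mo$scale %||% list()),
    solver = so,
    output = list(dir = ou$dir %||% "cardiotherm-run",
                  formats = ou$formats %||% "csv"))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' @param config A `run_config` (or raw nested list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the ionic model described by a configuration
#'
#' @param config A `run_config`.
#' @return An [ionic_model()].
#' @export
config_model <- function(config) {
  mo <- config$model
  scale <- do.call(voltage_scale, mo$scale)
  params <- if (mo$type == "ms") do.call(ms_params, mo$params)
            else do.call(ap_params, mo$params)
  thermo <- do.call(thermo_coupling, c(mo$thermo, list(model = mo$type)))
  ionic_model(mo$type, params = params, thermo = thermo, scale = scale)
}

#' Build the solver configuration described by a configuration
#'
#' @param config A `run_config`.
#' @return A [solver_config()].
#' @export
config_solver <- function(config) {
  do.call(solver_config, config$solver)
}

#' Build the protocol described by a configuration
#'
#' @param config A `run_config`.
#' @return A [protocol()].
#' @export
config_protocol <- function(config) {
  pr <- config$protocol
  args <- list(name = pr$name, tstar = pr$tstar, cooling = pr$cooling,
               T_cool = pr$T_cool)
  if (!is.null(pr$t_on)) args$t_on <- pr$t_on
  if (!is.null(pr$domain)) args$domain <- pr$domain
  if (!is.null(pr$duration)) args$duration <- pr$duration
  p <- do.call(build_protocol, args)
  if (length(config$model$params) || length(config$model$thermo) ||
      length(config$model$scale) || !identical(config$model$type, p$model$model)) {
    p$model <- config_model(config)
  }
  p
}

#' Write probe traces as CSV
#'
#' One row per time step: `time_ms`, then one `Vm_<k>` (and `T_<k>`) column
#' per probe.
#'
#' @param run A `cardiotherm_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(run, path) {
  df <- data.frame(time_ms = run$times)
  for (k in seq_len(ncol(run$trace_Vm))) df[[sprintf("Vm_%d", k)]] <- run$trace_Vm[, k]
  if (!is.null(run$trace_T)) {
    for (k in seq_len(ncol(run$trace_T))) df[[sprintf("T_%d", k)]] <- run$trace_T[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a 0-D cell trace as CSV
#'
#' @param trace Data frame from [cell_simulate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time_ms", "Vm_mV", "W", "T_C")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a field snapshot as a legacy-ASCII VTK structured grid
#'
#' @param state A [field_state()].
#' @param path Output `.vtk` path.
#' @param fields Which fields to include.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(state, path, fields = c("Vm", "phi_e", "W", "T")) {
  g <- state$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardiotherm field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", g$dx, g$dy),
               sprintf("POINT_DATA %d", g$nx * g$ny)), con)
  for (f in fields) {
    writeLines(c(sprintf("SCALARS %s double 1", f), "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(state[[f]]), digits = 10), collapse = " "),
               con)
  }
  invisible(path)
}

#' Write snapshots as plain CSV matrices
#'
#' One file per snapshot and field, `snap_<time>_<field>.csv`, holding the
#' `nx x ny` matrix.
#'
#' @param run A `cardiotherm_run`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_snapshots_csv <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sn in run$snapshots) {
    for (f in c("Vm", "phi_e", "W", "T")) {
      utils::write.table(sn$state[[f]],
                         file.path(dir, sprintf("snap_%07.1f_%s.csv", sn$time, f)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Write a complete run directory
#'
#' `traces.csv`, snapshots (CSV and/or VTK) and `manifest.json` (configuration
#' echo, parameter provenance, solver statistics) sufficient to re-run the
#' simulation exactly.
#'
#' @param run A `cardiotherm_run`.
#' @param dir Output directory.
#' @param config Optional `run_config` to echo into the manifest.
#' @param formats Snapshot formats, subset of `c("csv", "vtk")`.
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir, config = NULL, formats = "csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traces_csv(run, file.path(dir, "traces.csv"))
  if ("csv" %in% formats) write_snapshots_csv(run, file.path(dir, "snapshots"))
  if ("vtk" %in% formats) {
    vd <- file.path(dir, "vtk")
    dir.create(vd, showWarnings = FALSE)
    for (sn in run$snapshots) {
      write_vtk_snapshot(sn$state, file.path(vd, sprintf("snap_%07.1f.vtk", sn$time)))
    }
  }
  manifest <- list(
    package = "cardiotherm",
    version = as.character(utils::packageVersion("cardiotherm")),
    protocol = list(name = run$protocol$name,
                    domain_cm = run$protocol$domain,
                    duration_ms = run$protocol$duration,
                    model = run$protocol$model$model,
                    model_params = run$protocol$model$params,
                    thermo = run$protocol$model$thermo,
                    cooling = unclass(run$protocol$cooling),
                    probes_cm = run$protocol$probes),
    solver = unclass(run$config),
    config_echo = if (!is.null(config)) unclass(config) else NULL,
    parameter_provenance = param_provenance(),
    statistics = list(steps = length(run$times) - 1L,
                      newton_iterations_mean = mean(run$newton_iters),
                      newton_iterations_max = max(run$newton_iters),
                      stopped_at_ms = run$stopped_at,
                      simulated_ms = max(run$times)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(dir)
}

#' Execute a configuration end to end
#'
#' Builds the protocol and solver from a configuration, runs the simulation
#' and writes the run directory.
#'
#' @param config A `run_config` (see [load_config()]).
#' @param dir Output directory (default from the config's output section).
#' @param verbose Progress output?
#' @return The `cardiotherm_run`, invisibly; side effect: the run directory.
#' @export
run_from_config <- function(config, dir = NULL, verbose = FALSE) {
  p <- config_protocol(config)
  s <- config_solver(config)
  run <- run_simulation(p, s, verbose = verbose)
  write_run(run, dir %||% config$output$dir, config = config,
            formats = config$output$formats)
  invisible(run)
}
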