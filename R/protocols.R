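#' Cooling / hypothermia schedule
#'
#' The perfusion setpoint `T*` serves simultaneously as arterial-blood
#' temperature and cooling setpoint. Before `t_on` the whole domain is at
#' `T_body`; from `t_on` on, `T_cool` is applied either globally or inside a
#' disc, while `T_body` is maintained elsewhere.
#'
#' @param region `"global"` or `"disc"`.
#' @param T_cool Cooling setpoint, degC.
#' @param T_body Body (normothermic) setpoint, degC.
#' @param t_on Time at which cooling switches on, ms.
#' @param center Disc center `(x, y)`, cm (disc region only).
#' @param radius Disc radius, cm (disc region only).
#' @return An object of class `"cooling_spec"`.
#' @export
cooling_spec <- function(region = c("global", "disc"), T_cool = 37,
                         T_body = 37, t_on = 0, center = NULL, radius = 2) {
  region <- match.arg(region)
  if (region == "disc") stopifnot(radius > 0)
  stopifnot(t_on >= 0)
  structure(list(region = region, T_cool = T_cool, T_body = T_body,
                 t_on = t_on, center = center, radius = radius),
            class = "cooling_spec")
}

#' Perfusion setpoint field at a given time
#'
#' Evaluates the `T*` field of a [cooling_spec()] on the grid: uniform
#' `T_body` before `t_on`; afterwards `T_cool` inside the cooled region
#' (entire domain if global) and `T_body` outside, with a sharp node-resolved
#' boundary.
#'
#' @param grid A [grid2d()].
#' @param cooling A [cooling_spec()].
#' @param t Time, ms.
#' @return `nx x ny` matrix of `T*`, degC.
#' @export
tstar_field <- function(grid, cooling, t) {
  if (t < cooling$t_on) {
    return(matrix(cooling$T_body, grid$nx, grid$ny))
  }
  if (cooling$region == "global") {
    return(matrix(cooling$T_cool, grid$nx, grid$ny))
  }
  ctr <- cooling$center
  if (is.null(ctr)) ctr <- c(grid$Lx / 2, grid$Ly / 2)
  if (ctr[1] - cooling$radius < 0 || ctr[1] + cooling$radius > grid$Lx ||
      ctr[2] - cooling$radius < 0 || ctr[2] + cooling$radius > grid$Ly) {
    stop("cooling disc is not fully inside the domain")
  }
  co <- grid_coords(grid)
  inside <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 <= cooling$radius^2
  out <- matrix(cooling$T_body, grid$nx, grid$ny)
  out[inside] <- cooling$T_cool
  out
}

#' Declarative experiment protocol
#'
#' Bundles the domain, duration, ionic model, tissue and thermal constants,
#' cooling schedule, probe locations and the initial-state builder into one
#' description that [run_simulation()] executes.
#'
#' @param name Protocol name (free text).
#' @param domain `c(Lx, Ly)`, cm.
#' @param duration Simulated time, ms.
#' @param model An [ionic_model()].
#' @param cooling A [cooling_spec()].
#' @param probes Matrix (or 2-vector) of probe locations `(x, y)`, cm.
#' @param init_state Function `(grid, model, tstar0, config)` returning the
#'   initial [field_state()]. The initial temperature always equals the t = 0
#'   setpoint field.
#' @param tissue A [tissue_params()].
#' @param thermal A [thermal_params()].
#' @return An object of class `"protocol"`.
#' @export
protocol <- function(name, domain, duration, model,
                     cooling = cooling_spec(),
                     probes = c(domain[1] / 2, domain[2] / 2),
                     init_state,
                     tissue = tissue_params(),
                     thermal = thermal_params()) {
  stopifnot(duration > 0, length(domain) == 2, all(domain > 0))
  if (!is.matrix(probes)) probes <- matrix(probes, ncol = 2, byrow = TRUE)
  if (any(probes[, 1] < 0 | probes[, 1] > domain[1] |
          probes[, 2] < 0 | probes[, 2] > domain[2])) {
    stop("probes must lie inside the domain")
  }
  structure(list(name = name, domain = domain, duration = duration,
                 model = model, cooling = cooling, probes = probes,
                 init_state = init_state, tissue = tissue, thermal = thermal),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> '%s': %g x %g cm, %g ms, %s model\n",
              x$name, x$domain[1], x$domain[2], x$duration, x$model$model))
  cat(sprintf("  cooling: %s T_cool=%g degC (T_body=%g) from t=%g ms\n",
              x$cooling$region, x$cooling$T_cool, x$cooling$T_body,
              x$cooling$t_on))
  cat(sprintf("  probes: %s\n",
              paste(apply(x$probes, 1, function(p)
                sprintf("(%g, %g)", p[1], p[2])), collapse = ", ")))
  invisible(x)
}

#' Planar-wave initial state
#'
#' An excited disc of radius `sqrt(0.5)` cm at the domain center
#' (`Vm = v_peak` inside, `v_rest` outside), gate at `W = 0.9`, zero
#' extracellular potential, temperature equal to the setpoint field. On the
#' 10 cm x 10 cm domain this is the disc `(x-5)^2 + (y-5)^2 < 0.5`.
#'
#' @param grid A [grid2d()].
#' @param model An [ionic_model()] (supplies the voltage scale).
#' @param tstar0 Initial setpoint field (scalar or matrix), degC.
#' @param w0 Initial gate value (default 0.9).
#' @return A [field_state()].
#' @export
planar_initial_state <- function(grid, model = ionic_model("ms"), tstar0 = 37,
                                 w0 = 0.9) {
  co <- grid_coords(grid)
  cx <- grid$Lx / 2; cy <- grid$Ly / 2
  inside <- (co$x - cx)^2 + (co$y - cy)^2 < 0.5
  Vm <- matrix(model$scale$v_rest, grid$nx, grid$ny)
  Vm[inside] <- model$scale$v_peak
  field_state(grid, Vm = Vm, phi_e = 0, W = w0,
              T_c = .expand_field(tstar0, grid, "tstar0"))
}

## ---------------------------------------------------------------------------
## S1-S2 cross-field spiral initiation.
##
## S1 is a planar conditioning wave along +x. Because it is uniform in y, its
## profile is computed once on a thin strip with the same x-resolution and
## painted onto the 2-D domain with the repolarization tail at a prescribed
## position. S2 then excites a patch in the partially recovered wake; each
## interior horizontal patch edge leaves one free wavefront end that curls
## into a spiral. The construction is fully deterministic.

.s1_profile <- function(Lx, model, config, back_frac = 0.55, tissue, thermal) {
  dy <- config$dy
  ## generous duration bound: slow conduction (>= 0.08 m/s) plus a long
  ## action potential; snapshots every 5 ms, the one whose repolarization
  ## tail sits closest to back_frac*Lx is painted onto the sheet
  strip <- protocol(
    name = "s1-conditioning-strip",
    domain = c(Lx, 2 * dy),
    duration = back_frac * Lx / 0.008 + 700,
    model = model,
    cooling = cooling_spec("global", T_cool = 37, T_body = 37),
    probes = c(Lx / 2, dy),
    init_state = function(grid, model, tstar0, config) {
      co <- grid_coords(grid)
      Vm <- matrix(model$scale$v_rest, grid$nx, grid$ny)
      Vm[co$x < 0.5] <- model$scale$v_peak
      field_state(grid, Vm = Vm, phi_e = 0, W = rest_state(model)$W,
                  T_c = tstar0)
    },
    tissue = tissue, thermal = thermal)
  cfg <- config
  cfg$snapshot_stride_ms <- 5
  cfg$stop_when_quiescent <- FALSE
  run <- run_simulation(strip, cfg)
  x <- grid_x(run$grid)
  target <- back_frac * Lx
  best <- NULL; best_gap <- Inf
  for (sn in run$snapshots) {
    vm <- sn$state$Vm[, 1]
    act <- which(vm > -20)
    if (!length(act)) next
    back <- x[min(act)]
    gap <- abs(back - target)
    if (gap < best_gap) { best_gap <- gap; best <- sn }
  }
  if (is.null(best)) stop("S1 conditioning wave failed to propagate")
  list(x = x, Vm = best$state$Vm[, 1], W = best$state$W[, 1],
       phi_e = best$state$phi_e[, 1])
}

.paint_s1 <- function(grid, prof, model) {
  Vm <- matrix(prof$Vm, grid$nx, grid$ny)
  W <- matrix(prof$W, grid$nx, grid$ny)
  phi <- matrix(prof$phi_e, grid$nx, grid$ny)
  list(Vm = Vm, W = W, phi_e = phi)
}

## wave-back position: largest x below which Vm has fallen back under level
.wave_back <- function(x, vm, level = -20) {
  act <- which(vm > level)
  if (!length(act)) return(NA_real_)
  x[min(act)]
}

#' S1-S2 single-spiral initial state
#'
#' Builds a state containing exactly one phase singularity by cross-field
#' stimulation: a planar S1 wave travelling along +x (painted from a
#' conditioning strip simulation, tail mid-domain), then an S2 stimulus
#' exciting the lower-left part of its partially recovered wake, followed by
#' a short settling simulation at uniform 37 degC that lets the free
#' wavefront end curl up. The produced singularity count is verified with
#' [tip_locations()]; a count different from one raises an error carrying a
#' diagnostic snapshot.
#'
#' @param grid A [grid2d()].
#' @param model An [ionic_model()] (the spiral experiments use
#'   Aliev-Panfilov with `a = 0.1`).
#' @param config A [solver_config()].
#' @param tstar0 Temperature/setpoint field painted onto the returned state.
#' @param s2_gap Distance (cm) behind the S1 wave back at which the S2 patch
#'   ends; controls how recovered the re-excited tissue is.
#' @param s2_y_frac S2 patch height as a fraction of `Ly` (1 covers the whole
#'   domain and produces no wavebreak: degenerate, raises the count error).
#' @param settle_ms Settling time after S2, ms.
#' @param back_frac S1 repolarization-tail position (fraction of `Lx`) when
#'   S2 is applied.
#' @param tissue,thermal Tissue/thermal constants for the internal runs.
#' @return A [field_state()] containing one spiral.
#' @export
s1s2_spiral_state <- function(grid, model, config, tstar0 = 37,
                              s2_gap = 0.75, s2_y_frac = 0.5,
                              settle_ms = 120, back_frac = 0.55,
                              tissue = tissue_params(),
                              thermal = thermal_params()) {
  st <- .s1s2_state(grid, model, config,
                    s2_bands = rbind(c(0, s2_y_frac)),
                    s2_gap = s2_gap, settle_ms = settle_ms,
                    back_frac = back_frac, tissue = tissue,
                    thermal = thermal)
  tips <- attr(st, "tips")
  if (nrow(tips) != 1L) {
    cond <- simpleError(sprintf(
      "spiral initiation produced %d phase singularities (expected 1)",
      nrow(tips)))
    cond$snapshot <- st
    stop(cond)
  }
  st$T <- .expand_field(tstar0, grid, "tstar0")
  st
}

#' Three-spiral initial state
#'
#' Same cross-field construction as [s1s2_spiral_state()] but with a stack of
#' S2 patches whose three interior horizontal edges each shed one free
#' wavefront end, yielding exactly three phase singularities.
#'
#' @inheritParams s1s2_spiral_state
#' @param s2_bands Two-column matrix of `(y_lo, y_hi)` fractions of `Ly`
#'   defining the S2 patches; the default has three interior edges.
#' @return A [field_state()] containing three spirals.
#' @export
multi_spiral_state <- function(grid, model, config, tstar0 = 37,
                               s2_gap = 0.75,
                               s2_bands = rbind(c(0, 0.25), c(0.5, 0.75)),
                               settle_ms = 120, back_frac = 0.55,
                               tissue = tissue_params(),
                               thermal = thermal_params()) {
  st <- .s1s2_state(grid, model, config, s2_bands = s2_bands,
                    s2_gap = s2_gap, settle_ms = settle_ms,
                    back_frac = back_frac, tissue = tissue,
                    thermal = thermal)
  tips <- attr(st, "tips")
  if (nrow(tips) != 3L) {
    cond <- simpleError(sprintf(
      "multi-spiral initiation produced %d phase singularities (expected 3)",
      nrow(tips)))
    cond$snapshot <- st
    stop(cond)
  }
  st$T <- .expand_field(tstar0, grid, "tstar0")
  st
}

.s1s2_state <- function(grid, model, config, s2_bands, s2_gap, settle_ms,
                        back_frac, tissue, thermal) {
  prof <- .s1_profile(grid$Lx, model, config, back_frac = back_frac,
                      tissue = tissue, thermal = thermal)
  painted <- .paint_s1(grid, prof, model)
  xb <- .wave_back(prof$x, prof$Vm)
  if (is.na(xb)) stop("S1 wave has no active region to break")
  x_s2 <- xb - s2_gap
  if (x_s2 <= 0) stop("S2 cutoff fell outside the domain; reduce s2_gap")
  co <- grid_coords(grid)
  s2 <- matrix(FALSE, grid$nx, grid$ny)
  for (b in seq_len(nrow(s2_bands))) {
    s2 <- s2 | (co$y >= s2_bands[b, 1] * grid$Ly &
                  co$y <= s2_bands[b, 2] * grid$Ly)
  }
  s2 <- s2 & (co$x <= x_s2)
  Vm <- painted$Vm
  Vm[s2] <- model$scale$v_peak
  state0 <- field_state(grid, Vm = Vm, phi_e = painted$phi_e, W = painted$W,
                        T_c = 37)
  settle <- protocol(
    name = "s2-settle",
    domain = c(grid$Lx, grid$Ly),
    duration = settle_ms,
    model = model,
    cooling = cooling_spec("global", T_cool = 37, T_body = 37),
    probes = c(grid$Lx / 2, grid$Ly / 2),
    init_state = function(grid, model, tstar0, config) state0,
    tissue = tissue, thermal = thermal)
  cfg <- config
  cfg$snapshot_stride_ms <- settle_ms / 2
  cfg$stop_when_quiescent <- FALSE
  run <- run_simulation(settle, cfg)
  last_sn <- run$snapshots[[length(run$snapshots)]]
  tips <- tip_locations(last_sn$state$Vm, last_sn$Vm_prev, grid)
  structure(last_sn$state, tips = tips)
}

#' Named experiment builders
#'
#' Fully populated [protocol()]s for the four study designs:
#' \describe{
#'   \item{planar_q10}{Planar Mitchell-Schaeffer wave on a 10 cm x 10 cm
#'     sheet, 750 ms, uniform setpoint `tstar` (the temperature study spans
#'     27-43 degC), conduction probes at (5.5, 5) and (6.5, 5) and an APD
#'     probe at (6, 5).}
#'   \item{single_spiral}{One Aliev-Panfilov spiral (`a = 0.1`), 1680 ms,
#'     with optional regional (disc radius 2 cm) or global cooling from
#'     `t_on = 0`.}
#'   \item{multi_spiral}{Three Aliev-Panfilov spirals (`a = 0.1`,
#'     `mu1 = 0.135`, `eps0 = 0.001`), 1950 ms, cooling from `t_on = 600` ms.}
#'   \item{domain_size_check}{As multi_spiral on a 13 cm x 13 cm sheet.}
#' }
#'
#' @param name One of `"planar_q10"`, `"single_spiral"`, `"multi_spiral"`,
#'   `"domain_size_check"`.
#' @param tstar Uniform setpoint for `planar_q10`, degC.
#' @param cooling `"none"`, `"global"` or `"disc"` for the spiral protocols.
#' @param T_cool Cooling setpoint, degC.
#' @param t_on Cooling onset, ms (`multi_spiral` default 600, others 0).
#' @param domain Domain override `c(Lx, Ly)`, cm.
#' @param duration Duration override, ms.
#' @param ... Passed to the spiral initial-state builders
#'   ([s1s2_spiral_state()] / [multi_spiral_state()]).
#' @return A [protocol()].
#' @export
build_protocol <- function(name = c("planar_q10", "single_spiral",
                                    "multi_spiral", "domain_size_check"),
                           tstar = 37,
                           cooling = c("none", "global", "disc"),
                           T_cool = 30, t_on = NULL,
                           domain = NULL, duration = NULL, ...) {
  name <- match.arg(name)
  cooling <- match.arg(cooling)
  dots <- list(...)
  if (name == "planar_q10") {
    dom <- if (is.null(domain)) c(10, 10) else domain
    dur <- if (is.null(duration)) 750 else duration
    ym <- dom[2] / 2
    return(protocol(
      name = "planar_q10",
      domain = dom, duration = dur,
      model = ionic_model("ms"),
      cooling = cooling_spec("global", T_cool = tstar, T_body = tstar),
      probes = rbind(c(5.5, ym), c(6.5, ym), c(6, ym)),
      init_state = function(grid, model, tstar0, config) {
        planar_initial_state(grid, model, tstar0)
      }))
  }

  multi <- name %in% c("multi_spiral", "domain_size_check")
  dom <- if (!is.null(domain)) domain
         else if (name == "domain_size_check") c(13, 13) else c(10, 10)
  dur <- if (!is.null(duration)) duration else if (multi) 1950 else 1680
  ton <- if (!is.null(t_on)) t_on else if (multi) 600 else 0
  cool <- switch(cooling,
    none = cooling_spec("global", T_cool = 37, T_body = 37),
    global = cooling_spec("global", T_cool = T_cool, T_body = 37, t_on = ton),
    disc = cooling_spec("disc", T_cool = T_cool, T_body = 37, t_on = ton,
                        center = dom / 2, radius = 2))
  params <- if (multi) ap_params(a = 0.1, mu1 = 0.135, eps0 = 0.001)
            else ap_params(a = 0.1)
  model <- ionic_model("ap", params = params)
  builder <- if (multi) multi_spiral_state else s1s2_spiral_state
  init <- function(grid, model, tstar0, config) {
    do.call(builder, c(list(grid = grid, model = model, config = config,
                            tstar0 = tstar0), dots))
  }
  protocol(name = name, domain = dom, duration = dur, model = model,
           cooling = cool, probes = rbind(c(dom[1] / 2, dom[2] / 2)),
           init_state = init)
}
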