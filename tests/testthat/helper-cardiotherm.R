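## Shared fixtures. Expensive reference runs are computed lazily, once per
## test session, and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## thin planar strip: y-uniform physics, cheap stand-in for the full sheet
strip_protocol <- function(tstar = 37, duration = 120, Ly = 0.08,
                           probes_x = c(5.5, 6.5, 6)) {
  pr <- build_protocol("planar_q10", tstar = tstar, domain = c(10, Ly),
                       duration = duration)
  pr$probes <- cbind(probes_x, Ly / 2)
  pr
}

strip_config <- function(dt = 0.1, dx = 0.025, dy = 0.02, ...) {
  solver_config(dt = dt, dx = dx, dy = dy, ...)
}

## production-resolution planar runs shared by several acceptance checks
planar_reference_run <- function(tstar) {
  fixture(sprintf("planar_%g", tstar), function() {
    dur <- if (tstar >= 37) 420 else 750
    run_simulation(strip_protocol(tstar = tstar, duration = dur),
                   strip_config())
  })
}

## small grid + smooth field for operator tests
smooth_field <- function(grid, fx = 3, fy = 2, amp = 10) {
  co <- grid_coords(grid)
  amp * sin(fx * co$x) * cos(fy * co$y)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

## scaled-down single-spiral construction shared by the protocol tests
## (monodomain plumbing keeps it affordable; the tip count contract is the
## same as the full bidomain protocol's)
spiral_fixture <- function() {
  fixture("spiral_state", function() {
    model <- ionic_model("ap", params = ap_params(a = 0.1))
    config <- solver_config(dt = 0.3, dx = 0.0625, dy = 0.0625,
                            coupling_mode = "heat_monodomain",
                            snapshot_stride_ms = 45)
    grid <- grid2d(10, 10, dx = 0.0625)
    settle_ms <- 90
    state <- s1s2_spiral_state(grid, model, config, tstar0 = 37,
                               settle_ms = settle_ms)
    list(grid = grid, model = model, config = config, state = state,
         settle_ms = settle_ms)
  })
}

## the three reentry experiments of the cooling comparison, scaled down:
## heat-bidomain on the 10 cm sheet at dx = 0.1 cm, with the hypothermia run
## given the longest horizon the suite can afford
spiral_ordering_runs <- function() {
  dx <- 0.1
  cfg <- solver_config(dt = 0.3, dx = dx, dy = dx,
                       coupling_mode = "heat_bidomain",
                       snapshot_stride_ms = 60,
                       stop_when_quiescent = TRUE, quiescence_hold_ms = 120)
  one <- function(cooling, T_cool, duration) {
    proto <- build_protocol("single_spiral", cooling = cooling,
                            T_cool = T_cool, duration = duration,
                            settle_ms = 90, back_frac = 0.4)
    run_simulation(proto, cfg)
  }
  list(normothermic = one("none", 37, 600),
       hypothermia = one("global", 30, 1680),
       regional = one("disc", 30, 600))
}
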