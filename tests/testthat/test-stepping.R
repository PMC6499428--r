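coupled_params <- function() list(tissue = tissue_params(),
                                  thermal = thermal_params())

test_that("BDF2 formula is exact on polynomials up to degree two", {
  expect_equal(bdf2_derivative(5, 5, 5, 0.3), 0)
  expect_equal(bdf2_derivative(2, 1, 0, 1), 1)      # y = t at t = 2
  expect_equal(bdf2_derivative(4, 1, 0, 1), 4)      # y = t^2 at t = 2
  ## vectorized
  expect_equal(bdf2_derivative(c(2, 4), c(1, 1), c(0, 0), 1), c(1, 4))
})

test_that("resting equilibrium is a fixed point of the coupled step", {
  g <- grid2d(2, 2, dx = 0.25)
  m <- ionic_model("ms")
  st <- field_state(g, Vm = -85, phi_e = 0, W = 1, T_c = 37)
  hist <- step_history(st, st, 0)
  out <- step_coupled(hist, solver_config(dt = 0.3, dx = 0.25),
                      coupled_params(), m)
  expect_equal(max(abs(out$Vm + 85)), 0)
  expect_equal(max(abs(out$W - 1)), 0)
  expect_lt(max(abs(out$T - 37)), 1e-10)
})

test_that("static-temperature mode pins T bitwise to the setpoint", {
  g <- grid2d(2, 2, dx = 0.25)
  m <- ionic_model("ms")
  st <- planar_initial_state(grid2d(2, 2, dx = 0.25), m, tstar0 = 31)
  hist <- step_history(st, st, 0)
  cfg <- solver_config(dt = 0.3, dx = 0.25,
                       coupling_mode = "ionic_only_static_T")
  params <- coupled_params()
  params$thermal$Tstar <- 31
  out <- step_coupled(hist, cfg, params, m)
  expect_identical(out$T, matrix(31, g$nx, g$ny))
})

test_that("at uniform 37 degC one electrics step bit-matches the isothermal bidomain", {
  g <- grid2d(2, 2, dx = 0.2)
  m <- ionic_model("ms")
  st <- planar_initial_state(g, m, tstar0 = 37)
  hist <- step_history(st, st, 0)
  cfg <- solver_config(dt = 0.3, dx = 0.2)
  a <- advance_electrics(hist, cfg, tissue_params(), m)
  cfg$strip_thermal <- TRUE
  b <- advance_electrics(hist, cfg, tissue_params(), m)
  expect_identical(a$Vm, b$Vm)
  expect_identical(a$W, b$W)
  expect_identical(a$phi_e, b$phi_e)
})

test_that("heat step holds equilibrium and tracks the closed-form relaxation", {
  g <- grid2d(1, 1, dx = 0.125)
  cfg <- solver_config(dt = 1, dx = 0.125)
  th <- thermal_params() # Tstar = 37
  rest <- matrix(-85, g$nx, g$ny)

  ## equilibrium: T = T*, uniform Vm -> zero source
  st <- field_state(g, Vm = rest, T_c = 37)
  out <- advance_heat(step_history(st, st, 0), rest, cfg, th)
  expect_lt(max(abs(out - 37)), 1e-10)

  ## space-uniform source-free cooling: dT/dt = -(bc/(rho cp)) (T - T*),
  ## rate 2.0076e-5 /ms; BDF2 seeded with the exact history
  rate <- th$bc / (th$rho * th$cp)
  exact <- function(t) 37 + exp(-rate * t)
  Tm1 <- matrix(exact(-cfg$dt), g$nx, g$ny)
  T0 <- matrix(exact(0), g$nx, g$ny)
  Tn <- list(Tm1, T0)
  tcur <- 0
  for (k in 1:400) {
    hist <- step_history(field_state(g, Vm = rest, T_c = Tn[[1]]),
                         field_state(g, Vm = rest, T_c = Tn[[2]]), tcur)
    Tnew <- advance_heat(hist, rest, cfg, th)
    Tn <- list(Tn[[2]], Tnew)
    tcur <- tcur + cfg$dt
  }
  rel <- abs(Tn[[2]][1, 1] - exact(tcur)) / abs(exact(tcur) - 37)
  expect_lt(rel, 1e-6)
})

test_that("BDF2 converges at second order on a space-uniform configuration", {
  ## uniform fields: spatial operators vanish, the integrator reduces to the
  ## cell ODEs; smooth Aliev-Panfilov dynamics over a 20 ms window
  m <- ionic_model("ap", params = ap_params(a = 0.1))
  proto <- protocol(
    name = "uniform-cell", domain = c(0.2, 0.2), duration = 20, model = m,
    cooling = cooling_spec("global", T_cool = 37, T_body = 37),
    probes = c(0.1, 0.1),
    init_state = function(grid, model, tstar0, config) {
      field_state(grid, Vm = -30, phi_e = 0, W = 0.05, T_c = tstar0)
    })
  final_vm <- function(dt) {
    run <- run_simulation(proto, solver_config(dt = dt, dx = 0.1,
                                               snapshot_stride_ms = 1000))
    tail(run$trace_Vm[, 1], 1)
  }
  ref <- final_vm(0.003125)
  dts <- c(0.2, 0.1, 0.05, 0.025)
  errs <- vapply(dts, function(d) abs(final_vm(d) - ref), numeric(1))
  slope <- coef(lm(log(errs) ~ log(dts)))[2]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("planar run bookkeeping and outward activation order", {
  run <- fixture("coarse_strip_37", function() {
    run_simulation(strip_protocol(tstar = 37, duration = 60),
                   strip_config(dt = 0.2, dx = 0.05, dy = 0.04))
  })
  expect_equal(length(run$times), floor(60 / 0.2) + 1)
  expect_equal(nrow(run$trace_Vm), length(run$times))
  ## activation reaches (5.5, y) strictly before (6.5, y)
  up <- function(k) cardiotherm:::.upcrossings(run$times, run$trace_Vm[, k], -80)[1]
  expect_lt(up(1), up(2))
  ## phi_e snapshots keep the mean-zero gauge
  for (sn in run$snapshots) expect_lt(abs(mean(sn$state$phi_e)), 1e-9)
})

test_that("warmer tissue activates the probe earlier", {
  act_at <- function(tstar) {
    run <- run_simulation(strip_protocol(tstar = tstar, duration = 80,
                                         probes_x = c(6, 6.5, 5.5)),
                          strip_config(dt = 0.2, dx = 0.05, dy = 0.04))
    cardiotherm:::.upcrossings(run$times, run$trace_Vm[, 1], -80)[1]
  }
  ## (the 43 degC run legitimately warns that dt <= 0.1 ms is recommended)
  expect_lt(suppressWarnings(act_at(43)), act_at(31))
})

test_that("Newton divergence is reported with the simulated time", {
  cfg <- strip_config(dt = 0.2, dx = 0.05, dy = 0.04)
  cfg$newton_max_iter <- 1L
  expect_error(run_simulation(strip_protocol(duration = 10), cfg),
               "did not converge.*t = ")
})

test_that("bidomain and monodomain agree on CV under proportional tensors", {
  lam <- 1.5
  tissue_prop <- tissue_params(Ge = tensor2(3 / lam, 0.315 / lam))
  base <- strip_protocol(tstar = 37, duration = 70)
  base$tissue <- tissue_prop
  cv <- function(mode) {
    cfg <- strip_config(dt = 0.2, dx = 0.05, dy = 0.04, coupling_mode = mode,
                        lambda = lam)
    run <- run_simulation(base, cfg)
    as.numeric(conduction_velocity(run_trace(run, 1), run_trace(run, 2)))
  }
  cv_bi <- cv("heat_bidomain")
  cv_mono <- cv("heat_monodomain")
  expect_lt(abs(cv_bi - cv_mono) / cv_bi, 0.02)
})
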