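square_pulse <- function(t, lo = -85, hi = 20, on = 10, off = 110) {
  v <- ifelse(t >= on & t < off, hi, lo)
  probe_trace(t, v, position = c(1, 0))
}

test_that("APD measures a square pulse and interpolates a triangle", {
  t <- seq(0, 200, by = 0.5)
  ## crossing times are interpolated inside the jump samples: exact to
  ## within one sample step
  expect_lt(abs(as.numeric(apd(square_pulse(t))) - 100), 0.5)

  ## triangle -85 -> 35 -> -85 over [0, 100]; threshold -80 crossed at
  ## t = 25/12 on the way up and 100 - 25/12 on the way down
  t <- seq(0, 100, by = 0.1)
  v <- ifelse(t <= 50, -85 + 120 * t / 50, 35 - 120 * (t - 50) / 50)
  a <- apd(probe_trace(t, v, position = c(0, 0)))
  expect_equal(as.numeric(a), 95.83333, tolerance = 1e-5)
  expect_equal(attr(a, "threshold"), -80)
})

test_that("APD errors are informative", {
  t <- seq(0, 100, by = 1)
  expect_error(apd(probe_trace(t, rep(-85, length(t)))), "NoActivation")
  expect_error(apd(probe_trace(t, rep(0, length(t)))), "NoRepolarization")
  ## two episodes need an index
  v <- rep(-85, length(t)); v[10:20] <- 0; v[60:70] <- 0
  tr <- probe_trace(t, v)
  expect_error(apd(tr), "episode")
  expect_equal(as.numeric(apd(tr, episode = 1)), as.numeric(apd(tr, episode = 2)))
})

test_that("rise time interpolates within one upstroke", {
  ## linear ramp -85 -> 40 over 2.5 ms: 110 mV span at 50 mV/ms
  t <- seq(0, 5, by = 0.01)
  v <- pmin(-85 + 50 * t, 40)
  expect_equal(as.numeric(rise_time(probe_trace(t, v))), 2.2, tolerance = 1e-9)
  ## instantaneous jump: bounded by one sample step
  t <- seq(0, 20, by = 0.5)
  expect_lte(as.numeric(rise_time(square_pulse(t, hi = 35))), 0.5)
  expect_error(rise_time(probe_trace(t, rep(-85, length(t)))), "NoActivation")
})

test_that("conduction velocity recovers a constructed wave speed", {
  ## translating upstroke Vm(x - ct), c = 0.05 cm/ms = 0.5 m/s
  t <- seq(0, 100, by = 0.1)
  wave <- function(x) {
    arr <- (x - 1) / 0.05
    probe_trace(t, ifelse(t >= arr, 20, -85), position = c(x, 0))
  }
  a <- wave(2); b <- wave(4)
  expect_equal(as.numeric(conduction_velocity(a, b)), 0.5, tolerance = 1e-6)
  ## invariant under swapping the probes
  expect_equal(as.numeric(conduction_velocity(b, a)),
               as.numeric(conduction_velocity(a, b)))
  expect_error(conduction_velocity(a, a), "distinct")
  same_pos <- probe_trace(t, ifelse(t >= 20, 20, -85), position = c(2, 0))
  expect_error(conduction_velocity(a, same_pos), "delay|distinct")
})

test_that("Q10 formulas match the tabulated reference values", {
  ## values measured at 27 and 37 degC
  expect_equal(q10(644, 266, 27, 37, "apd"), 2.42, tolerance = 0.005)
  expect_equal(q10(0.337, 0.741, 27, 37, "cv"), 2.199, tolerance = 0.001)
  expect_equal(q10(100, 100, 27, 37, "apd"), 1)
  expect_equal(q10(0.4, 0.4, 27, 37, "cv"), 1)
  expect_error(q10(-1, 2, 27, 37, "apd"), "positive")
  expect_error(q10(1, 2, 37, 27, "apd"), "exceed")
})

test_that("Q10 is invariant under common rescaling of its inputs", {
  for (s in c(0.01, 1, 250)) {
    expect_equal(q10(644 * s, 266 * s, 27, 37, "apd"),
                 q10(644, 266, 27, 37, "apd"))
    expect_equal(q10(0.337 * s, 0.741 * s, 27, 37, "cv"),
                 q10(0.337, 0.741, 27, 37, "cv"))
  }
})

test_that("termination time scans the snapshot sequence from the tail", {
  g <- grid2d(1, 1, dx = 0.25)
  snap <- function(time, vmax) {
    list(time = time, state = field_state(g, Vm = vmax))
  }
  ## all resting: terminated from the start
  s <- lapply(seq(0, 300, 50), snap, vmax = -85)
  expect_equal(as.numeric(termination_time(s)), 0)
  ## active until 150, quiet afterwards
  s <- c(lapply(c(0, 50, 100, 150), snap, vmax = 10),
         lapply(c(200, 250, 300), snap, vmax = -85))
  expect_equal(as.numeric(termination_time(s)), 200)
  ## persistent activity
  s <- lapply(seq(0, 300, 50), snap, vmax = 0)
  expect_true(is.na(termination_time(s)))
  ## a transient re-excitation resets the clock
  s <- c(lapply(c(0, 50), snap, vmax = -85), list(snap(100, 0)),
         lapply(c(150, 200), snap, vmax = -85))
  expect_equal(as.numeric(termination_time(s)), 150)
  expect_error(termination_time(list()), "empty")
})

test_that("tip detector finds a constructed rotation center and ignores plane waves", {
  g <- grid2d(4, 4, dx = 0.05)
  co <- grid_coords(g)
  ## rigidly rotating Archimedean spiral: Vm = cos(theta - r/lambda + omega t)
  spiral_field <- function(phase) {
    r <- sqrt((co$x - 2)^2 + (co$y - 2)^2)
    th <- atan2(co$y - 2, co$x - 2)
    -22.5 + 60 * cos(th - r / 0.3 + phase)
  }
  tips <- tip_locations(spiral_field(0.4), spiral_field(0), g)
  expect_equal(nrow(tips), 1)
  expect_lt(sqrt(sum((tips[1, ] - c(2, 2))^2)), 2 * g$dx)

  ## translating plane wave has no phase singularity
  plane <- function(shift) -22.5 + 60 * cos((co$x - shift) / 0.3)
  expect_equal(nrow(tip_locations(plane(0.1), plane(0), g)), 0)

  ## deterministic
  t2 <- tip_locations(spiral_field(0.4), spiral_field(0), g)
  expect_identical(tips, t2)
})

test_that("heat accumulation reports the maximum and its location", {
  g <- grid2d(2, 2, dx = 0.25)
  expect_equal(heat_accumulation(matrix(37, g$nx, g$ny), 37, g)$max, 0)
  T_c <- matrix(37, g$nx, g$ny)
  T_c[5, 7] <- 37.002
  h <- heat_accumulation(T_c, 37, g)
  expect_equal(h$max, 0.002)
  expect_equal(unname(h$argmax), c(4 * 0.25, 6 * 0.25))
  expect_equal(dim(h$delta), c(g$nx, g$ny))
})

test_that("Joule heat accumulates at the spiral tip and shrinks under cooling", {
  runs <- fixture("spiral_ordering", spiral_ordering_runs)
  g <- runs$normothermic$grid
  hits <- 0L; tot <- 0L; max_dT_normo <- 0
  for (sn in runs$normothermic$snapshots[-1]) {
    tips <- tip_locations(sn$state$Vm, sn$Vm_prev, g)
    if (!nrow(tips)) next
    h <- heat_accumulation(sn$state$T, 37, g)
    max_dT_normo <- max(max_dT_normo, h$max)
    d <- min(sqrt((tips[, 1] - h$argmax[1])^2 + (tips[, 2] - h$argmax[2])^2))
    tot <- tot + 1L
    hits <- hits + (d <= 0.5)
  }
  expect_gt(tot, 3)
  expect_gte(hits / tot, 0.6)
  ## self-heating is on the micro-degC scale
  expect_gt(max_dT_normo, 1e-7)
  expect_lt(max_dT_normo, 1e-3)

  ## under global hypothermia conduction is slower, gradients are weaker and
  ## the accumulated heat is smaller (compared over the same time span)
  horizon <- max(vapply(runs$normothermic$snapshots, `[[`, numeric(1), "time"))
  max_dT_hypo <- 0
  for (sn in runs$hypothermia$snapshots[-1]) {
    if (sn$time > horizon) break
    max_dT_hypo <- max(max_dT_hypo, heat_accumulation(sn$state$T, 30, g)$max)
  }
  expect_lt(max_dT_hypo, max_dT_normo)
})
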