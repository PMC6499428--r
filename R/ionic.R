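#' Dimensional voltage scaling of the two-variable ionic models
#'
#' Both phenomenological ionic models are formulated on a normalized voltage
#' `u = (Vm - v_rest)/v_amp` and rescaled to physiological millivolts. The
#' defaults give a resting potential of -85 mV, a peak of 40 mV and an action
#' potential amplitude of 125 mV.
#'
#' @param v_rest Resting membrane potential, mV.
#' @param v_peak Peak membrane potential, mV.
#' @return An object of class `"voltage_scale"` with fields `v_rest`, `v_peak`
#'   and the derived amplitude `v_amp = v_peak - v_rest`.
#' @export
#' @examples
#' sc <- voltage_scale()
#' sc$v_amp # 125 mV
voltage_scale <- function(v_rest = -85, v_peak = 40) {
  if (!(v_peak > v_rest)) stop("v_peak must exceed v_rest")
  structure(list(v_rest = v_rest, v_peak = v_peak, v_amp = v_peak - v_rest),
            class = "voltage_scale")
}

#' Mitchell-Schaeffer model parameters
#'
#' Time constants of the dimensional Mitchell-Schaeffer model. The defaults
#' are calibrated so that, in tissue with the default conductivities, the
#' action potential has an upstroke of about 1 ms and a conduction velocity of
#' about 0.7 m/s at 37 degrees C.
#'
#' @param tau_in,tau_out Fast inward / slow outward current time constants, ms.
#' @param tau_open,tau_close Gate opening / closing time constants, ms.
#' @param v_gate Dimensionless threshold on the normalized voltage `u` that
#'   switches the gate between its opening and closing branches.
#' @return An object of class `"ms_params"`.
#' @export
ms_params <- function(tau_in = 0.05, tau_out = 1, tau_open = 95,
                      tau_close = 162, v_gate = 0.13) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0,
            v_gate > 0, v_gate < 1)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate),
            class = "ms_params")
}

#' Aliev-Panfilov model parameters
#'
#' Dimensionless parameters of the Aliev-Panfilov model; the cubic-root
#' voltage `v_a = v_amp * a + v_rest` (mV) is derived from the excitation
#' threshold `a` wherever a [voltage_scale()] is supplied. Both model
#' equations carry the fixed 1/12.9 per-ms time-scale factor (the model's
#' 12.9 ms time unit).
#'
#' @param k Strength of the cubic ionic current, dimensionless.
#' @param a Excitation threshold, dimensionless. Spiral-wave experiments use
#'   `a = 0.1`.
#' @param mu1,mu2 Recovery-rate shape parameters, dimensionless.
#' @param eps0 Baseline recovery rate, dimensionless.
#' @return An object of class `"ap_params"`.
#' @export
ap_params <- function(k = 8, a = 0.15, mu1 = 0.2, mu2 = 0.3, eps0 = 0.002) {
  stopifnot(k > 0, a > 0, a < 1, mu1 >= 0, mu2 > 0, eps0 > 0)
  structure(list(k = k, a = a, mu1 = mu1, mu2 = mu2, eps0 = eps0),
            class = "ap_params")
}

#' Thermal coupling constants of the ionic kinetics
#'
#' Temperature enters the ionic models through two multiplicative factors:
#' a linear factor `A * (1 + B * (T - T_a))` on the ionic current and a
#' Q10-type factor `Q ^ ((T - T_a) / 10)` on the gating rate, both equal to 1
#' at the reference temperature `T_a` (37 degrees C for cardiac cells).
#'
#' @param A Dimensionless current-factor gain.
#' @param B Linear temperature sensitivity of the current, 1/degC.
#' @param Q Q10 coefficient of the gating kinetics, dimensionless.
#' @param T_a Reference temperature, degC.
#' @param model Convenience: `"ms"` or `"ap"` fills the per-model default `B`
#'   (0.07 for Mitchell-Schaeffer, 0.081 for Aliev-Panfilov).
#' @return An object of class `"thermo_coupling"`.
#' @export
thermo_coupling <- function(A = 1, B = NULL, Q = 2.4, T_a = 37,
                            model = c("ms", "ap")) {
  model <- match.arg(model)
  if (is.null(B)) B <- if (model == "ms") 0.07 else 0.081
  stopifnot(Q > 0)
  structure(list(A = A, B = B, Q = Q, T_a = T_a), class = "thermo_coupling")
}

#' Normalized membrane voltage
#'
#' Affine map from millivolts to the dimensionless voltage used by the ionic
#' models: `u = (Vm - v_rest) / v_amp`, so rest maps to 0 and peak to 1.
#'
#' @param Vm Membrane potential, mV (vectorized).
#' @param scale A [voltage_scale()].
#' @return Dimensionless `u`, same shape as `Vm`.
#' @export
normalized_voltage <- function(Vm, scale = voltage_scale()) {
  (Vm - scale$v_rest) / scale$v_amp
}

#' Temperature factor on the ionic current
#'
#' Returns `A * (1 + B * (T - T_a))`, the linear factor scaling the total
#' ionic current with temperature. Equals `A` at `T = T_a`. A warning (not an
#' error) is emitted if the factor is non-positive, which happens only in the
#' physically meaningless regime `T < T_a - 1/B`.
#'
#' @param T_c Temperature, degC (vectorized).
#' @param tc A [thermo_coupling()].
#' @return Dimensionless factor, same shape as `T_c`.
#' @export
thermal_current_factor <- function(T_c, tc = thermo_coupling()) {
  f <- tc$A * (1 + tc$B * (T_c - tc$T_a))
  if (any(f <= 0)) {
    warning("thermal current factor is non-positive for some temperatures ",
            "(T below T_a - 1/B); results are physically meaningless there")
  }
  f
}

#' Temperature factor on the gating rate
#'
#' Returns the Q10 scaling `Q ^ ((T - T_a) / 10)` applied to the gating-rate
#' function. Strictly positive, equal to 1 at `T = T_a`, and satisfying the
#' exact property `factor(T + 10) / factor(T) = Q`.
#'
#' @inheritParams thermal_current_factor
#' @return Dimensionless factor, same shape as `T_c`.
#' @export
thermal_gate_factor <- function(T_c, tc = thermo_coupling()) {
  stopifnot(tc$Q > 0)
  tc$Q ^ ((T_c - tc$T_a) / 10)
}

#' Mitchell-Schaeffer ionic current
#'
#' `I_ion = (v_amp / tau_in) * W * u^2 * (u - 1) + v_amp * u / tau_out`
#' with `u = normalized_voltage(Vm)`; microA/cm^2. The repolarizing term uses
#' the dimensionally consistent form `(Vm - v_rest)/tau_out`. Vanishes
#' identically at `Vm = v_rest` for all `W`.
#'
#' @param Vm Membrane potential, mV (vectorized).
#' @param W Gating variable in `[0, 1]` (vectorized, recycled with `Vm`).
#' @param p [ms_params()].
#' @param scale [voltage_scale()].
#' @return Ionic current density, microA/cm^2.
#' @export
ms_current <- function(Vm, W, p = ms_params(), scale = voltage_scale()) {
  u <- normalized_voltage(Vm, scale)
  (scale$v_amp / p$tau_in) * W * u^2 * (u - 1) + scale$v_amp * u / p$tau_out
}

#' Mitchell-Schaeffer gating rate
#'
#' Piecewise rate `(1 - W)/tau_open` for `u < v_gate` and `-W/tau_close` for
#' `u >= v_gate` (the closing branch is taken at equality); 1/ms.
#'
#' @inheritParams ms_current
#' @return Gating rate dW/dt, 1/ms.
#' @export
ms_gate_rate <- function(Vm, W, p = ms_params(), scale = voltage_scale()) {
  u <- normalized_voltage(Vm, scale)
  ifelse(u < p$v_gate, (1 - W) / p$tau_open, -W / p$tau_close)
}

## branch mask (TRUE = closing branch, u >= v_gate); NULL for models with
## smooth kinetics. The implicit solvers freeze this mask over a whole time
## step (evaluated at the step's starting state) so the within-step Newton
## system is smooth; the gate switches branches between steps, an O(dt) lag.
.gate_branch <- function(m, Vm) {
  if (m$model != "ms") return(NULL)
  normalized_voltage(Vm, m$scale) >= m$params$v_gate
}

.ms_gate_rate_mask <- function(Vm, W, p, closing) {
  ifelse(closing, -W / p$tau_close, (1 - W) / p$tau_open)
}

#' Aliev-Panfilov ionic current
#'
#' `I_ion = (1/12.9) * ((k / v_amp^2) * (Vm - v_rest) * (Vm - v_a) *
#' (Vm - v_peak) + (Vm - v_rest) * W)` with `v_a = v_amp * a + v_rest`;
#' microA/cm^2. Cubic in `Vm`, vanishing at `Vm = v_rest` for all `W`. The
#' 1/12.9 per-ms factor is the dimensionalization of the model's single time
#' unit (12.9 ms) and therefore scales the whole right-hand side of both the
#' voltage and the recovery equation; without it on the current, the voltage
#' kinetics would be an order of magnitude faster than the recovery and the
#' model loses its reentrant-wave regime on centimeter-scale tissue.
#'
#' @param Vm Membrane potential, mV (vectorized).
#' @param W Recovery variable, non-negative (vectorized).
#' @param p [ap_params()].
#' @param scale [voltage_scale()].
#' @return Ionic current density, microA/cm^2.
#' @export
ap_current <- function(Vm, W, p = ap_params(), scale = voltage_scale()) {
  v_a <- scale$v_amp * p$a + scale$v_rest
  ((p$k / scale$v_amp^2) * (Vm - scale$v_rest) * (Vm - v_a) * (Vm - scale$v_peak) +
    (Vm - scale$v_rest) * W) / 12.9
}

#' Aliev-Panfilov recovery rate
#'
#' `F_ion = (1/12.9) * (eps0 + mu1 * W / (u + mu2)) *
#' (-W - k * u * (u - a - 1))`, 1/ms, with `u = normalized_voltage(Vm)`.
#' The 1/12.9 factor is the model's fixed time rescaling, carried in 1/ms.
#'
#' @inheritParams ap_current
#' @return Recovery rate dW/dt, 1/ms.
#' @export
ap_gate_rate <- function(Vm, W, p = ap_params(), scale = voltage_scale()) {
  u <- normalized_voltage(Vm, scale)
  if (any(u + p$mu2 == 0)) {
    stop("degenerate Aliev-Panfilov parameterization: u + mu2 = 0")
  }
  (1 / 12.9) * (p$eps0 + p$mu1 * W / (u + p$mu2)) *
    (-W - p$k * u * (u - p$a - 1))
}

## Analytic derivatives used by the Newton solvers (internal). Branch choice
## in the MS gate is frozen at the supplied (Vm, W) iterate.

.ms_dIdV <- function(Vm, W, p, scale) {
  u <- normalized_voltage(Vm, scale)
  (1 / p$tau_in) * W * (3 * u^2 - 2 * u) + 1 / p$tau_out
}

.ms_dIdW <- function(Vm, W, p, scale) {
  u <- normalized_voltage(Vm, scale)
  (scale$v_amp / p$tau_in) * u^2 * (u - 1)
}

.ms_dFdV <- function(Vm, W, p, scale) {
  Vm * 0
}

.ms_dFdW <- function(Vm, W, p, scale) {
  u <- normalized_voltage(Vm, scale)
  ifelse(u < p$v_gate, -1 / p$tau_open, -1 / p$tau_close)
}

.ms_dFdW_mask <- function(W, p, closing) {
  ifelse(closing, -1 / p$tau_close, -1 / p$tau_open)
}

.ap_dIdV <- function(Vm, W, p, scale) {
  v_a <- scale$v_amp * p$a + scale$v_rest
  d1 <- Vm - scale$v_rest
  d2 <- Vm - v_a
  d3 <- Vm - scale$v_peak
  ((p$k / scale$v_amp^2) * (d2 * d3 + d1 * d3 + d1 * d2) + W) / 12.9
}

.ap_dIdW <- function(Vm, W, p, scale) {
  (Vm - scale$v_rest) / 12.9
}

.ap_dFdV <- function(Vm, W, p, scale) {
  u <- normalized_voltage(Vm, scale)
  g <- p$eps0 + p$mu1 * W / (u + p$mu2)
  h <- -W - p$k * u * (u - p$a - 1)
  dg <- -p$mu1 * W / (u + p$mu2)^2 / scale$v_amp
  dh <- -p$k * (2 * u - p$a - 1) / scale$v_amp
  (1 / 12.9) * (dg * h + g * dh)
}

.ap_dFdW <- function(Vm, W, p, scale) {
  u <- normalized_voltage(Vm, scale)
  g <- p$eps0 + p$mu1 * W / (u + p$mu2)
  h <- -W - p$k * u * (u - p$a - 1)
  (1 / 12.9) * ((p$mu1 / (u + p$mu2)) * h - g)
}

#' Assemble an ionic model specification
#'
#' Bundles the kinetics choice, its parameters, the voltage scaling and the
#' thermal coupling constants into a single object consumed by the cell and
#' tissue solvers.
#'
#' @param model `"ms"` (Mitchell-Schaeffer) or `"ap"` (Aliev-Panfilov).
#' @param params [ms_params()] or [ap_params()]; defaults per model.
#' @param thermo [thermo_coupling()]; defaults per model.
#' @param scale [voltage_scale()].
#' @return An object of class `"ionic_model"`.
#' @export
#' @examples
#' m <- ionic_model("ms")
#' ionic_current(m, Vm = -22.5, W = 1) # -250 microA/cm^2
ionic_model <- function(model = c("ms", "ap"), params = NULL, thermo = NULL,
                        scale = voltage_scale()) {
  model <- match.arg(model)
  if (is.null(params)) params <- if (model == "ms") ms_params() else ap_params()
  if (is.null(thermo)) thermo <- thermo_coupling(model = model)
  ok <- if (model == "ms") inherits(params, "ms_params") else inherits(params, "ap_params")
  if (!ok) stop("params class does not match the chosen model")
  structure(list(model = model, params = params, thermo = thermo, scale = scale),
            class = "ionic_model")
}

#' @export
print.ionic_model <- function(x, ...) {
  name <- if (x$model == "ms") "Mitchell-Schaeffer" else "Aliev-Panfilov"
  cat(sprintf("<ionic_model> %s (dimensional)\n", name))
  cat(sprintf("  voltage scale: rest %g mV, peak %g mV, amplitude %g mV\n",
              x$scale$v_rest, x$scale$v_peak, x$scale$v_amp))
  cat("  parameters: ",
      paste(sprintf("%s=%g", names(x$params), unlist(x$params)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  thermal coupling: A=%g, B=%g /degC, Q=%g, T_a=%g degC\n",
              x$thermo$A, x$thermo$B, x$thermo$Q, x$thermo$T_a))
  invisible(x)
}

#' Evaluate the ionic current of a model specification
#'
#' @param m An [ionic_model()].
#' @param Vm,W State (vectorized).
#' @return Ionic current density, microA/cm^2.
#' @export
ionic_current <- function(m, Vm, W) {
  if (m$model == "ms") ms_current(Vm, W, m$params, m$scale)
  else ap_current(Vm, W, m$params, m$scale)
}

#' Evaluate the gating/recovery rate of a model specification
#'
#' @inheritParams ionic_current
#' @return dW/dt, 1/ms.
#' @export
ionic_gate_rate <- function(m, Vm, W) {
  if (m$model == "ms") ms_gate_rate(Vm, W, m$params, m$scale)
  else ap_gate_rate(Vm, W, m$params, m$scale)
}

## gating rate with an optionally frozen MS branch mask
.gate_rate <- function(m, Vm, W, branch = NULL) {
  if (m$model == "ms" && !is.null(branch)) {
    .ms_gate_rate_mask(Vm, W, m$params, branch)
  } else {
    ionic_gate_rate(m, Vm, W)
  }
}

.ionic_derivs <- function(m, Vm, W, branch = NULL) {
  if (m$model == "ms") {
    dFdW <- if (is.null(branch)) .ms_dFdW(Vm, W, m$params, m$scale)
            else .ms_dFdW_mask(W, m$params, branch)
    list(dIdV = .ms_dIdV(Vm, W, m$params, m$scale),
         dIdW = .ms_dIdW(Vm, W, m$params, m$scale),
         dFdV = .ms_dFdV(Vm, W, m$params, m$scale),
         dFdW = dFdW)
  } else {
    list(dIdV = .ap_dIdV(Vm, W, m$params, m$scale),
         dIdW = .ap_dIdW(Vm, W, m$params, m$scale),
         dFdV = .ap_dFdV(Vm, W, m$params, m$scale),
         dFdW = .ap_dFdW(Vm, W, m$params, m$scale))
  }
}

#' Resting state of an ionic model
#'
#' Mitchell-Schaeffer rests at `(v_rest, W = 1)` (gate fully open);
#' Aliev-Panfilov rests at `(v_rest, W = 0)`.
#'
#' @param m An [ionic_model()].
#' @return List with `Vm` (mV) and `W`.
#' @export
rest_state <- function(m) {
  list(Vm = m$scale$v_rest, W = if (m$model == "ms") 1 else 0)
}

#' Integrate a single cell (0-D) at fixed temperature
#'
#' Space-clamped restriction of the tissue model: `Cm dVm/dt = -fI * I_ion`,
#' `dW/dt = fF * F_ion`, where `fI` and `fF` are the thermal factors evaluated
#' at the constant temperature `T_c`. Integrated with BDF2 (one backward-Euler
#' startup step) and a damped Newton solve per step, the same scheme as the
#' tissue integrator.
#'
#' @param m An [ionic_model()].
#' @param T_c Temperature, degC.
#' @param init List with `Vm` (mV) and `W`; default [rest_state()].
#' @param duration Total simulated time, ms.
#' @param dt Time step, ms (default 0.01; the cell upstroke of ~1 ms needs a
#'   finer step than the tissue default of 0.3 ms).
#' @param Cm Membrane capacitance, microF/cm^2.
#' @param newton_tol,newton_max_iter Newton stopping controls.
#' @return A data.frame with columns `time_ms`, `Vm_mV`, `W`, `T_C` of length
#'   `floor(duration/dt) + 1`.
#' @export
#' @examples
#' m <- ionic_model("ms")
#' tr <- cell_simulate(m, T_c = 37, init = list(Vm = 0, W = 1),
#'                     duration = 5, dt = 0.05)
#' range(tr$Vm_mV)
cell_simulate <- function(m, T_c = 37, init = rest_state(m), duration, dt = 0.01,
                          Cm = 1, newton_tol = 1e-10, newton_max_iter = 50) {
  stopifnot(dt > 0, duration >= dt)
  fI <- thermal_current_factor(T_c, m$thermo)
  fF <- thermal_gate_factor(T_c, m$thermo)
  n <- floor(duration / dt)
  V <- numeric(n + 1); W <- numeric(n + 1)
  V[1] <- init$Vm; W[1] <- init$W

  step_newton <- function(gam, rhsV, rhsW, V0, W0, istep) {
    v <- V0; w <- W0
    branch <- .gate_branch(m, V0)
    for (it in seq_len(newton_max_iter)) {
      rV <- Cm * (gam * v - rhsV) + fI * ionic_current(m, v, w)
      rW <- (gam * w - rhsW) - fF * .gate_rate(m, v, w, branch)
      res <- max(abs(rV), abs(rW))
      if (res < newton_tol * max(1, abs(Cm * gam * v), abs(gam * w))) {
        return(c(v, w))
      }
      d <- .ionic_derivs(m, v, w, branch)
      j11 <- Cm * gam + fI * d$dIdV
      j12 <- fI * d$dIdW
      j21 <- -fF * d$dFdV
      j22 <- gam - fF * d$dFdW
      det <- j11 * j22 - j12 * j21
      if (abs(det) < 1e-300) stop("singular cell Newton system at step ", istep)
      dv <- (-rV * j22 + rW * j12) / det
      dw <- (j21 * rV - j11 * rW) / det
      v <- v + dv; w <- w + dw
    }
    stop("cell integrator Newton failed to converge at step ", istep)
  }

  ## backward-Euler startup step
  s <- step_newton(1 / dt, V[1] / dt, W[1] / dt, V[1], W[1], 1L)
  V[2] <- s[1]; W[2] <- s[2]
  gam <- 3 / (2 * dt)
  if (n >= 2) {
    for (i in 2:n) {
      rhsV <- (4 * V[i] - V[i - 1]) / (2 * dt)
      rhsW <- (4 * W[i] - W[i - 1]) / (2 * dt)
      s <- step_newton(gam, rhsV, rhsW, V[i], W[i], i)
      V[i + 1] <- s[1]; W[i + 1] <- s[2]
    }
  }
  data.frame(time_ms = dt * (0:n), Vm_mV = V, W = W, T_C = T_c)
}
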