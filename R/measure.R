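#' Membrane-potential trace at a probe
#'
#' @param time_ms Strictly increasing, uniformly spaced time axis, ms.
#' @param Vm_mV Membrane potential samples, mV.
#' @param position Probe location `(x, y)`, cm.
#' @return An object of class `"probe_trace"`.
#' @export
probe_trace <- function(time_ms, Vm_mV, position = c(NA_real_, NA_real_)) {
  stopifnot(length(time_ms) == length(Vm_mV), length(time_ms) >= 2)
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)) {
    stop("time axis must be strictly increasing with constant step")
  }
  structure(list(t = as.numeric(time_ms), Vm = as.numeric(Vm_mV),
                 position = as.numeric(position)),
            class = "probe_trace")
}

#' @export
print.probe_trace <- function(x, ...) {
  cat(sprintf("<probe_trace> at (%g, %g) cm: %d samples, dt = %g ms, Vm in [%.1f, %.1f] mV\n",
              x$position[1], x$position[2], length(x$t), x$t[2] - x$t[1],
              min(x$Vm), max(x$Vm)))
  invisible(x)
}

## linearly interpolated upward crossing times of `level`; a trace that
## starts at/above level opens an episode at t[1]
.upcrossings <- function(t, v, level) {
  idx <- which(v[-length(v)] < level & v[-1] >= level)
  tc <- t[idx] + (level - v[idx]) / (v[idx + 1] - v[idx]) * (t[idx + 1] - t[idx])
  if (v[1] >= level) tc <- c(t[1], tc)
  tc
}

.downcrossings <- function(t, v, level) {
  idx <- which(v[-length(v)] >= level & v[-1] < level)
  t[idx] + (v[idx] - level) / (v[idx] - v[idx + 1]) * (t[idx + 1] - t[idx])
}

#' Action potential duration
#'
#' Duration for which the membrane potential is maintained above the
#' threshold (default -80 mV): linearly interpolated down-crossing time minus
#' up-crossing time of one supra-threshold episode.
#'
#' @param trace A [probe_trace()].
#' @param threshold Threshold, mV.
#' @param episode Episode index for multi-episode traces; a trace with
#'   several episodes and no explicit index is an error.
#' @return APD, ms, with attribute `"threshold"`.
#' @export
apd <- function(trace, threshold = -80, episode = NULL) {
  up <- .upcrossings(trace$t, trace$Vm, threshold)
  if (!length(up)) stop("NoActivation: trace never exceeds the threshold")
  dn <- .downcrossings(trace$t, trace$Vm, threshold)
  if (length(up) > 1L && is.null(episode)) {
    stop("trace contains ", length(up),
         " supra-threshold episodes; supply an episode index")
  }
  k <- if (is.null(episode)) 1L else as.integer(episode)
  if (k > length(up)) stop("episode index exceeds the number of episodes")
  dn_k <- dn[dn > up[k]]
  if (!length(dn_k)) {
    stop("NoRepolarization: potential still above threshold at trace end")
  }
  structure(dn_k[1] - up[k], threshold = threshold)
}

#' Action-potential rise time
#'
#' Time for the upstroke to rise from `lo` (default -80 mV) to `hi`
#' (default 30 mV), using linearly interpolated crossings within the same
#' upstroke.
#'
#' @param trace A [probe_trace()].
#' @param lo,hi Lower/upper levels, mV.
#' @return Rise time, ms, with attributes `"lo"`, `"hi"`.
#' @export
rise_time <- function(trace, lo = -80, hi = 30) {
  t_lo <- .upcrossings(trace$t, trace$Vm, lo)
  if (!length(t_lo)) stop("NoActivation: trace never reaches the lower level")
  t_hi <- .upcrossings(trace$t, trace$Vm, hi)
  t_hi <- t_hi[t_hi >= t_lo[1]]
  if (!length(t_hi)) stop("trace never reaches the upper level after activation")
  structure(t_hi[1] - t_lo[1], lo = lo, hi = hi)
}

#' Conduction velocity between two probes
#'
#' Euclidean probe distance divided by the difference of the first
#' interpolated upward threshold crossings, converted to m/s
#' (cm/ms x 10 = m/s). Positive by convention (invariant under swapping the
#' probes).
#'
#' @param trace_a,trace_b [probe_trace()]s at two distinct, both-activating
#'   probes on the propagation axis.
#' @param threshold Activation threshold, mV.
#' @return Conduction velocity, m/s, with attribute `"threshold"`.
#' @export
conduction_velocity <- function(trace_a, trace_b, threshold = -80) {
  d <- sqrt(sum((trace_a$position - trace_b$position)^2))
  if (!is.finite(d) || d == 0) stop("probes must be distinct")
  ta <- .upcrossings(trace_a$t, trace_a$Vm, threshold)
  tb <- .upcrossings(trace_b$t, trace_b$Vm, threshold)
  if (!length(ta) || !length(tb)) stop("NoActivation at one of the probes")
  delay <- abs(tb[1] - ta[1])
  if (delay <= 0) stop("non-positive activation delay between probes")
  structure(d / delay * 10, threshold = threshold)
}

#' Q10 temperature coefficient
#'
#' Factor by which a quantity changes per 10 degC. For APD (which lengthens
#' on cooling) `Q10 = (cold/warm)^(10/(T_warm - T_cold))`; for conduction
#' velocity (which slows on cooling) the exponent's sign flips:
#' `Q10 = (cold/warm)^(10/(T_cold - T_warm))`.
#'
#' @param cold_value,warm_value Measured values at the two temperatures.
#' @param T_cold,T_warm Temperatures, degC (`T_warm > T_cold`).
#' @param kind `"apd"` or `"cv"`.
#' @return Dimensionless Q10.
#' @export
#' @examples
#' q10(644, 266, 27, 37, "apd") # about 2.42
#' q10(0.337, 0.741, 27, 37, "cv") # about 2.20
q10 <- function(cold_value, warm_value, T_cold, T_warm, kind = c("apd", "cv")) {
  kind <- match.arg(kind)
  if (cold_value <= 0 || warm_value <= 0) stop("values must be positive")
  if (!(T_warm > T_cold)) stop("T_warm must exceed T_cold")
  expo <- if (kind == "apd") 10 / (T_warm - T_cold) else 10 / (T_cold - T_warm)
  (cold_value / warm_value)^expo
}

#' Termination time of electrical activity
#'
#' Earliest snapshot time from which the maximum membrane potential stays
#' below the threshold (default -70 mV) for the remainder of the run, or `NA`
#' if activity persists to the end.
#'
#' @param snapshots A `cardiotherm_run` or its `snapshots` list (elements
#'   with `time` and `state`).
#' @param threshold Quiescence threshold, mV.
#' @return Termination time, ms, or `NA_real_`; attribute `"threshold"`.
#' @export
termination_time <- function(snapshots, threshold = -70) {
  if (inherits(snapshots, "cardiotherm_run")) snapshots <- snapshots$snapshots
  if (!length(snapshots)) stop("empty snapshot sequence")
  mx <- vapply(snapshots, function(s) max(s$state$Vm), numeric(1))
  tms <- vapply(snapshots, function(s) s$time, numeric(1))
  below <- rev(cumprod(rev(mx < threshold))) > 0 # quiet from here onward
  if (!any(below)) return(structure(NA_real_, threshold = threshold))
  structure(tms[which(below)[1]], threshold = threshold)
}

#' Spiral-tip locations
#'
#' Phase singularities located as intersections of the `Vm = iso` isoline
#' with the zero isoline of the temporal difference `Vm - Vm_prev` (the
#' standard isopotential-crossing tip definition) between two consecutive
#' snapshots. Intersections are found per grid cell from the bilinear
#' interpolants and nearby duplicates are merged. Empty for plane waves.
#'
#' @param Vm,Vm_prev Consecutive `nx x ny` snapshots of the potential, mV.
#' @param grid A [grid2d()].
#' @param iso Isopotential level, mV (default the mid-amplitude -22.5 mV).
#' @param merge_radius Cluster radius for duplicate suppression, cm (default
#'   `3 * max(dx, dy)`).
#' @return Matrix with columns `x`, `y` (cm), one row per tip (0 rows if
#'   none).
#' @export
tip_locations <- function(Vm, Vm_prev, grid, iso = -22.5,
                          merge_radius = 3 * max(grid$dx, grid$dy)) {
  f <- Vm - iso
  g <- Vm - Vm_prev
  nx <- grid$nx; ny <- grid$ny
  f00 <- f[-nx, -ny]; f10 <- f[-1, -ny]; f01 <- f[-nx, -1]; f11 <- f[-1, -1]
  g00 <- g[-nx, -ny]; g10 <- g[-1, -ny]; g01 <- g[-nx, -1]; g11 <- g[-1, -1]
  fmin <- pmin(f00, f10, f01, f11); fmax <- pmax(f00, f10, f01, f11)
  gmin <- pmin(g00, g10, g01, g11); gmax <- pmax(g00, g10, g01, g11)
  cand <- which(fmin < 0 & fmax > 0 & gmin < 0 & gmax > 0, arr.ind = TRUE)
  pts <- matrix(numeric(0), 0, 2)
  if (nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      a <- c(f00[i, j], f10[i, j], f01[i, j], f11[i, j])
      b <- c(g00[i, j], g10[i, j], g01[i, j], g11[i, j])
      s <- 0.5; tt <- 0.5
      ok <- FALSE
      for (it in 1:20) {
        Fv <- a[1] * (1 - s) * (1 - tt) + a[2] * s * (1 - tt) +
          a[3] * (1 - s) * tt + a[4] * s * tt
        Gv <- b[1] * (1 - s) * (1 - tt) + b[2] * s * (1 - tt) +
          b[3] * (1 - s) * tt + b[4] * s * tt
        if (abs(Fv) < 1e-10 && abs(Gv) < 1e-10) { ok <- TRUE; break }
        dFs <- (a[2] - a[1]) * (1 - tt) + (a[4] - a[3]) * tt
        dFt <- (a[3] - a[1]) * (1 - s) + (a[4] - a[2]) * s
        dGs <- (b[2] - b[1]) * (1 - tt) + (b[4] - b[3]) * tt
        dGt <- (b[3] - b[1]) * (1 - s) + (b[4] - b[2]) * s
        det <- dFs * dGt - dFt * dGs
        if (abs(det) < 1e-14) break
        ds <- (-Fv * dGt + Gv * dFt) / det
        dtt <- (dGs * Fv - dFs * Gv) / det
        s <- s + ds; tt <- tt + dtt
        if (s < -0.5 || s > 1.5 || tt < -0.5 || tt > 1.5) break
      }
      if (ok && s >= -0.01 && s <= 1.01 && tt >= -0.01 && tt <= 1.01) {
        pts <- rbind(pts, c((i - 1 + s) * grid$dx, (j - 1 + tt) * grid$dy))
      }
    }
  }
  if (nrow(pts) > 1L) {
    keep <- rep(TRUE, nrow(pts))
    for (r in 2:nrow(pts)) {
      if (!keep[r]) next
      for (q in 1:(r - 1)) {
        if (keep[q] &&
            sum((pts[r, ] - pts[q, ])^2) < merge_radius^2) {
          keep[r] <- FALSE
          break
        }
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Joule heat accumulation relative to the setpoint
#'
#' @param T_c Temperature field, degC.
#' @param Tstar Setpoint field (scalar or matrix), degC.
#' @param grid A [grid2d()].
#' @return List with the `delta` field `T - T*`, its maximum `max` (degC) and
#'   the location `argmax` `(x, y)` (cm).
#' @export
heat_accumulation <- function(T_c, Tstar, grid) {
  delta <- T_c - .expand_field(Tstar, grid, "Tstar")
  k <- which.max(delta)
  i <- (k - 1L) %% grid$nx + 1L
  j <- (k - 1L) %/% grid$nx + 1L
  list(delta = delta, max = delta[k],
       argmax = c(x = (i - 1) * grid$dx, y = (j - 1) * grid$dy))
}

#' Measure a finished planar run
#'
#' Convenience extraction of APD, rise time and conduction velocity from a
#' `planar_q10`-style run whose probes are (CV pair, APD probe).
#'
#' @param run A `cardiotherm_run`.
#' @param cv_probes Indices of the two conduction-velocity probes.
#' @param apd_probe Index of the APD/rise-time probe.
#' @param apd_threshold,rise_lo,rise_hi Thresholds, mV.
#' @return An object of class `"measurement_result"` with fields `apd_ms`,
#'   `rise_time_ms`, `cv_m_per_s` and the thresholds used.
#' @export
measure_run <- function(run, cv_probes = c(1L, 2L), apd_probe = 3L,
                        apd_threshold = -80, rise_lo = -80, rise_hi = 30) {
  tr_apd <- run_trace(run, apd_probe)
  a <- apd(tr_apd, threshold = apd_threshold)
  r <- rise_time(tr_apd, lo = rise_lo, hi = rise_hi)
  cv <- conduction_velocity(run_trace(run, cv_probes[1]),
                            run_trace(run, cv_probes[2]),
                            threshold = apd_threshold)
  structure(list(apd_ms = as.numeric(a), rise_time_ms = as.numeric(r),
                 cv_m_per_s = as.numeric(cv),
                 thresholds = list(apd = apd_threshold, rise = c(rise_lo, rise_hi),
                                   cv = apd_threshold)),
            class = "measurement_result")
}

#' @export
print.measurement_result <- function(x, ...) {
  cat(sprintf("APD  %8.1f ms   (above %g mV)\n", x$apd_ms, x$thresholds$apd))
  cat(sprintf("rise %8.3f ms   (%g to %g mV)\n", x$rise_time_ms,
              x$thresholds$rise[1], x$thresholds$rise[2]))
  cat(sprintf("CV   %8.3f m/s (first %g mV crossings)\n", x$cv_m_per_s,
              x$thresholds$cv))
  invisible(x)
}
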