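#' Solver configuration
#'
#' Controls of the staggered implicit integrator: BDF2 (Gear) in time with a
#' Newton solve of the monolithic electrics block (transmembrane and
#' extracellular potentials and gating variable, with the temperature lagged
#' one step), followed by the linear bioheat solve using the fresh potential.
#'
#' @param dt Time step, ms (default 0.3).
#' @param dx,dy Grid spacing, cm (resolution is a configuration choice).
#' @param newton_tol Relative residual tolerance of the Newton iteration.
#' @param newton_max_iter Maximum Newton iterations per step.
#' @param linear_tol Residual tolerance of linear sub-solves (direct sparse
#'   factorization is used; this guards the elliptic solve).
#' @param scheme Time discretization; only `"bdf2"` (with one backward-Euler
#'   startup step).
#' @param coupling_mode `"heat_bidomain"` (full model), `"heat_monodomain"`
#'   (scalar reduction, elliptic solve skipped), or `"ionic_only_static_T"`
#'   (temperature pinned to the setpoint field; heat equation skipped, so
#'   temperature enters through the ionic factors only).
#' @param lambda Anisotropy ratio used by the monodomain reduction.
#' @param joule_source `"simplified"` (`Gi grad Vm . grad Vm`, the form used
#'   for all production simulations) or `"full"` (intra- plus extracellular).
#' @param snapshot_stride_ms Interval between stored field snapshots, ms.
#' @param trace_T Also record temperature at the probes?
#' @param strip_thermal Testing aid: force both thermal factors to exactly 1
#'   and freeze the temperature field (a plain isothermal bidomain solver).
#' @param stop_when_quiescent Stop early once the whole tissue has been below
#'   `quiescence_threshold_mV` for `quiescence_hold_ms` (used by termination
#'   studies; the early-stopped tail is electrically dead).
#' @param quiescence_threshold_mV,quiescence_hold_ms Early-stop controls.
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(dt = 0.3, dx = 0.025, dy = dx,
                          newton_tol = 1e-8, newton_max_iter = 20,
                          linear_tol = 1e-8,
                          scheme = "bdf2",
                          coupling_mode = c("heat_bidomain", "heat_monodomain",
                                            "ionic_only_static_T"),
                          lambda = 1,
                          joule_source = c("simplified", "full"),
                          snapshot_stride_ms = 30,
                          trace_T = TRUE,
                          strip_thermal = FALSE,
                          stop_when_quiescent = FALSE,
                          quiescence_threshold_mV = -70,
                          quiescence_hold_ms = 150) {
  stopifnot(dt > 0, newton_max_iter >= 1, dx > 0, dy > 0, lambda > 0)
  scheme <- match.arg(scheme, "bdf2")
  structure(list(dt = dt, dx = dx, dy = dy,
                 newton_tol = newton_tol, newton_max_iter = newton_max_iter,
                 linear_tol = linear_tol, scheme = scheme,
                 coupling_mode = match.arg(coupling_mode),
                 lambda = lambda,
                 joule_source = match.arg(joule_source),
                 snapshot_stride_ms = snapshot_stride_ms,
                 trace_T = trace_T,
                 strip_thermal = strip_thermal,
                 stop_when_quiescent = stop_when_quiescent,
                 quiescence_threshold_mV = quiescence_threshold_mV,
                 quiescence_hold_ms = quiescence_hold_ms),
            class = "solver_config")
}

#' BDF2 (Gear) backward differentiation formula
#'
#' `(3 y_np1 - 4 y_n + y_nm1) / (2 dt)`: second-order approximation of the
#' time derivative at the new level, exact for polynomials up to degree 2.
#'
#' @param y_np1,y_n,y_nm1 Values at the three time levels (vectorized).
#' @param dt Time step.
#' @return Approximate dy/dt at the new level.
#' @export
bdf2_derivative <- function(y_np1, y_n, y_nm1, dt) {
  stopifnot(dt > 0)
  (3 * y_np1 - 4 * y_n + y_nm1) / (2 * dt)
}

## ---------------------------------------------------------------------------
## Internal solver contexts. The electrics Jacobian is a constant sparse
## skeleton (stiffness blocks + gauge constraint) plus a diagonal that varies
## with the ionic state; factorizations are cached and reused across Newton
## iterations and across steps while they still contract the residual.

.make_ectx <- function(grid, tissue, model, config) {
  n <- grid$nx * grid$ny
  vol <- as.vector(.cell_volumes(grid))
  mode <- config$coupling_mode
  ctx <- new.env(parent = emptyenv())
  ctx$grid <- grid; ctx$n <- n; ctx$vol <- vol
  ctx$chi <- tissue$chi; ctx$Cm <- tissue$Cm
  ctx$mode <- mode
  if (mode == "heat_monodomain") {
    G <- monodomain_conductivity(tissue$Gi, config$lambda)
    ctx$G <- G
    ctx$Ki <- -divgrad_matrix(G, grid, weighted = TRUE)
    ctx$J0 <- methods::as(Matrix::forceSymmetric(ctx$Ki), "CsparseMatrix")
    ctx$m <- n
    ctx$diag_idx <- .block_diag_index(ctx$J0, seq_len(n))
    ctx$r2scale <- (G$gxx / grid$dx^2 + G$gyy / grid$dy^2)
  } else {
    Ki <- -divgrad_matrix(tissue$Gi, grid, weighted = TRUE)
    Gie <- tensor2(tissue$Gi$gxx + tissue$Ge$gxx, tissue$Gi$gyy + tissue$Ge$gyy)
    Kie <- -divgrad_matrix(Gie, grid, weighted = TRUE)
    ctx$Ki <- Ki; ctx$Kie <- Kie
    ctx$r2scale <- (Gie$gxx / grid$dx^2 + Gie$gyy / grid$dy^2)
    ## The monolithic Jacobian is symmetric; the pure-Neumann elliptic block
    ## is singular (constant nullspace), so its zero mode is fixed by a tiny
    ## diagonal penalty. The penalty only acts on the constant mode (the
    ## elliptic residual always has zero sum) and is ~1e-8 of the smallest
    ## physical mode, far below the Newton tolerance; the mean-zero gauge is
    ## restored exactly by re-centering after each converged solve.
    eps <- 1e-8 * ctx$r2scale
    J0 <- rbind(cbind(Ki, Ki),
                cbind(Ki, Kie + Matrix::Diagonal(x = eps * vol)))
    ctx$J0 <- methods::as(Matrix::forceSymmetric(J0), "CsparseMatrix")
    ctx$m <- 2L * n
    ctx$diag_idx <- .block_diag_index(ctx$J0, seq_len(n))
  }
  ctx$fact <- NULL
  ctx$fact_gamma <- NA_real_
  ctx$fresh <- FALSE
  ctx$model <- model
  ctx
}

## positions inside the @x slot of a dgCMatrix holding the diagonal entries
## of the listed columns (which must exist in the pattern)
.block_diag_index <- function(M, cols) {
  p <- M@p; i <- M@i
  idx <- integer(length(cols))
  for (kk in seq_along(cols)) {
    k <- cols[kk]
    lo <- p[k] + 1L; hi <- p[k + 1L]
    w <- which(i[lo:hi] == k - 1L)
    if (length(w) != 1L) stop("Jacobian pattern is missing a diagonal entry")
    idx[kk] <- lo + w - 1L
  }
  idx
}

.factor_ectx <- function(ctx, gam, Deff) {
  J <- ctx$J0
  x <- J@x
  x[ctx$diag_idx] <- x[ctx$diag_idx] + gam * ctx$chi * ctx$Cm * ctx$vol +
    ctx$vol * Deff
  J@x <- x
  ## CHOLMOD (supernodal, symbolic analysis reused across refactorizations)
  ## when the system is positive definite; sparse LU otherwise
  if (!isTRUE(ctx$use_lu)) {
    ## CHOLMOD emits a warning alongside its error when the matrix is not
    ## positive definite; both simply mean "switch to LU"
    f <- suppressWarnings(tryCatch({
      if (is.null(ctx$chol)) {
        Matrix::Cholesky(J, LDL = FALSE, perm = TRUE, super = TRUE)
      } else {
        Matrix::update(ctx$chol, J)
      }
    }, error = function(e) NULL))
    if (!is.null(f)) {
      ctx$chol <- f
      ctx$fact <- f
    } else {
      ctx$use_lu <- TRUE
    }
  }
  if (isTRUE(ctx$use_lu)) {
    ctx$fact <- Matrix::lu(methods::as(J, "generalMatrix"), order = 1L)
  }
  ctx$fact_gamma <- gam
  ctx$fresh <- TRUE
  invisible(ctx)
}

.fact_solve <- function(ctx, b) {
  if (isTRUE(ctx$use_lu)) {
    as.vector(Matrix::solve(ctx$fact, b))
  } else {
    as.vector(Matrix::solve(ctx$fact, b, system = "A"))
  }
}

## One implicit electrics solve. V, phi, W are vectors (length n); fI, fF the
## thermal factor vectors at the lagged temperature; gam the BDF coefficient;
## rhsV, rhsW the history terms so that the time derivative is
## gam*y - rhsY. Returns updated vectors plus iteration statistics.
.solve_electrics <- function(ctx, gam, rhsV, rhsW, V, phi, W, fI, fF, config,
                             t_now = NA_real_) {
  model <- ctx$model
  n <- ctx$n; vol <- ctx$vol
  chi <- ctx$chi; chiCm <- ctx$chi * ctx$Cm
  bidomain <- ctx$mode != "heat_monodomain"
  tol <- config$newton_tol
  ## MS gate branch frozen over the step at the entry state
  branch <- .gate_branch(model, V)

  resid <- function(V, phi, W) {
    Iion <- ionic_current(model, V, W)
    Fion <- .gate_rate(model, V, W, branch)
    KiV <- as.vector(ctx$Ki %*% V)
    r1 <- vol * (chiCm * (gam * V - rhsV) + chi * fI * Iion) + KiV
    if (bidomain) {
      Kiphi <- as.vector(ctx$Ki %*% phi)
      r1 <- r1 + Kiphi
      r2 <- KiV + as.vector(ctx$Kie %*% phi)
    } else {
      r2 <- NULL
    }
    r3 <- gam * W - rhsW - fF * Fion
    list(r1 = r1, r2 = r2, r3 = r3)
  }
  nrm <- function(r) {
    s1 <- r$r1 / (vol * chiCm * gam)
    s3 <- r$r3 / gam
    if (bidomain) {
      s2 <- r$r2 / (vol * ctx$r2scale)
      sqrt(mean(c(s1^2, s2^2, s3^2)))
    } else {
      sqrt(mean(c(s1^2, s3^2)))
    }
  }

  r <- resid(V, phi, W)
  rn0 <- nrm(r)
  if (rn0 < 1e-13) {
    return(list(V = V, phi = phi, W = W, iters = 0L, refactored = 0L,
                residual = rn0))
  }
  rn <- rn0
  nref <- 0L
  for (it in seq_len(config$newton_max_iter)) {
    d <- .ionic_derivs(model, V, W, branch)
    denomW <- gam - fF * d$dFdW
    Deff <- chi * fI * (d$dIdV + d$dIdW * fF * d$dFdV / denomW)
    if (is.null(ctx$fact) || !identical(ctx$fact_gamma, gam)) {
      .factor_ectx(ctx, gam, Deff); nref <- nref + 1L
    }
    b1 <- -(r$r1) + vol * chi * fI * d$dIdW * r$r3 / denomW
    rhs <- if (bidomain) c(b1, -(r$r2)) else b1
    delta <- .fact_solve(ctx, rhs)
    dV <- delta[seq_len(n)]
    dphi <- if (bidomain) delta[n + seq_len(n)] else NULL
    dW <- (-r$r3 + fF * d$dFdV * dV) / denomW
    step <- 1
    repeat {
      Vn <- V + step * dV
      phin <- if (bidomain) phi + step * dphi else phi
      Wn <- W + step * dW
      rn_new <- nrm(rnew <- resid(Vn, phin, Wn))
      if (rn_new <= rn || step < 0.2) break
      step <- step / 2
    }
    improved <- rn_new <= 0.5 * rn
    inc_small <- step * max(abs(dV)) < 1e-8 && step * max(abs(dW)) < 1e-10
    V <- Vn; phi <- if (bidomain) phin else phi; W <- Wn
    r <- rnew; rn <- rn_new
    ## the discontinuous MS gate branch can flip between iterates and hold
    ## the residual in a tiny limit cycle; accept once the update itself is
    ## negligible and the residual has already dropped by >= 1e-3
    if (rn <= max(tol * rn0, 1e-13) || (inc_small && rn <= 1e-3 * rn0)) {
      ctx$fresh <- FALSE
      if (bidomain) phi <- phi - mean(phi) # mean-zero gauge
      return(list(V = V, phi = phi, W = W, iters = it, refactored = nref,
                  residual = rn / rn0))
    }
    ## a reused factorization only contracts linearly; refreshing costs many
    ## triangular solves, so keep a stale factor while it still halves the
    ## residual per sweep and rebuild once it stops contracting (or after a
    ## longer stretch of merely-linear progress)
    ctx$fresh <- FALSE
    if (!improved || it >= 6L) {
      dd <- .ionic_derivs(model, V, W, branch)
      denomW <- gam - fF * dd$dFdW
      Deff <- chi * fI * (dd$dIdV + dd$dIdW * fF * dd$dFdV / denomW)
      .factor_ectx(ctx, gam, Deff); nref <- nref + 1L
    }
  }
  stop(sprintf(paste0("Newton iteration did not converge (relative residual ",
                      "%.3e after %d iterations%s)"),
               rn / rn0, config$newton_max_iter,
               if (is.na(t_now)) "" else sprintf(" at t = %g ms", t_now)))
}

.make_hctx <- function(grid, thermal, config) {
  n <- grid$nx * grid$ny
  vol <- as.vector(.cell_volumes(grid))
  KT <- -divgrad_matrix(tensor2(thermal$kT, thermal$kT), grid, weighted = TRUE)
  ctx <- new.env(parent = emptyenv())
  ctx$grid <- grid; ctx$n <- n; ctx$vol <- vol
  ctx$KT <- KT
  ctx$thermal <- thermal
  ctx$chols <- list()
  ctx
}

.solve_heat <- function(ctx, gam, rhsT, Tstar_vec, q_vec) {
  key <- sprintf("%.17g", gam)
  ch <- ctx$chols[[key]]
  if (is.null(ch)) {
    th <- ctx$thermal
    A <- ctx$KT + Matrix::Diagonal(x = (gam * th$rho * th$cp + th$bc) * ctx$vol)
    ch <- Matrix::Cholesky(methods::as(A, "CsparseMatrix"), LDL = FALSE)
    ctx$chols[[key]] <- ch
  }
  th <- ctx$thermal
  b <- ctx$vol * (th$rho * th$cp * rhsT + th$bc * Tstar_vec + q_vec)
  as.vector(Matrix::solve(ch, b, system = "A"))
}

## ---------------------------------------------------------------------------
## Exported single-step interfaces (construct their contexts on the fly; the
## run loop below keeps persistent contexts for speed).

#' Two-level history for the BDF2 integrator
#'
#' @param state_nm1,state_n [field_state()] objects at levels n-1 and n.
#' @param time Current time (of level n), ms.
#' @return An object of class `"step_history"`.
#' @export
step_history <- function(state_nm1, state_n, time = 0) {
  stopifnot(inherits(state_nm1, "field_state"), inherits(state_n, "field_state"),
            identical(state_nm1$grid, state_n$grid))
  structure(list(nm1 = state_nm1, n = state_n, time = time),
            class = "step_history")
}

#' Advance the electrics block one BDF2 step
#'
#' Solves the coupled implicit system for the transmembrane potential,
#' extracellular potential and gating variable at the new time level with the
#' temperature lagged at level n (the thermal factors are evaluated at
#' `T^(n)`), using Newton iteration on the monolithic residual. The
#' extracellular gauge (zero spatial mean) is enforced exactly through a
#' Lagrange multiplier.
#'
#' @param hist A [step_history()].
#' @param config A [solver_config()].
#' @param params A [tissue_params()].
#' @param model An [ionic_model()].
#' @return List with matrices `Vm`, `phi_e`, `W` at level n+1 and the Newton
#'   iteration count `iters`.
#' @export
advance_electrics <- function(hist, config, params, model) {
  grid <- hist$n$grid
  ctx <- .make_ectx(grid, params, model, config)
  dt <- config$dt
  gam <- 3 / (2 * dt)
  rhsV <- (4 * as.vector(hist$n$Vm) - as.vector(hist$nm1$Vm)) / (2 * dt)
  rhsW <- (4 * as.vector(hist$n$W) - as.vector(hist$nm1$W)) / (2 * dt)
  Tlag <- as.vector(hist$n$T)
  if (config$strip_thermal) {
    fI <- rep(1, ctx$n); fF <- rep(1, ctx$n)
  } else {
    fI <- thermal_current_factor(Tlag, model$thermo)
    fF <- thermal_gate_factor(Tlag, model$thermo)
  }
  out <- .solve_electrics(ctx, gam, rhsV, rhsW,
                          as.vector(hist$n$Vm), as.vector(hist$n$phi_e),
                          as.vector(hist$n$W), fI, fF, config,
                          t_now = hist$time + dt)
  list(Vm = matrix(out$V, grid$nx, grid$ny),
       phi_e = matrix(out$phi, grid$nx, grid$ny),
       W = matrix(out$W, grid$nx, grid$ny),
       iters = out$iters)
}

#' Advance the bioheat equation one BDF2 step
#'
#' Linear, unconditionally stable solve of the BDF2-discretized Pennes
#' equation with the Joule source evaluated from the freshly computed
#' transmembrane potential (electrics first, then heat).
#'
#' @param hist A [step_history()].
#' @param Vm_np1 Transmembrane potential at the new level, `nx x ny`, mV.
#' @param config A [solver_config()].
#' @param thermal A [thermal_params()] (its `Tstar` supplies the setpoint
#'   field).
#' @param tissue A [tissue_params()] (conductivities for the Joule source).
#' @param phi_e_np1 Extracellular potential at the new level (used only by the
#'   `"full"` Joule source form).
#' @return Temperature matrix at level n+1, degC.
#' @export
advance_heat <- function(hist, Vm_np1, config, thermal,
                         tissue = tissue_params(), phi_e_np1 = NULL) {
  grid <- hist$n$grid
  ctx <- .make_hctx(grid, thermal, config)
  dt <- config$dt
  gam <- 3 / (2 * dt)
  rhsT <- (4 * as.vector(hist$n$T) - as.vector(hist$nm1$T)) / (2 * dt)
  q <- .joule_source_for(config, Vm_np1, phi_e_np1, tissue, grid)
  Tstar_vec <- as.vector(.expand_field(thermal$Tstar, grid, "Tstar"))
  Tn <- .solve_heat(ctx, gam, rhsT, Tstar_vec, as.vector(q))
  matrix(Tn, grid$nx, grid$ny)
}

.joule_source_for <- function(config, Vm, phi_e, tissue, grid) {
  if (config$coupling_mode == "heat_monodomain") {
    G <- monodomain_conductivity(tissue$Gi, config$lambda)
    return(joule_source_simplified(Vm, G, grid))
  }
  if (config$joule_source == "full") {
    if (is.null(phi_e)) stop("full Joule source requires phi_e")
    joule_source_full(Vm, phi_e, tissue, grid)
  } else {
    joule_source_simplified(Vm, tissue$Gi, grid)
  }
}

#' One coupled step: electrics, then heat
#'
#' Composition of [advance_electrics()] and [advance_heat()]. In
#' `ionic_only_static_T` mode the heat solve is skipped and the temperature is
#' pinned (bitwise) to the setpoint field; in `heat_monodomain` mode the
#' elliptic solve is skipped and the reduced conductivity
#' [monodomain_conductivity()] is used.
#'
#' @param hist A [step_history()].
#' @param config A [solver_config()].
#' @param params List with components `tissue` ([tissue_params()]) and
#'   `thermal` ([thermal_params()]).
#' @param model An [ionic_model()].
#' @return A [field_state()] at level n+1.
#' @export
step_coupled <- function(hist, config, params, model) {
  grid <- hist$n$grid
  el <- advance_electrics(hist, config, params$tissue, model)
  Tstar <- .expand_field(params$thermal$Tstar, grid, "Tstar")
  T_new <- switch(config$coupling_mode,
    ionic_only_static_T = Tstar,
    {
      if (config$strip_thermal) hist$n$T
      else advance_heat(hist, el$Vm, config, params$thermal, params$tissue,
                        el$phi_e)
    })
  field_state(grid, Vm = el$Vm, phi_e = el$phi_e, W = el$W, T_c = T_new)
}

## ---------------------------------------------------------------------------
## Full simulation driver.

#' Run a protocol with the coupled implicit solver
#'
#' Drives the staggered BDF2/Newton integrator over a declarative
#' [protocol()]: builds the grid and initial state, applies the cooling
#' schedule through the setpoint field, records probe traces every step and
#' field snapshots at the configured stride. The whole computation is
#' deterministic: there is no randomness anywhere in the model.
#'
#' @param protocol A [protocol()] (see [build_protocol()] for the named
#'   experiment builders).
#' @param config A [solver_config()].
#' @param verbose Print progress every ~10% of the run?
#' @return An object of class `"cardiotherm_run"`: probe traces (`times`,
#'   `trace_Vm`, `trace_T`), snapshots (list of time-stamped
#'   [field_state()]s), per-step Newton iteration counts, and the inputs
#'   needed to reproduce the run.
#' @export
run_simulation <- function(protocol, config = solver_config(), verbose = FALSE) {
  stopifnot(inherits(protocol, "protocol"), inherits(config, "solver_config"))
  grid <- grid2d(protocol$domain[1], protocol$domain[2], config$dx, config$dy)
  model <- protocol$model
  tissue <- protocol$tissue
  thermal <- protocol$thermal
  dt <- config$dt
  mode <- config$coupling_mode

  tstar_at <- function(t) tstar_field(grid, protocol$cooling, t)
  ts0 <- tstar_at(0)
  if (max(ts0) >= 43 && dt > 0.1) {
    warning("T* >= 43 degC sharpens the wavefront; a time step dt <= 0.1 ms ",
            "is recommended")
  }
  state0 <- protocol$init_state(grid, model, ts0, config)
  stopifnot(inherits(state0, "field_state"))

  probes_ij <- lapply(seq_len(nrow(protocol$probes)), function(k) {
    .nearest_node(grid, protocol$probes[k, 1], protocol$probes[k, 2])
  })
  pidx <- vapply(probes_ij,
                 function(ij) as.integer((ij[2] - 1L) * grid$nx + ij[1]),
                 integer(1))

  nsteps <- floor(protocol$duration / dt + 1e-9)
  times <- dt * (0:nsteps)
  np <- length(pidx)
  trace_Vm <- matrix(NA_real_, nsteps + 1L, np)
  trace_T <- if (config$trace_T) matrix(NA_real_, nsteps + 1L, np) else NULL
  trace_Vm[1L, ] <- state0$Vm[pidx]
  if (config$trace_T) trace_T[1L, ] <- state0$T[pidx]

  stride_steps <- max(1L, round(config$snapshot_stride_ms / dt))
  snapshots <- list(list(time = 0, state = state0))

  ectx <- .make_ectx(grid, tissue, model, config)
  hctx <- if (mode != "ionic_only_static_T" && !config$strip_thermal) {
    .make_hctx(grid, thermal, config)
  } else NULL
  thermal_run <- thermal

  V_nm1 <- NULL; W_nm1 <- NULL; T_nm1 <- NULL
  V_n <- as.vector(state0$Vm); phi_n <- as.vector(state0$phi_e)
  W_n <- as.vector(state0$W); T_n <- as.vector(state0$T)
  niter <- integer(nsteps)
  nfact <- 0L
  quiescent_since <- NA_real_
  stopped_at <- NA_real_

  for (k in seq_len(nsteps)) {
    t_new <- times[k + 1L]
    if (k == 1L) {
      gam <- 1 / dt
      rhsV <- V_n / dt; rhsW <- W_n / dt; rhsT <- T_n / dt
    } else {
      gam <- 3 / (2 * dt)
      rhsV <- (4 * V_n - V_nm1) / (2 * dt)
      rhsW <- (4 * W_n - W_nm1) / (2 * dt)
      rhsT <- (4 * T_n - T_nm1) / (2 * dt)
    }
    ts_new <- tstar_at(t_new)
    Tlag <- if (mode == "ionic_only_static_T") as.vector(ts_new) else T_n
    if (config$strip_thermal) {
      fI <- rep(1, ectx$n); fF <- rep(1, ectx$n)
    } else {
      fI <- thermal_current_factor(Tlag, model$thermo)
      fF <- thermal_gate_factor(Tlag, model$thermo)
    }
    el <- .solve_electrics(ectx, gam, rhsV, rhsW, V_n, phi_n, W_n, fI, fF,
                           config, t_now = t_new)
    niter[k] <- el$iters
    nfact <- nfact + el$refactored

    if (mode == "ionic_only_static_T" || config$strip_thermal) {
      T_new <- if (config$strip_thermal) T_n else as.vector(ts_new)
    } else {
      Vmat <- matrix(el$V, grid$nx, grid$ny)
      phimat <- matrix(el$phi, grid$nx, grid$ny)
      q <- .joule_source_for(config, Vmat, phimat, tissue, grid)
      T_new <- .solve_heat(hctx, gam, rhsT, as.vector(ts_new), as.vector(q))
    }

    V_nm1 <- V_n; W_nm1 <- W_n; T_nm1 <- T_n
    V_n <- el$V; phi_n <- el$phi; W_n <- el$W; T_n <- T_new

    trace_Vm[k + 1L, ] <- V_n[pidx]
    if (config$trace_T) trace_T[k + 1L, ] <- T_n[pidx]
    if (k %% stride_steps == 0L || k == nsteps) {
      ## Vm one step earlier is kept alongside: tip detection needs a
      ## dt-separated pair
      snapshots[[length(snapshots) + 1L]] <-
        list(time = t_new,
             state = field_state(grid,
                                 Vm = matrix(V_n, grid$nx, grid$ny),
                                 phi_e = matrix(phi_n, grid$nx, grid$ny),
                                 W = matrix(W_n, grid$nx, grid$ny),
                                 T_c = matrix(T_n, grid$nx, grid$ny)),
             Vm_prev = matrix(V_nm1, grid$nx, grid$ny))
    }
    if (verbose && k %% max(1L, nsteps %/% 20L) == 0L) {
      message(sprintf("  t = %7.1f ms (%3.0f%%), newton %d, factorizations %d",
                      t_new, 100 * k / nsteps, el$iters, nfact))
    }
    if (config$stop_when_quiescent) {
      if (max(V_n) < config$quiescence_threshold_mV) {
        if (is.na(quiescent_since)) quiescent_since <- t_new
        if (t_new - quiescent_since >= config$quiescence_hold_ms) {
          stopped_at <- t_new
          times <- times[seq_len(k + 1L)]
          trace_Vm <- trace_Vm[seq_len(k + 1L), , drop = FALSE]
          if (config$trace_T) trace_T <- trace_T[seq_len(k + 1L), , drop = FALSE]
          niter <- niter[seq_len(k)]
          break
        }
      } else {
        quiescent_since <- NA_real_
      }
    }
  }

  structure(list(times = times,
                 trace_Vm = trace_Vm,
                 trace_T = trace_T,
                 probes = protocol$probes,
                 snapshots = snapshots,
                 newton_iters = niter,
                 factorizations = nfact,
                 stopped_at = stopped_at,
                 grid = grid, protocol = protocol, config = config),
            class = "cardiotherm_run")
}

#' @export
print.cardiotherm_run <- function(x, ...) {
  cat(sprintf("<cardiotherm_run> '%s', %s mode\n", x$protocol$name,
              x$config$coupling_mode))
  cat(sprintf("  domain %g x %g cm, grid %d x %d, dt %g ms\n",
              x$protocol$domain[1], x$protocol$domain[2],
              x$grid$nx, x$grid$ny, x$config$dt))
  cat(sprintf("  simulated %g ms (%d steps, %d snapshots, %d probes)\n",
              max(x$times), length(x$times) - 1L, length(x$snapshots),
              nrow(x$probes)))
  if (!is.na(x$stopped_at)) {
    cat(sprintf("  stopped early (quiescent) at %g ms\n", x$stopped_at))
  }
  cat(sprintf("  newton iterations: mean %.2f, max %d\n",
              mean(x$newton_iters), max(x$newton_iters)))
  invisible(x)
}

#' @export
summary.cardiotherm_run <- function(object, ...) {
  x <- object
  last <- x$snapshots[[length(x$snapshots)]]$state
  cat(sprintf("Run '%s': %g ms simulated\n", x$protocol$name, max(x$times)))
  cat(sprintf("  final Vm range: [%.2f, %.2f] mV\n", min(last$Vm), max(last$Vm)))
  cat(sprintf("  final T range:  [%.4f, %.4f] degC\n", min(last$T), max(last$T)))
  ts <- tstar_field(x$grid, x$protocol$cooling, max(x$times))
  cat(sprintf("  max self-heating T - T*: %.3e degC\n", max(last$T - ts)))
  invisible(x)
}

#' Extract a probe trace from a run
#'
#' @param run A `cardiotherm_run`.
#' @param probe Probe index (row of `run$probes`).
#' @return A [probe_trace()].
#' @export
run_trace <- function(run, probe = 1L) {
  probe_trace(run$times, run$trace_Vm[, probe],
              position = as.numeric(run$probes[probe, ]))
}
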