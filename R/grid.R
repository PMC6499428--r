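#' Uniform structured 2-D grid
#'
#' Node-centered rectangular grid on `[0, Lx] x [0, Ly]` with node `(i, j)` at
#' `((i-1)*dx, (j-1)*dy)`, so `(nx-1)*dx = Lx`. Fields on the grid are stored
#' as `nx x ny` matrices (x varies along rows).
#'
#' @param Lx,Ly Domain size, cm.
#' @param dx Grid spacing in x, cm.
#' @param dy Grid spacing in y, cm (default `dx`).
#' @return An object of class `"grid2d"` with fields `nx`, `ny`, `dx`, `dy`,
#'   `Lx`, `Ly`.
#' @export
#' @examples
#' g <- grid2d(10, 10, dx = 0.1)
#' c(g$nx, g$ny)
grid2d <- function(Lx, Ly, dx, dy = dx) {
  stopifnot(Lx > 0, Ly > 0, dx > 0, dy > 0)
  nx <- round(Lx / dx) + 1L
  ny <- round(Ly / dy) + 1L
  if (abs((nx - 1L) * dx - Lx) > 1e-9 * Lx || abs((ny - 1L) * dy - Ly) > 1e-9 * Ly) {
    stop("dx (dy) must divide Lx (Ly) into a whole number of cells")
  }
  if (nx < 3L || ny < 3L) stop("grid must have at least 3 nodes per direction")
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy, Lx = Lx, Ly = Ly),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %g cm x %g cm, %d x %d nodes (dx = %g, dy = %g cm)\n",
              x$Lx, x$Ly, x$nx, x$ny, x$dx, x$dy))
  invisible(x)
}

#' Node coordinates of a grid
#'
#' @param grid A [grid2d()].
#' @return `grid_x`/`grid_y`: vectors of node coordinates (cm);
#'   `grid_coords`: list of `x` and `y` matrices matching the field layout.
#' @export
grid_x <- function(grid) (seq_len(grid$nx) - 1) * grid$dx

#' @rdname grid_x
#' @export
grid_y <- function(grid) (seq_len(grid$ny) - 1) * grid$dy

#' @rdname grid_x
#' @export
grid_coords <- function(grid) {
  list(x = matrix(grid_x(grid), grid$nx, grid$ny),
       y = matrix(grid_y(grid), grid$nx, grid$ny, byrow = TRUE))
}

## index of the grid node nearest to a point (cm); internal
.nearest_node <- function(grid, x, y) {
  i <- round(x / grid$dx) + 1L
  j <- round(y / grid$dy) + 1L
  if (i < 1L || i > grid$nx || j < 1L || j > grid$ny) {
    stop(sprintf("point (%g, %g) lies outside the domain", x, y))
  }
  c(i = i, j = j)
}

## nodal control volumes (cm^2 per unit depth): half cells on edges,
## quarter cells at corners; internal
.cell_volumes <- function(grid) {
  wx <- rep(grid$dx, grid$nx); wx[c(1L, grid$nx)] <- grid$dx / 2
  wy <- rep(grid$dy, grid$ny); wy[c(1L, grid$ny)] <- grid$dy / 2
  outer(wx, wy)
}

#' Diagonal 2-by-2 conductivity tensor
#'
#' Axis-aligned anisotropic conductivity with the fiber direction along the
#' grid x-axis: `gxx` is the longitudinal and `gyy` the transverse
#' conductivity, mS/cm. Must be symmetric positive definite (both entries
#' positive).
#'
#' @param gxx,gyy Conductivities along x and y, mS/cm.
#' @return An object of class `"tensor2"`.
#' @export
tensor2 <- function(gxx, gyy) {
  stopifnot(gxx > 0, gyy > 0)
  structure(list(gxx = gxx, gyy = gyy), class = "tensor2")
}

#' Bidomain tissue parameters
#'
#' Membrane surface-to-volume ratio, membrane capacitance and the intra- and
#' extracellular conductivity tensors. Defaults are the standard calibrated
#' bidomain values: `chi = 2000` 1/cm, `Cm = 1` microF/cm^2,
#' `Gi = diag(3.0, 0.315)` and `Ge = diag(2.0, 1.35)` mS/cm.
#'
#' @param chi Membrane surface-to-volume ratio, 1/cm.
#' @param Cm Membrane capacitance, microF/cm^2.
#' @param Gi,Ge Intra-/extracellular conductivity [tensor2()], mS/cm.
#' @return An object of class `"tissue_params"`.
#' @export
tissue_params <- function(chi = 2000, Cm = 1,
                          Gi = tensor2(3.0, 0.315),
                          Ge = tensor2(2.0, 1.35)) {
  stopifnot(chi > 0, Cm > 0, inherits(Gi, "tensor2"), inherits(Ge, "tensor2"))
  structure(list(chi = chi, Cm = Cm, Gi = Gi, Ge = Ge), class = "tissue_params")
}

#' Pennes bioheat parameters
#'
#' Thermal constants of perfused cardiac tissue: density `rho` (kg/cm^3), heat
#' capacity `cp` (J/(kg degC)), thermal conductivity `kT` (J/(ms cm degC)),
#' perfusion heat-sink strength `bc` (J/(ms cm^3 degC)) and the perfusion
#' (arterial blood / cooling setpoint) temperature `Tstar` (degC; scalar or a
#' field on the grid).
#'
#' @param rho Tissue density, kg/cm^3.
#' @param cp Specific heat capacity, J/(kg degC).
#' @param kT Thermal conductivity, J/(ms cm degC).
#' @param bc Blood-perfusion heat-sink coefficient, J/(ms cm^3 degC).
#' @param Tstar Perfusion temperature setpoint, degC.
#' @return An object of class `"thermal_params"`.
#' @export
thermal_params <- function(rho = 1.084e-3, cp = 3676, kT = 5.6e-6, bc = 8e-5,
                           Tstar = 37) {
  stopifnot(rho > 0, cp > 0, kT > 0, bc > 0)
  structure(list(rho = rho, cp = cp, kT = kT, bc = bc, Tstar = Tstar),
            class = "thermal_params")
}

#' Unit bridge between electrical Joule power and the bioheat equation
#'
#' The Joule source is naturally produced in electrical units of
#' mS mV^2 / cm^3; since 1 mS mV^2 = 1e-9 W, this equals 1e-12 J/(ms cm^3).
#' All Joule sources are multiplied by this constant before entering the
#' bioheat equation, which makes the self-heating of a propagating action
#' potential come out on the micro-degC scale.
#'
#' @return The conversion factor 1e-12 (J/(ms cm^3) per mS mV^2/cm^3).
#' @export
joule_unit_conversion <- function() 1e-12

## expand a scalar to a field matrix if needed; internal
.expand_field <- function(x, grid, name = "field") {
  if (length(x) == 1L) return(matrix(as.numeric(x), grid$nx, grid$ny))
  if (is.matrix(x) && nrow(x) == grid$nx && ncol(x) == grid$ny) return(x)
  stop(name, " must be a scalar or an nx x ny matrix matching the grid")
}

#' Coupled field state on a grid
#'
#' The four coupled unknowns at one time level: transmembrane potential `Vm`
#' (mV), extracellular potential `phi_e` (mV), gating variable `W` and
#' temperature `T` (degC), all `nx x ny` matrices on the same grid.
#'
#' @param grid A [grid2d()].
#' @param Vm,phi_e,W,T_c Fields (scalars are expanded).
#' @return An object of class `"field_state"`.
#' @export
field_state <- function(grid, Vm = -85, phi_e = 0, W = 1, T_c = 37) {
  structure(list(grid = grid,
                 Vm = .expand_field(Vm, grid, "Vm"),
                 phi_e = .expand_field(phi_e, grid, "phi_e"),
                 W = .expand_field(W, grid, "W"),
                 T = .expand_field(T_c, grid, "T")),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> on %d x %d grid\n", x$grid$nx, x$grid$ny))
  for (f in c("Vm", "phi_e", "W", "T")) {
    cat(sprintf("  %-6s [%g, %g]\n", f, min(x[[f]]), max(x[[f]])))
  }
  invisible(x)
}
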