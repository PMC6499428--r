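## Spatial discretization: 5-point second-order finite differences for the
## anisotropic div-grad operators on uniform grids, with homogeneous Neumann
## (zero co-normal flux) boundary closure via mirrored ghost nodes.

## 1-D second-difference matrix with mirrored-ghost Neumann closure (strong
## form, 1/h^2 scaling); n x n sparse
.d2_matrix_1d <- function(n, h) {
  i <- c(2:(n - 1), 2:(n - 1), 2:(n - 1), 1L, 1L, n, n)
  j <- c(1:(n - 2), 2:(n - 1), 3:n,       1L, 2L, n, n - 1L)
  x <- c(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2), -2, 2, -2, 2) / h^2
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Discrete anisotropic div-grad matrix
#'
#' Assembles the sparse matrix of the discrete operator `div(g grad .)` on a
#' [grid2d()] with a diagonal conductivity [tensor2()] and homogeneous Neumann
#' boundary closure, acting on fields vectorized column-major (x fastest).
#' The strong form (`weighted = FALSE`) approximates the operator pointwise;
#' the volume-weighted form (`weighted = TRUE`) is the strong form multiplied
#' by the nodal control volumes, which makes the matrix symmetric negative
#' semi-definite with nullspace exactly the constants.
#'
#' @param g A [tensor2()], mS/cm.
#' @param grid A [grid2d()].
#' @param weighted Return the symmetric volume-weighted form?
#' @return A sparse `dgCMatrix` of dimension `(nx*ny) x (nx*ny)`.
#' @export
divgrad_matrix <- function(g, grid, weighted = FALSE) {
  Dx <- .d2_matrix_1d(grid$nx, grid$dx)
  Dy <- .d2_matrix_1d(grid$ny, grid$dy)
  Ix <- Matrix::Diagonal(grid$nx)
  Iy <- Matrix::Diagonal(grid$ny)
  L <- g$gxx * Matrix::kronecker(Iy, Dx) + g$gyy * Matrix::kronecker(Dy, Ix)
  if (weighted) {
    L <- Matrix::Diagonal(x = as.vector(.cell_volumes(grid))) %*% L
  }
  methods::as(L, "CsparseMatrix")
}

#' Apply the discrete anisotropic div-grad operator to a field
#'
#' Matrix-free application of `div(g grad field)` (strong form, second-order,
#' mirrored-ghost Neumann closure). Exact zero on constant fields; equals
#' `2*gxx` (resp. `2*gyy`) on `x^2` (resp. `y^2`) away from the boundary.
#'
#' @param field `nx x ny` matrix.
#' @param g A [tensor2()].
#' @param grid A [grid2d()].
#' @return `nx x ny` matrix of the same shape, mS/cm times field units /cm^2.
#' @export
anisotropic_divgrad <- function(field, g, grid) {
  if (!is.matrix(field) || nrow(field) != grid$nx || ncol(field) != grid$ny) {
    stop("field shape does not match grid")
  }
  nx <- grid$nx; ny <- grid$ny
  up <- field[c(2L, seq_len(nx - 1L)), , drop = FALSE]
  dn <- field[c(seq.int(2L, nx), nx - 1L), , drop = FALSE]
  d2x <- (up + dn - 2 * field) / grid$dx^2
  lf <- field[, c(2L, seq_len(ny - 1L)), drop = FALSE]
  rt <- field[, c(seq.int(2L, ny), ny - 1L), drop = FALSE]
  d2y <- (lf + rt - 2 * field) / grid$dy^2
  g$gxx * d2x + g$gyy * d2y
}

## centered-difference gradient with mirrored ghosts (zero normal gradient on
## the boundary, consistent with the Neumann closure); internal
.gradient <- function(field, grid) {
  nx <- grid$nx; ny <- grid$ny
  up <- field[c(2L, seq_len(nx - 1L)), , drop = FALSE]
  dn <- field[c(seq.int(2L, nx), nx - 1L), , drop = FALSE]
  gx <- (dn - up) / (2 * grid$dx)
  lf <- field[, c(2L, seq_len(ny - 1L)), drop = FALSE]
  rt <- field[, c(seq.int(2L, ny), ny - 1L), drop = FALSE]
  gy <- (rt - lf) / (2 * grid$dy)
  list(gx = gx, gy = gy)
}

#' Solve the extracellular elliptic problem
#'
#' Solves `div((Gi+Ge) grad phi_e) = -div(Gi grad Vm)` with homogeneous
#' Neumann boundary conditions. The pure-Neumann problem is singular with
#' nullspace the constants; the gauge is fixed to zero spatial mean of
#' `phi_e`, enforced exactly through a Lagrange multiplier. Compatibility of
#' the right-hand side holds automatically because the discrete operator
#' annihilates constants.
#'
#' @param Vm `nx x ny` matrix of transmembrane potential, mV.
#' @param p A [tissue_params()].
#' @param grid A [grid2d()].
#' @param tol Acceptable residual (RMS of the volume-weighted discrete
#'   equation) relative to the right-hand side scale.
#' @return `nx x ny` matrix `phi_e` (mV) with `mean(phi_e) == 0` up to
#'   roundoff; attribute `"residual"` carries the achieved relative residual.
#' @export
solve_extracellular <- function(Vm, p, grid, tol = 1e-8) {
  if (any(!is.finite(Vm))) stop("Vm must be finite")
  n <- grid$nx * grid$ny
  Gie <- tensor2(p$Gi$gxx + p$Ge$gxx, p$Gi$gyy + p$Ge$gyy)
  Kie <- divgrad_matrix(Gie, grid, weighted = TRUE)
  vol <- as.vector(.cell_volumes(grid))
  rhs_field <- anisotropic_divgrad(Vm, p$Gi, grid)
  rhs <- -vol * as.vector(rhs_field)
  A <- rbind(cbind(Kie, Matrix::Matrix(1, n, 1)),
             cbind(Matrix::Matrix(1, 1, n), Matrix::Matrix(0, 1, 1)))
  sol <- Matrix::solve(methods::as(A, "CsparseMatrix"), c(rhs, 0))
  phi <- as.vector(sol)[seq_len(n)]
  phi <- phi - mean(phi)
  res <- as.vector(Kie %*% phi) - rhs
  scale <- max(sqrt(mean(rhs^2)), 1e-14)
  rel <- sqrt(mean(res^2)) / scale
  if (rel > tol && sqrt(mean(res^2)) > 1e-10) {
    stop(sprintf("extracellular solve did not reach tolerance (residual %.3e)", rel))
  }
  out <- matrix(phi, grid$nx, grid$ny)
  attr(out, "residual") <- rel
  out
}

#' Simplified Joule heating source
#'
#' Volumetric power dissipated by the transmembrane-potential gradient,
#' `Gi grad(Vm) . grad(Vm)`, converted from electrical units by
#' [joule_unit_conversion()]. Non-negative everywhere; zero exactly where the
#' discrete gradient vanishes. This is the source form used by the coupled
#' simulations.
#'
#' @param Vm `nx x ny` matrix, mV.
#' @param Gi Intracellular conductivity [tensor2()], mS/cm.
#' @param grid A [grid2d()].
#' @param conversion Unit bridge, J/(ms cm^3) per mS mV^2/cm^3.
#' @return `nx x ny` matrix of volumetric power, J/(ms cm^3).
#' @export
joule_source_simplified <- function(Vm, Gi, grid,
                                    conversion = joule_unit_conversion()) {
  gr <- .gradient(Vm, grid)
  (Gi$gxx * gr$gx^2 + Gi$gyy * gr$gy^2) * conversion
}

#' Full intra/extracellular Joule heating source
#'
#' `Gi grad(Vm + phi_e) . grad(Vm + phi_e) + Ge grad(phi_e) . grad(phi_e)`,
#' the heat generation rate of the intra- and extracellular media. Reduces
#' exactly (bitwise) to [joule_source_simplified()] when `phi_e` is zero.
#'
#' @param Vm,phi_e `nx x ny` matrices, mV.
#' @param p A [tissue_params()].
#' @param grid A [grid2d()].
#' @param conversion Unit bridge, J/(ms cm^3) per mS mV^2/cm^3.
#' @return `nx x ny` matrix of volumetric power, J/(ms cm^3).
#' @export
joule_source_full <- function(Vm, phi_e, p, grid,
                              conversion = joule_unit_conversion()) {
  if (!all(dim(Vm) == dim(phi_e))) stop("fields must share a grid")
  gi <- .gradient(Vm + phi_e, grid)
  ge <- .gradient(phi_e, grid)
  ((p$Gi$gxx * gi$gx^2 + p$Gi$gyy * gi$gy^2) +
     (p$Ge$gxx * ge$gx^2 + p$Ge$gyy * ge$gy^2)) * conversion
}

#' Monodomain conductivity tensor
#'
#' Under equal anisotropy ratios `Gi = lambda * Ge`, the bidomain reduces to a
#' monodomain reaction-diffusion equation with conductivity
#' `G = Gi / (1 + lambda)`.
#'
#' @param Gi Intracellular conductivity [tensor2()].
#' @param lam Anisotropy ratio `lambda > 0`.
#' @return A [tensor2()] with entries `Gi / (1 + lambda)`.
#' @export
monodomain_conductivity <- function(Gi, lam) {
  if (!(lam > 0)) stop("lambda must be positive")
  tensor2(Gi$gxx / (1 + lam), Gi$gyy / (1 + lam))
}

#' Right-hand side of the Pennes bioheat equation
#'
#' `dT/dt = (div(kT grad T) + bc (Tstar - T) + source) / (rho cp)`. At
#' `T = Tstar` with zero source the field is in equilibrium.
#'
#' @param T_c `nx x ny` temperature matrix, degC.
#' @param source Volumetric power, J/(ms cm^3) (scalar or matrix).
#' @param tp A [thermal_params()] (supplies `Tstar`).
#' @param grid A [grid2d()].
#' @return `nx x ny` matrix of dT/dt, degC/ms.
#' @export
bioheat_rhs <- function(T_c, source, tp, grid) {
  Tstar <- .expand_field(tp$Tstar, grid, "Tstar")
  src <- .expand_field(source, grid, "source")
  kT <- tensor2(tp$kT, tp$kT)
  (anisotropic_divgrad(T_c, kT, grid) + tp$bc * (Tstar - T_c) + src) /
    (tp$rho * tp$cp)
}
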