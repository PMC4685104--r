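flow_mask <- function(cls) cls == .CANCELLOUS | cls == .VENT

#' Solve the pressure equation
#'
#' Incompressible two-phase Darcy flow reduces to an elliptic pressure
#' equation \eqn{\nabla\cdot(\alpha \lambda_t \nabla P) = -q}: Darcy's law
#' \eqn{\nabla P = -(\mu/\alpha) v} for each phase, summed over phases with
#' total mobility \eqn{\lambda_t(s)}. Discretization is a cell-centered
#' conservative finite volume with harmonic-mean face transmissibilities
#' \eqn{T_f = h\,2 a_i a_j/(a_i+a_j)}, \eqn{a = \alpha\lambda_t}. Cortical
#' and exterior faces carry zero flux (zero permeability realizes both the
#' impermeable shell and the no-slip wall); vent cells impose Dirichlet
#' pressures (default 0, the reference). The sparse SPD system is solved with
#' conjugate gradients under a symmetric Gauss–Seidel preconditioner.
#'
#' @param phantom A `porous_phantom`.
#' @param s Oil saturation array (fraction of pore space), same dim as the
#'   grid; used to evaluate the total mobility everywhere including vents.
#' @param protocol An [injection_protocol()] or `NULL`; its `rate` enters as
#'   a point source at the phantom's injection cell.
#' @param fluids A [fluid_pair()].
#' @param tol Relative residual tolerance.
#' @param maxit Maximum CG iterations.
#' @param vent_pressure Scalar or full array of Dirichlet pressures at vent
#'   cells (Pa).
#' @param P0 Optional initial guess (warm start).
#' @param gravity Logical; include the mixture buoyancy term.
#' @param g Gravitational acceleration (m/s^2).
#' @return Pressure array (Pa); zero on cortical/exterior cells. Attributes
#'   `iters` and `relres` report solver effort.
#' @export
solve_pressure <- function(phantom, s, protocol = NULL,
                           fluids = fluid_pair(), tol = 1e-10,
                           maxit = 10000L, vent_pressure = 0, P0 = NULL,
                           gravity = FALSE, g = 9.81) {
  grid <- phantom$grid
  dims <- c(grid$nx, grid$ny, grid$nz)
  cls <- phantom$cell_class
  stopifnot(all(dim(s) == dims))
  rate <- if (is.null(protocol)) 0 else protocol$rate
  q <- array(0, dims)
  if (rate > 0) {
    ii <- phantom$injection_site$index
    q[ii[1], ii[2], ii[3]] <- rate
  }
  if (!any(cls == .VENT)) {
    if (rate > 0)
      stop(paste("configuration error: pressure system is singular --",
                 "injecting into a phantom with no vent cells; add a vent",
                 "(Dirichlet pressure reference) so displaced air can escape"))
    out <- array(0, dims)
    attr(out, "iters") <- 0L; attr(out, "relres") <- 0
    return(out)
  }
  lam <- total_mobility(s, fluids)
  amob <- phantom$permeability * lam
  amob[!flow_mask(cls)] <- 0
  ventP <- if (length(vent_pressure) == 1L) array(vent_pressure, dims)
           else { stopifnot(all(dim(vent_pressure) == dims)); vent_pressure }
  if (is.null(P0)) P0 <- array(0, dims)
  rhog <- if (gravity) (s * fluids$rho_oil + (1 - s) * fluids$rho_air) * g
          else numeric(0)
  res <- cpp_solve_pressure(as.integer(dims), as.integer(cls),
                            as.numeric(amob), grid$h, as.numeric(q),
                            as.numeric(ventP), as.numeric(P0), tol,
                            as.integer(maxit), as.numeric(rhog))
  if (res$relres > tol)
    stop(sprintf("numerical error: pressure solve did not converge (relative residual %.3g after %d iterations)",
                 res$relres, res$iters))
  P <- array(res$P, dims)
  attr(P, "iters") <- res$iters
  attr(P, "relres") <- res$relres
  P
}

#' Face Darcy fluxes from a pressure field
#'
#' Darcy's law rearranged on faces: \eqn{v = -\alpha\lambda_t \nabla P},
#' evaluated with the same harmonic-mean transmissibilities as the pressure
#' solve, so the fluxes are discretely conservative (cell-wise divergence
#' equals the source). Face velocities are face-normal superficial velocities
#' (m/s), positive toward +axis; the volume rate through a face is
#' \eqn{v h^2}.
#'
#' @inheritParams solve_pressure
#' @param P Pressure array from [solve_pressure()].
#' @return A `face_flux` list with arrays `vx` (nx+1, ny, nz), `vy`
#'   (nx, ny+1, nz), `vz` (nx, ny, nz+1).
#' @export
darcy_flux <- function(P, phantom, s, fluids = fluid_pair(),
                       vent_pressure = 0, gravity = FALSE, g = 9.81) {
  grid <- phantom$grid
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz; h <- grid$h
  cls <- phantom$cell_class
  lam <- total_mobility(s, fluids)
  amob <- phantom$permeability * lam
  amob[!flow_mask(cls)] <- 0
  Pf <- P
  if (any(cls == .VENT)) {
    ventP <- if (length(vent_pressure) == 1L) vent_pressure
             else vent_pressure[cls == .VENT]
    Pf[cls == .VENT] <- ventP
  }
  harm <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)
  vx <- array(0, c(nx + 1, ny, nz))
  vy <- array(0, c(nx, ny + 1, nz))
  vz <- array(0, c(nx, ny, nz + 1))
  Tx <- h * harm(amob[1:(nx - 1), , , drop = FALSE], amob[2:nx, , , drop = FALSE])
  vx[2:nx, , ] <- Tx * (Pf[1:(nx - 1), , ] - Pf[2:nx, , ]) / h^2
  Ty <- h * harm(amob[, 1:(ny - 1), , drop = FALSE], amob[, 2:ny, , drop = FALSE])
  vy[, 2:ny, ] <- Ty * (Pf[, 1:(ny - 1), ] - Pf[, 2:ny, ]) / h^2
  Tz <- h * harm(amob[, , 1:(nz - 1), drop = FALSE], amob[, , 2:nz, drop = FALSE])
  dPz <- Pf[, , 1:(nz - 1)] - Pf[, , 2:nz]
  if (gravity) {
    rho <- s * fluids$rho_oil + (1 - s) * fluids$rho_air
    rbar <- 0.5 * (rho[, , 1:(nz - 1)] + rho[, , 2:nz])
    dPz <- dPz - rbar * g * h
  }
  vz[, , 2:nz] <- Tz * dPz / h^2
  structure(list(vx = vx, vy = vy, vz = vz), class = "face_flux")
}

#' Cell-wise flux divergence
#'
#' Net volumetric outflow per cell (m^3/s) implied by a face flux field.
#' Away from the source this is the discrete conservation defect and should
#' vanish to solver tolerance.
#'
#' @param v A `face_flux`.
#' @param phantom A `porous_phantom`.
#' @return Array of net outflow rates (m^3/s).
#' @export
flux_divergence <- function(v, phantom) {
  h <- phantom$grid$h
  nx <- phantom$grid$nx; ny <- phantom$grid$ny; nz <- phantom$grid$nz
  (v$vx[2:(nx + 1), , ] - v$vx[1:nx, , ] +
   v$vy[, 2:(ny + 1), ] - v$vy[, 1:ny, ] +
   v$vz[, , 2:(nz + 1)] - v$vz[, , 1:nz]) * h^2
}
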