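#' Numerics configuration
#'
#' Tunable numerical parameters of the sequential (IMPES-style) scheme.
#'
#' @param cfl Front CFL safety factor in (0, 1]; each step the front may
#'   advance at most `cfl` cells.
#' @param tol Pressure-solve relative residual tolerance.
#' @param maxit Maximum CG iterations per pressure solve.
#' @param pressure_lag Re-solve pressure every `pressure_lag` transport steps.
#' @param transport `"implicit"` (default, unconditionally stable) or
#'   `"explicit"` (classical CFL-bound upwind; impractical at the physical
#'   oil/air viscosity ratio).
#' @param gravity Logical; include the mixture buoyancy term (off by
#'   default: the oil viscosity dominates over the injection time scale).
#' @param max_steps Hard cap on time steps.
#' @return A `numerics_config` list.
#' @export
numerics_config <- function(cfl = 0.5, tol = 1e-10, maxit = 10000L,
                            pressure_lag = 1L, transport = c("implicit",
                                                             "explicit"),
                            gravity = FALSE, max_steps = 200000L) {
  transport <- match.arg(transport)
  stopifnot(cfl > 0, cfl <= 1, tol > 0, pressure_lag >= 1)
  structure(list(cfl = cfl, tol = tol, maxit = as.integer(maxit),
                 pressure_lag = as.integer(pressure_lag),
                 transport = transport, gravity = gravity,
                 max_steps = as.integer(max_steps)),
            class = "numerics_config")
}

sim_state <- function(t, P, s, flux) {
  structure(list(t = t, P = P, s = s, flux = flux), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %g s, saturated cells (s >= 0.5): %d\n",
              x$t, sum(x$s >= 0.5)))
  invisible(x)
}

# upwind net oil inflow rate per cell (m^3/s), the explicit-update rate;
# used by the adaptive time-step controller: dt is chosen so no cell's
# saturation changes by more than `cfl` per step. Stagnant oil/air
# interfaces (zero net flux, e.g. inside a sealed channel) impose no limit,
# while at the moving front this reduces to the usual front CFL.
oil_rate_field <- function(s, v, phantom, fluids, Q = 0, src = NULL) {
  g <- phantom$grid
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  A <- g$h^2
  fo <- fractional_flow(s, fluids)
  upw <- function(f_lo, f_hi, vf) ifelse(vf > 0, f_lo, f_hi) * vf * A
  Fx <- array(0, c(nx + 1, ny, nz))
  Fx[2:nx, , ] <- upw(fo[1:(nx - 1), , ], fo[2:nx, , ], v$vx[2:nx, , ])
  Fy <- array(0, c(nx, ny + 1, nz))
  Fy[, 2:ny, ] <- upw(fo[, 1:(ny - 1), ], fo[, 2:ny, ], v$vy[, 2:ny, ])
  Fz <- array(0, c(nx, ny, nz + 1))
  Fz[, , 2:nz] <- upw(fo[, , 1:(nz - 1)], fo[, , 2:nz], v$vz[, , 2:nz])
  net <- Fx[1:nx, , ] - Fx[2:(nx + 1), , ] +
    Fy[, 1:ny, ] - Fy[, 2:(ny + 1), ] +
    Fz[, , 1:nz] - Fz[, , 2:(nz + 1)]
  if (Q > 0 && !is.null(src)) net[src[1], src[2], src[3]] <-
      net[src[1], src[2], src[3]] + Q
  net
}

#' Run a full injection simulation
#'
#' Sequential pressure/saturation scheme: at each step the pressure field is
#' solved implicitly from the current saturation-dependent mobilities
#' ([solve_pressure()]), face fluxes are evaluated ([darcy_flux()]), a time
#' step is chosen so the displacement front advances at most `cfl` cells,
#' and the saturation is advanced by upwind transport
#' ([advect_saturation()]). Snapshots are taken at exactly the requested
#' output times (the step is shortened to land on them). The run aborts with
#' a diagnostic if the oil volume balance drifts by more than 1%.
#'
#' The initial condition is an air-filled phantom (oil saturation 0
#' everywhere); injection is a constant-rate oil point source at the
#' phantom's injection cell for `protocol$duration` seconds.
#'
#' @param phantom A `porous_phantom`.
#' @param protocol An [injection_protocol()].
#' @param fluids A [fluid_pair()].
#' @param numerics A [numerics_config()].
#' @param verbose Print per-step progress.
#' @return A `vp_run` object: list with `snapshots` (one `sim_state` per
#'   output time), `log` (per-step data frame), `outflow` (cumulative oil
#'   vented, m^3), and the inputs.
#' @export
run_simulation <- function(phantom, protocol, fluids = fluid_pair(),
                           numerics = numerics_config(), verbose = FALSE) {
  grid <- phantom$grid
  dims <- c(grid$nx, grid$ny, grid$nz)
  h <- grid$h
  src <- phantom$injection_site$index
  phi_src <- phantom$porosity[src[1], src[2], src[3]]
  out_times <- protocol$output_times
  t_end <- max(protocol$duration, out_times)

  s <- array(0, dims)
  P <- array(0, dims)
  flux <- NULL
  t <- 0
  outflow_cum <- 0
  snapshots <- list()
  log_rows <- list()
  if (length(out_times) && abs(out_times[1]) < 1e-12) {
    snapshots[[1]] <- sim_state(0, P, s, NULL)
    out_times <- out_times[-1]
  }
  step <- 0L
  while (t < t_end - 1e-12) {
    Q <- if (t < protocol$duration - 1e-12) protocol$rate else 0
    if (step %% numerics$pressure_lag == 0L || is.null(flux)) {
      prot_now <- if (Q > 0) protocol else NULL
      P <- solve_pressure(phantom, s, prot_now, fluids,
                          tol = numerics$tol, maxit = numerics$maxit,
                          P0 = P, gravity = numerics$gravity)
      flux <- darcy_flux(P, phantom, s, fluids, gravity = numerics$gravity)
    }
    rate <- oil_rate_field(s, flux, phantom, fluids, Q, src)
    canc <- phantom$cell_class == .CANCELLOUS
    rmax <- max(abs(rate[canc]) / phantom$porosity[canc])
    vmax <- rmax / h^2   # equivalent front speed, for the log
    dt_front <- if (rmax > 0) numerics$cfl * h^3 / rmax else Inf
    t_next <- min(c(out_times[out_times > t + 1e-12],
                    if (t < protocol$duration) protocol$duration, t_end))
    dt <- min(dt_front, t_next - t)
    if (numerics$transport == "explicit") {
      sdt <- stable_dt(flux, phantom, fluids, cfl = numerics$cfl)
      dt <- min(dt, sdt)
    }
    if (!is.finite(dt) || dt <= 0) dt <- t_next - t
    s <- advect_saturation(s, flux, phantom, dt, fluids, q_oil = Q,
                           method = numerics$transport, P = P,
                           cfl = numerics$cfl)
    outflow_cum <- outflow_cum + attr(s, "outflow")
    t <- t + dt
    step <- step + 1L
    injected <- protocol$rate * min(t, protocol$duration)
    in_grid <- oil_volume(s, phantom)
    mass_err <- if (injected > 0)
      (in_grid + outflow_cum - injected) / injected else 0
    log_rows[[step]] <- data.frame(
      step = step, t = t, dt = dt, vmax = vmax,
      injected = injected, oil_in_grid = in_grid,
      outflow = outflow_cum, mass_error = mass_err,
      pressure_iters = attr(P, "iters") %||% NA_integer_)
    if (abs(mass_err) > 0.01)
      stop(sprintf("mass-balance drift %.3g%% at t = %.4g s exceeds 1%% -- aborting",
                   100 * mass_err, t))
    if (verbose)
      message(sprintf("step %d  t=%.4g  dt=%.3g  mass_err=%.2e", step, t,
                      dt, mass_err))
    if (length(out_times) && abs(t - out_times[1]) < 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- sim_state(t, P, s, flux)
      out_times <- out_times[-1]
    }
    if (step >= numerics$max_steps)
      stop("run_simulation: max_steps exceeded")
  }
  structure(list(phantom = phantom, protocol = protocol, fluids = fluids,
                 numerics = numerics, snapshots = snapshots,
                 log = do.call(rbind, log_rows), outflow = outflow_cum),
            class = "vp_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vp_run <- function(x, ...) {
  cat(sprintf(paste0("<vp_run> %s injection, Q = %g mL/s, %d snapshots, ",
                     "%d steps\n  final mass-balance error: %.3g\n"),
              x$protocol$site, x$protocol$rate * 1e6, length(x$snapshots),
              nrow(x$log), x$log$mass_error[nrow(x$log)]))
  invisible(x)
}

#' Equivalent spherical radius of the oil body
#'
#' Radius of the sphere with the same volume as the thresholded saturation
#' region: \eqn{(3 V_{s\ge\theta} / 4\pi)^{1/3}}. Before wall contact this
#' tracks the closed-form [front_radius_theory()].
#'
#' @param s Saturation array or `sim_state`.
#' @param phantom A `porous_phantom`.
#' @param theta Saturation threshold.
#' @return Radius (m); 0 for an empty superlevel set.
#' @export
equivalent_sphere_radius <- function(s, phantom, theta = 0.5) {
  if (inherits(s, "sim_state")) s <- s$s
  V <- sum(s >= theta) * phantom$grid$h^3
  (3 * V / (4 * pi))^(1 / 3)
}
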