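#' Oil/air fluid pair
#'
#' Dynamic viscosities and densities of the injected silicone oil (the
#' constant-viscosity PMMA surrogate) and the resident air. The 100,000 cSt
#' kinematic viscosity of the oil converts to a dynamic viscosity of
#' 97 Pa s at the default PDMS density of 970 kg/m^3. Densities are used only
#' for the cSt conversion and the optional gravity term; gravity is off by
#' default because the oil viscosity dominates over the injection time scale.
#'
#' @param mu_oil Oil dynamic viscosity (Pa s).
#' @param mu_air Air dynamic viscosity (Pa s).
#' @param rho_oil,rho_air Densities (kg/m^3).
#' @return A `fluid_pair` object.
#' @export
fluid_pair <- function(mu_oil = 97, mu_air = 1.8e-5,
                       rho_oil = 970, rho_air = 1.2) {
  if (!(mu_air > 0) || !(mu_oil >= mu_air))
    stop("fluid_pair: need mu_oil >= mu_air > 0")
  structure(list(mu_oil = mu_oil, mu_air = mu_air,
                 rho_oil = rho_oil, rho_air = rho_air),
            class = "fluid_pair")
}

#' @export
print.fluid_pair <- function(x, ...) {
  cat(sprintf("<fluid_pair> mu_oil = %g Pa s, mu_air = %g Pa s (ratio %.3g)\n",
              x$mu_oil, x$mu_air, x$mu_oil / x$mu_air))
  invisible(x)
}

#' Dynamic viscosity from kinematic viscosity in centistokes
#'
#' @param cSt Kinematic viscosity (centistokes; 1 cSt = 1e-6 m^2/s).
#' @param rho Density (kg/m^3).
#' @return Dynamic viscosity (Pa s).
#' @export
dynamic_viscosity_from_cSt <- function(cSt, rho = 970) {
  cSt * 1e-6 * rho
}

#' Injection protocol
#'
#' Constant-rate volumetric injection of oil at a named site, with snapshot
#' report times. The default 0.3 mL/s for 7 s (2.1 mL total) is a clinically
#' plausible cement dose that keeps the front inside the default phantom.
#'
#' @param site `"body_center"` or `"pedicle_junction"`.
#' @param rate Volumetric injection rate Q (m^3/s), > 0 (0 allowed for
#'   no-injection control runs).
#' @param duration Injection duration (s).
#' @param output_times Report times (s), all within `[0, duration]`.
#' @return An `injection_protocol` object.
#' @export
injection_protocol <- function(site = c("body_center", "pedicle_junction"),
                               rate = 3e-7, duration = 7,
                               output_times = c(1, 4, 7)) {
  site <- match.arg(site)
  if (rate < 0) stop("injection_protocol: rate must be >= 0")
  if (duration <= 0) stop("injection_protocol: duration must be > 0")
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0 | output_times > duration))
    stop("injection_protocol: output_times must lie in [0, duration]")
  structure(list(site = site, rate = rate, duration = duration,
                 output_times = output_times),
            class = "injection_protocol")
}

#' @export
print.injection_protocol <- function(x, ...) {
  cat(sprintf("<injection_protocol> %s, Q = %g mL/s for %g s, outputs at %s s\n",
              x$site, x$rate * 1e6, x$duration,
              paste(x$output_times, collapse = ", ")))
  invisible(x)
}
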