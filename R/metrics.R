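#' Sample the saturation field on an observation plane
#'
#' Returns the voxel layer whose cell centers are nearest the section
#' coordinate (ties broken toward the injection point, i.e. toward
#' coordinate 0), together with the interior mask of the phantom on that
#' layer. Transverse sections are fixed-z layers, longitudinal sections
#' fixed-y layers; the endplate section is the topmost cancellous layer.
#'
#' @param state A `sim_state` (or a bare saturation array).
#' @param phantom A `porous_phantom`.
#' @param section A `section_spec` (plane or endplate kind), or the name of
#'   one in the phantom's catalog.
#' @return A `plane_field`: list with `section`, `values` (2-D saturation
#'   matrix), `mask` (interior logical matrix), and the in-plane axis
#'   coordinates `u`, `w` (m).
#' @export
extract_plane <- function(state, phantom, section) {
  s <- if (inherits(state, "sim_state")) state$s else state
  if (is.character(section)) {
    if (!section %in% names(phantom$sections))
      stop(sprintf("unknown section '%s'", section))
    section <- phantom$sections[[section]]
  }
  if (section$kind == "wall_ring")
    stop("type error: section is a wall ring; use extract_wall_ring()")
  grid <- phantom$grid
  axis <- section$axis
  coords <- grid_axis(grid, axis)
  # nearest layer; ties toward the injection point (coordinate 0)
  d <- abs(coords - section$coordinate)
  cand <- which(d < min(d) + 1e-12)
  layer <- cand[which.min(abs(coords[cand]))]
  canc <- phantom$cell_class == .CANCELLOUS
  if (axis == "z") {
    vals <- s[, , layer]
    mask <- canc[, , layer]
    u <- grid_axis(grid, "x"); w <- grid_axis(grid, "y")
  } else if (axis == "y") {
    vals <- s[, layer, ]
    mask <- canc[, layer, ]
    u <- grid_axis(grid, "x"); w <- grid_axis(grid, "z")
  } else {
    vals <- s[layer, , ]
    mask <- canc[layer, , ]
    u <- grid_axis(grid, "y"); w <- grid_axis(grid, "z")
  }
  vals[!mask] <- 0
  structure(list(section = section, values = vals, mask = mask,
                 u = u, w = w, h = grid$h),
            class = "plane_field")
}

#' Distribution area percentage on a section
#'
#' Percentage of the section's interior area where the oil saturation is at
#' least `theta`: the per-plane distribution-area measure of the observation
#' protocol (100 * thresholded pixels / interior pixels).
#'
#' @param plane A `plane_field` from [extract_plane()].
#' @param theta Saturation threshold in (0, 1); default 0.5, the midpoint of
#'   a piston-like front.
#' @return Percentage in `[0, 100]`.
#' @export
distribution_area_fraction <- function(plane, theta = 0.5) {
  stopifnot(theta > 0, theta < 1)
  n_int <- sum(plane$mask)
  if (n_int == 0L) stop("domain error: section has an empty interior mask")
  100 * sum(plane$values >= theta & plane$mask) / n_int
}

#' Equivalent distribution radius on a section
#'
#' Radius of the disc with the same area as the thresholded region:
#' \eqn{\sqrt{A_\theta/\pi}}. Used as the per-section "distribution radius"
#' because the spread is circle-like but not exactly circular.
#'
#' @inheritParams distribution_area_fraction
#' @return Radius (m); 0 for an empty superlevel set.
#' @export
equivalent_radius <- function(plane, theta = 0.5) {
  stopifnot(theta > 0, theta < 1)
  A <- sum(plane$values >= theta & plane$mask) * plane$h^2
  sqrt(A / pi)
}

#' Saturation on a wall-ring section
#'
#' Per-face oil saturation of the interior cells adjacent to the ring faces,
#' the fraction of ring area with saturation at least `theta`, and an
#' unrolled (arc angle x z) parameterization for plotting.
#'
#' @param state A `sim_state` or saturation array.
#' @param phantom A `porous_phantom`.
#' @param section A wall-ring `section_spec` or its name.
#' @param theta Saturation threshold.
#' @return A `wall_ring_field`: list with `contacted_fraction` (percent),
#'   `faces` (data frame with per-face `s`, angular coordinate `angle_deg`,
#'   and `z`), and `section`.
#' @export
extract_wall_ring <- function(state, phantom, section, theta = 0.5) {
  s <- if (inherits(state, "sim_state")) state$s else state
  if (is.character(section)) {
    if (!section %in% names(phantom$sections))
      stop(sprintf("unknown section '%s'", section))
    section <- phantom$sections[[section]]
  }
  if (section$kind != "wall_ring")
    stop("type error: section is not a wall ring; use extract_plane()")
  f <- section$faces
  if (is.null(f) || nrow(f) == 0L) stop("wall ring has no faces")
  sat <- s[cbind(f$i, f$j, f$k)]
  ctr <- phantom$params$body_center %||% c(0, 0, 0)
  ang <- atan2(f$fy - ctr[2], f$fx - ctr[1]) * 180 / pi
  structure(list(section = section,
                 contacted_fraction = 100 * mean(sat >= theta),
                 faces = data.frame(angle_deg = ang, z = f$fz, s = sat)),
            class = "wall_ring_field")
}

#' Sphere-likeness of the oil body
#'
#' Ratio of the smallest to the largest eigenvalue of the second-moment
#' (covariance) matrix of the thresholded saturation region's voxel centers:
#' 1 for a perfect ball, near 0 for a slab. Quantifies the observation that
#' the injected oil forms a sphere-like body as a whole.
#'
#' @param state A `sim_state` or saturation array.
#' @param phantom A `porous_phantom`.
#' @param theta Saturation threshold.
#' @return Score in (0, 1].
#' @export
sphericity <- function(state, phantom, theta = 0.5) {
  s <- if (inherits(state, "sim_state")) state$s else state
  sel <- which(s >= theta)
  if (!length(sel)) stop("domain error: empty superlevel set")
  ijk <- arrayInd(sel, dim(s))
  h <- phantom$grid$h
  pts <- cbind(grid_axis(phantom$grid, "x")[ijk[, 1]],
               grid_axis(phantom$grid, "y")[ijk[, 2]],
               grid_axis(phantom$grid, "z")[ijk[, 3]])
  # add the voxel's own second moment h^2/12 so single-layer sets are
  # measured at voxel thickness rather than zero
  C <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) + diag(h^2 / 12, 3)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev[3] / ev[1]
}

#' Per-section metric time series
#'
#' Assembles the distribution metrics of every requested section at every
#' snapshot: area percentage and equivalent radius for planes/endplate,
#' contacted-area fraction for wall rings. This is the tabular form behind
#' the per-section line charts (metric versus time, one curve per section).
#'
#' @param snapshots List of `sim_state` (e.g. `run$snapshots`), time-ordered.
#' @param phantom A `porous_phantom`.
#' @param sections Character vector of section names (default: all in the
#'   phantom catalog).
#' @param theta Saturation threshold.
#' @return Data frame with columns `time_s`, `section`, `kind`,
#'   `area_fraction_pct`, `equivalent_radius_mm`, `contacted_fraction_pct`.
#' @export
series_report <- function(snapshots, phantom,
                          sections = names(phantom$sections), theta = 0.5) {
  rows <- list()
  for (st in snapshots) {
    for (nm in sections) {
      sec <- phantom$sections[[nm]]
      if (is.null(sec)) stop(sprintf("unknown section '%s'", nm))
      if (sec$kind == "wall_ring") {
        wr <- extract_wall_ring(st, phantom, sec, theta)
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = st$t, section = nm, kind = sec$kind,
          area_fraction_pct = NA_real_, equivalent_radius_mm = NA_real_,
          contacted_fraction_pct = wr$contacted_fraction)
      } else {
        pl <- extract_plane(st, phantom, sec)
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = st$t, section = nm, kind = sec$kind,
          area_fraction_pct = distribution_area_fraction(pl, theta),
          equivalent_radius_mm = 1000 * equivalent_radius(pl, theta),
          contacted_fraction_pct = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Line chart of a section metric versus time
#'
#' One curve per section, mirroring the distribution-area / distribution-
#' radius charts of the observation protocol.
#'
#' @param series Data frame from [series_report()].
#' @param metric Column to plot.
#' @return A ggplot object.
#' @export
plot_series <- function(series,
                        metric = c("area_fraction_pct",
                                   "equivalent_radius_mm",
                                   "contacted_fraction_pct")) {
  metric <- match.arg(metric)
  df <- series[!is.na(series[[metric]]), ]
  lab <- switch(metric,
                area_fraction_pct = "distribution area (% of section)",
                equivalent_radius_mm = "equivalent radius (mm)",
                contacted_fraction_pct = "wall area contacted (%)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data[[metric]],
                                   color = .data$section)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time after injection start (s)", y = lab,
                  color = "section") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
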