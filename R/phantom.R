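#' @useDynLib vertebroflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# cell-class codes used throughout the voxel volumes
.CANCELLOUS <- 1L
.CORTICAL   <- 2L
.EXTERIOR   <- 3L
.VENT       <- 4L

#' Cell-class codes of the voxel phantom
#'
#' The phantom volume labels every voxel as cancellous interior, impermeable
#' cortical shell, exterior space, or pressure-reference vent.
#'
#' @return Named integer vector of the four class codes.
#' @export
cell_classes <- function() {
  c(cancellous = .CANCELLOUS, cortical = .CORTICAL,
    exterior = .EXTERIOR, vent = .VENT)
}

#' Uniform voxel grid specification
#'
#' Cell-centered uniform grid. The physical coordinate origin coincides with
#' the center of the cell at `origin_index`; by convention the injection point
#' is placed there. Axes follow the anatomical frame: x short (transverse)
#' axis, y long (anteroposterior) axis, z vertical.
#'
#' @param nx,ny,nz Voxel counts (each >= 8).
#' @param h Voxel edge length (m).
#' @param origin_index Integer vector `c(i0, j0, k0)`: index of the cell whose
#'   center is the coordinate origin.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(nx, ny, nz, h, origin_index) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (min(nx, ny, nz) < 8L) stop("grid_spec: nx, ny, nz must each be >= 8")
  if (!is.numeric(h) || h <= 0) stop("grid_spec: voxel size h must be > 0")
  origin_index <- as.integer(origin_index)
  if (length(origin_index) != 3L ||
      any(origin_index < 1L | origin_index > c(nx, ny, nz)))
    stop("grid_spec: origin_index must lie inside the grid")
  structure(list(nx = nx, ny = ny, nz = nz, h = h,
                 origin_index = origin_index),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, h = %g mm, origin cell (%d,%d,%d)\n",
              x$nx, x$ny, x$nz, 1000 * x$h,
              x$origin_index[1], x$origin_index[2], x$origin_index[3]))
  invisible(x)
}

# cell-center coordinates along one axis
grid_axis <- function(grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- switch(axis, x = 1L, y = 2L, z = 3L)
  n <- c(grid$nx, grid$ny, grid$nz)[d]
  (seq_len(n) - grid$origin_index[d]) * grid$h
}

# grid that covers [xr, yr, zr] (physical, m) plus `margin` voxels, with the
# origin exactly on a cell center
make_grid_for_extent <- function(xr, yr, zr, h, margin = 2L) {
  rng <- function(r) {
    lo <- floor(r[1] / h - 0.5) - margin
    hi <- ceiling(r[2] / h + 0.5) + margin
    c(lo, hi)
  }
  ix <- rng(xr); iy <- rng(yr); iz <- rng(zr)
  grid_spec(diff(ix) + 1L, diff(iy) + 1L, diff(iz) + 1L, h,
            origin_index = c(1L - ix[1], 1L - iy[1], 1L - iz[1]))
}

#' Named observation section
#'
#' Sections mirror the observation protocol of the experiment: transverse
#' planes (fixed z), longitudinal planes (fixed y), the upper endplate layer,
#' and ring-shaped wall sections.
#'
#' @param name Section name (e.g. `"plane1"`, `"endplate"`,
#'   `"posterior_wall_ring"`).
#' @param kind One of `"transverse"`, `"longitudinal"`, `"endplate"`,
#'   `"wall_ring"`.
#' @param axis Plane normal axis (`"z"` for transverse, `"y"` for
#'   longitudinal); unused for wall rings.
#' @param coordinate Physical offset of the plane from the origin (m).
#' @param faces For wall rings: data frame of interior-surface voxel faces
#'   (columns `i`, `j`, `k` of the adjacent cancellous cell, `dir`, and face
#'   center coordinates `fx`, `fy`, `fz`).
#' @return A `section_spec` object.
#' @export
section_spec <- function(name, kind, axis = NULL, coordinate = NULL,
                         faces = NULL) {
  kind <- match.arg(kind, c("transverse", "longitudinal", "endplate",
                            "wall_ring"))
  structure(list(name = name, kind = kind, axis = axis,
                 coordinate = coordinate, faces = faces),
            class = "section_spec")
}

# classify one elliptical-cylinder body (center = physical center, m).
# Interior: (x/ax)^2 + (y/ay)^2 <= 1, |z| <= hh. Shell: the same test with
# semiaxes/half-height grown by `shell` (for shell << a the offset surface is
# within O(shell^2/a) of the true normal offset).
classify_body <- function(grid, center, a_x, a_y, half_height, shell) {
  x <- grid_axis(grid, "x") - center[1]
  y <- grid_axis(grid, "y") - center[2]
  z <- grid_axis(grid, "z") - center[3]
  ex2 <- outer((x / a_x)^2, (y / a_y)^2, "+")               # nx x ny
  ex2s <- outer((x / (a_x + shell))^2, (y / (a_y + shell))^2, "+")
  cls <- array(.EXTERIOR, dim = c(grid$nx, grid$ny, grid$nz))
  for (k in seq_len(grid$nz)) {
    zk <- abs(z[k])
    if (zk <= half_height + shell) {
      sl <- ifelse(ex2s <= 1, .CORTICAL, .EXTERIOR)
      if (zk <= half_height) sl[ex2 <= 1] <- .CANCELLOUS
      cls[, , k] <- sl
    }
  }
  cls
}

# 6-neighborhood shift of a logical/integer array; out-of-range filled with NA
shift_arr <- function(a, d) {
  nx <- dim(a)[1]; ny <- dim(a)[2]; nz <- dim(a)[3]
  out <- array(NA, dim = dim(a))
  if (d == "+x") out[1:(nx - 1), , ] <- a[2:nx, , ]
  if (d == "-x") out[2:nx, , ] <- a[1:(nx - 1), , ]
  if (d == "+y") out[, 1:(ny - 1), ] <- a[, 2:ny, ]
  if (d == "-y") out[, 2:ny, ] <- a[, 1:(ny - 1), ]
  if (d == "+z") out[, , 1:(nz - 1)] <- a[, , 2:nz]
  if (d == "-z") out[, , 2:nz] <- a[, , 1:(nz - 1)]
  out
}

# any 6-neighbor of each voxel satisfies `pred` on cls
adjacent_to <- function(cls, code) {
  hit <- array(FALSE, dim = dim(cls))
  for (d in c("+x", "-x", "+y", "-y", "+z", "-z")) {
    s <- shift_arr(cls, d)
    hit <- hit | (!is.na(s) & s == code)
  }
  hit
}

# convert exterior voxels that touch cancellous voxels into cortical, so the
# shell topologically separates the interior everywhere (voxelization corners,
# channel walls and end cap included)
seal_shell <- function(cls) {
  leak <- cls == .EXTERIOR & adjacent_to(cls, .CANCELLOUS)
  cls[leak] <- .CORTICAL
  cls
}

# pick n cortical wall cells adjacent to the interior, nearest to `target`
# (physical coords), and convert them to vents
place_vents <- function(cls, grid, target, n_vent) {
  cand <- which(cls == .CORTICAL & adjacent_to(cls, .CANCELLOUS))
  if (length(cand) == 0L) stop("no interior-surface cortical cells found")
  ijk <- arrayInd(cand, dim(cls))
  xs <- grid_axis(grid, "x")[ijk[, 1]]
  ys <- grid_axis(grid, "y")[ijk[, 2]]
  zs <- grid_axis(grid, "z")[ijk[, 3]]
  d2 <- (xs - target[1])^2 + (ys - target[2])^2 + (zs - target[3])^2
  sel <- cand[order(d2)[seq_len(min(n_vent, length(cand)))]]
  cls[sel] <- .VENT
  cls
}

finish_phantom <- function(grid, cls, porosity, permeability, injection_index,
                           site_name, sections, params) {
  poro <- array(0, dim = dim(cls))
  perm <- array(0, dim = dim(cls))
  flow <- cls == .CANCELLOUS | cls == .VENT
  poro[flow] <- porosity
  perm[flow] <- permeability
  structure(list(grid = grid, porosity = poro, permeability = perm,
                 cell_class = cls,
                 injection_site = list(index = as.integer(injection_index),
                                       name = site_name),
                 sections = sections, params = params,
                 cache = new.env(parent = emptyenv())),
            class = "porous_phantom")
}

#' @export
print.porous_phantom <- function(x, ...) {
  n <- tabulate(x$cell_class, 4L)
  cat(sprintf(paste0("<porous_phantom> %s injection\n",
                     "  grid %d x %d x %d (h = %g mm)\n",
                     "  cells: %d cancellous, %d cortical, %d exterior, %d vent\n",
                     "  sections: %s\n"),
              x$injection_site$name, x$grid$nx, x$grid$ny, x$grid$nz,
              1000 * x$grid$h, n[1], n[2], n[3], n[4],
              paste(names(x$sections), collapse = ", ")))
  invisible(x)
}

#' Permeability from mean pore diameter (Kozeny–Carman)
#'
#' Granular-bed Kozeny–Carman closure
#' \eqn{\alpha = \phi^3 d^2 / (180 (1-\phi)^2)} relating permeability to
#' porosity and mean pore diameter. Used to derive the cancellous-bone
#' permeability from the measured pore size (0.90 mm) and porosity (0.75),
#' which gives \eqn{\alpha \approx 3.04\times 10^{-8}} m^2.
#'
#' @param d Mean pore diameter (m), >= 0.
#' @param phi Porosity in `[0, 1)`.
#' @return Permeability (m^2); 0 when `d = 0` or `phi = 0`.
#' @export
permeability_from_pore_diameter <- function(d, phi) {
  if (any(phi < 0) || any(phi >= 1))
    stop("permeability_from_pore_diameter: phi must lie in [0, 1)")
  if (any(d < 0)) stop("permeability_from_pore_diameter: d must be >= 0")
  phi^3 * d^2 / (180 * (1 - phi)^2)
}

default_body_params <- function() {
  list(a_x = 0.021, a_y = 0.015, half_height = 0.010,
       shell_thickness = 0.001, porosity = 0.75, pore_diameter = 0.90e-3)
}

#' Build the vertebral-body phantom (central injection)
#'
#' The vertebral body is modeled as an elliptical cylinder of cancellous bone
#' wrapped in an impermeable cortical shell. The injection point is the
#' physical center of the body and the coordinate origin. The section catalog
#' holds the transverse planes 1/2/3 (z = 0, +2, -2 mm) and longitudinal
#' planes 6/5/7 (y = 0, +5, -5 mm) of the observation protocol. A small patch
#' of vent cells on the posterior wall at z = 0 (the basivertebral
#' foramen/needle tract) gives displaced air a pressure-reference escape path.
#'
#' @param a_x,a_y Transverse and anteroposterior interior semiaxes (m).
#' @param half_height Interior half-height (m).
#' @param shell_thickness Cortical shell thickness (m), >= h.
#' @param h Voxel edge length (m).
#' @param porosity Cancellous porosity (pore volume fraction).
#' @param pore_diameter Mean pore diameter (m), used to derive permeability
#'   via [permeability_from_pore_diameter()] unless `permeability` is given.
#' @param permeability Optional explicit cancellous permeability (m^2).
#' @param n_vent Number of vent cells in the posterior wall patch.
#' @param margin Exterior voxel margin around the shell.
#' @return A `porous_phantom`.
#' @export
build_vertebral_body <- function(a_x = 0.021, a_y = 0.015,
                                 half_height = 0.010,
                                 shell_thickness = 0.001, h = 0.5e-3,
                                 porosity = 0.75, pore_diameter = 0.90e-3,
                                 permeability = NULL, n_vent = 5L,
                                 margin = 2L) {
  if (min(a_x, a_y, half_height) < 4 * h)
    stop("geometry error: semiaxes and half_height must each be >= 4*h")
  if (shell_thickness < h)
    stop("geometry error: shell_thickness must be >= h")
  if (is.null(permeability))
    permeability <- permeability_from_pore_diameter(pore_diameter, porosity)
  ext <- c(a_x, a_y, half_height) + shell_thickness
  grid <- make_grid_for_extent(c(-ext[1], ext[1]), c(-ext[2], ext[2]),
                               c(-ext[3], ext[3]), h, margin)
  cls <- classify_body(grid, c(0, 0, 0), a_x, a_y, half_height,
                       shell_thickness)
  cls <- seal_shell(cls)
  cls <- place_vents(cls, grid, c(0, -a_y - shell_thickness / 2, 0), n_vent)
  sections <- list(
    plane1 = section_spec("plane1", "transverse", "z", 0),
    plane2 = section_spec("plane2", "transverse", "z", 0.002),
    plane3 = section_spec("plane3", "transverse", "z", -0.002),
    plane6 = section_spec("plane6", "longitudinal", "y", 0),
    plane5 = section_spec("plane5", "longitudinal", "y", 0.005),
    plane7 = section_spec("plane7", "longitudinal", "y", -0.005)
  )
  for (s in sections) {
    lim <- if (s$axis == "z") half_height else a_y
    if (abs(s$coordinate) >= lim)
      stop(sprintf("configuration error: section %s coordinate outside interior",
                   s$name))
  }
  ph <- finish_phantom(grid, cls, porosity, permeability,
                       grid$origin_index, "body_center", sections,
                       list(a_x = a_x, a_y = a_y, half_height = half_height,
                            shell_thickness = shell_thickness,
                            porosity = porosity,
                            pore_diameter = pore_diameter,
                            permeability = permeability))
  stopifnot(ph$cell_class[ph$injection_site$index[1],
                          ph$injection_site$index[2],
                          ph$injection_site$index[3]] == .CANCELLOUS)
  ph
}

# wall-ring faces: x/y-direction faces of cancellous cells that border the
# cortical wall, inside the body ellipse, |z - z0| <= half-width, and whose
# angular position (body frame) lies in [ang_lo, ang_hi] degrees
wall_ring_faces <- function(cls, grid, body_center, a_x, a_y,
                            ring_halfwidth, ang_lo, ang_hi) {
  xs <- grid_axis(grid, "x"); ys <- grid_axis(grid, "y")
  zs <- grid_axis(grid, "z")
  out <- list()
  for (d in c("+x", "-x", "+y", "-y")) {
    s <- shift_arr(cls, d)
    sel <- which(cls == .CANCELLOUS & !is.na(s) & s == .CORTICAL)
    if (!length(sel)) next
    ijk <- arrayInd(sel, dim(cls))
    fx <- xs[ijk[, 1]] + (d == "+x") * grid$h / 2 - (d == "-x") * grid$h / 2
    fy <- ys[ijk[, 2]] + (d == "+y") * grid$h / 2 - (d == "-y") * grid$h / 2
    fz <- zs[ijk[, 3]]
    inside <- ((xs[ijk[, 1]] - body_center[1]) / a_x)^2 +
      ((ys[ijk[, 2]] - body_center[2]) / a_y)^2 <= 1
    ang <- atan2(fy - body_center[2], fx - body_center[1]) * 180 / pi
    keep <- inside & abs(fz) <= ring_halfwidth & ang >= ang_lo & ang <= ang_hi
    if (any(keep))
      out[[d]] <- data.frame(i = ijk[keep, 1], j = ijk[keep, 2],
                             k = ijk[keep, 3], dir = d,
                             fx = fx[keep], fy = fy[keep], fz = fz[keep])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Build the pedicle-injection phantom
#'
#' The vertebral body of [build_vertebral_body()] plus a cylindrical
#' cancellous channel through the posterolateral cortical shell, standing for
#' the pedicle. The injection point sits on the channel axis at the
#' pedicle–body junction and is the coordinate origin; the upper endplate
#' interior surface lies at z = `half_height` above it. The section catalog
#' holds planes 1/2/3 (z = 0, ±2 mm), plane 4 (z = 9.7 mm, 0.3 mm below the
#' endplate surface), the endplate layer, and the lateral and posterior
#' wall-ring sections. The channel's outer end is capped (the cannula seals
#' the tract); vents sit on the anterior wall.
#'
#' @inheritParams build_vertebral_body
#' @param pedicle_radius Channel radius (m), >= 2*h.
#' @param pedicle_length Channel length beyond the shell (m).
#' @param pedicle_offset_x Lateral (x) offset of the channel axis from the
#'   body midline (m); the channel runs in the -y direction.
#' @param ring_halfwidth Half-extent in z of the wall-ring sections (m).
#' @return A `porous_phantom`.
#' @export
build_pedicle_phantom <- function(a_x = 0.021, a_y = 0.015,
                                  half_height = 0.010,
                                  shell_thickness = 0.001, h = 0.5e-3,
                                  porosity = 0.75, pore_diameter = 0.90e-3,
                                  permeability = NULL,
                                  pedicle_radius = 2.5e-3,
                                  pedicle_length = 5e-3,
                                  pedicle_offset_x = 0.012,
                                  ring_halfwidth = 6e-3,
                                  n_vent = 5L, margin = 2L) {
  if (pedicle_radius < 2 * h)
    stop("geometry error: pedicle channel radius must be >= 2*h")
  if (abs(pedicle_offset_x) >= a_x)
    stop("geometry error: pedicle channel does not reach the interior")
  if (is.null(permeability))
    permeability <- permeability_from_pore_diameter(pore_diameter, porosity)
  # body center in injection-point coordinates: junction on the posterior
  # boundary of the ellipse at lateral offset pedicle_offset_x
  y_b <- a_y * sqrt(1 - (pedicle_offset_x / a_x)^2)
  center <- c(-pedicle_offset_x, y_b, 0)
  ext_lo <- c(center[1] - a_x - shell_thickness,
              -(shell_thickness + pedicle_length + 2 * h),
              -half_height - shell_thickness)
  ext_hi <- c(center[1] + a_x + shell_thickness,
              center[2] + a_y + shell_thickness,
              half_height + shell_thickness)
  grid <- make_grid_for_extent(c(ext_lo[1], ext_hi[1]),
                               c(ext_lo[2], ext_hi[2]),
                               c(ext_lo[3], ext_hi[3]), h, margin)
  cls <- classify_body(grid, center, a_x, a_y, half_height, shell_thickness)
  # carve the channel: cylinder about the line x = 0, z = 0 running in -y
  xs <- grid_axis(grid, "x"); ys <- grid_axis(grid, "y")
  zs <- grid_axis(grid, "z")
  in_rad <- outer(xs^2, zs^2, "+") <= pedicle_radius^2      # nx x nz
  jsel <- which(ys >= -(shell_thickness + pedicle_length) & ys <= 0)
  for (j in jsel) {
    sl <- cls[, j, ]
    carve <- in_rad & sl != .CANCELLOUS
    sl[carve] <- .CANCELLOUS
    cls[, j, ] <- sl
  }
  cls <- seal_shell(cls)   # walls + end cap for the channel, corner sealing
  cls <- place_vents(cls, grid,
                     c(center[1], center[2] + a_y + shell_thickness / 2, 0),
                     n_vent)
  endplate_z <- half_height
  sections <- list(
    plane1 = section_spec("plane1", "transverse", "z", 0),
    plane2 = section_spec("plane2", "transverse", "z", 0.002),
    plane3 = section_spec("plane3", "transverse", "z", -0.002),
    plane4 = section_spec("plane4", "transverse", "z", 0.0097),
    endplate = section_spec("endplate", "endplate", "z", endplate_z),
    lateral_wall_ring = section_spec(
      "lateral_wall_ring", "wall_ring",
      faces = wall_ring_faces(cls, grid, center, a_x, a_y, ring_halfwidth,
                              -45, 45)),
    posterior_wall_ring = section_spec(
      "posterior_wall_ring", "wall_ring",
      faces = wall_ring_faces(cls, grid, center, a_x, a_y, ring_halfwidth,
                              -135, -45))
  )
  if (sections$plane4$coordinate >= endplate_z)
    stop("configuration error: plane 4 must lie below the endplate surface")
  ph <- finish_phantom(grid, cls, porosity, permeability,
                       grid$origin_index, "pedicle_junction", sections,
                       list(a_x = a_x, a_y = a_y, half_height = half_height,
                            shell_thickness = shell_thickness,
                            porosity = porosity,
                            pore_diameter = pore_diameter,
                            permeability = permeability,
                            pedicle_radius = pedicle_radius,
                            pedicle_length = pedicle_length,
                            pedicle_offset_x = pedicle_offset_x,
                            body_center = center))
  if (ph$cell_class[ph$injection_site$index[1], ph$injection_site$index[2],
                    ph$injection_site$index[3]] != .CANCELLOUS)
    stop("geometry error: pedicle injection site is not a cancellous cell")
  ph
}

#' Rectangular test phantom
#'
#' A homogeneous cancellous box wrapped in a one-voxel boundary layer, used
#' for solver verification (point-source pressure fields, 1-D columns).
#' Boundary faces listed in `vent_sides` become vent (Dirichlet-pressure)
#' cells; the rest of the boundary is cortical.
#'
#' @param n Interior voxel counts `c(nx, ny, nz)`.
#' @param h Voxel edge length (m).
#' @param porosity,permeability Homogeneous material properties.
#' @param vent_sides Character vector among `"-x","+x","-y","+y","-z","+z"`,
#'   or `"all"`.
#' @return A `porous_phantom` with the injection site at the center cell.
#' @export
phantom_box <- function(n = c(32, 32, 32), h = 1e-3, porosity = 0.75,
                        permeability = permeability_from_pore_diameter(0.90e-3, 0.75),
                        vent_sides = "all") {
  n <- as.integer(n)
  ctr <- (n + 1L) %/% 2L + 1L      # center interior cell, 1 boundary layer
  grid <- grid_spec(n[1] + 2L, n[2] + 2L, n[3] + 2L, h, origin_index = ctr)
  cls <- array(.CORTICAL, dim = c(grid$nx, grid$ny, grid$nz))
  cls[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- .CANCELLOUS
  if (identical(vent_sides, "all"))
    vent_sides <- c("-x", "+x", "-y", "+y", "-z", "+z")
  for (s in vent_sides) {
    if (s == "-x") cls[1, , ] <- ifelse(cls[1, , ] == .CORTICAL, .VENT, cls[1, , ])
    if (s == "+x") cls[grid$nx, , ] <- ifelse(cls[grid$nx, , ] == .CORTICAL, .VENT, cls[grid$nx, , ])
    if (s == "-y") cls[, 1, ] <- ifelse(cls[, 1, ] == .CORTICAL, .VENT, cls[, 1, ])
    if (s == "+y") cls[, grid$ny, ] <- ifelse(cls[, grid$ny, ] == .CORTICAL, .VENT, cls[, grid$ny, ])
    if (s == "-z") cls[, , 1] <- ifelse(cls[, , 1] == .CORTICAL, .VENT, cls[, , 1])
    if (s == "+z") cls[, , grid$nz] <- ifelse(cls[, , grid$nz] == .CORTICAL, .VENT, cls[, , grid$nz])
  }
  finish_phantom(grid, cls, porosity, permeability, ctr, "body_center",
                 list(), list(porosity = porosity,
                              permeability = permeability))
}

#' Validate phantom invariants
#'
#' Checks the structural invariants of a phantom: zero porosity and
#' permeability on cortical/exterior cells, positive values on cancellous
#' cells, a cancellous injection site, a nonempty vent set adjacent to the
#' interior, and topological separation of the interior from the exterior by
#' the shell (no cancellous cell touches an exterior cell face-on).
#'
#' @param phantom A `porous_phantom`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_phantom <- function(phantom) {
  cls <- phantom$cell_class
  if (any(phantom$porosity[cls == .CORTICAL | cls == .EXTERIOR] != 0) ||
      any(phantom$permeability[cls == .CORTICAL | cls == .EXTERIOR] != 0))
    stop("invariant violated: nonzero porosity/permeability on cortical or exterior cells")
  canc <- cls == .CANCELLOUS
  if (!any(canc)) stop("invariant violated: no cancellous cells")
  if (any(phantom$porosity[canc] <= 0) || any(phantom$porosity[canc] > 1) ||
      any(phantom$permeability[canc] <= 0))
    stop("invariant violated: cancellous cells need porosity in (0,1] and permeability > 0")
  ii <- phantom$injection_site$index
  if (cls[ii[1], ii[2], ii[3]] != .CANCELLOUS)
    stop("invariant violated: injection site is not a cancellous cell")
  if (!any(cls == .VENT))
    stop("invariant violated: vent cell set is empty")
  if (!any(cls == .VENT & adjacent_to(cls, .CANCELLOUS)))
    stop("invariant violated: no vent cell touches the interior")
  if (any(canc & adjacent_to(cls, .EXTERIOR)))
    stop("invariant violated: cancellous cell in face contact with exterior")
  bdry <- array(FALSE, dim = dim(cls))
  bdry[c(1, dim(cls)[1]), , ] <- TRUE
  bdry[, c(1, dim(cls)[2]), ] <- TRUE
  bdry[, , c(1, dim(cls)[3])] <- TRUE
  if (any(canc & bdry))
    stop("invariant violated: phantom interior touches the grid boundary (no exterior margin)")
  invisible(TRUE)
}

#' Interior pore volume of a phantom
#'
#' @param phantom A `porous_phantom`.
#' @return Total pore volume of the cancellous interior (m^3).
#' @export
interior_pore_volume <- function(phantom) {
  canc <- phantom$cell_class == .CANCELLOUS
  sum(phantom$porosity[canc]) * phantom$grid$h^3
}
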