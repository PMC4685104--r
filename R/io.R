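# ---- VTK legacy structured-points export/import (ASCII) ----

#' Write scalar fields to a legacy VTK structured-points file
#'
#' Cell-centered voxel fields are written as POINT_DATA on the lattice of
#' cell centers (uniform spacing `h`), one SCALARS array per field. The
#' format is the plain-text legacy VTK format readable by ParaView/VisIt.
#'
#' @param file Output path.
#' @param grid A `grid_spec`.
#' @param fields Named list of arrays with the grid's dimensions.
#' @param title Dataset title line.
#' @return Invisibly `file`.
#' @export
write_vtk_structured_points <- function(file, grid, fields,
                                        title = "vertebroflow field") {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  con <- file(file, "w")
  on.exit(close(con))
  origin <- -(grid$origin_index - 1L) * grid$h
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz),
               sprintf("ORIGIN %.9g %.9g %.9g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %.9g %.9g %.9g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", grid$nx * grid$ny * grid$nz)), con)
  for (nm in names(fields)) {
    a <- fields[[nm]]
    stopifnot(all(dim(a) == c(grid$nx, grid$ny, grid$nz)))
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(a), digits = 9, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(file)
}

#' Read scalar fields from a legacy VTK structured-points file
#'
#' Minimal reader for files produced by [write_vtk_structured_points()].
#'
#' @param file Input path.
#' @return List with `grid` (a `grid_spec`) and `fields` (named list of
#'   arrays).
#' @export
read_vtk_structured_points <- function(file) {
  lines <- readLines(file)
  dim_ln <- grep("^DIMENSIONS", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(trimws(dim_ln), "\\s+")[[1]][2:4])
  org_ln <- grep("^ORIGIN", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(org_ln), "\\s+")[[1]][2:4])
  sp_ln <- grep("^SPACING", lines, value = TRUE)[1]
  h <- as.numeric(strsplit(trimws(sp_ln), "\\s+")[[1]][2])
  origin_index <- as.integer(round(1 - origin / h))
  grid <- grid_spec(dims[1], dims[2], dims[3], h, origin_index)
  n <- prod(dims)
  fields <- list()
  sc <- grep("^SCALARS", lines)
  for (p in sc) {
    nm <- strsplit(trimws(lines[p]), "\\s+")[[1]][2]
    vals <- as.numeric(lines[(p + 2):(p + 1 + n)])
    fields[[nm]] <- array(vals, dims)
  }
  list(grid = grid, fields = fields)
}

# ---- phantom export/import: VTK volume + JSON sidecar ----

section_to_list <- function(s) {
  out <- list(name = s$name, kind = s$kind)
  if (!is.null(s$axis)) out$axis <- s$axis
  if (!is.null(s$coordinate)) out$coordinate <- s$coordinate
  if (!is.null(s$faces)) out$faces <- s$faces
  out
}

#' Export a phantom to disk
#'
#' Writes `<prefix>.vtk` (porosity, permeability, cell_class volumes) and
#' `<prefix>.json` (grid spec, injection site, section catalog, build
#' parameters).
#'
#' @param phantom A `porous_phantom`.
#' @param prefix Output path prefix.
#' @return Invisibly the two file paths.
#' @export
write_phantom <- function(phantom, prefix) {
  vtk <- paste0(prefix, ".vtk")
  js <- paste0(prefix, ".json")
  write_vtk_structured_points(vtk, phantom$grid,
                              list(porosity = phantom$porosity,
                                   permeability = phantom$permeability,
                                   cell_class = phantom$cell_class),
                              title = "vertebroflow phantom")
  side <- list(grid = phantom$grid[c("nx", "ny", "nz", "h", "origin_index")],
               injection_site = phantom$injection_site,
               sections = lapply(phantom$sections, section_to_list),
               params = phantom$params)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(vtk, js))
}

#' Import a phantom written by [write_phantom()]
#'
#' @param prefix Path prefix used at export time.
#' @return A `porous_phantom`.
#' @export
read_phantom <- function(prefix) {
  v <- read_vtk_structured_points(paste0(prefix, ".vtk"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sections <- lapply(side$sections, function(s) {
    faces <- s$faces
    if (!is.null(faces)) faces <- as.data.frame(faces)
    section_spec(s$name, s$kind, s$axis %||% NULL,
                 s$coordinate %||% NULL, faces)
  })
  names(sections) <- vapply(sections, function(s) s$name, "")
  cls <- array(as.integer(round(v$fields$cell_class)), dim(v$fields$cell_class))
  structure(list(grid = v$grid, porosity = v$fields$porosity,
                 permeability = v$fields$permeability, cell_class = cls,
                 injection_site = list(
                   index = as.integer(side$injection_site$index),
                   name = side$injection_site$name),
                 sections = sections,
                 params = side$params,
                 cache = new.env(parent = emptyenv())),
            class = "porous_phantom")
}

#' Export a simulation snapshot to VTK
#'
#' Writes the pressure and saturation fields of one `sim_state` as scalar
#' arrays in a legacy VTK structured-points file.
#'
#' @param state A `sim_state`.
#' @param phantom A `porous_phantom`.
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_snapshot <- function(state, phantom, file) {
  write_vtk_structured_points(file, phantom$grid,
                              list(pressure = state$P %||% array(0, dim(state$s)),
                                   saturation = state$s),
                              title = sprintf("t = %g s", state$t))
}
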