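# shared fixtures, memoized so expensive runs happen once per test session
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# coarse body phantom/run (h = 1 mm) for unit tests
coarse_body_phantom <- function() memo("coarse_body", build_vertebral_body(h = 1e-3))

coarse_body_run <- function() memo("coarse_body_run", {
  run_simulation(coarse_body_phantom(),
                 injection_protocol(rate = 3e-7, duration = 1,
                                    output_times = c(0.5, 1)))
})

# default-resolution runs (h = 0.5 mm) for the acceptance properties
body_run_default <- function() memo("body_run_default", {
  run_simulation(build_vertebral_body(),
                 injection_protocol(rate = 3e-7, duration = 7,
                                    output_times = c(1, 4, 7)))
})

pedicle_run_default <- function() memo("pedicle_run_default", {
  run_simulation(build_pedicle_phantom(),
                 injection_protocol("pedicle_junction", rate = 3e-7,
                                    duration = 7, output_times = 1:7))
})

mirror_x <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

# synthetic saturated ball of radius R (m) centered at the origin
ball_field <- function(phantom, R) {
  g <- phantom$grid
  x <- (seq_len(g$nx) - g$origin_index[1]) * g$h
  y <- (seq_len(g$ny) - g$origin_index[2]) * g$h
  z <- (seq_len(g$nz) - g$origin_index[3]) * g$h
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  s <- array(0, c(g$nx, g$ny, g$nz))
  s[r2 <= R^2] <- 1
  s[phantom$cell_class != cell_classes()[["cancellous"]]] <- 0
  s
}

# uniform face flux field for transport-only tests
uniform_flux <- function(phantom, vx = 0, vy = 0, vz = 0) {
  g <- phantom$grid
  structure(list(vx = array(vx, c(g$nx + 1, g$ny, g$nz)),
                 vy = array(vy, c(g$nx, g$ny + 1, g$nz)),
                 vz = array(vz, c(g$nx, g$ny, g$nz + 1))),
            class = "face_flux")
}
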