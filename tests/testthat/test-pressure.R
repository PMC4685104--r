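test_that("no forcing gives a zero pressure field and zero fluxes", {
  ph <- phantom_box(c(10, 10, 10), h = 1e-3, vent_sides = "all")
  s <- array(0.3, dim(ph$cell_class))
  s[ph$cell_class > 2] <- 0
  s[ph$cell_class == 2] <- 0
  P <- solve_pressure(ph, s, NULL, fluid_pair())
  expect_equal(max(abs(P)), 0)
  v <- darcy_flux(P, ph, s, fluid_pair())
  expect_equal(max(abs(v$vx)), 0)
  expect_equal(max(abs(v$vy)), 0)
  expect_equal(max(abs(v$vz)), 0)
})

test_that("1-D column with Dirichlet ends has a linear pressure profile and constant flux", {
  ph <- phantom_box(c(20, 6, 6), h = 1e-3, vent_sides = c("-x", "+x"))
  fl <- fluid_pair()
  s <- array(1, dim(ph$cell_class))
  dims <- dim(ph$cell_class)
  vp <- array(0, dims); vp[1, , ] <- 1
  P <- solve_pressure(ph, s, NULL, fl, vent_pressure = vp)
  prof <- P[2:21, 4, 4]
  # discrete Laplace identity: linear decay between the Dirichlet cell
  # centers, which sit one cell outside the interior (21 gaps)
  expected <- 1 - seq_len(20) / 21
  expect_equal(prof, expected, tolerance = 1e-8)
  v <- darcy_flux(P, ph, s, fl, vent_pressure = vp)
  vx <- v$vx[2:21, 4, 4]
  # Darcy's law in 1-D: v = alpha*lambda*dP/L over the 21-cell span
  alpha <- ph$params$permeability
  expect_equal(vx, rep(alpha * (1 / fl$mu_oil) * 1 / 0.021, 20),
               tolerance = 1e-8)
})

test_that("pressure solve agrees with an independent direct sparse solve", {
  skip_if_not_installed("Matrix")
  # heterogeneous deterministic permeability field, mixed saturation
  ph <- phantom_box(c(8, 8, 8), h = 1e-3, vent_sides = c("+z"))
  dims <- dim(ph$cell_class)
  ii <- which(ph$cell_class == cell_classes()[["cancellous"]] |
                ph$cell_class == cell_classes()[["vent"]])
  ph$permeability[ii] <- 1e-8 * (1 + 0.5 * sin(seq_along(ii)))
  s <- array(0, dims)
  s[2:5, 2:5, 2:5] <- 0.8
  s[ph$cell_class != cell_classes()[["cancellous"]]] <- 0
  fl <- fluid_pair(mu_oil = 10, mu_air = 0.1)
  prot <- injection_protocol(rate = 1e-9, duration = 1, output_times = 1)
  P <- solve_pressure(ph, s, prot, fl, tol = 1e-12)

  # independent route: assemble the finite-volume system with Matrix and
  # solve directly
  cc <- cell_classes()
  lam <- s / fl$mu_oil + (1 - s) / fl$mu_air
  amob <- ph$permeability * lam
  amob[ph$cell_class == cc[["cortical"]] |
         ph$cell_class == cc[["exterior"]]] <- 0
  canc <- which(ph$cell_class == cc[["cancellous"]])
  map <- array(0L, dims); map[canc] <- seq_along(canc)
  n <- length(canc)
  trip <- list(); b <- numeric(n)
  src <- ph$injection_site$index
  b[map[src[1], src[2], src[3]]] <- prot$rate
  h <- ph$grid$h
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  diagv <- numeric(n)
  for (r in seq_len(n)) {
    ijk <- arrayInd(canc[r], dims)
    for (m in 1:6) {
      nb <- ijk + offs[m, ]
      if (any(nb < 1) || any(nb > dims)) next
      a <- amob[ijk[1], ijk[2], ijk[3]]; bb <- amob[nb[1], nb[2], nb[3]]
      if (a <= 0 || bb <= 0) next
      cl <- ph$cell_class[nb[1], nb[2], nb[3]]
      if (cl != cc[["cancellous"]] && cl != cc[["vent"]]) next
      Tf <- h * 2 * a * bb / (a + bb)
      diagv[r] <- diagv[r] + Tf
      if (cl == cc[["cancellous"]])
        trip[[length(trip) + 1L]] <- c(r, map[nb[1], nb[2], nb[3]], -Tf)
    }
  }
  tr <- do.call(rbind, trip)
  A <- Matrix::sparseMatrix(i = c(tr[, 1], seq_len(n)),
                            j = c(tr[, 2], seq_len(n)),
                            x = c(tr[, 3], diagv), dims = c(n, n))
  x <- as.numeric(Matrix::solve(A, b))
  expect_equal(P[canc], x, tolerance = 1e-8)
})

test_that("fluxes are conservative: divergence vanishes away from the source", {
  ph <- phantom_box(c(16, 16, 16), h = 1e-3, vent_sides = "all")
  fl <- fluid_pair()
  s <- array(1, dim(ph$cell_class))
  Q <- 1e-9
  prot <- injection_protocol(rate = Q, duration = 1, output_times = 1)
  P <- solve_pressure(ph, s, prot, fl, tol = 1e-12)
  div <- flux_divergence(darcy_flux(P, ph, s, fl), ph)
  cc <- cell_classes()
  mask <- ph$cell_class == cc[["cancellous"]]
  src <- ph$injection_site$index
  mask[src[1], src[2], src[3]] <- FALSE
  expect_lt(max(abs(div[mask])) / Q, 1e-10)
  # at the source, divergence equals the injection rate
  expect_equal(div[src[1], src[2], src[3]], Q, tolerance = 1e-8)
})

test_that("point-source pressure matches the Darcy Green's function", {
  # single-phase oil, analytic Dirichlet boundary data, 32^3 cube
  fl <- fluid_pair()
  alpha <- permeability_from_pore_diameter(0.9e-3, 0.75)
  n <- 32; h <- 1e-3; Q <- 1e-8
  ph <- phantom_box(c(n, n, n), h = h, vent_sides = "all")
  dims <- dim(ph$cell_class)
  s <- array(1, dims)
  x <- (seq_len(dims[1]) - ph$grid$origin_index[1]) * h
  R <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  Pan <- Q * fl$mu_oil / (4 * pi * alpha * pmax(R, h / 2))
  prot <- injection_protocol(rate = Q, duration = 1, output_times = 1)
  P <- solve_pressure(ph, s, prot, fl, vent_pressure = Pan)
  shell <- ph$cell_class == cell_classes()[["cancellous"]] &
    R > 5 * h & R < n * h / 4
  err <- abs(P[shell] - Pan[shell]) / Pan[shell]
  expect_lt(max(err), 0.05)
})

test_that("injecting without a vent is reported as a singular configuration", {
  ph <- phantom_box(c(10, 10, 10), h = 1e-3, vent_sides = character(0))
  s <- array(0, dim(ph$cell_class))
  prot <- injection_protocol(rate = 1e-9, duration = 1, output_times = 1)
  expect_error(solve_pressure(ph, s, prot, fluid_pair()), "vent")
  # but a quiescent no-vent phantom is fine (P = 0 reference)
  expect_equal(max(abs(solve_pressure(ph, s, NULL, fluid_pair()))), 0)
})
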