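test_that("total mobility and fractional flow match hand-evaluated closures", {
  fl <- fluid_pair(mu_oil = 97, mu_air = 1.8e-5)
  # single-phase limits
  expect_equal(total_mobility(1, fl), 1 / 97, tolerance = 1e-12)
  expect_equal(total_mobility(0, fl), 1 / 1.8e-5, tolerance = 1e-12)
  # mixed cell, hand evaluation: 0.5/97 + 0.5/1.8e-5 = 2.77783...e4
  expect_equal(total_mobility(0.5, fl), 0.5 / 97 + 0.5 / 1.8e-5,
               tolerance = 1e-12)
  expect_equal(total_mobility(0.5, fl), 2.778e4, tolerance = 1e-3)
  expect_equal(fractional_flow(0, fl), 0)
  expect_equal(fractional_flow(1, fl), 1)
  # (0.5/97) / 2.7778e4 = 1.8557e-7: the piston-like front in numbers
  expect_equal(fractional_flow(0.5, fl), 1.855e-7, tolerance = 1e-3)
  expect_error(total_mobility(1.5, fl))
})

test_that("fractional flow is monotone nondecreasing for any viscosity pair", {
  s <- seq(0, 1, by = 0.001)
  for (mu in list(c(97, 1.8e-5), c(1, 1), c(10, 1), c(2, 1.9))) {
    fl <- fluid_pair(mu_oil = mu[1], mu_air = mu[2])
    f <- fractional_flow(s, fl)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("stable_dt follows the CFL scaling in h and v", {
  fl <- fluid_pair(mu_oil = 1, mu_air = 1)  # max f' = 1
  ph1 <- phantom_box(c(10, 6, 6), h = 1e-3, porosity = 0.75)
  ph2 <- phantom_box(c(10, 6, 6), h = 0.5e-3, porosity = 0.75)
  v1 <- uniform_flux(ph1, vx = 1e-4)
  v2 <- uniform_flux(ph2, vx = 1e-4)
  dt1 <- stable_dt(v1, ph1, fl, cfl = 0.5)
  dt2 <- stable_dt(v2, ph2, fl, cfl = 0.5)
  expect_equal(dt1, 0.5 * 0.75 * 1e-3 / 1e-4, tolerance = 1e-12)
  expect_equal(dt2 / dt1, 0.5, tolerance = 1e-12)
  # quiescent field: unbounded step (caller caps at the output interval)
  expect_identical(stable_dt(uniform_flux(ph1), ph1, fl), Inf)
  # the extreme viscosity ratio enters through max f' = mu_oil/mu_air
  flx <- fluid_pair(mu_oil = 97, mu_air = 1.8e-5)
  expect_equal(stable_dt(v1, ph1, flx, cfl = 0.5) / dt1, 1.8e-5 / 97,
               tolerance = 1e-10)
})

test_that("explicit update rejects time steps beyond the CFL bound", {
  fl <- fluid_pair(mu_oil = 1, mu_air = 1)
  ph <- phantom_box(c(10, 6, 6), h = 1e-3)
  v <- uniform_flux(ph, vx = 1e-4)
  s <- array(0, dim(ph$cell_class))
  sdt <- stable_dt(v, ph, fl, cfl = 1)
  expect_error(advect_saturation(s, v, ph, dt = 2 * sdt, fl,
                                 method = "explicit"),
               "CFL violation")
})

test_that("no transport happens without flow or source", {
  ph <- phantom_box(c(10, 6, 6), h = 1e-3)
  fl <- fluid_pair()
  s <- array(0, dim(ph$cell_class))
  s[8:10, 5:7, 5:7] <- 0.5
  s[ph$cell_class != cell_classes()[["cancellous"]]] <- 0
  v <- uniform_flux(ph)
  P <- array(0, dim(ph$cell_class))
  for (m in c("implicit", "explicit")) {
    s2 <- advect_saturation(s, v, ph, dt = 1, fl, method = m, P = P)
    expect_equal(as.numeric(s2), as.numeric(s), tolerance = 1e-15)
  }
})

test_that("source accounting telescopes: oil volume grows by exactly Q dt per step", {
  ph <- phantom_box(c(12, 12, 12), h = 1e-3, vent_sides = "all")
  fl <- fluid_pair()
  Q <- 1e-9
  s <- array(0, dim(ph$cell_class))
  prot <- injection_protocol(rate = Q, duration = 10, output_times = 10)
  dt <- 0.05
  n <- 40
  for (i in seq_len(n)) {
    P <- solve_pressure(ph, s, prot, fl, P0 = if (i > 1) P else NULL)
    v <- darcy_flux(P, ph, s, fl)
    s <- advect_saturation(s, v, ph, dt, fl, q_oil = Q, method = "implicit",
                           P = P)
  }
  expect_equal(oil_volume(s, ph), Q * n * dt, tolerance = 1e-10)
})

test_that("equal-viscosity slug translates at v/phi (method of characteristics)", {
  # linear advection limit: f(s) = s, uniform v; the front must move v*T/phi
  fl <- fluid_pair(mu_oil = 1, mu_air = 1, rho_oil = 1000, rho_air = 1000)
  ph <- phantom_box(c(120, 6, 6), h = 1e-3, porosity = 0.75,
                    vent_sides = c("-x", "+x"))
  dims <- dim(ph$cell_class)
  vp <- array(0, dims); vp[1, , ] <- 100
  s <- array(0, dims)
  s[2:21, , ] <- 1
  s[ph$cell_class != cell_classes()[["cancellous"]]] <- 0
  P <- solve_pressure(ph, s, NULL, fl, vent_pressure = vp)
  v <- darcy_flux(P, ph, s, fl, vent_pressure = vp)
  vx <- v$vx[60, 4, 4]
  expect_gt(vx, 0)
  dt <- 0.5 * stable_dt(v, ph, fl, cfl = 1)
  Tend <- 60 * 1e-3 * 0.75 / vx           # travel ~60 cells
  nst <- ceiling(Tend / dt); dt <- Tend / nst
  for (i in seq_len(nst)) s <- advect_saturation(s, v, ph, dt, fl,
                                                 method = "explicit")
  prof <- s[2:121, 4, 4]
  i1 <- max(which(prof >= 0.5))
  front <- i1 + (prof[i1] - 0.5) / (prof[i1] - prof[i1 + 1])
  expected <- 20.5 + vx * Tend / 0.75 / 1e-3
  expect_lt(abs(front - expected), 1)     # within one cell
})

test_that("implicit and explicit schemes agree in a resolved mild-ratio displacement", {
  fl <- fluid_pair(mu_oil = 5, mu_air = 1, rho_oil = 1000, rho_air = 1)
  ph <- phantom_box(c(40, 6, 6), h = 1e-3, porosity = 0.75,
                    vent_sides = c("-x", "+x"))
  dims <- dim(ph$cell_class)
  vp <- array(0, dims); vp[1, , ] <- 50
  s0 <- array(0, dims); s0[2:9, , ] <- 1
  s0[ph$cell_class != cell_classes()[["cancellous"]]] <- 0
  run_one <- function(method) {
    s <- s0
    P <- solve_pressure(ph, s, NULL, fl, vent_pressure = vp)
    v <- darcy_flux(P, ph, s, fl, vent_pressure = vp)
    dt <- 0.02 * stable_dt(v, ph, fl, cfl = 1)
    for (i in 1:150) {
      P <- solve_pressure(ph, s, NULL, fl, vent_pressure = vp, P0 = P)
      v <- darcy_flux(P, ph, s, fl, vent_pressure = vp)
      s <- advect_saturation(s, v, ph, dt, fl, method = method, P = P)
    }
    s
  }
  si <- run_one("implicit"); se <- run_one("explicit")
  expect_lt(max(abs(si - se)), 0.02)
})

test_that("front radius closed form reproduces the hand-computed values", {
  expect_equal(1000 * front_radius_theory(3e-7, c(1, 4, 7), 0.75),
               c(4.57, 7.26, 8.74), tolerance = 2e-3)
})
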