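test_that("plane extraction slices a saturated ball into the right disc", {
  ph <- coarse_body_phantom()
  R <- 8.74e-3
  s <- ball_field(ph, R)
  # initial state: all-zero plane
  pl0 <- extract_plane(array(0, dim(s)), ph, "plane1")
  expect_equal(max(pl0$values), 0)
  expect_equal(distribution_area_fraction(pl0), 0)
  expect_equal(equivalent_radius(pl0), 0)
  # plane at z = 2 mm cuts a disc of radius sqrt(R^2 - z^2) = 8.51 mm
  pl2 <- extract_plane(s, ph, "plane2")
  expect_equal(equivalent_radius(pl2), sqrt(R^2 - 0.002^2),
               tolerance = ph$grid$h / sqrt(R^2 - 0.002^2))
  # area percentage equals the analytic disc/ellipse area ratio
  r_disc <- sqrt(R^2 - 0.002^2)
  expect_equal(distribution_area_fraction(pl2),
               100 * r_disc^2 / (0.021 * 0.015), tolerance = 3)
  # symmetric planes of a z-symmetric field are mirror-identical
  pl3 <- extract_plane(s, ph, "plane3")
  expect_identical(pl2$values, pl3$values)
  # wall-ring sections are rejected by extract_plane
  php <- build_pedicle_phantom(h = 1e-3)
  expect_error(extract_plane(s, php, "lateral_wall_ring"), "wall ring")
})

test_that("area fraction spans trivial limits and is monotone in the threshold", {
  ph <- coarse_body_phantom()
  dims <- dim(ph$cell_class)
  full <- array(1, dims); full[ph$cell_class != 1] <- 0
  expect_equal(distribution_area_fraction(extract_plane(full, ph, "plane1")),
               100)
  # radially decaying field: superlevel area shrinks with theta
  g <- ph$grid
  x <- (seq_len(g$nx) - g$origin_index[1]) * g$h
  y <- (seq_len(g$ny) - g$origin_index[2]) * g$h
  z <- (seq_len(g$nz) - g$origin_index[3]) * g$h
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  s <- exp(-r2 / (2 * 0.006^2))
  s[ph$cell_class != 1] <- 0
  pl <- extract_plane(s, ph, "plane1")
  af <- vapply(seq(0.05, 0.95, by = 0.05),
               function(th) distribution_area_fraction(pl, th), 0)
  expect_true(all(diff(af) <= 0))
  expect_error(distribution_area_fraction(pl, 0), "theta")
})

test_that("sphericity separates balls from slabs", {
  ph <- coarse_body_phantom()
  s <- ball_field(ph, 7e-3)
  expect_gte(sphericity(s, ph), 0.95)
  # one-voxel-thick slab: strongly anisotropic second moments
  slab <- array(0, dim(ph$cell_class))
  k0 <- ph$grid$origin_index[3]
  slab[, , k0] <- 1
  slab[ph$cell_class != 1] <- 0
  expect_lt(sphericity(slab, ph), 0.1)
  expect_error(sphericity(array(0, dim(ph$cell_class)), ph), "empty")
})

test_that("wall-ring extraction reports contact fractions in [0, 100]", {
  ph <- build_pedicle_phantom(h = 1e-3)
  dims <- dim(ph$cell_class)
  wr0 <- extract_wall_ring(array(0, dims), ph, "posterior_wall_ring")
  expect_equal(wr0$contacted_fraction, 0)
  flooded <- array(1, dims)
  wr1 <- extract_wall_ring(flooded, ph, "posterior_wall_ring")
  expect_equal(wr1$contacted_fraction, 100)
  expect_true(all(c("angle_deg", "z", "s") %in% names(wr1$faces)))
  expect_error(extract_wall_ring(flooded, ph, "plane1"), "not a wall ring")
})

test_that("series_report assembles one row per snapshot and section", {
  run <- coarse_body_run()
  ph <- coarse_body_phantom()
  ser <- series_report(run$snapshots, ph)
  expect_equal(nrow(ser), length(run$snapshots) * length(ph$sections))
  expect_true(all(ser$area_fraction_pct >= 0 & ser$area_fraction_pct <= 100))
  # monotone growth in time during injection, per section
  for (nm in unique(ser$section)) {
    sub <- ser[ser$section == nm, ]
    expect_true(all(diff(sub$area_fraction_pct[order(sub$time_s)]) >= 0))
  }
  p <- plot_series(ser, "equivalent_radius_mm")
  expect_s3_class(p, "ggplot")
})
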