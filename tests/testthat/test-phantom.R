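test_that("Kozeny-Carman permeability matches hand-computed values", {
  # alpha = phi^3 d^2 / (180 (1-phi)^2); for d = 0.90 mm, phi = 0.75:
  # 0.421875 * 8.1e-7 / 11.25 = 3.0375e-8 m^2
  expect_equal(permeability_from_pore_diameter(0.90e-3, 0.75), 3.0375e-8,
               tolerance = 1e-12)
  expect_identical(permeability_from_pore_diameter(0, 0.75), 0)
  expect_identical(permeability_from_pore_diameter(0.90e-3, 0), 0)
  expect_error(permeability_from_pore_diameter(0.90e-3, 1), "phi")
  expect_error(permeability_from_pore_diameter(-1e-3, 0.5), "d")
})

test_that("body phantom satisfies all structural invariants", {
  ph <- coarse_body_phantom()
  expect_invisible(validate_phantom(ph))
  cc <- cell_classes()
  # injection site at the body center, on a cell center
  ii <- ph$injection_site$index
  expect_identical(ii, ph$grid$origin_index)
  expect_equal(ph$cell_class[ii[1], ii[2], ii[3]], cc[["cancellous"]],
               ignore_attr = TRUE)
  # porosity/permeability zero exactly on cortical and exterior cells
  blocked <- ph$cell_class == cc[["cortical"]] | ph$cell_class == cc[["exterior"]]
  expect_true(all(ph$porosity[blocked] == 0))
  expect_true(all(ph$permeability[blocked] == 0))
})

test_that("body phantom geometry is mirror-symmetric in x and z", {
  ph <- coarse_body_phantom()
  cls <- ph$cell_class
  expect_identical(cls, cls[dim(cls)[1]:1, , ])
  expect_identical(cls, cls[, , dim(cls)[3]:1])
})

test_that("cortical shell separates interior from exterior along every axis ray", {
  ph <- build_vertebral_body(h = 1e-3, shell_thickness = 2e-3)
  cc <- cell_classes()
  cls <- ph$cell_class
  # along each x-row that contains cancellous cells, walking outward must
  # cross >= 2 cortical voxels before any exterior voxel (vents excepted)
  for (k in seq(1, dim(cls)[3], by = 3)) {
    for (j in seq(1, dim(cls)[2], by = 3)) {
      row <- cls[, j, k]
      canc <- which(row == cc[["cancellous"]])
      if (!length(canc)) next
      for (side in c("lo", "hi")) {
        seg <- if (side == "lo") rev(row[1:(min(canc) - 1)])
               else row[(max(canc) + 1):length(row)]
        first_ext <- which(seg == cc[["exterior"]])[1]
        wall <- seg[seq_len(first_ext - 1)]
        expect_gte(sum(wall == cc[["cortical"]] | wall == cc[["vent"]]), 2)
      }
    }
  }
})

test_that("voxelized interior volume converges under grid refinement", {
  p <- list(a_x = 0.021, a_y = 0.015, half_height = 0.010)
  analytic <- pi * p$a_x * p$a_y * 2 * p$half_height
  vol <- function(h) {
    ph <- build_vertebral_body(h = h)
    sum(ph$cell_class == cell_classes()[["cancellous"]]) * h^3
  }
  v1 <- vol(1e-3); v05 <- vol(0.5e-3)
  expect_lt(abs(v05 - v1) / v1, 0.05)
  # boundary-inclusive voxelization overcounts by O(h * surface area)
  expect_lt(abs(v05 - analytic) / analytic, 0.03)
})

test_that("phantom generation is deterministic", {
  a <- build_vertebral_body(h = 1e-3)
  b <- build_vertebral_body(h = 1e-3)
  expect_identical(a$cell_class, b$cell_class)
  expect_identical(a$porosity, b$porosity)
  expect_identical(a$permeability, b$permeability)
})

test_that("section catalog matches the observation protocol coordinates", {
  ph <- coarse_body_phantom()
  expect_setequal(names(ph$sections),
                  c("plane1", "plane2", "plane3", "plane5", "plane6",
                    "plane7"))
  expect_equal(ph$sections$plane2$coordinate, 0.002)
  expect_equal(ph$sections$plane3$coordinate, -0.002)
  expect_equal(ph$sections$plane5$coordinate, 0.005)
  expect_equal(ph$sections$plane7$coordinate, -0.005)
  expect_equal(ph$sections$plane6$axis, "y")
})

test_that("pedicle phantom places plane 4 just beneath the endplate and builds wall rings", {
  ph <- build_pedicle_phantom(h = 1e-3)
  expect_invisible(validate_phantom(ph))
  cc <- cell_classes()
  # plane 4 is 0.3 mm below the interior endplate surface
  expect_equal(ph$sections$endplate$coordinate - ph$sections$plane4$coordinate,
               3e-4, tolerance = 1e-12)
  ii <- ph$injection_site$index
  expect_equal(ph$cell_class[ii[1], ii[2], ii[3]], cc[["cancellous"]],
               ignore_attr = TRUE)
  expect_identical(ph$injection_site$name, "pedicle_junction")
  for (ring in c("lateral_wall_ring", "posterior_wall_ring")) {
    f <- ph$sections[[ring]]$faces
    expect_gt(nrow(f), 10)
    # every ring face borders a cortical cell
    for (r in seq_len(nrow(f))) {
      di <- switch(f$dir[r], "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
                   "+y" = c(0, 1, 0), "-y" = c(0, -1, 0))
      nb <- c(f$i[r], f$j[r], f$k[r]) + di
      expect_equal(ph$cell_class[nb[1], nb[2], nb[3]], cc[["cortical"]],
                   ignore_attr = TRUE)
    }
  }
  # posterior ring faces sit on the posterior (-y) side of the body center
  ctr <- ph$params$body_center
  expect_true(all(ph$sections$posterior_wall_ring$faces$fy < ctr[2]))
  # lateral ring faces sit on the +x side
  expect_true(all(ph$sections$lateral_wall_ring$faces$fx > ctr[1]))
})

test_that("degenerate geometry requests are rejected", {
  expect_error(build_vertebral_body(a_x = 2e-3, h = 1e-3), "geometry")
  expect_error(build_vertebral_body(shell_thickness = 1e-4, h = 1e-3),
               "shell")
  expect_error(build_pedicle_phantom(pedicle_radius = 1e-3, h = 1e-3),
               "radius")
  expect_error(build_pedicle_phantom(pedicle_offset_x = 0.03, h = 1e-3),
               "reach")
})
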