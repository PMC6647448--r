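test_that("region areas match closed forms and Monte-Carlo sampling", {
  gr <- build_geometry(geometry_params("radial"))
  expect_equal(gr$osteon_area, pi * 75e-6^2, tolerance = 1e-12)

  gl <- build_geometry(geometry_params("longitudinal"))
  # stadium: rectangle plus two half-circle caps
  expect_equal(gl$osteon_area, (650e-6 - 150e-6) * 150e-6 + pi * 75e-6^2,
               tolerance = 1e-12)

  # Monte-Carlo cross-check of the stadium area via point membership
  set.seed(42)
  n <- 2e5
  pts <- cbind(runif(n, 0, 1e-3), runif(n, 0, 1e-3))
  inside <- mean(osteon_sdist(gl, pts) < 0)
  mc_area <- inside * (1e-3)^2
  se <- sqrt(inside * (1 - inside) / n) * (1e-3)^2
  expect_lt(abs(mc_area - gl$osteon_area), 4 * se)
})

test_that("initial crack is a horizontal mid-edge segment of length 0.1 L", {
  g <- build_geometry(geometry_params("radial"))
  expect_equal(g$notch[1, ], c(0, 5e-4))
  expect_equal(g$notch[2, ], c(1e-4, 5e-4))
  g2 <- build_geometry(geometry_params("radial", crack_fraction = 0.25))
  expect_equal(g2$notch[2, 1], 0.25e-3)
})

test_that("parameter validation rejects degenerate geometries", {
  expect_error(geometry_params("radial", crack_fraction = 0.6), "crack_fraction")
  expect_error(geometry_params("radial", osteon_diameter = 1.1e-3), "d \\+ 2t")
  expect_error(geometry_params("longitudinal", osteon_length = 100e-6),
               "stadium length")
  # cement band may not touch the domain boundary
  expect_error(build_geometry(geometry_params("longitudinal",
                                              osteon_length = 999e-6,
                                              osteon_diameter = 900e-6)),
               "d \\+ 2t|boundary")
})

test_that("interface normals match circle/stadium geometry and the distance
           field gradient", {
  g <- build_geometry(geometry_params("radial"))
  ctr <- g$center; r <- g$radius
  expect_equal(interface_normal_at(ctr + c(r, 0), g), c(1, 0))
  expect_equal(interface_normal_at(ctr + c(0, r), g), c(0, 1))
  expect_error(interface_normal_at(c(0, 0), g), "outside")

  # stadium flank: normal is (0,1) rotated by the osteon rotation
  gl <- build_geometry(geometry_params("longitudinal"))
  ang <- pi / 2 + 10 * pi / 180          # stadium axis direction
  flank_normal <- c(cos(ang - pi / 2), sin(ang - pi / 2))
  p <- gl$center + 75e-6 * flank_normal  # point on the straight flank
  expect_equal(sum(interface_normal_at(p, gl) * flank_normal), 1,
               tolerance = 1e-9)

  # gradient check at random boundary points, both shapes
  set.seed(7)
  for (geom in list(g, gl)) {
    th <- runif(100, 0, 2 * pi)
    for (t1 in th) {
      rho <- osteocrack:::ray_to_level(geom, t1, 0)
      p <- geom$center + rho * c(cos(t1), sin(t1))
      h <- 1e-9
      grad <- c(osteon_sdist(geom, p + c(h, 0)) - osteon_sdist(geom, p - c(h, 0)),
                osteon_sdist(geom, p + c(0, h)) - osteon_sdist(geom, p - c(0, h))) /
        (2 * h)
      grad <- grad / sqrt(sum(grad^2))
      nrm <- interface_normal_at(p, geom)
      expect_lt(acos(pmin(1, sum(grad * nrm))) * 180 / pi, 1)
    }
  }
})

test_that("phase membership follows the signed distance band", {
  g <- build_geometry(geometry_params("radial"))
  ctr <- g$center; r <- g$radius; t <- g$params$cement_thickness
  pts <- rbind(ctr,                      # osteon centre
               ctr + c(r + t / 2, 0),    # inside the band
               ctr + c(r + 10 * t, 0))   # matrix
  expect_equal(phase_at(g, pts), c("osteon", "cement_line", "matrix"))
})
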