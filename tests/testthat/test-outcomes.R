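test_that("max force and fracture energy on simple curves", {
  cv <- data.frame(u = c(0, 1, 2), force = c(0, 2, 1))
  expect_equal(max_force(cv), 2)
  expect_equal(max_force(data.frame(u = 0:3, force = c(0, 1, 2, 3))), 3)
  expect_equal(max_force(data.frame(u = 0:2, force = rep(0, 3))), 0)
  expect_error(max_force(data.frame(u = numeric(0), force = numeric(0))),
               "empty")

  # triangle curve rising to (1e-3, 2) then down to (2e-3, 0): area 2e-3 J
  tri <- data.frame(u = c(0, 1e-3, 2e-3), force = c(0, 2, 0))
  expect_equal(fracture_energy(tri), 2e-3)
  expect_equal(fracture_energy(data.frame(u = c(0, 1), force = c(0, 0))), 0)
  expect_error(fracture_energy(data.frame(u = c(0, 2, 1),
                                          force = c(0, 1, 1))),
               "non-monotone")
})

test_that("fracture energy is stable under curve resampling", {
  u <- seq(0, 4e-6, length.out = 41)
  f <- 5 * sin(pi * u / 4e-6)
  e1 <- fracture_energy(data.frame(u = u, force = f))
  u2 <- seq(0, 4e-6, length.out = 81)
  e2 <- fracture_energy(data.frame(u = u2, force = 5 * sin(pi * u2 / 4e-6)))
  expect_equal(e1, e2, tolerance = 0.01)
})

test_that("crack length sums segment lengths including the notch", {
  notch <- data.frame(length = 100e-6)
  expect_equal(crack_length(notch), 100e-6)
  expect_equal(crack_length(rbind(notch, data.frame(length = 10e-6))), 110e-6)
  expect_equal(crack_length(NULL), 0)

  # semicircular arc oracle: notch + pi r within discretization error
  g <- radial_geom()
  arc <- osteocrack:::band_arc(g, pi, pi * (g$radius +
                                              g$params$cement_thickness), 1)
  segs <- rbind(data.frame(length = 100e-6),
                data.frame(length = osteocrack:::seg_rows(arc, "QUADE")$length))
  expect_equal(crack_length(segs), 100e-6 + pi * (g$radius + 5e-6),
               tolerance = 0.01)
})

test_that("crack score rules on hand-built paths", {
  g <- radial_geom()
  t <- g$params$cement_thickness
  mk <- function(mid, len, prov)
    data.frame(mid_x = mid[1], mid_y = mid[2], length = len, provenance = prov)
  ctr <- g$center; r <- g$radius

  # straight through: penetration, zero deflection -> 1
  p1 <- rbind(mk(c(0.2e-3, 0.5e-3), 1e-4, "initial"),
              mk(ctr, 1e-4, "MAXPE"))
  expect_identical(crack_score(p1, g), 1L)

  # 20 um interface arc then osteon entry -> 2
  p2 <- rbind(p1, mk(ctr + c(0, r + t / 2), 20e-6, "QUADE"))
  expect_identical(crack_score(p2, g), 2L)

  # 30 um -> 3
  p3 <- rbind(p1, mk(ctr + c(0, r + t / 2), 30e-6, "QUADE"))
  expect_identical(crack_score(p3, g), 3L)

  # no penetration, exit on the far side -> 4
  p4 <- rbind(mk(c(0.2e-3, 0.5e-3), 1e-4, "initial"),
              mk(ctr + c(0, r + t / 2), 200e-6, "QUADE"),
              mk(c(0.9e-3, 0.5e-3), 1e-4, "MAXPE"))
  expect_identical(crack_score(p4, g), 4L)

  # >= 95% perimeter coverage -> 5
  p5 <- rbind(mk(c(0.2e-3, 0.5e-3), 1e-4, "initial"),
              mk(ctr + c(0, r + t / 2), 0.96 * g$perimeter, "QUADE"))
  expect_identical(crack_score(p5, g), 5L)

  # never reached the band: undefined
  expect_error(crack_score(mk(c(0.1e-3, 0.5e-3), 5e-5, "initial"), g),
               "undefined")
})

test_that("interface chords of a discretized arc do not register as
           penetration", {
  g <- radial_geom()
  fx <- fixture_crack_path(5, g, seed = 2)
  sd <- osteon_sdist(g, cbind(fx$mid_x, fx$mid_y))
  arc <- fx$provenance == "QUADE"
  expect_true(all(sd[arc] > -g$params$cement_thickness / 2))
  expect_identical(crack_score(fx, g), 5L)
})
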