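# Propagation on the homogeneous notched strip: symmetry, energy bookkeeping,
# dissipation, and mesh convergence. One strip simulation is shared across
# several expectations to keep the suite fast.

strip_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- plate_geom()
      m <- generate_mesh(g, mesh_spec(plate_nx = 14, plate_ny = 14))
      cache <<- propagate(g, material_params("longitudinal"), mesh = m,
                          load = load_program(u_max = 25e-6, step0 = 0.1e-6,
                                              step_max = 1e-6))
    }
    cache
  }
})

test_that("homogeneous strip: straight symmetric crack, severed load path", {
  sim <- strip_sim()
  # crack follows the mid-height symmetry line
  expect_true(all(abs(sim$path[, 2] - 5e-4) < 1e-12))
  expect_true(all(sim$segments$provenance[-(1:1)] %in% c("initial", "MAXPE")))
  # severed plate carries (almost) no load
  expect_lt(sim$curve$force[nrow(sim$curve)], 0.011 * max(sim$curve$force))
  # crack spans the plate
  expect_equal(crack_length(sim$segments), 1e-3, tolerance = 1e-9)
})

test_that("global energy balance holds at every increment", {
  cv <- strip_sim()$curve
  imbalance <- abs(cv$W_ext - cv$U_elastic - cv$E_dissipated)
  expect_true(all(imbalance <= 0.02 * pmax(cv$W_ext, 1e-12)))
})

test_that("dissipated energy per fully opened crack area equals G", {
  sim <- strip_sim()
  th <- sim$geom$params$thickness
  act <- sim$segments[sim$segments$provenance != "initial", ]
  expect_gt(mean(act$damage == 1), 0.9)   # the strip failed completely
  A_failed <- sum(act$length[act$damage == 1]) * th
  # ledger dissipation of fully opened faces (partial faces add their share)
  D <- sim$curve$E_dissipated[nrow(sim$curve)]
  D_partial <- sum(with(act[act$damage < 1, ],
                        length * th * 0.5 * T0 * delta_hist))
  expect_equal((D - D_partial) / A_failed, 200, tolerance = 0.03)
})

test_that("segment damage is irreversible and the crack is one component", {
  sim <- strip_sim()
  expect_true(all(sim$segments$damage >= 0 & sim$segments$damage <= 1))
  # the path polyline is connected: consecutive vertices are segment ends
  d <- sqrt(rowSums((sim$path[-1, , drop = FALSE] -
                       sim$path[-nrow(sim$path), , drop = FALSE])^2))
  expect_equal(d, sim$segments$length, tolerance = 1e-12)
})

test_that("unload/reload of a cohesive segment adds no dissipation", {
  T0 <- 60e6; G <- 200
  dh <- 0.3 * 2 * G / T0
  base <- cohesive_traction(dh, T0, G)
  reloaded <- cohesive_traction(dh, T0, G, delta_hist = dh)
  unloaded <- cohesive_traction(0, T0, G, delta_hist = dh)
  expect_equal(unloaded$dissipated, base$dissipated, tolerance = 1e-12)
  expect_equal(reloaded$dissipated, base$dissipated, tolerance = 1e-12)
  expect_equal(reloaded$traction, base$traction, tolerance = 1e-12)
})

test_that("peak force converges under mesh refinement", {
  g <- plate_geom()
  peaks <- vapply(c(10, 14, 20), function(n) {
    m <- generate_mesh(g, mesh_spec(plate_nx = n, plate_ny = n))
    sim <- propagate(g, material_params("longitudinal"), mesh = m,
                     load = load_program(u_max = 8e-6, step0 = 0.1e-6))
    max(sim$curve$force)
  }, numeric(1))
  expect_lt(abs(peaks[3] - peaks[2]) / peaks[3], 0.05)
})

test_that("a doubled prescribed displacement doubles a crack-free field", {
  g <- plate_geom()
  m <- generate_mesh(g, mesh_spec(plate_nx = 6, plate_ny = 6))
  mat <- material_params("radial")
  r1 <- uniaxial_reaction(m, mat, strain = 5e-4)
  r2 <- uniaxial_reaction(m, mat, strain = 1e-3)
  expect_equal(r2$force, 2 * r1$force, tolerance = 1e-12)
})
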