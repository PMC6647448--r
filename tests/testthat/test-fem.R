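test_that("stiffness of a single element is symmetric with zero-force rigid
           translation", {
  g <- plate_geom(side = 1)
  m <- generate_mesh(g, mesh_spec(plate_nx = 1, plate_ny = 1))
  mat <- material_params("longitudinal")
  mat["E_mat"] <- 1; mat["nu_mat"] <- 0
  K <- as.matrix(assemble_stiffness(m, mat))
  expect_equal(K, t(K))
  # rigid x- and y-translations produce no force
  ux <- rep(c(1, 0), 4); uy <- rep(c(0, 1), 4)
  expect_equal(max(abs(K %*% ux)), 0, tolerance = 1e-15)
  expect_equal(max(abs(K %*% uy)), 0, tolerance = 1e-15)
})

test_that("patch test: distorted patches reproduce arbitrary linear fields", {
  set.seed(11)
  mat <- material_params("radial")
  for (rep in 1:100) {
    g <- plate_geom(side = 1)
    m <- generate_mesh(g, mesh_spec(plate_nx = 2, plate_ny = 2))
    m$nodes[5, ] <- c(0.5, 0.5) + runif(2, -0.2, 0.2)  # interior node
    a <- runif(3, -1e-4, 1e-4); b <- runif(3, -1e-4, 1e-4)
    ux <- a[1] * m$nodes[, 1] + a[2] * m$nodes[, 2] + a[3]
    uy <- b[1] * m$nodes[, 1] + b[2] * m$nodes[, 2] + b[3]
    bnd <- which(m$nodes[, 1] %in% c(0, 1) | m$nodes[, 2] %in% c(0, 1))
    K <- assemble_stiffness(m, mat)
    sol <- solve_increment(K, c(2L * bnd - 1L, 2L * bnd),
                           c(ux[bnd], uy[bnd]))
    expect_equal(sol$u, as.vector(rbind(ux, uy)), tolerance = 1e-10)
  }
})

test_that("uniaxial plane-stress plate matches the closed form", {
  g <- plate_geom()
  m <- generate_mesh(g, mesh_spec(plate_nx = 8, plate_ny = 8))
  mat <- material_params("longitudinal")  # E_mat = 15 GPa, nu = 0.3
  r <- uniaxial_reaction(m, mat, strain = 0.001)
  # F = E * eps * L * thickness, lateral contraction free
  expect_equal(r$force, 15e9 * 0.001 * 1e-3 * 100e-6, tolerance = 1e-6)
})

test_that("zero displacement and linearity of the solved field", {
  g <- plate_geom()
  m <- generate_mesh(g, mesh_spec(plate_nx = 6, plate_ny = 6))
  mat <- material_params("longitudinal")
  K <- assemble_stiffness(m, mat)
  bot <- osteocrack:::boundary_nodes(m, "bottom")
  top <- osteocrack:::boundary_nodes(m, "top")
  fd <- c(2L * bot, 2L * top, 2L * bot[1] - 1L)
  z <- solve_increment(K, fd, rep(0, length(fd)))
  expect_equal(max(abs(z$u)), 0)
  u1 <- solve_increment(K, fd, c(rep(0, length(bot)), rep(1e-6, length(top)), 0))
  u2 <- solve_increment(K, fd, c(rep(0, length(bot)), rep(2e-6, length(top)), 0))
  expect_equal(u2$u, 2 * u1$u, tolerance = 1e-12)
})

test_that("element strains: principal values and interface resolution", {
  g <- plate_geom(side = 1)
  m <- generate_mesh(g, mesh_spec(plate_nx = 1, plate_ny = 1))
  # impose a uniform strain field through nodal displacements
  impose <- function(exx, eyy, gxy) {
    u <- numeric(8)
    u[seq(1, 8, 2)] <- exx * m$nodes[, 1] + gxy * m$nodes[, 2]
    u[seq(2, 8, 2)] <- eyy * m$nodes[, 2]
    element_strain(m, u)
  }
  s <- impose(0.004, 0, 0)
  expect_equal(s$eps1, 0.004)
  expect_equal(abs(s$dir1x), 1)
  # pure shear gamma: eps1 = gamma/2 at 45 degrees
  s <- impose(0, 0, 0.002)
  expect_equal(s$eps1, 0.001)
  expect_equal(abs(c(s$dir1x, s$dir1y)), c(cos(pi / 4), sin(pi / 4)))
  # worked principal-strain example, cross-checked by eigen decomposition
  s <- impose(0.003, 0.001, 0.002)   # tensor exy = 0.001
  ev <- eigen(matrix(c(0.003, 0.001, 0.001, 0.001), 2))$values
  expect_equal(s$eps1, max(ev))
  expect_equal(s$eps1, 0.002 + sqrt(1e-6 + 1e-6), tolerance = 1e-12)
  expect_equal(s$eps2, min(ev))
})

test_that("cement-line strain resolution uses the interface frame", {
  g <- build_geometry(geometry_params("radial"))
  m <- generate_mesh(g, mesh_spec(level = "coarse"))
  exx <- 0.002
  u <- numeric(2 * nrow(m$nodes))
  u[seq(1, length(u), 2)] <- exx * m$nodes[, 1]
  s <- element_strain(m, u)
  cem <- which(m$phase == "cement_line")
  # eps_n = exx * nx^2 for uniaxial exx
  expect_equal(s$eps_n[cem], exx * s$nx[cem]^2, tolerance = 1e-9)
  # engineering interface shear: gamma_ns = -2 exx nx ny
  expect_equal(s$eps_s[cem], -2 * exx * s$nx[cem] * s$ny[cem],
               tolerance = 1e-9)
})

test_that("energy consistency on a crack-free model: W = F u / 2", {
  g <- plate_geom()
  m <- generate_mesh(g, mesh_spec(plate_nx = 6, plate_ny = 6))
  mat <- material_params("longitudinal")
  r <- uniaxial_reaction(m, mat, strain = 0.001)
  U <- 0.001 * 1e-3
  W_int <- 0.5 * sum(r$sol$u * as.vector(r$K %*% r$sol$u))
  expect_equal(W_int, 0.5 * r$force * U, tolerance = 1e-9)
})
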