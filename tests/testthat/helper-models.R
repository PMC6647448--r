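# shared small models for the test suite

radial_geom <- function() build_geometry(geometry_params("radial"))

plate_geom <- function(side = 1e-3)
  build_geometry(geometry_params("none", side = side))

# quick uniaxial tension solve on a homogeneous plate; returns reaction force
uniaxial_reaction <- function(mesh, mat, strain = 0.001) {
  K <- assemble_stiffness(mesh, mat)
  L <- mesh$geom$params$side
  bot <- osteocrack:::boundary_nodes(mesh, "bottom")
  top <- osteocrack:::boundary_nodes(mesh, "top")
  corner <- bot[which.min(mesh$nodes[bot, 1])]
  fd <- c(2L * bot, 2L * top, 2L * corner - 1L)
  fv <- c(rep(0, length(bot)), rep(strain * L, length(top)), 0)
  sol <- solve_increment(K, fd, fv)
  list(force = sum(sol$reactions[as.character(2L * top)]), sol = sol, K = K)
}

fast_load <- function(...) load_program(...)
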