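#' Mesh size specification
#'
#' Controls the graded quad mesh built by [generate_mesh()]. Osteon models use
#' a conforming O-grid: a small axis-aligned structured core inside the osteon,
#' rings of quads out to the osteon boundary, exactly one ring of elements
#' across the cement-line band (thickness t), and geometrically graded rings
#' of matrix elements out to the square boundary along a fan of rays from the
#' osteon centre. The fan always contains the horizontal rays (0 and 180
#' degrees), so a straight mid-height edge path exists for the initial crack.
#' Homogeneous plates (`orientation = "none"`) use a structured nx x ny grid.
#'
#' @param n_fan number of fan rays (multiple of 8; the core is n_fan/4 per
#'   side and must be even so edge-midpoint rays exist).
#' @param rings_osteon rings of osteon elements between core and boundary.
#' @param rings_matrix graded rings of matrix elements between the outer band
#'   edge and the square boundary.
#' @param core_frac core square half-width as a fraction of the smallest
#'   centre-to-boundary distance of the osteon.
#' @param plate_nx,plate_ny structured grid divisions for plate meshes.
#' @param level convenience preset: `"coarse"`, `"medium"` or `"fine"`
#'   overrides the counts above.
#' @return an object of class `mesh_spec`.
#' @export
mesh_spec <- function(n_fan = 64, rings_osteon = 6, rings_matrix = 18,
                      core_frac = 0.4, plate_nx = 10, plate_ny = 10,
                      level = NULL) {
  if (!is.null(level)) {
    level <- match.arg(level, c("coarse", "medium", "fine"))
    preset <- switch(level,
                     coarse = list(n_fan = 32, rings_osteon = 3, rings_matrix = 10),
                     medium = list(n_fan = 48, rings_osteon = 4, rings_matrix = 14),
                     fine   = list(n_fan = 64, rings_osteon = 6, rings_matrix = 18))
    n_fan <- preset$n_fan; rings_osteon <- preset$rings_osteon
    rings_matrix <- preset$rings_matrix
  }
  stopifnot(n_fan %% 8 == 0, rings_osteon >= 1, rings_matrix >= 2,
            core_frac > 0.1, core_frac < 0.8)
  structure(list(n_fan = as.integer(n_fan),
                 rings_osteon = as.integer(rings_osteon),
                 rings_matrix = as.integer(rings_matrix),
                 core_frac = core_frac,
                 plate_nx = as.integer(plate_nx),
                 plate_ny = as.integer(plate_ny)),
            class = "mesh_spec")
}

#' Generate a quad mesh for a single-osteon model
#'
#' Builds a conforming bilinear quad mesh of the region description from
#' [build_geometry()] with per-element phase labels. The cement-line band is
#' exactly one element across its thickness t; matrix rings are geometrically
#' graded from interface-scale elements to coarse far-field elements.
#'
#' @param geom a `bone_geometry` object.
#' @param spec a `mesh_spec` object.
#' @return an object of class `bone_mesh`: list with `nodes` (N x 2), `elems`
#'   (E x 4, counter-clockwise), `phase` (length E character), `elem_size`
#'   (sqrt of element area), `geom`, `spec`.
#' @export
generate_mesh <- function(geom, spec = mesh_spec()) {
  stopifnot(inherits(geom, "bone_geometry"), inherits(spec, "mesh_spec"))
  if (geom$params$orientation == "none") {
    mesh <- plate_mesh_(geom, spec$plate_nx, spec$plate_ny)
  } else {
    mesh <- fan_mesh_(geom, spec)
  }
  mesh$spec <- spec
  areas <- elem_areas(mesh)
  if (any(areas <= 0))
    stop(sprintf("meshing failure: %d inverted elements", sum(areas <= 0)))
  mesh$elem_size <- sqrt(areas)
  mesh
}

# structured plate mesh, all matrix phase
plate_mesh_ <- function(geom, nx, ny) {
  L <- geom$params$side
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, L, length.out = ny + 1)
  nid <- function(i, j) (j - 1) * (nx + 1) + i   # i along x, j along y
  nodes <- cbind(rep(xs, ny + 1), rep(ys, each = nx + 1))
  elems <- matrix(0L, nx * ny, 4)
  k <- 1
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    elems[k, ] <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1))
    k <- k + 1
  }
  structure(list(nodes = nodes, elems = elems,
                 phase = rep("matrix", nrow(elems)), geom = geom),
            class = "bone_mesh")
}

# O-grid fan mesh for osteon models
fan_mesh_ <- function(geom, spec) {
  n_core <- spec$n_fan / 4L
  M <- spec$n_fan
  ctr <- geom$center

  # core half-width: keep the core (corners included) inside the osteon
  thetas_probe <- seq(0, 2 * pi, length.out = 65)[-65]
  rho_min <- min(vapply(thetas_probe, function(th) ray_to_level(geom, th, 0),
                        numeric(1)))
  rho_c <- spec$core_frac * rho_min

  # structured axis-aligned core grid
  g <- seq(-rho_c, rho_c, length.out = n_core + 1)
  core_nid <- function(i, j) (j - 1L) * (n_core + 1L) + i
  core_nodes <- cbind(ctr[1] + rep(g, n_core + 1),
                      ctr[2] + rep(g, each = n_core + 1))
  core_elems <- matrix(0L, n_core^2, 4)
  k <- 1
  for (j in seq_len(n_core)) for (i in seq_len(n_core)) {
    core_elems[k, ] <- c(core_nid(i, j), core_nid(i + 1, j),
                         core_nid(i + 1, j + 1), core_nid(i, j + 1))
    k <- k + 1
  }

  # core boundary node ids ordered counter-clockwise from the left-edge
  # midpoint (direction 180 degrees); n_core is even so midpoints are nodes
  half <- n_core / 2L
  bot <- core_nid(seq_len(n_core + 1L), 1L)                 # left -> right
  rgt <- core_nid(n_core + 1L, seq_len(n_core + 1L))        # bottom -> top
  top <- core_nid(rev(seq_len(n_core + 1L)), n_core + 1L)   # right -> left
  lft <- core_nid(1L, rev(seq_len(n_core + 1L)))            # top -> bottom
  loop <- c(bot[-(n_core + 1L)], rgt[-(n_core + 1L)],
            top[-(n_core + 1L)], lft[-(n_core + 1L)])       # ccw from bottom-left corner
  start <- which(loop == core_nid(1L, half + 1L))           # left-edge midpoint
  ring0 <- c(loop[start:length(loop)], loop[seq_len(start - 1L)])
  stopifnot(length(ring0) == M)

  thetas <- atan2(core_nodes[ring0, 2] - ctr[2], core_nodes[ring0, 1] - ctr[1])
  rho0 <- sqrt((core_nodes[ring0, 1] - ctr[1])^2 +
               (core_nodes[ring0, 2] - ctr[2])^2)
  rho_ost <- vapply(thetas, function(th) ray_to_level(geom, th, 0), numeric(1))
  t_cl <- geom$params$cement_thickness
  rho_cl <- vapply(thetas, function(th) ray_to_level(geom, th, t_cl), numeric(1))
  rho_box <- vapply(thetas, function(th) ray_to_box(geom, th), numeric(1))

  nodes <- core_nodes
  ring_ids <- vector("list", 0)
  add_ring <- function(rho_vec) {
    ids <- nrow(nodes) + seq_len(M)
    nodes <<- rbind(nodes, cbind(ctr[1] + rho_vec * cos(thetas),
                                 ctr[2] + rho_vec * sin(thetas)))
    ids
  }

  rings <- list(ring0)
  # osteon rings: linear blend core boundary -> osteon boundary
  for (k in seq_len(spec$rings_osteon)) {
    f <- k / spec$rings_osteon
    rings[[length(rings) + 1]] <- add_ring(rho0 + f * (rho_ost - rho0))
  }
  # one cement ring
  rings[[length(rings) + 1]] <- add_ring(rho_cl)
  # matrix rings, geometric grading: first layer ~ interface element scale
  Km <- spec$rings_matrix
  h_int <- mean(rho_cl) * 2 * pi / M
  for (k in seq_len(Km)) {
    if (k == Km) {  # land exactly on the square boundary
      rings[[length(rings) + 1]] <- add_ring(rho_box)
      next
    }
    frac <- vapply(seq_along(thetas), function(i) {
      D <- rho_box[i] - rho_cl[i]
      w0 <- min(h_int, D / Km)
      ratio <- geometric_ratio(D, w0, Km)
      if (abs(ratio - 1) < 1e-9) k / Km
      else w0 * (ratio^k - 1) / (ratio - 1) / D
    }, numeric(1))
    rings[[length(rings) + 1]] <- add_ring(rho_cl + pmin(frac, 1) * (rho_box - rho_cl))
  }

  n_rings <- length(rings) - 1L
  fan_elems <- matrix(0L, n_rings * M, 4)
  fan_phase <- character(n_rings * M)
  k <- 1
  for (l in seq_len(n_rings)) {
    inner <- rings[[l]]; outer <- rings[[l + 1]]
    ph <- if (l <= spec$rings_osteon) "osteon"
          else if (l == spec$rings_osteon + 1L) "cement_line"
          else "matrix"
    for (i in seq_len(M)) {
      ip <- if (i == M) 1L else i + 1L
      fan_elems[k, ] <- c(inner[i], outer[i], outer[ip], inner[ip])
      fan_phase[k] <- ph
      k <- k + 1
    }
  }

  structure(list(nodes = nodes,
                 elems = rbind(core_elems, fan_elems),
                 phase = c(rep("osteon", nrow(core_elems)), fan_phase),
                 geom = geom),
            class = "bone_mesh")
}

# solve w0 * (g^K - 1)/(g - 1) = D for the geometric ratio g >= 1
geometric_ratio <- function(D, w0, K) {
  if (w0 * K >= D) return(1)
  f <- function(g) w0 * (g^K - 1) / (g - 1) - D
  stats::uniroot(f, c(1 + 1e-9, 50), tol = 1e-12)$root
}

#' Element areas of a quad mesh
#'
#' Shoelace area of each (counter-clockwise) quad; negative values indicate
#' inverted elements.
#'
#' @param mesh a `bone_mesh` object.
#' @return numeric vector of length `nrow(mesh$elems)` (m^2).
#' @export
elem_areas <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  y <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
         (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
         (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

#' Element centroids
#' @param mesh a `bone_mesh` object.
#' @return numeric matrix (E x 2).
#' @export
elem_centroids <- function(mesh) {
  cbind(rowMeans(matrix(mesh$nodes[mesh$elems, 1], ncol = 4)),
        rowMeans(matrix(mesh$nodes[mesh$elems, 2], ncol = 4)))
}

# internal: node ids on a domain edge ("left","right","bottom","top")
boundary_nodes <- function(mesh, edge, tol = NULL) {
  L <- mesh$geom$params$side
  if (is.null(tol)) tol <- 1e-9 * L
  switch(edge,
         left   = which(abs(mesh$nodes[, 1]) < tol),
         right  = which(abs(mesh$nodes[, 1] - L) < tol),
         bottom = which(abs(mesh$nodes[, 2]) < tol),
         top    = which(abs(mesh$nodes[, 2] - L) < tol),
         stop("unknown edge"))
}

#' Write a quad mesh to legacy VTK format
#'
#' Unstructured-grid ASCII VTK with the phase label as cell data, viewable in
#' ParaView. Optionally attaches a per-node displacement field.
#'
#' @param mesh a `bone_mesh` object.
#' @param path output file path.
#' @param displacement optional N x 2 matrix of nodal displacements.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, displacement = NULL) {
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "osteocrack mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9e %.9e 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", e, 5 * e), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                     mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(rep("9", e), con)
  writeLines(c(sprintf("CELL_DATA %d", e), "SCALARS phase int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$phase,
                                c("matrix", "osteon", "cement_line"))), con)
  if (!is.null(displacement)) {
    writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS displacement double"), con)
    writeLines(sprintf("%.9e %.9e 0", displacement[, 1], displacement[, 2]), con)
  }
  invisible(path)
}
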