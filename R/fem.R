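# Plane-stress bilinear quad FEM core. Full 2x2 Gauss integration; damage
# criteria are evaluated at element centroids.

# plane-stress constitutive matrix entries for given E, nu (vectorized)
d_planestress <- function(E, nu) {
  c0 <- E / (1 - nu^2)
  list(D11 = c0, D12 = c0 * nu, D22 = c0, D33 = c0 * (1 - nu) / 2)
}

# per-element elastic constants from the phase label
phase_constants <- function(mesh, mat) {
  E <- c(matrix = mat[["E_mat"]], osteon = mat[["E_ost"]],
         cement_line = mat[["E_cl"]])[mesh$phase]
  nu <- c(matrix = mat[["nu_mat"]], osteon = mat[["nu_ost"]],
          cement_line = mat[["nu_cl"]])[mesh$phase]
  list(E = unname(E), nu = unname(nu))
}

# shape function derivatives of the bilinear quad at (xi, eta)
quad_dshape <- function(xi, eta) {
  cbind(dxi  = 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
        deta = 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
}

# physical shape-function gradients and jacobians for all elements at (xi,eta)
# returns list(dNdx, dNdy: E x 4 matrices; detJ: E vector)
grad_all <- function(mesh, xi, eta) {
  dn <- quad_dshape(xi, eta)
  x <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  y <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  J11 <- x %*% dn[, 1]; J12 <- y %*% dn[, 1]
  J21 <- x %*% dn[, 2]; J22 <- y %*% dn[, 2]
  detJ <- as.vector(J11 * J22 - J12 * J21)
  iJ11 <- J22 / detJ; iJ12 <- -J12 / detJ
  iJ21 <- -J21 / detJ; iJ22 <- J11 / detJ
  dNdx <- outer(as.vector(iJ11), dn[, 1]) + outer(as.vector(iJ12), dn[, 2])
  dNdy <- outer(as.vector(iJ21), dn[, 1]) + outer(as.vector(iJ22), dn[, 2])
  list(dNdx = dNdx, dNdy = dNdy, detJ = detJ)
}

#' Assemble the plane-stress stiffness matrix
#'
#' Global bulk stiffness of the meshed model with per-phase isotropic elastic
#' constants, 4-node bilinear quads, full 2 x 2 Gauss integration, scaled by
#' the out-of-plane thickness. Node n owns dofs 2n-1 (x) and 2n (y).
#'
#' @param mesh a `bone_mesh` object.
#' @param mat named material parameter vector (needs `E_*`, `nu_*`).
#' @return sparse symmetric stiffness matrix (`dgCMatrix`, 2N x 2N).
#' @export
assemble_stiffness <- function(mesh, mat) {
  pc <- phase_constants(mesh, mat)
  D <- d_planestress(pc$E, pc$nu)
  th <- mesh$geom$params$thickness
  nE <- nrow(mesh$elems)
  gp <- 1 / sqrt(3)
  Ke <- array(0, c(nE, 8, 8))  # dof order: u1x,u1y,u2x,u2y,...
  for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) {
    g <- grad_all(mesh, xi, eta)
    if (any(g$detJ <= 0)) stop("non-positive Jacobian at a Gauss point")
    w <- th * g$detJ
    for (i in 1:4) for (j in 1:4) {
      ax <- 2 * i - 1; ay <- 2 * i; bx <- 2 * j - 1; by <- 2 * j
      Ke[, ax, bx] <- Ke[, ax, bx] +
        w * (D$D11 * g$dNdx[, i] * g$dNdx[, j] + D$D33 * g$dNdy[, i] * g$dNdy[, j])
      Ke[, ax, by] <- Ke[, ax, by] +
        w * (D$D12 * g$dNdx[, i] * g$dNdy[, j] + D$D33 * g$dNdy[, i] * g$dNdx[, j])
      Ke[, ay, bx] <- Ke[, ay, bx] +
        w * (D$D12 * g$dNdy[, i] * g$dNdx[, j] + D$D33 * g$dNdx[, i] * g$dNdy[, j])
      Ke[, ay, by] <- Ke[, ay, by] +
        w * (D$D22 * g$dNdy[, i] * g$dNdy[, j] + D$D33 * g$dNdx[, i] * g$dNdx[, j])
    }
  }
  dofs <- matrix(0L, nE, 8)
  dofs[, seq(1, 8, 2)] <- 2L * mesh$elems - 1L
  dofs[, seq(2, 8, 2)] <- 2L * mesh$elems
  ii <- dofs[, rep(1:8, each = 8)]
  jj <- dofs[, rep(1:8, times = 8)]
  vv <- aperm(Ke, c(1, 3, 2))  # [e, b, a] so that flattening matches ii/jj
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(vv), dims = rep(2L * nrow(mesh$nodes), 2))
}

# triplet (i, j, x) form of the bulk stiffness, for cheap re-assembly with
# cohesive contributions
stiffness_triplets <- function(K) {
  Kt <- methods::as(K, "TsparseMatrix")
  list(i = Kt@i + 1L, j = Kt@j + 1L, x = Kt@x)
}

#' Solve the constrained linear system of one displacement increment
#'
#' Eliminates prescribed dofs and solves `K_ff u_f = -K_fc u_c` (no external
#' loads beyond the prescribed displacements). Returns the full displacement
#' vector and the reaction forces at constrained dofs.
#'
#' @param K global stiffness (sparse, 2N x 2N), including any cohesive
#'   contributions.
#' @param fixed_dofs integer vector of prescribed dof indices.
#' @param fixed_vals prescribed values (same length).
#' @return list with `u` (length 2N) and `reactions` (named by dof index).
#' @export
solve_increment <- function(K, fixed_dofs, fixed_vals) {
  n <- nrow(K)
  stopifnot(length(fixed_dofs) == length(fixed_vals), n %% 2 == 0)
  free <- setdiff(seq_len(n), fixed_dofs)
  u <- numeric(n)
  u[fixed_dofs] <- fixed_vals
  rhs <- -K[free, fixed_dofs, drop = FALSE] %*% fixed_vals
  sol <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K[free, free]), LDL = FALSE)
    Matrix::solve(ch, rhs)
  }, error = function(e)
    stop("singular system after constraints (rigid body modes?): ",
         conditionMessage(e)))
  u[free] <- as.vector(sol)
  r <- as.vector(K[fixed_dofs, , drop = FALSE] %*% u)
  list(u = u, reactions = stats::setNames(r, fixed_dofs))
}

#' Element strain states at centroids
#'
#' Evaluates the in-plane strain tensor at element centroids from a solved
#' displacement field, with principal decomposition (`eps1 >= eps2`,
#' principal direction `dir1`), and, for cement-line elements, the strains
#' resolved on the local interface frame: `eps_n` (normal) and `eps_s`
#' (engineering shear), with the outward interface `normal`.
#'
#' @param mesh a `bone_mesh` object.
#' @param u displacement vector (length 2N).
#' @param elements element indices (default all).
#' @return data.frame with columns `elem, exx, eyy, gxy, eps1, eps2,
#'   dir1x, dir1y, eps_n, eps_s, nx, ny` (interface columns `NA` outside the
#'   cement line). Helper rows can be passed to [initiation_check()] via
#'   [strain_row()].
#' @export
element_strain <- function(mesh, u, elements = seq_len(nrow(mesh$elems))) {
  sub <- mesh
  sub$elems <- mesh$elems[elements, , drop = FALSE]
  g <- grad_all(sub, 0, 0)
  ux <- matrix(u[2 * sub$elems - 1], ncol = 4)
  uy <- matrix(u[2 * sub$elems], ncol = 4)
  exx <- rowSums(g$dNdx * ux)
  eyy <- rowSums(g$dNdy * uy)
  gxy <- rowSums(g$dNdy * ux) + rowSums(g$dNdx * uy)
  avg <- (exx + eyy) / 2
  R <- sqrt(((exx - eyy) / 2)^2 + (gxy / 2)^2)
  eps1 <- avg + R
  eps2 <- avg - R
  ang <- 0.5 * atan2(gxy, exx - eyy)
  out <- data.frame(elem = elements, exx = exx, eyy = eyy, gxy = gxy,
                    eps1 = eps1, eps2 = eps2,
                    dir1x = cos(ang), dir1y = sin(ang),
                    eps_n = NA_real_, eps_s = NA_real_,
                    nx = NA_real_, ny = NA_real_)
  cem <- which(mesh$phase[elements] == "cement_line")
  if (length(cem)) {
    ctr <- elem_centroids(sub)[cem, , drop = FALSE]
    nrm <- osteon_normal(mesh$geom, ctr)
    nx <- nrm[, 1]; ny <- nrm[, 2]
    sx <- -ny; sy <- nx   # tangent: normal rotated +90 degrees
    e11 <- exx[cem]; e22 <- eyy[cem]; e12 <- gxy[cem] / 2
    out$eps_n[cem] <- nx^2 * e11 + ny^2 * e22 + 2 * nx * ny * e12
    out$eps_s[cem] <- 2 * (nx * sx * e11 + ny * sy * e22 +
                             (nx * sy + ny * sx) * e12)
    out$nx[cem] <- nx; out$ny[cem] <- ny
  }
  out
}

#' Extract one element's strain state as a list
#'
#' Convenience accessor turning a row of [element_strain()] output into the
#' list form consumed by [initiation_check()].
#'
#' @param strains data.frame from [element_strain()].
#' @param i row index.
#' @return list with `eps1`, `eps2`, `dir1`, `eps_n`, `eps_s`, `normal`.
#' @export
strain_row <- function(strains, i) {
  r <- strains[i, ]
  list(eps1 = r$eps1, eps2 = r$eps2, dir1 = c(r$dir1x, r$dir1y),
       eps_n = r$eps_n, eps_s = r$eps_s, normal = c(r$nx, r$ny))
}

# element centroid stress for one element (plane stress), used to set the
# initiation traction T0 of a fresh cohesive segment
elem_stress <- function(mesh, u, elem, mat) {
  s <- element_strain(mesh, u, elem)
  pc <- phase_constants(mesh, mat)
  E <- pc$E[elem]; nu <- pc$nu[elem]
  c0 <- E / (1 - nu^2)
  sxx <- c0 * (s$exx + nu * s$eyy)
  syy <- c0 * (s$eyy + nu * s$exx)
  sxy <- c0 * (1 - nu) / 2 * s$gxy
  c(sxx = sxx, syy = syy, sxy = sxy)
}
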