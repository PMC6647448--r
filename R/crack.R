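# Cohesive crack tracking by element-edge release (node splitting).
#
# The crack is an ordered polyline of mesh edges. Faces are created by
# duplicating nodes along the path; cohesive segments tie the two faces with
# the mode-independent linear-softening law until the effective separation
# reaches delta_f = 2 G / T0. Segments are addressed through their two
# adjacent elements (element id + local edge), which stays valid as node
# splitting rewires connectivity.

#' Displacement-controlled loading program
#'
#' Quasi-static tensile loading perpendicular to the initial crack: the
#' bottom edge is fixed in the loading direction (one bottom corner in both),
#' the top edge receives a uniform prescribed displacement growing by
#' adaptive increments. The step halves when an increment initiates more
#' than `burst` crack segments and doubles (up to `step_max`) after `quiet`
#' increments without initiation.
#'
#' @param u_max maximum applied displacement (m).
#' @param step0 initial displacement increment (m).
#' @param step_min,step_max adaptive increment bounds (m).
#' @param drop_frac terminate when the force falls below this fraction of
#'   the running peak (after a peak has developed).
#' @param burst segment count per increment that triggers step halving.
#' @param quiet quiet-increment count that triggers step doubling.
#' @param max_increments hard cap on the number of increments.
#' @return object of class `load_program`.
#' @export
load_program <- function(u_max = 12e-6, step0 = 0.1e-6, step_min = 2e-9,
                         step_max = 0.5e-6, drop_frac = 0.01, burst = 3,
                         quiet = 5, max_increments = 400) {
  stopifnot(u_max > 0, step0 > 0, step_min > 0, step_max >= step0,
            drop_frac >= 0, drop_frac < 1)
  structure(list(u_max = u_max, step0 = step0, step_min = step_min,
                 step_max = step_max, drop_frac = drop_frac, burst = burst,
                 quiet = quiet, max_increments = max_increments),
            class = "load_program")
}

# ---- mesh topology helpers -------------------------------------------------

# rows of mesh$elems containing node v
elems_with_node <- function(mesh, v) {
  unique(((which(mesh$elems == v) - 1L) %% nrow(mesh$elems)) + 1L)
}

# the (up to 2) elements adjacent to edge {a, b}
edge_adjacent <- function(mesh, a, b) {
  cand <- intersect(elems_with_node(mesh, a), elems_with_node(mesh, b))
  keep <- vapply(cand, function(e) {
    nd <- mesh$elems[e, ]
    ia <- match(a, nd); ib <- match(b, nd)
    abs(ia - ib) %in% c(1L, 3L)   # adjacent in cyclic order
  }, logical(1))
  cand[keep]
}

# local edge index k of element e whose nodes are {a, b}
local_edge <- function(mesh, e, a, b) {
  nd <- mesh$elems[e, ]
  for (k in 1:4) {
    kp <- if (k == 4L) 1L else k + 1L
    if ((nd[k] == a && nd[kp] == b) || (nd[k] == b && nd[kp] == a)) return(k)
  }
  stop("edge not found in element")
}

# current node pair of side L / side R of a segment
seg_side_nodes <- function(mesh, seg, side = "L") {
  e <- if (side == "L") seg$elemL else seg$elemR
  k <- if (side == "L") seg$edgeL else seg$edgeR
  kp <- if (k == 4L) 1L else k + 1L
  c(mesh$elems[e, k], mesh$elems[e, kp])
}

# refresh cached node/dof ids of every segment (call after any node split)
refresh_seg_cache <- function(model) {
  mesh <- model$mesh
  for (s in seq_along(model$segments)) {
    seg <- model$segments[[s]]
    nodes <- c(seg_side_nodes(mesh, seg, "L"), seg_side_nodes(mesh, seg, "R"))
    model$segments[[s]]$nodes4 <- nodes
    model$segments[[s]]$dofs8 <- as.integer(rbind(2L * nodes - 1L, 2L * nodes))
  }
}

# scalar secant stiffness of a segment from its history separation
seg_secant <- function(seg) {
  dh <- seg$delta_hist
  if (dh <= seg$delta0) seg$T0 / seg$delta0
  else if (dh < seg$delta_f)
    seg$T0 * (seg$delta_f - dh) / ((seg$delta_f - seg$delta0) * dh)
  else 0
}

# unordered node pairs of all crack edges (both faces), as a 2-column matrix
crack_edge_pairs <- function(model) {
  if (!length(model$segments)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, lapply(model$segments, function(s)
    rbind(sort(seg_side_nodes(model$mesh, s, "L")),
          sort(seg_side_nodes(model$mesh, s, "R")))))
}

# ---- node splitting --------------------------------------------------------

# split node v where crack faces disconnect its element fan; returns TRUE if
# a duplicate node was created
split_node <- function(model, v) {
  mesh <- model$mesh
  fan <- elems_with_node(mesh, v)
  if (length(fan) < 2) return(FALSE)
  blocked <- crack_edge_pairs(model)
  is_blocked <- function(a, b) {
    if (!nrow(blocked)) return(FALSE)
    any(blocked[, 1] == min(a, b) & blocked[, 2] == max(a, b))
  }
  # adjacency among fan elements through non-crack edges at v
  adj <- matrix(FALSE, length(fan), length(fan))
  for (i in seq_along(fan)) {
    nd <- mesh$elems[fan[i], ]
    k <- match(v, nd)
    nbrs <- nd[c(if (k == 1L) 4L else k - 1L, if (k == 4L) 1L else k + 1L)]
    for (w in nbrs) {
      if (is_blocked(v, w)) next
      for (j in seq_along(fan)) {
        if (j == i) next
        if (w %in% mesh$elems[fan[j], ] &&
            length(edge_adjacent(mesh, v, w)) >= 2 &&
            all(c(fan[i], fan[j]) %in% edge_adjacent(mesh, v, w)))
          adj[i, j] <- TRUE
      }
    }
  }
  comp <- rep(0L, length(fan))
  cid <- 0L
  for (i in seq_along(fan)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[cur] > 0L) next
      comp[cur] <- cid
      stack <- c(stack, which(adj[cur, ] & comp == 0L))
    }
  }
  if (cid < 2L) return(FALSE)
  for (cc in 2:cid) {
    new_id <- nrow(mesh$nodes) + 1L
    mesh$nodes <- rbind(mesh$nodes, mesh$nodes[v, , drop = FALSE])
    for (e in fan[comp == cc])
      mesh$elems[e, mesh$elems[e, ] == v] <- new_id
    model$u <- c(model$u, model$u[c(2L * v - 1L, 2L * v)])
  }
  model$mesh <- mesh
  TRUE
}

# ---- cohesive segments -----------------------------------------------------

# create a cohesive segment on edge {a, b}; T0/G/provenance from the
# triggering criterion. failed = TRUE builds a fully failed (traction-free)
# face pair, used for the initial notch.
add_segment <- function(model, a, b, G, T0, provenance, failed = FALSE) {
  mesh <- model$mesh
  adj <- edge_adjacent(mesh, a, b)
  if (length(adj) != 2L)
    stop("cannot release a boundary edge (", length(adj), " adjacent elements)")
  pa <- mesh$nodes[a, ]; pb <- mesh$nodes[b, ]
  tv <- pb - pa; len <- sqrt(sum(tv^2)); tv <- tv / len
  n <- c(-tv[2], tv[1])
  mid <- (pa + pb) / 2
  ctr1 <- colMeans(mesh$nodes[mesh$elems[adj[1], ], ])
  if (sum((ctr1 - mid) * n) > 0) adj <- adj[2:1]   # adj[1] on -n side (L)
  delta_f <- 2 * G / T0
  seg <- list(elemL = adj[1], edgeL = local_edge(mesh, adj[1], a, b),
              elemR = adj[2], edgeR = local_edge(mesh, adj[2], a, b),
              normal = n, tangent = tv, length = len, mid = mid,
              T0 = T0, G = G, delta_f = delta_f,
              delta0 = 0.01 * delta_f,
              delta_hist = if (failed) delta_f * (1 + 1e-9) else 0.01 * delta_f,
              k_pen = 10 * model$mat[["E_mat"]] / len,
              contact = FALSE,
              provenance = provenance, active = !failed)
  model$segments[[length(model$segments) + 1L]] <- seg
  invisible(seg)
}

# secant-stiffness cohesive contribution as triplets (i, j, x)
cohesive_triplets <- function(model) {
  segs <- model$segments
  ns <- length(segs)
  if (!ns) return(list(i = integer(0), j = integer(0), x = numeric(0)))
  th <- model$mesh$geom$params$thickness
  ii <- matrix(0L, ns, 64); jj <- matrix(0L, ns, 64); vv <- matrix(0, ns, 64)
  cvec <- rep(c(-0.5, -0.5, 0.5, 0.5), each = 2)
  dir <- rep(1:2, 4)
  cc <- outer(cvec, cvec)
  for (s in seq_len(ns)) {
    seg <- segs[[s]]
    k <- seg_secant(seg)
    kn <- if (isTRUE(seg$contact)) seg$k_pen else k
    n <- seg$normal; tv <- seg$tangent
    C <- kn * outer(n, n) + k * outer(tv, tv)
    A <- seg$length * th
    dofs <- seg$dofs8
    ii[s, ] <- rep(dofs, times = 8)
    jj[s, ] <- rep(dofs, each = 8)
    vv[s, ] <- A * as.vector(cc * C[dir, dir])
  }
  list(i = as.vector(t(ii)), j = as.vector(t(jj)), x = as.vector(t(vv)))
}

# current global stiffness (bulk + cohesive), from cached bulk triplets
global_K <- function(model) {
  ct <- cohesive_triplets(model)
  ndof <- 2L * nrow(model$mesh$nodes)
  Matrix::sparseMatrix(i = c(model$Kb_ijx$i, ct$i),
                       j = c(model$Kb_ijx$j, ct$j),
                       x = c(model$Kb_ijx$x, ct$x),
                       dims = c(ndof, ndof))
}

# displacement jump (midpoint) of a segment resolved on its normal/tangent
seg_jump <- function(model, seg) {
  u <- model$u
  d8 <- seg$dofs8
  dx <- 0.5 * (u[d8[5]] + u[d8[7]] - u[d8[1]] - u[d8[3]])
  dy <- 0.5 * (u[d8[6]] + u[d8[8]] - u[d8[2]] - u[d8[4]])
  dn <- dx * seg$normal[1] + dy * seg$normal[2]
  ds <- dx * seg$tangent[1] + dy * seg$tangent[2]
  c(dn = dn, ds = ds, deff = sqrt(max(dn, 0)^2 + ds^2))
}

# ---- equilibrium under the softening law -----------------------------------

# solve at fixed prescribed displacements; inner fixed point over the secant
# cohesive state (history separations + contact set). The linearly converging
# history vector is Aitken-extrapolated; the symbolic Cholesky factorization
# is reused across iterations (the sparsity pattern is fixed in between
# topology changes).
equilibrate <- function(model, fixed_dofs, fixed_vals, tol = 1e-6,
                        max_iter = 300L) {
  ndof <- 2L * nrow(model$mesh$nodes)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  ch <- NULL
  X0 <- X1 <- NULL
  nseg <- length(model$segments)
  change <- Inf
  for (it in seq_len(max_iter)) {
    K <- global_K(model)
    Kff <- Matrix::forceSymmetric(K[free, free])
    # tiny diagonal shift: keeps the factorization definite when fully
    # failed faces leave a region (e.g. an encircled osteon) floating
    reg <- 1e-9 * max(Matrix::diag(Kff))
    Kff <- Kff + Matrix::Diagonal(length(free), reg)
    rhs <- -K[free, fixed_dofs, drop = FALSE] %*% fixed_vals
    ch <- if (is.null(ch)) Matrix::Cholesky(Kff, LDL = FALSE)
    else tryCatch(suppressWarnings(Matrix::update(ch, Kff)),
                  error = function(e) Matrix::Cholesky(Kff, LDL = FALSE))
    u <- numeric(ndof)
    u[fixed_dofs] <- fixed_vals
    u[free] <- as.vector(Matrix::solve(ch, rhs))
    model$u <- u
    change <- 0
    flipped <- FALSE
    Xn <- numeric(nseg)
    for (s in seq_along(model$segments)) {
      seg <- model$segments[[s]]
      d <- seg_jump(model, seg)
      if (it <= 50L) {  # freeze the contact set late to stop chattering
        contact <- d[["dn"]] < 0
        if (!identical(contact, isTRUE(seg$contact))) flipped <- TRUE
        model$segments[[s]]$contact <- contact
      }
      if (d[["deff"]] > seg$delta_hist) {
        change <- max(change, (d[["deff"]] - seg$delta_hist) / seg$delta_f)
        model$segments[[s]]$delta_hist <- d[["deff"]]
      }
      Xn[s] <- model$segments[[s]]$delta_hist
    }
    if (change < tol && !flipped) {
      model$reactions <- stats::setNames(
        as.vector(K[fixed_dofs, , drop = FALSE] %*% u), fixed_dofs)
      return(invisible(it))
    }
    # Aitken extrapolation of geometrically converging components
    if (!is.null(X0)) {
      d1 <- X1 - X0; d2 <- Xn - X1
      ok <- which(d2 > 0 & d1 > d2 & d2 / pmax(d1, 1e-300) < 0.95)
      if (length(ok)) {
        xhat <- Xn[ok] + d2[ok]^2 / (d1[ok] - d2[ok])
        for (s in seq_along(ok))
          model$segments[[ok[s]]]$delta_hist <-
            max(model$segments[[ok[s]]]$delta_hist, xhat[s])
        X0 <- X1 <- NULL
        next
      }
    }
    X0 <- X1
    X1 <- Xn
  }
  if (change < 100 * tol) {   # accept a near-converged state with a warning
    warning(sprintf("softening loop accepted at relative change %.3g", change))
    model$reactions <- stats::setNames(
      as.vector(global_K(model)[fixed_dofs, , drop = FALSE] %*% model$u),
      fixed_dofs)
    return(invisible(max_iter))
  }
  stop(sprintf("softening loop did not converge (last relative change %.3g)",
               change))
}

# ---- crack extension -------------------------------------------------------

# evaluate initiation on the element fan around the tip; returns NULL or
# list(f, criterion, normal, elems_f)
tip_initiation <- function(model) {
  mesh <- model$mesh
  fan <- elems_with_node(mesh, model$tip)
  st <- element_strain(mesh, model$u, fan)
  best <- NULL
  for (i in seq_along(fan)) {
    chk <- initiation_check(strain_row(st, i), mesh$phase[fan[i]], model$mat)
    if (is.null(chk)) next
    chk$elem <- fan[i]
    if (is.null(best) || chk$f > best$f) best <- chk
  }
  best
}

# pick the fan edge best aligned with the propagation direction (perpendicular
# to the crack normal, continuing forward); NULL if none qualifies
choose_edge <- function(model, normal, min_score = 0.2) {
  mesh <- model$mesh
  v <- model$tip
  tc <- c(-normal[2], normal[1])
  dp <- model$prev_dir
  if (sum(tc * dp) < 0) tc <- -tc    # forward; ties keep the ccw tangent
  blocked <- crack_edge_pairs(model)
  fan <- elems_with_node(mesh, v)
  cand <- integer(0)
  for (e in fan) {
    nd <- mesh$elems[e, ]
    k <- match(v, nd)
    cand <- c(cand, nd[c(if (k == 1L) 4L else k - 1L, if (k == 4L) 1L else k + 1L)])
  }
  cand <- setdiff(unique(cand), model$path_ids)
  best <- NULL; best_score <- min_score
  for (w in sort(cand)) {
    if (nrow(blocked) &&
        any(blocked[, 1] == min(v, w) & blocked[, 2] == max(v, w))) next
    if (length(edge_adjacent(mesh, v, w)) != 2L) next  # boundary edge
    e <- mesh$nodes[w, ] - mesh$nodes[v, ]
    e <- e / sqrt(sum(e^2))
    if (sum(e * dp) < -0.3) next                       # no backtracking
    score <- sum(e * tc)
    if (score > best_score) { best <- w; best_score <- score }
  }
  best
}

# extend the crack by one edge; returns TRUE if extended
extend_crack <- function(model, chk) {
  w <- choose_edge(model, chk$normal)
  if (is.null(w)) return(FALSE)
  v <- model$tip
  # initiation traction: stress at the triggering element resolved on the
  # crack plane (mode-independent effective traction), floored for stability
  sg <- elem_stress(model$mesh, model$u, chk$elem, model$mat)
  ev <- model$mesh$nodes[w, ] - model$mesh$nodes[v, ]
  ev <- ev / sqrt(sum(ev^2))
  n <- c(-ev[2], ev[1])
  tn <- sg[["sxx"]] * n[1]^2 + sg[["syy"]] * n[2]^2 + 2 * sg[["sxy"]] * n[1] * n[2]
  ts <- (sg[["syy"]] - sg[["sxx"]]) * n[1] * n[2] + sg[["sxy"]] * (n[1]^2 - n[2]^2)
  T0 <- max(sqrt(max(tn, 0)^2 + ts^2), 1e4)
  G <- switch(model$mesh$phase[chk$elem],
              matrix = model$mat[["G_mat"]], osteon = model$mat[["G_ost"]],
              cement_line = model$mat[["G_cl"]])
  prov <- if (chk$criterion == "QUADE") "QUADE" else "MAXPE"
  add_segment(model, v, w, G = G, T0 = T0, provenance = prov)
  split_node(model, v)
  refresh_seg_cache(model)
  model$path_ids <- c(model$path_ids, w)
  model$path <- rbind(model$path, model$mesh$nodes[w, ])
  model$prev_dir <- ev
  model$tip <- w
  model$K_bulk <- assemble_stiffness(model$mesh, model$mat)
  model$Kb_ijx <- stiffness_triplets(model$K_bulk)
  TRUE
}

# insert the initial traction-free notch along the mid-height edge path
insert_notch <- function(model) {
  mesh <- model$mesh
  L <- mesh$geom$params$side
  target <- mesh$geom$params$crack_fraction * L
  tol <- 1e-7 * L
  mid <- which(abs(mesh$nodes[, 2] - L / 2) < tol & mesh$nodes[, 1] < L / 2)
  mid <- mid[order(mesh$nodes[mid, 1])]
  if (!length(mid) || abs(mesh$nodes[mid[1], 1]) > tol)
    stop("no mid-height boundary node for the initial crack")
  xs <- mesh$nodes[mid, 1]
  tip_idx <- which.min(abs(xs - target))
  if (tip_idx < 2L) stop("mesh too coarse for the initial crack")
  path <- mid[seq_len(tip_idx)]
  mat <- model$mat
  T0n <- mat[["E_mat"]] * mat[["eps0_mat"]]
  for (i in seq_len(length(path) - 1L)) {
    if (length(edge_adjacent(mesh, path[i], path[i + 1L])) != 2L)
      stop("mid-height nodes do not form an interior edge path")
    add_segment(model, path[i], path[i + 1L], G = mat[["G_mat"]], T0 = T0n,
                provenance = "initial", failed = TRUE)
  }
  model$path_ids <- path
  model$path <- mesh$nodes[path, , drop = FALSE]
  model$tip <- path[tip_idx]
  model$prev_dir <- c(1, 0)
  for (v in path[seq_len(tip_idx - 1L)]) split_node(model, v)
  refresh_seg_cache(model)
}

# ---- energies --------------------------------------------------------------

model_energies <- function(model) {
  th <- model$mesh$geom$params$thickness
  U_bulk <- 0.5 * sum(model$u * as.vector(model$K_bulk %*% model$u))
  U_coh <- 0; D <- 0
  for (seg in model$segments) {
    A <- seg$length * th
    d <- seg_jump(model, seg)
    k <- seg_secant(seg)
    kn <- if (d[["dn"]] < 0) seg$k_pen else k
    U_coh <- U_coh + 0.5 * A * (kn * min(d[["dn"]], 0)^2 +
                                  k * (max(d[["dn"]], 0)^2 + d[["ds"]]^2))
    if (seg$active)
      D <- D + A * cohesive_traction(0, seg$T0, seg$G, seg$delta_hist,
                                     seg$delta0)$dissipated
  }
  c(U_elastic = U_bulk + U_coh, E_dissipated = D)
}

# ---- main driver -----------------------------------------------------------

#' Simulate quasi-static crack propagation
#'
#' Runs the displacement-controlled tensile test on a single-osteon model (or
#' homogeneous plate): per increment the equilibrium is solved with the
#' current cohesive state, initiation criteria are evaluated on the element
#' fan ahead of the crack tip, and the crack extends one edge-length segment
#' at a time (re-solving at fixed displacement) until no criterion exceeds 1.
#' A single crack is tracked; elements satisfying a criterion away from the
#' tip cannot fracture.
#'
#' @param geom a `bone_geometry` object (its notch defines the initial crack).
#' @param mat named 14-parameter material vector, see [material_params()].
#' @param spec a `mesh_spec`; ignored when `mesh` is supplied.
#' @param load a `load_program`.
#' @param mesh optional pre-built `bone_mesh` (phase labels required).
#' @param verbose print per-increment progress.
#' @return object of class `crack_sim`: list with `curve` (data.frame:
#'   `step, u, force, new_segments, W_ext, U_elastic, E_dissipated`),
#'   `segments` (data.frame, one row per cohesive segment with endpoints,
#'   provenance, damage), `path` (polyline coordinates), `status`
#'   (termination reason), `geom`, `mesh` (final, with split nodes), `mat`.
#' @export
propagate <- function(geom, mat, spec = mesh_spec(level = "coarse"),
                      load = load_program(), mesh = NULL, verbose = FALSE) {
  stopifnot(inherits(geom, "bone_geometry"))
  if (is.null(mesh)) mesh <- generate_mesh(geom, spec)
  model <- new.env(parent = emptyenv())
  model$mesh <- mesh
  model$mat <- mat
  model$segments <- list()
  model$u <- numeric(2L * nrow(mesh$nodes))
  insert_notch(model)
  model$K_bulk <- assemble_stiffness(model$mesh, mat)
  model$Kb_ijx <- stiffness_triplets(model$K_bulk)

  U <- 0; step <- load$step0; quiet_run <- 0L
  peak <- 0; status <- "max_increments"; spanned <- FALSE
  curve <- data.frame()
  W <- 0; F_prev <- 0
  for (inc in seq_len(load$max_increments)) {
    # BC node sets from the current mesh: node splitting can add nodes
    bot <- boundary_nodes(model$mesh, "bottom")
    top <- boundary_nodes(model$mesh, "top")
    corner <- bot[which.min(model$mesh$nodes[bot, 1])]
    fixed_dofs <- c(2L * bot, 2L * top, 2L * corner - 1L)
    top_dofs <- as.character(2L * top)
    U_prev <- U
    U <- min(U + step, load$u_max)
    dU <- U - U_prev
    fixed_vals <- c(rep(0, length(bot)), rep(U, length(top)), 0)
    equilibrate(model, fixed_dofs, fixed_vals)
    n_new <- 0L
    while (!spanned) {
      chk <- tip_initiation(model)
      if (is.null(chk)) break
      if (!extend_crack(model, chk)) break
      n_new <- n_new + 1L
      # re-solve at fixed displacement with the new face pair
      equilibrate(model, fixed_dofs, fixed_vals)
      tipxy <- model$mesh$nodes[model$tip, ]
      Lside <- geom$params$side
      if (min(tipxy, Lside - tipxy) < 1e-7 * Lside) {
        spanned <- TRUE   # crack reached the boundary: sever the last node
        if (split_node(model, model$tip)) {
          refresh_seg_cache(model)
          model$K_bulk <- assemble_stiffness(model$mesh, model$mat)
          model$Kb_ijx <- stiffness_triplets(model$K_bulk)
          equilibrate(model, fixed_dofs, fixed_vals)
        }
        break
      }
      if (n_new > 200L) stop("runaway crack extension in one increment")
    }
    FF <- sum(model$reactions[top_dofs])
    W <- W + 0.5 * (F_prev + FF) * dU
    F_prev <- FF
    en <- model_energies(model)
    curve <- rbind(curve, data.frame(step = inc, u = U, force = FF,
                                     new_segments = n_new, W_ext = W,
                                     U_elastic = en[["U_elastic"]],
                                     E_dissipated = en[["E_dissipated"]]))
    if (verbose)
      message(sprintf("inc %3d u=%.3g F=%.4g new=%d segs=%d", inc, U, FF,
                      n_new, length(model$segments)))
    peak <- max(peak, FF)
    if (U >= load$u_max) {
      status <- if (spanned) "crack_reached_boundary" else "u_max"
      break
    }
    if (peak > 0 && FF < load$drop_frac * peak && n_new == 0L) {
      status <- if (spanned) "crack_reached_boundary" else "force_drop"
      break
    }
    if (n_new > load$burst) {
      step <- max(step / 2, load$step_min); quiet_run <- 0L
    } else if (n_new == 0L) {
      quiet_run <- quiet_run + 1L
      if (quiet_run >= load$quiet) {
        step <- min(step * 2, load$step_max); quiet_run <- 0L
      }
    } else quiet_run <- 0L
  }

  segs <- do.call(rbind, lapply(model$segments, function(s) {
    law <- cohesive_traction(0, s$T0, s$G, s$delta_hist, s$delta0)
    data.frame(x1 = NA_real_, y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
               mid_x = s$mid[1], mid_y = s$mid[2], length = s$length,
               provenance = s$provenance, damage = law$damage,
               delta_hist = s$delta_hist, T0 = s$T0, G = s$G)
  }))
  # endpoints from the path polyline (order of creation)
  if (nrow(segs)) {
    segs$x1 <- model$path[seq_len(nrow(segs)), 1]
    segs$y1 <- model$path[seq_len(nrow(segs)), 2]
    segs$x2 <- model$path[seq_len(nrow(segs)) + 1L, 1]
    segs$y2 <- model$path[seq_len(nrow(segs)) + 1L, 2]
  }
  structure(list(curve = curve, segments = segs, path = model$path,
                 status = status, geom = geom, mesh = model$mesh, mat = mat,
                 u = model$u),
            class = "crack_sim")
}

#' @export
print.crack_sim <- function(x, ...) {
  cat("crack_sim:", nrow(x$curve), "increments,",
      nrow(x$segments), "cohesive segments, status:", x$status, "\n")
  cat(sprintf("  peak force %.4g N, final force %.4g N, crack length %.4g m\n",
              max(x$curve$force), x$curve$force[nrow(x$curve)],
              sum(x$segments$length)))
  invisible(x)
}
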