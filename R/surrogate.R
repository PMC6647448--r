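# Synthetic-data stage: surrogate polynomial responses with known
# statistical structure (so the DOE/ANOVA machinery is testable without
# finite element runs), crack-path fixtures of every score class, and small
# deterministic meshes for solver tests.

#' Surrogate response specification
#'
#' Defines a polynomial response on coded units,
#' `y = b0 + sum main_i x_i + sum inter_ij x_i x_j + sum quad_i x_i^2 + e`,
#' with seeded Gaussian noise `e ~ N(0, sigma^2)`. Coefficient names refer
#' to design factors (interactions as `"A:B"`, quadratics as `"A^2"`). The
#' default noise is 10% of the largest absolute coefficient, which exercises
#' the significance machinery without drowning the planted effects.
#'
#' @param main named numeric vector of main-effect coefficients.
#' @param interaction named numeric vector of interaction coefficients
#'   (names `"A:B"`).
#' @param quadratic named numeric vector of quadratic coefficients
#'   (names `"A^2"` or bare factor names).
#' @param intercept intercept b0.
#' @param sigma noise standard deviation; `NULL` for the 10% default.
#' @param seed RNG seed: identical seeds give identical response tables.
#' @return object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(main = NULL, interaction = NULL, quadratic = NULL,
                           intercept = 0, sigma = NULL, seed = 1L) {
  coefs <- c(main, interaction, quadratic)
  if (is.null(sigma))
    sigma <- if (length(coefs)) 0.1 * max(abs(coefs)) else 1
  stopifnot(sigma >= 0)
  structure(list(main = main, interaction = interaction,
                 quadratic = quadratic, intercept = intercept,
                 sigma = sigma, seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Surrogate responses on a design
#'
#' Evaluates the surrogate polynomial on the coded design rows and adds
#' seeded Gaussian noise. Reproducible: the same spec (including seed) on
#' the same design returns identical tables.
#'
#' @param design a `doe_design`.
#' @param spec a `surrogate_spec`.
#' @return data.frame with columns `run`, `y`.
#' @export
surrogate_response <- function(design, spec) {
  stopifnot(inherits(design, "doe_design"), inherits(spec, "surrogate_spec"))
  X <- design$matrix
  fns <- colnames(X)
  y <- rep(spec$intercept, nrow(X))
  for (nm in names(spec$main)) {
    if (!nm %in% fns) stop("unknown factor in surrogate main effects: ", nm)
    y <- y + spec$main[[nm]] * X[, nm]
  }
  for (nm in names(spec$interaction)) {
    fs <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(fs) != 2 || !all(fs %in% fns))
      stop("unknown interaction in surrogate spec: ", nm)
    y <- y + spec$interaction[[nm]] * X[, fs[1]] * X[, fs[2]]
  }
  for (nm in names(spec$quadratic)) {
    f <- sub("\\^2$", "", nm)
    if (!f %in% fns) stop("unknown quadratic in surrogate spec: ", nm)
    y <- y + spec$quadratic[[nm]] * X[, f]^2
  }
  if (spec$sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    y <- y + stats::rnorm(length(y), 0, spec$sigma)
  }
  data.frame(run = seq_len(nrow(X)), y = y)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- crack-path fixtures ---------------------------------------------------

# point on the outer cement-band edge (signed distance = level) at angle th
band_point <- function(geom, th, level) {
  geom$center + ray_to_level(geom, th, level) * c(cos(th), sin(th))
}

# march along the band edge from th0 in direction dir (+1 ccw) until the
# polyline length reaches target_len; returns the point matrix
band_arc <- function(geom, th0, target_len, dir = 1, dth = 2 * pi / 256) {
  t <- geom$params$cement_thickness
  pts <- matrix(band_point(geom, th0, t), ncol = 2)
  len <- 0; th <- th0
  while (len < target_len) {
    th <- th + dir * dth
    p <- band_point(geom, th, t)
    len <- len + sqrt(sum((p - pts[nrow(pts), ])^2))
    pts <- rbind(pts, p)
  }
  attr(pts, "theta_end") <- th
  pts
}

# polyline points -> segment table rows
seg_rows <- function(pts, provenance) {
  n <- nrow(pts) - 1L
  if (n < 1L) return(NULL)
  data.frame(x1 = pts[-nrow(pts), 1], y1 = pts[-nrow(pts), 2],
             x2 = pts[-1, 1], y2 = pts[-1, 2],
             mid_x = (pts[-nrow(pts), 1] + pts[-1, 1]) / 2,
             mid_y = (pts[-nrow(pts), 2] + pts[-1, 2]) / 2,
             length = sqrt(rowSums((pts[-1, , drop = FALSE] -
                                      pts[-nrow(pts), , drop = FALSE])^2)),
             provenance = provenance)
}

# straight polyline from a to b in nseg segments
line_pts <- function(a, b, nseg = 4) {
  f <- seq(0, 1, length.out = nseg + 1)
  cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]))
}

#' Randomized crack-path fixture of a given score class
#'
#' Constructs a crack segment table (same shape as `crack_sim$segments`)
#' satisfying exactly one score class's defining conditions: interface
#' (QUADE) arc length, osteon penetration, far-side matrix exit, perimeter
#' coverage. Used to validate [crack_score()] independently of the solver.
#' Arc lengths are drawn away from the class boundaries (e.g. class 2 draws
#' its deflection in 1-22 um so the discretized arc stays below the 25 um
#' threshold).
#'
#' @param class integer score class 1..5.
#' @param geom a `bone_geometry` with an osteon (radial is typical).
#' @param seed RNG seed.
#' @return segment data.frame with columns `x1, y1, x2, y2, mid_x, mid_y,
#'   length, provenance`.
#' @export
fixture_crack_path <- function(class, geom, seed = 1L) {
  stopifnot(class %in% 1:5, inherits(geom, "bone_geometry"),
            geom$params$orientation != "none")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- geom$params$side
  t <- geom$params$cement_thickness
  yc <- L / 2
  th0 <- pi
  notch_tip <- c(geom$params$crack_fraction * L, yc)
  B0 <- band_point(geom, th0, t)
  segs <- rbind(seg_rows(line_pts(c(0, yc), notch_tip, 2), "initial"),
                seg_rows(line_pts(notch_tip, B0, 4), "MAXPE"))
  cross_in <- function(th) {  # outer band edge -> osteon boundary
    seg_rows(rbind(band_point(geom, th, t), band_point(geom, th, 0)), "MAXPE")
  }
  chord <- function(th_in, th_out) {  # through the osteon via the centre
    rbind(seg_rows(line_pts(band_point(geom, th_in, 0), geom$center, 3),
                   "MAXPE"),
          seg_rows(line_pts(geom$center, band_point(geom, th_out, 0), 3),
                   "MAXPE"))
  }
  exit_right <- function(th) {  # band edge -> far-side matrix -> right edge
    p <- band_point(geom, th, t)
    out <- p + 50e-6 * c(cos(th), sin(th))
    rbind(seg_rows(rbind(p, out), "MAXPE"),
          seg_rows(line_pts(out, c(L, out[2]), 4), "MAXPE"))
  }
  dir <- sample(c(-1, 1), 1)
  if (class == 1) {
    segs <- rbind(segs, cross_in(th0), chord(th0, 0), exit_right(0))
  } else if (class == 2) {
    arc <- band_arc(geom, th0, stats::runif(1, 1e-6, 22e-6), dir)
    th_e <- attr(arc, "theta_end")
    segs <- rbind(segs, seg_rows(arc, "QUADE"), cross_in(th_e),
                  chord(th_e, th_e + pi), exit_right(th_e + pi))
  } else if (class == 3) {
    arc <- band_arc(geom, th0,
                    stats::runif(1, 50e-6, 0.4 * geom$perimeter), dir)
    th_e <- attr(arc, "theta_end")
    segs <- rbind(segs, seg_rows(arc, "QUADE"), cross_in(th_e),
                  chord(th_e, th_e + pi), exit_right(th_e + pi))
  } else if (class == 4) {
    arc <- band_arc(geom, th0,
                    stats::runif(1, 0.3, 0.6) * geom$perimeter, dir)
    segs <- rbind(segs, seg_rows(arc, "QUADE"),
                  exit_right(attr(arc, "theta_end")))
  } else {
    arc <- band_arc(geom, th0,
                    stats::runif(1, 0.955, 0.99) * geom$perimeter, dir)
    segs <- rbind(segs, seg_rows(arc, "QUADE"))
  }
  rownames(segs) <- NULL
  segs
}

#' Small deterministic meshes for solver and propagation tests
#'
#' \describe{
#'   \item{unit_patch}{2 x 2 element patch on the unit square with a
#'     deterministically displaced interior node (for patch tests).}
#'   \item{notched_strip}{homogeneous 14 x 14 plate whose geometry carries
#'     the standard 10% edge notch.}
#'   \item{mini_radial}{radial single-osteon model at the coarse mesh
#'     preset; all three phases present.}
#' }
#'
#' @param kind `"unit_patch"`, `"notched_strip"` or `"mini_radial"`.
#' @return a `bone_mesh`.
#' @export
fixture_mesh <- function(kind = c("unit_patch", "notched_strip",
                                  "mini_radial")) {
  kind <- match.arg(kind)
  if (kind == "unit_patch") {
    geom <- build_geometry(geometry_params("none", side = 1))
    mesh <- generate_mesh(geom, mesh_spec(plate_nx = 2, plate_ny = 2))
    mesh$nodes[5, ] <- c(0.42, 0.61)  # displace the interior node
    mesh$elem_size <- sqrt(elem_areas(mesh))
    mesh
  } else if (kind == "notched_strip") {
    geom <- build_geometry(geometry_params("none"))
    generate_mesh(geom, mesh_spec(plate_nx = 14, plate_ny = 14))
  } else {
    geom <- build_geometry(geometry_params("radial"))
    generate_mesh(geom, mesh_spec(level = "coarse"))
  }
}
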