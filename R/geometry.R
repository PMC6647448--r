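#' Geometry parameters for a single-osteon microstructural model
#'
#' Defines the parametric plane geometry used throughout: an L x L square of
#' interstitial matrix containing one osteon (a circle in the radial model, a
#' stadium -- rectangle with two half-circle end caps -- in the longitudinal and
#' transversal models) surrounded by a thin cement-line band, with an initial
#' edge crack entering horizontally from the midpoint of the left edge.
#'
#' Units are SI (metres, radians). Defaults are the study dimensions:
#' L = 1 mm, h = 650 um, d = 150 um, t = 5 um, out-of-plane thickness 100 um,
#' osteon rotation 10 degrees, initial crack length 10% of L.
#'
#' @param orientation one of `"longitudinal"` (osteon long axis along the
#'   loading direction), `"radial"` (circular cross-section), `"transversal"`
#'   (long axis perpendicular to the load) or `"none"` (homogeneous plate,
#'   no osteon).
#' @param side side length L of the square domain (m).
#' @param osteon_length total stadium length h, caps included (m).
#' @param osteon_diameter osteon diameter d (m); stadium width and cap
#'   diameter, or circle diameter in the radial model.
#' @param cement_thickness cement-line band thickness t (m).
#' @param thickness out-of-plane model thickness (m).
#' @param rotation osteon rotation angle (rad), counter-clockwise, applied to
#'   the stadium axis. Ignored for radial/none.
#' @param crack_fraction initial crack length as a fraction of L, in (0, 0.5).
#' @return an object of class `geometry_params`.
#' @export
geometry_params <- function(orientation = c("longitudinal", "radial",
                                            "transversal", "none"),
                            side = 1e-3,
                            osteon_length = 650e-6,
                            osteon_diameter = 150e-6,
                            cement_thickness = 5e-6,
                            thickness = 100e-6,
                            rotation = 10 * pi / 180,
                            crack_fraction = 0.1) {
  orientation <- match.arg(orientation)
  stopifnot(side > 0, osteon_length > 0, osteon_diameter > 0,
            cement_thickness > 0, thickness > 0)
  if (!(crack_fraction > 0 && crack_fraction < 0.5))
    stop("crack_fraction must lie in (0, 0.5)")
  if (orientation != "none") {
    if (osteon_diameter + 2 * cement_thickness >= side)
      stop("invalid geometry: d + 2t must be smaller than L")
    if (osteon_length > side)
      stop("invalid geometry: h must not exceed L")
    if (orientation != "radial" && osteon_length < osteon_diameter)
      stop("invalid geometry: stadium length h must be >= diameter d")
  }
  structure(list(orientation = orientation,
                 side = side,
                 osteon_length = osteon_length,
                 osteon_diameter = osteon_diameter,
                 cement_thickness = cement_thickness,
                 thickness = thickness,
                 rotation = rotation,
                 crack_fraction = crack_fraction),
            class = "geometry_params")
}

#' Build the region description of a single-osteon model
#'
#' Turns [geometry_params()] into a concrete region description: the osteon
#' region (circle or rotated stadium, centred in the square), the cement-line
#' band of uniform thickness t offset outward from the osteon boundary, the
#' surrounding matrix, and the initial traction-free edge crack.
#'
#' The osteon boundary is described by its signed distance field (negative
#' inside the osteon); the cement band is `0 <= sdist <= t`.
#'
#' @param params a `geometry_params` object.
#' @return an object of class `bone_geometry` with fields `params`, `center`,
#'   `axis` (stadium axis unit vector or `NULL`), `cap_half` (half distance
#'   between cap centres), `radius`, `perimeter` (osteon boundary length),
#'   `osteon_area`, `cement_area`, `notch` (2 x 2 matrix of initial crack
#'   endpoints).
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  L <- params$side
  ctr <- c(L / 2, L / 2)
  r <- params$osteon_diameter / 2
  t <- params$cement_thickness
  orient <- params$orientation
  if (orient == "none") {
    geom <- list(params = params, center = ctr, axis = NULL, cap_half = 0,
                 radius = 0, perimeter = 0, osteon_area = 0, cement_area = 0)
  } else if (orient == "radial") {
    if (r + t >= L / 2) stop("invalid geometry: cement band touches the domain boundary")
    geom <- list(params = params, center = ctr, axis = NULL, cap_half = 0,
                 radius = r,
                 perimeter = 2 * pi * r,
                 osteon_area = pi * r^2,
                 cement_area = 2 * pi * r * t + pi * t^2)
  } else {
    a <- (params$osteon_length - params$osteon_diameter) / 2
    # longitudinal: axis along the load (vertical); transversal: horizontal.
    base_ang <- if (orient == "longitudinal") pi / 2 else 0
    ang <- base_ang + params$rotation
    u <- c(cos(ang), sin(ang))
    # conservative containment check: farthest band point from the centre
    if (a + r + t >= L / 2)
      stop("invalid geometry: cement band touches the domain boundary")
    geom <- list(params = params, center = ctr, axis = u, cap_half = a,
                 radius = r,
                 perimeter = 4 * a + 2 * pi * r,
                 osteon_area = 2 * a * 2 * r + pi * r^2,
                 cement_area = (4 * a + 2 * pi * r) * t + pi * t^2)
  }
  geom$notch <- rbind(c(0, L / 2), c(params$crack_fraction * L, L / 2))
  class(geom) <- "bone_geometry"
  geom
}

#' Signed distance to the osteon boundary
#'
#' Negative inside the osteon, zero on its boundary, positive outside. The
#' cement-line band is the set `0 <= sdist <= t`.
#'
#' @param geom a `bone_geometry` object.
#' @param pts numeric matrix (n x 2) of points, or a length-2 vector.
#' @return numeric vector of signed distances (m); `Inf` when the geometry
#'   has no osteon.
#' @export
osteon_sdist <- function(geom, pts) {
  pts <- rbind2mat(pts)
  if (geom$params$orientation == "none") return(rep(Inf, nrow(pts)))
  dx <- pts[, 1] - geom$center[1]
  dy <- pts[, 2] - geom$center[2]
  if (is.null(geom$axis)) return(sqrt(dx^2 + dy^2) - geom$radius)
  u <- geom$axis
  s <- pmin(pmax(dx * u[1] + dy * u[2], -geom$cap_half), geom$cap_half)
  ex <- dx - s * u[1]
  ey <- dy - s * u[2]
  sqrt(ex^2 + ey^2) - geom$radius
}

#' Phase membership of points
#'
#' @param geom a `bone_geometry` object.
#' @param pts numeric matrix (n x 2) of points, or a length-2 vector.
#' @return character vector in `{"osteon", "cement_line", "matrix"}`.
#' @export
phase_at <- function(geom, pts) {
  sd <- unname(osteon_sdist(geom, pts))
  t <- geom$params$cement_thickness
  ifelse(sd < 0, "osteon", ifelse(sd <= t, "cement_line", "matrix"))
}

# internal: vectorized outward normal of the osteon boundary nearest each point
osteon_normal <- function(geom, pts) {
  pts <- rbind2mat(pts)
  dx <- pts[, 1] - geom$center[1]
  dy <- pts[, 2] - geom$center[2]
  if (!is.null(geom$axis)) {
    u <- geom$axis
    s <- pmin(pmax(dx * u[1] + dy * u[2], -geom$cap_half), geom$cap_half)
    dx <- dx - s * u[1]
    dy <- dy - s * u[2]
  }
  nrm <- sqrt(dx^2 + dy^2)
  if (any(nrm < 1e-15))
    stop("point coincides with the osteon medial axis; normal undefined")
  cbind(dx / nrm, dy / nrm)
}

#' Unit outward normal of the cement-line interface at a point
#'
#' Returns the outward unit normal of the osteon boundary curve nearest to
#' `point`. Used as the crack normal of the QUADE interface criterion and to
#' resolve cement-line strains into normal/shear components.
#'
#' @param point length-2 numeric, a point in or near the cement-line band.
#' @param geom a `bone_geometry` object.
#' @param band_tol allowed distance beyond the band `[0, t]` (m); defaults to
#'   the band thickness t.
#' @return unit vector (length-2 numeric) pointing from osteon to matrix.
#' @export
interface_normal_at <- function(point, geom, band_tol = NULL) {
  stopifnot(inherits(geom, "bone_geometry"))
  if (geom$params$orientation == "none")
    stop("geometry has no cement-line interface")
  t <- geom$params$cement_thickness
  if (is.null(band_tol)) band_tol <- t
  sd <- osteon_sdist(geom, point)
  if (sd < -band_tol || sd > t + band_tol)
    stop(sprintf("point is outside the cement-line band (signed distance %.3g m)", sd))
  drop(osteon_normal(geom, point))
}

# internal: distance from the centre along direction theta to the square edge
ray_to_box <- function(geom, theta) {
  L <- geom$params$side
  e <- c(cos(theta), sin(theta))
  cand <- c(if (e[1] > 0) (L - geom$center[1]) / e[1],
            if (e[1] < 0) (0 - geom$center[1]) / e[1],
            if (e[2] > 0) (L - geom$center[2]) / e[2],
            if (e[2] < 0) (0 - geom$center[2]) / e[2])
  min(cand)
}

# internal: distance along ray theta from the centre to the level set
# sdist = level (level = 0 -> osteon boundary, level = t -> outer band edge)
ray_to_level <- function(geom, theta, level = 0) {
  e <- c(cos(theta), sin(theta))
  f <- function(rho) osteon_sdist(geom, geom$center + rho * e) - level
  upper <- ray_to_box(geom, theta)
  stats::uniroot(f, c(1e-12, upper), tol = 1e-13)$root
}

# internal: coerce a 2-vector or n x 2 matrix to matrix form
rbind2mat <- function(pts) {
  if (is.null(dim(pts))) matrix(pts, ncol = 2) else as.matrix(pts)
}
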