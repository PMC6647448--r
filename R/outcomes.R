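# The four outcome parameters extracted from a simulation: maximum force,
# fracture energy, crack length and crack score.

#' Maximum force of a load curve
#' @param curve data.frame with columns `u` (displacement, m) and `force` (N).
#' @return peak force (N).
#' @export
max_force <- function(curve) {
  if (is.null(curve) || !nrow(curve)) stop("empty load curve")
  max(curve$force)
}

#' Fracture energy of a load curve
#'
#' Total external work: the trapezoidal area under the force-displacement
#' curve up to termination. The curve is assumed sampled from zero
#' displacement; a linear ramp from the origin to the first sample is
#' included when the first sample is at `u > 0`.
#'
#' @param curve data.frame with columns `u` and `force`.
#' @return energy (J).
#' @export
fracture_energy <- function(curve) {
  if (is.null(curve) || !nrow(curve)) stop("empty load curve")
  u <- curve$u; f <- curve$force
  if (any(diff(u) < 0)) stop("non-monotone displacement in load curve")
  if (u[1] > 0) { u <- c(0, u); f <- c(0, f) }
  sum(0.5 * (f[-1] + f[-length(f)]) * diff(u))
}

#' Crack length
#'
#' Sum of Euclidean segment lengths of the crack polyline, initial notch
#' included.
#'
#' @param segments crack segment table (from a `crack_sim` or a fixture):
#'   needs a `length` column.
#' @return length (m).
#' @export
crack_length <- function(segments) {
  if (is.null(segments) || !nrow(segments)) return(0)
  sum(segments$length)
}

#' Crack score: ordinal 1-5 classification of the crack trajectory
#'
#' Deterministic classification of how the crack interacted with the cement
#' line, from straight osteon penetration to full interface encirclement:
#' \describe{
#'   \item{1}{unaffected by the cement line, propagated straight through the
#'     osteon (no interface deflection).}
#'   \item{2}{deflected a short distance (< 25 um) into the interface before
#'     entering the osteon.}
#'   \item{3}{propagated mostly along the cement line but also through the
#'     osteon (deflection >= 25 um with osteon penetration).}
#'   \item{4}{deflected into the cement line and never penetrated the osteon,
#'     leaving into the far-side matrix (or arresting after substantial
#'     deflection).}
#'   \item{5}{followed the interface essentially all around the osteon
#'     (>= 95\% of the cement-line perimeter).}
#' }
#' Deflection is measured as the summed length `D` of QUADE-provenance
#' segments; penetration `P` as any segment midpoint strictly inside the
#' osteon (tolerance t/2 below the boundary, so interface chords of a
#' discretized arc do not count as penetration).
#'
#' @param segments crack segment table with columns `mid_x, mid_y, length,
#'   provenance`.
#' @param geom the `bone_geometry` the crack grew in.
#' @param short_deflection deflection length separating scores 2 and 3 (m).
#' @param perimeter_frac interface coverage fraction defining score 5.
#' @return integer score in 1..5.
#' @export
crack_score <- function(segments, geom, short_deflection = 25e-6,
                        perimeter_frac = 0.95) {
  stopifnot(inherits(geom, "bone_geometry"))
  if (geom$params$orientation == "none")
    stop("crack score needs an osteon/cement-line geometry")
  if (is.null(segments) || !nrow(segments))
    stop("crack score undefined: no crack segments")
  t <- geom$params$cement_thickness
  sd <- osteon_sdist(geom, cbind(segments$mid_x, segments$mid_y))
  P <- any(sd < -t / 2)
  D <- sum(segments$length[segments$provenance == "QUADE"])
  reached <- any(sd <= t + t / 2) || D > 0
  if (!reached)
    stop("crack score undefined: crack never reached the cement line")
  if (P) {
    if (D == 0) return(1L)
    if (D < short_deflection) return(2L)
    return(3L)
  }
  if (D >= perimeter_frac * geom$perimeter) return(5L)
  exit_far <- any(sd > 1.5 * t & segments$mid_x > geom$center[1])
  if (exit_far) return(4L)
  if (D >= short_deflection) return(4L)  # arrested after substantial deflection
  stop("crack score undefined: crack arrested at the interface")
}

#' Outcome parameters of a simulation
#'
#' @param sim a `crack_sim` object.
#' @param score_error `"error"` to propagate an undefined crack score as an
#'   error, `"na"` to return `NA` instead (useful in parameter sweeps).
#' @return data.frame with one row: `max_force` (N), `fracture_energy` (J),
#'   `crack_length` (m), `crack_score`.
#' @export
outcomes <- function(sim, score_error = c("error", "na")) {
  score_error <- match.arg(score_error)
  stopifnot(inherits(sim, "crack_sim"))
  score <- if (score_error == "error")
    crack_score(sim$segments, sim$geom)
  else
    tryCatch(crack_score(sim$segments, sim$geom),
             error = function(e) NA_integer_)
  data.frame(max_force = max_force(sim$curve),
             fracture_energy = fracture_energy(sim$curve),
             crack_length = crack_length(sim$segments),
             crack_score = score)
}

#' Write a load curve to CSV
#' @param sim a `crack_sim` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_load_curve_csv <- function(sim, path) {
  utils::write.csv(sim$curve, path, row.names = FALSE)
  invisible(path)
}

#' Write the crack polyline to legacy VTK format
#' @param sim a `crack_sim` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_crack_vtk <- function(sim, path) {
  p <- sim$path
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "osteocrack crack path", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9e %.9e 0", p[, 1], p[, 2]), con)
  writeLines(sprintf("LINES 1 %d", n + 1), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  invisible(path)
}

#' Simulation result as a JSON string or file
#'
#' Serializes outcomes, status, crack polyline and per-segment provenance.
#'
#' @param sim a `crack_sim` object.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when `path` given).
#' @export
sim_to_json <- function(sim, path = NULL) {
  out <- tryCatch(outcomes(sim), error = function(e) outcomes(sim, "na"))
  obj <- list(outcomes = as.list(out), status = sim$status,
              path = unname(apply(sim$path, 1, function(r) c(r[1], r[2]),
                                  simplify = FALSE)),
              provenance = sim$segments$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
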