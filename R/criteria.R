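#' MAXPE damage initiation criterion
#'
#' Maximum principal strain criterion used in matrix, osteon and (competing
#' with QUADE) cement-line elements: `f = <eps_max> / eps0`, where `< >` is
#' the positive part, so compressive principal strain never initiates damage.
#' Damage initiates when `f > 1`; the crack normal is then the maximum
#' principal strain direction.
#'
#' @param eps_max maximum principal strain (dimensionless); vectorized.
#' @param eps0 critical damage initiation strain, > 0.
#' @return criterion value(s) `f >= 0`.
#' @export
f_maxpe <- function(eps_max, eps0) {
  stopifnot(eps0 > 0)
  pmax(eps_max, 0) / eps0
}

#' QUADE quadratic nominal strain interface criterion
#'
#' Interface damage criterion of the cement line:
#' `f = (<eps_n>/eps0_n)^2 + (eps_s/eps0_s)^2`. The normal strain enters
#' through its positive part (no initiation under interface compression);
#' shear contributes irrespective of sign. Damage initiates when `f > 1`;
#' the crack normal is then the interface normal, so the crack deflects along
#' the cement line.
#'
#' @param eps_n strain normal to the interface; vectorized.
#' @param eps_s (engineering) shear strain resolved on the interface.
#' @param eps0_n,eps0_s critical normal/shear interface strains, > 0.
#' @return criterion value(s) `f >= 0`.
#' @export
f_quade <- function(eps_n, eps_s, eps0_n, eps0_s) {
  stopifnot(eps0_n > 0, eps0_s > 0)
  (pmax(eps_n, 0) / eps0_n)^2 + (eps_s / eps0_s)^2
}

#' Three-dimensional generalization of the QUADE criterion
#'
#' Adds the second interface shear direction:
#' `f = (<eps_n>/eps0_n)^2 + (eps_s/eps0_s)^2 + (eps_t/eps0_t)^2`.
#' Provided as a standalone function (no 3D solver accompanies it); with
#' `eps_t = 0` it reduces exactly to [f_quade()].
#'
#' @param eps_n interface normal strain; vectorized.
#' @param eps_s,eps_t the two interface shear strains.
#' @param eps0_n,eps0_s,eps0_t critical strains, > 0.
#' @return criterion value(s) `f >= 0`.
#' @export
f_quade_3d <- function(eps_n, eps_s, eps_t, eps0_n, eps0_s, eps0_t) {
  stopifnot(eps0_t > 0)
  f_quade(eps_n, eps_s, eps0_n, eps0_s) + (eps_t / eps0_t)^2
}

#' Damage initiation check for one element
#'
#' Applies the phase-dependent initiation rule: matrix and osteon elements
#' evaluate MAXPE only; cement-line elements evaluate both MAXPE and QUADE,
#' and damage initiates when `max(f_QUADE, f_MAXPE) > 1`. When both criteria
#' exceed 1 within one displacement increment, the winner is the criterion
#' whose threshold is crossed first under proportional scaling of the strain
#' state: MAXPE is linear in strain while QUADE is quadratic, so the
#' first-crossing comparison is `f_MAXPE` vs `sqrt(f_QUADE)`. (Comparing raw
#' `f` values would bias the choice toward the quadratic criterion whenever
#' a finite increment overshoots the threshold.) Ties go to MAXPE
#' (penetration), mirroring the strict inequality that defines deflection in
#' the crack-score rules.
#'
#' @param strain a strain state from [element_strain()] (one row), holding
#'   `eps1`, principal direction `dir1`, and for cement elements `eps_n`,
#'   `eps_s` and the interface `normal`.
#' @param phase `"matrix"`, `"osteon"` or `"cement_line"`.
#' @param mat named material parameter vector (see [material_params()]).
#' @return `NULL` when no criterion exceeds 1, else a list with `criterion`
#'   (`"MAXPE"` or `"QUADE"`), `f`, and the crack `normal` (unit 2-vector).
#' @export
initiation_check <- function(strain, phase, mat) {
  if (phase == "cement_line") {
    fm <- f_maxpe(strain$eps1, mat[["eps0_cl"]])
    fq <- f_quade(strain$eps_n, strain$eps_s, mat[["epsn_cl"]], mat[["epss_cl"]])
    if (max(fm, fq) <= 1) return(NULL)
    quade_first <- fq > 1 && (fm <= 1 || sqrt(fq) > fm)
    if (quade_first)
      list(criterion = "QUADE", f = fq, normal = strain$normal)
    else
      list(criterion = "MAXPE", f = fm, normal = strain$dir1)
  } else {
    eps0 <- switch(phase, matrix = mat[["eps0_mat"]], osteon = mat[["eps0_ost"]],
                   stop("unknown phase: ", phase))
    fm <- f_maxpe(strain$eps1, eps0)
    if (fm <= 1) return(NULL)
    list(criterion = "MAXPE", f = fm, normal = strain$dir1)
  }
}

#' Linear-softening cohesive traction-separation law
#'
#' Mode-independent linear softening: a cohesive segment initiated at
#' traction `T0` loses load-carrying capacity linearly with the effective
#' separation `delta = sqrt(<delta_n>^2 + delta_s^2)`, reaching zero at the
#' final separation `delta_f = 2 G / T0`; the area under the
#' traction-separation curve equals the strain energy release rate `G`
#' exactly. Unloading and reloading follow the secant through the origin, so
#' damage is irreversible: the history-maximum separation `delta_hist` sets
#' the damage `d` and the secant stiffness.
#'
#' `delta0 > 0` selects a regularized bilinear variant with a short initial
#' elastic branch up to `delta0` (peak still `T0`, area still exactly `G`);
#' the default `delta0 = 0` is the pure softening limit.
#'
#' @param delta current effective separation (m), >= 0; vectorized.
#' @param T0 initiation traction (Pa), > 0.
#' @param G strain energy release rate (J/m^2), > 0.
#' @param delta_hist history-maximum separation (m); defaults to `delta`.
#' @param delta0 initial elastic branch length (m), >= 0.
#' @return list with `traction` (Pa), `damage` in [0, 1], `dissipated`
#'   energy per crack area (J/m^2), `stiffness` (secant, Pa/m) and `delta_f`.
#' @export
cohesive_traction <- function(delta, T0, G, delta_hist = delta, delta0 = 0) {
  stopifnot(T0 > 0, G > 0, all(delta >= 0), delta0 >= 0)
  delta_f <- 2 * G / T0
  stopifnot(delta0 < delta_f)
  dh <- pmax(delta_hist, delta)
  envelope <- function(x)
    ifelse(x < delta0, T0 * x / delta0,
           ifelse(x < delta_f, T0 * (delta_f - x) / (delta_f - delta0), 0))
  # secant stiffness through the origin at the history point
  k <- ifelse(dh <= delta0,
              if (delta0 > 0) T0 / delta0 else Inf,
              envelope(dh) / dh)
  traction <- ifelse(is.infinite(k),
                     ifelse(delta == 0, T0, 0),  # pure limit: T(0) = T0
                     k * delta)
  if (delta0 == 0) traction <- pmin(traction, T0 * pmax(1 - dh / delta_f, 0))
  damage <- pmin(pmax((dh - delta0) / (delta_f - delta0), 0), 1)
  # envelope area up to dh minus the recoverable secant energy
  env_area <- ifelse(dh <= delta0, 0.5 * envelope(dh) * dh,
                     0.5 * T0 * delta0 +
                       0.5 * (pmin(dh, delta_f) - delta0) *
                         (T0 + envelope(pmin(dh, delta_f))))
  dissipated <- env_area - 0.5 * envelope(dh) * dh
  list(traction = traction, damage = damage, dissipated = dissipated,
       stiffness = k, delta_f = delta_f)
}
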