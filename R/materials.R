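#' Baseline material parameters (the 14-factor vector)
#'
#' Returns the baseline values of the 14 material parameters governing the
#' model, in SI units: Young's moduli (Pa) and Poisson's ratios of matrix,
#' osteon and cement line; critical damage initiation strains of the MAXPE
#' criterion per phase; critical normal/shear interface strains of the QUADE
#' criterion in the cement line; and strain energy release rates (J/m^2) per
#' phase. The critical interface strains are orientation specific: their
#' baseline is the midpoint between crack penetration and deflection for each
#' osteon orientation (longitudinal 0.00105, radial 0.0015, transversal
#' 0.0035).
#'
#' @param orientation `"longitudinal"`, `"radial"` or `"transversal"`.
#' @return named numeric vector of length 14 with names `E_mat, E_ost, E_cl,
#'   nu_mat, nu_ost, nu_cl, eps0_mat, eps0_ost, eps0_cl, epsn_cl, epss_cl,
#'   G_mat, G_ost, G_cl`.
#' @export
material_params <- function(orientation = c("longitudinal", "radial",
                                            "transversal")) {
  orientation <- match.arg(orientation)
  eps_cl <- switch(orientation, longitudinal = 0.00105, radial = 0.0015,
                   transversal = 0.0035)
  c(E_mat = 15e9, E_ost = 12e9, E_cl = 18e9,
    nu_mat = 0.3, nu_ost = 0.3, nu_cl = 0.3,
    eps0_mat = 0.004, eps0_ost = 0.004, eps0_cl = 0.004,
    epsn_cl = eps_cl, epss_cl = eps_cl,
    G_mat = 200, G_ost = 200, G_cl = 200)
}

#' Factor names of the two experiment designs
#'
#' The screening design varies all 14 material parameters. The response
#' surface (Box-Behnken) design varies the 7 parameters found important for
#' fracture energy, crack length and crack score, with the interface normal
#' and shear strains tied together as one factor `eps_cl`.
#'
#' @param design `"screening"` or `"box_behnken"`.
#' @return character vector of factor names.
#' @export
factor_names <- function(design = c("screening", "box_behnken")) {
  design <- match.arg(design)
  if (design == "screening")
    c("E_mat", "E_ost", "E_cl", "nu_mat", "nu_ost", "nu_cl",
      "eps0_mat", "eps0_ost", "eps0_cl", "epsn_cl", "epss_cl",
      "G_mat", "G_ost", "G_cl")
  else
    c("E_ost", "E_cl", "eps0_cl", "eps_cl", "G_mat", "G_ost", "G_cl")
}

#' Factor levels: baseline and +/- 20% span
#'
#' Builds the low/baseline/high level table used by both experiment designs:
#' low = 0.8 x baseline, high = 1.2 x baseline for every factor. The combined
#' interface-strain factor `eps_cl` (response surface designs) sets
#' `epsn_cl = epss_cl` to a common value.
#'
#' @param orientation osteon orientation (selects the interface baselines).
#' @param design which factor set to tabulate.
#' @param span relative half-width of the parameter space (default 0.2).
#' @return data.frame with columns `factor`, `low`, `baseline`, `high`.
#' @export
factor_levels <- function(orientation = c("longitudinal", "radial",
                                          "transversal"),
                          design = c("screening", "box_behnken"),
                          span = 0.2) {
  orientation <- match.arg(orientation)
  design <- match.arg(design)
  base <- material_params(orientation)
  fns <- factor_names(design)
  baseline <- vapply(fns, function(f)
    if (f == "eps_cl") unname(base[["epsn_cl"]]) else unname(base[[f]]),
    numeric(1))
  data.frame(factor = fns,
             low = (1 - span) * baseline,
             baseline = baseline,
             high = (1 + span) * baseline,
             row.names = NULL)
}

#' Map a coded design matrix to physical material parameter vectors
#'
#' Coded levels -1/0/+1 map to low/baseline/high of [factor_levels()].
#' Factors absent from the design stay at baseline. The combined factor
#' `eps_cl` writes both `epsn_cl` and `epss_cl`.
#'
#' @param design a `doe_design` object (see [screening_design()]).
#' @param levels a factor-level table from [factor_levels()].
#' @param orientation orientation whose baseline fills unvaried parameters.
#' @return list of named 14-parameter vectors, one per design run.
#' @export
map_levels <- function(design, levels,
                       orientation = c("longitudinal", "radial",
                                       "transversal")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(design, "doe_design"))
  X <- design$matrix
  if (!all(colnames(X) %in% levels$factor))
    stop("design factors missing from the level table: ",
         paste(setdiff(colnames(X), levels$factor), collapse = ", "))
  base <- material_params(orientation)
  lapply(seq_len(nrow(X)), function(i) {
    p <- base
    for (f in colnames(X)) {
      row <- levels[levels$factor == f, ]
      v <- row$baseline * (1 + (row$high / row$baseline - 1) * X[i, f])
      if (f == "eps_cl") p[c("epsn_cl", "epss_cl")] <- v else p[[f]] <- v
    }
    p
  })
}
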