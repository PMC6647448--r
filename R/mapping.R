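# Crack-score region mapping: sweeps of grouped toughness G and critical
# interface strain over coarse grids, optionally at several cement-line
# stiffness levels.

#' Sweep crack scores over a (G, interface strain) grid
#'
#' Runs one simulation per grid cell with all other parameters at baseline:
#' the toughness values are grouped (`G = G_mat = G_ost = G_cl`, or matrix
#' toughness only with the others fixed at baseline when
#' `vary = "matrix"`) and the critical interface strains are grouped
#' (`eps_cl = epsn_cl = epss_cl`). Non-convergent cells are flagged
#' (`score = NA`) and the map is still returned.
#'
#' @param orientation osteon orientation.
#' @param G_grid strain energy release rates (J/m^2), increasing.
#' @param eps_grid critical interface strains, increasing.
#' @param E_cl cement-line Young's modulus (Pa); `NULL` keeps baseline.
#' @param spec mesh specification (coarse preset by default: maps are about
#'   region structure, not mesh-converged forces).
#' @param load loading program.
#' @param vary `"all"` (grouped toughness) or `"matrix"` (vary G_mat only).
#' @param verbose print one line per cell.
#' @return data.frame of class `region_map`: `orientation, E_cl, G, eps_cl,
#'   score, status`.
#' @export
sweep_scores <- function(orientation, G_grid, eps_grid, E_cl = NULL,
                         spec = mesh_spec(level = "coarse"),
                         load = load_program(), vary = c("all", "matrix"),
                         verbose = FALSE) {
  vary <- match.arg(vary)
  stopifnot(!is.unsorted(G_grid, strictly = TRUE),
            !is.unsorted(eps_grid, strictly = TRUE), all(G_grid > 0),
            all(eps_grid > 0))
  geom <- build_geometry(geometry_params(orientation))
  mesh <- generate_mesh(geom, spec)
  base <- material_params(orientation)
  if (!is.null(E_cl)) base[["E_cl"]] <- E_cl
  cells <- expand.grid(G = G_grid, eps_cl = eps_grid)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    mat <- base
    if (vary == "all") mat[c("G_mat", "G_ost", "G_cl")] <- cells$G[i]
    else mat[["G_mat"]] <- cells$G[i]
    mat[c("epsn_cl", "epss_cl")] <- cells$eps_cl[i]
    sim <- tryCatch(propagate(geom, mat, mesh = mesh, load = load),
                    error = function(e) NULL)
    score <- if (is.null(sim)) NA_integer_
    else tryCatch(crack_score(sim$segments, geom),
                  error = function(e) NA_integer_)
    status <- if (is.null(sim)) "nonconvergent" else sim$status
    if (verbose)
      message(sprintf("%s G=%.3g eps=%.3g -> score %s (%s)", orientation,
                      cells$G[i], cells$eps_cl[i], score, status))
    data.frame(orientation = orientation,
               E_cl = base[["E_cl"]], G = cells$G[i],
               eps_cl = cells$eps_cl[i], score = score, status = status)
  })
  out <- do.call(rbind, res)
  class(out) <- c("region_map", class(out))
  out
}

#' Region maps at several cement-line stiffness levels
#'
#' Repeats [sweep_scores()] for the longitudinal model at the cement-line
#' stiffness levels of interest: 20% below the osteon stiffness (9.6 GPa),
#' equal to the matrix stiffness (15 GPa) and the 18 GPa baseline.
#'
#' @param G_grid,eps_grid grids passed to [sweep_scores()]; the interface
#'   strain grid conventionally spans 0.0005-0.003 here.
#' @param E_cl_levels cement-line stiffness levels (Pa).
#' @param orientation osteon orientation (longitudinal for the study).
#' @param ... passed on to [sweep_scores()].
#' @return a `region_map` data.frame covering all stiffness levels.
#' @export
stiffness_variants <- function(G_grid, eps_grid,
                               E_cl_levels = c(9.6e9, 15e9, 18e9),
                               orientation = "longitudinal", ...) {
  out <- do.call(rbind, lapply(E_cl_levels, function(E)
    sweep_scores(orientation, G_grid, eps_grid, E_cl = E, ...)))
  class(out) <- c("region_map", class(out))
  out
}

#' Plot a crack-score region map
#'
#' Tile plot of crack score over the (interface strain, toughness) grid,
#' facetted by orientation and cement-line stiffness. Requires ggplot2.
#'
#' @param map a `region_map`.
#' @return a ggplot object.
#' @export
plot_region_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(map, ggplot2::aes(x = factor(eps_cl), y = factor(G),
                                    fill = factor(score))) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::facet_grid(orientation ~ E_cl / 1e9,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_d(name = "crack score", na.value = "grey80") +
    ggplot2::labs(x = "critical interface strain",
                  y = "strain energy release rate (J/m²)")
}
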