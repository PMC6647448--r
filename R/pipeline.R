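# Orchestration of the three study stages: screening -> response surface ->
# mapping, with CSV artifacts and a reproducible run manifest.

#' Study configuration
#'
#' Collects everything a pipeline stage needs. `mode = "fem"` runs the
#' finite element model for every treatment condition; `mode = "surrogate"`
#' substitutes seeded surrogate responses with known coefficients, which
#' exercises every downstream stage in seconds and is the default for tests.
#'
#' @param out_dir output directory for stage artifacts.
#' @param orientations osteon orientations to analyze.
#' @param mode `"surrogate"` or `"fem"`.
#' @param mesh_level mesh preset for FEM runs.
#' @param seed base RNG seed (surrogate noise; per-outcome seeds derive
#'   from it).
#' @param G_grid,eps_grid mapping-stage grids (J/m^2, dimensionless). The
#'   defaults cover the mapped toughness range 50-400 J/m^2 and interface
#'   strains 1e-5 to 0.0045 on a desk-scale 4 x 4 grid.
#' @param eps_grid_stiffness interface grid for the stiffness variants
#'   (conventionally 0.0005-0.003).
#' @param surrogate named list of `surrogate_spec`s per outcome; `NULL`
#'   selects [default_surrogate_specs()].
#' @param geometry named list of [geometry_params()] overrides applied to
#'   every orientation (e.g. `list(cement_thickness = 4e-6)`).
#' @return object of class `study_config`.
#' @export
study_config <- function(out_dir = tempfile("osteocrack_"),
                         orientations = c("longitudinal", "radial",
                                          "transversal"),
                         mode = c("surrogate", "fem"),
                         mesh_level = "coarse",
                         seed = 1L,
                         G_grid = c(50, 100, 200, 400),
                         eps_grid = c(1e-5, 5e-4, 1.5e-3, 4.5e-3),
                         eps_grid_stiffness = c(5e-4, 1e-3, 2e-3, 3e-3),
                         surrogate = NULL,
                         geometry = list()) {
  mode <- match.arg(mode)
  orientations <- match.arg(orientations, several.ok = TRUE)
  stopifnot(is.list(geometry))
  structure(list(out_dir = out_dir, orientations = orientations, mode = mode,
                 mesh_level = mesh_level, seed = as.integer(seed),
                 G_grid = G_grid, eps_grid = eps_grid,
                 eps_grid_stiffness = eps_grid_stiffness,
                 surrogate = surrogate, geometry = geometry),
            class = "study_config")
}

# geometry for one orientation with config overrides applied
config_geometry <- function(config, orientation) {
  build_geometry(do.call(geometry_params,
                         c(list(orientation = orientation),
                           config$geometry)))
}

#' Default surrogate coefficient sets per outcome
#'
#' Emulates the qualitative response structure the analysis stages expect:
#' maximum force dominated by matrix stiffness and matrix initiation strain,
#' fracture energy by the toughness parameters, crack length and score by
#' the cement-line factors; modest interactions and quadratics on the
#' cement-line terms. Purely synthetic test data with known ground truth.
#'
#' @param factors design factor names.
#' @param seed base seed; per-outcome seeds are offsets of it.
#' @return named list of `surrogate_spec` objects.
#' @export
default_surrogate_specs <- function(factors, seed = 1L) {
  pick <- function(cand, coefs) {
    keep <- intersect(cand, factors)
    stats::setNames(coefs[seq_along(keep)], keep)
  }
  list(
    max_force = surrogate_spec(
      main = pick(c("E_mat", "eps0_mat", "E_ost", "G_mat"),
                  c(10, 8, 2, 1)),
      intercept = 100, seed = seed),
    fracture_energy = surrogate_spec(
      main = pick(c("G_mat", "G_ost", "G_cl", "eps0_cl", "E_cl"),
                  c(10, 5, 4, 3, 2)),
      intercept = 50, seed = seed + 1L),
    crack_length = surrogate_spec(
      main = pick(c("eps0_cl", "E_cl", "epss_cl", "eps_cl", "E_ost"),
                  c(10, 6, 4, 4, 2)),
      quadratic = pick(c("eps0_cl"), 3),
      intercept = 30, seed = seed + 2L),
    crack_score = surrogate_spec(
      main = pick(c("eps0_cl", "E_cl", "epss_cl", "eps_cl", "E_ost"),
                  c(1.2, 0.9, 0.6, 0.6, 0.3)),
      intercept = 3, seed = seed + 3L)
  )
}

# run one FEM treatment condition and return the outcome row; failures are
# skipped (all-NA row) and flagged downstream
run_condition <- function(geom, mesh, mat, load = load_program()) {
  tryCatch({
    sim <- propagate(geom, mat, mesh = mesh, load = load)
    outcomes(sim, score_error = "na")
  }, error = function(e) {
    warning("treatment condition failed: ", conditionMessage(e))
    data.frame(max_force = NA_real_, fracture_energy = NA_real_,
               crack_length = NA_real_, crack_score = NA_integer_)
  })
}

# ANOVA on the complete runs only (failed conditions are dropped from both
# the responses and the design rows); a constant outcome has SS_T = 0 and
# undefined %TSS -- it is flagged as NULL rather than aborting the stage
anova_complete <- function(out, design, terms) {
  lapply(out, function(y) {
    ok <- !is.na(y)
    d <- design
    d$matrix <- design$matrix[ok, , drop = FALSE]
    tryCatch(anova_table(y[ok], d, terms), error = function(e) {
      warning("outcome skipped in ANOVA: ", conditionMessage(e))
      NULL
    })
  })
}

# responses for a design: FEM or surrogate
design_responses <- function(config, design, orientation) {
  outs <- c("max_force", "fracture_energy", "crack_length", "crack_score")
  if (config$mode == "surrogate") {
    specs <- config$surrogate
    if (is.null(specs))
      specs <- default_surrogate_specs(colnames(design$matrix), config$seed)
    Y <- do.call(cbind, lapply(outs, function(o)
      surrogate_response(design, specs[[o]])$y))
    colnames(Y) <- outs
    return(as.data.frame(Y))
  }
  geom <- config_geometry(config, orientation)
  mesh <- generate_mesh(geom, mesh_spec(level = config$mesh_level))
  lvls <- factor_levels(orientation,
                        if (design$design_class == "box_behnken")
                          "box_behnken" else "screening")
  mats <- map_levels(design, lvls, orientation)
  do.call(rbind, lapply(mats, function(mat)
    run_condition(geom, mesh, mat)))
}

# write a manifest with content hashes of all stage artifacts
write_manifest <- function(files, config, path) {
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = config$mode, seed = config$seed,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}

#' Run the screening stage
#'
#' Generates the 32-run resolution IV design over the 14 material
#' parameters, obtains the four outcome parameters for every treatment
#' condition (FEM or surrogate) and per orientation, runs the main-effects
#' ANOVA for each outcome, and writes design/outcome/ANOVA CSVs plus a
#' manifest into `config$out_dir`.
#'
#' @param config a `study_config`.
#' @return invisible list per orientation: `design`, `outcomes`
#'   (data.frame), `anova` (named list of tables).
#' @export
run_screening <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- screening_design()
  files <- character(0)
  result <- list()
  for (ori in config$orientations) {
    out <- design_responses(config, design, ori)
    lvls <- factor_levels(ori, "screening")
    phys <- do.call(rbind, lapply(map_levels(design, lvls, ori), function(p)
      as.data.frame(as.list(p))))
    tab <- cbind(run = seq_len(nrow(out)), phys, out)
    an <- anova_complete(out, design, "main")
    f1 <- file.path(config$out_dir, sprintf("screening_%s_design.csv", ori))
    f2 <- file.path(config$out_dir, sprintf("screening_%s_outcomes.csv", ori))
    f3 <- file.path(config$out_dir, sprintf("screening_%s_anova.csv", ori))
    write_design_csv(design, f1)
    utils::write.csv(tab, f2, row.names = FALSE)
    write_anova_csv(an, f3)
    files <- c(files, f1, f2, f3)
    result[[ori]] <- list(design = design, outcomes = tab, anova = an)
  }
  write_manifest(files, config,
                 file.path(config$out_dir, "screening_manifest.json"))
  invisible(result)
}

#' Run the response-surface stage
#'
#' Box-Behnken design (62 runs) over the 7 important factors, full-quadratic
#' ANOVA per outcome, and a prediction-profile table (fitted mean outcome at
#' each factor's three levels with all other factors at baseline).
#'
#' @param config a `study_config`; orientations conventionally longitudinal
#'   and radial for this stage.
#' @return invisible list per orientation: `design`, `outcomes`, `anova`,
#'   `profile`.
#' @export
run_surface <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- box_behnken_design()
  files <- character(0)
  result <- list()
  for (ori in config$orientations) {
    out <- design_responses(config, design, ori)
    an <- anova_complete(out, design, "quadratic")
    prof <- prediction_profile(out, design)
    f2 <- file.path(config$out_dir, sprintf("surface_%s_outcomes.csv", ori))
    f3 <- file.path(config$out_dir, sprintf("surface_%s_anova.csv", ori))
    f4 <- file.path(config$out_dir, sprintf("surface_%s_profile.csv", ori))
    utils::write.csv(cbind(run = seq_len(nrow(out)), out), f2,
                     row.names = FALSE)
    write_anova_csv(an, f3)
    utils::write.csv(prof, f4, row.names = FALSE)
    files <- c(files, f2, f3, f4)
    result[[ori]] <- list(design = design, outcomes = out, anova = an,
                          profile = prof)
  }
  write_manifest(files, config,
                 file.path(config$out_dir, "surface_manifest.json"))
  invisible(result)
}

#' Prediction profiles from a full-quadratic fit
#'
#' Fits the full quadratic response surface on coded units and predicts each
#' outcome at every factor's three coded levels (-1, 0, +1) with all other
#' factors at their baseline (coded 0) — the response-surface analogue of a
#' one-factor-at-a-time profile.
#'
#' @param out data.frame of outcomes (one column per outcome).
#' @param design a `doe_design` (three-level).
#' @return data.frame: `factor, level, <one column per outcome>`.
#' @export
prediction_profile <- function(out, design) {
  tc <- term_columns(design, "quadratic")
  Xmod <- do.call(cbind, tc$cols)
  fns <- colnames(design$matrix)
  grid <- expand.grid(factor = fns, level = c(-1, 0, 1),
                      stringsAsFactors = FALSE)
  preds <- lapply(out, function(y) {
    fit <- stats::lm.fit(cbind(1, Xmod), y)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    vapply(seq_len(nrow(grid)), function(i) {
      x <- stats::setNames(rep(0, length(fns)), fns)
      x[grid$factor[i]] <- grid$level[i]
      # rebuild the term vector in the same order as Xmod
      tv <- numeric(ncol(Xmod))
      names(tv) <- colnames(Xmod)
      for (nm in names(tc$cols)) {
        if (tc$type[[nm]] == "main") tv[nm] <- x[nm]
        else if (tc$type[[nm]] == "interaction") {
          fs <- strsplit(nm, ":", fixed = TRUE)[[1]]
          tv[nm] <- x[fs[1]] * x[fs[2]]
        } else tv[nm] <- x[sub("\\^2$", "", nm)]^2
      }
      sum(beta * c(1, tv))
    }, numeric(1))
  })
  cbind(grid, as.data.frame(preds))
}

#' Run the mapping stage
#'
#' Crack-score region maps over the (G, interface strain) grid for all
#' configured orientations, plus the cement-line stiffness variants
#' (9.6 / 15 / 18 GPa) for the longitudinal model. Cells already present in
#' an existing map CSV are not recomputed, so an aborted sweep resumes from
#' completed cells. Only meaningful in FEM mode.
#'
#' @param config a `study_config`.
#' @return invisible list with `maps` (per orientation) and `stiffness`.
#' @export
run_mapping <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$mode != "fem")
    stop("the mapping stage runs simulations; use mode = 'fem'")
  spec <- mesh_spec(level = config$mesh_level)
  files <- character(0)
  maps <- list()
  for (ori in config$orientations) {
    f <- file.path(config$out_dir, sprintf("map_%s.csv", ori))
    maps[[ori]] <- resume_sweep(f, ori, config$G_grid, config$eps_grid,
                                E_cl = NULL, spec = spec)
    files <- c(files, f)
  }
  fstiff <- file.path(config$out_dir, "map_longitudinal_stiffness.csv")
  stiff <- do.call(rbind, lapply(c(9.6e9, 15e9, 18e9), function(E)
    resume_sweep(fstiff, "longitudinal", config$G_grid,
                 config$eps_grid_stiffness, E_cl = E, spec = spec)))
  files <- c(files, fstiff)
  write_manifest(files, config,
                 file.path(config$out_dir, "mapping_manifest.json"))
  invisible(list(maps = maps, stiffness = stiff))
}

# sweep with cell-level resume through a CSV cache
resume_sweep <- function(path, orientation, G_grid, eps_grid, E_cl, spec) {
  done <- if (file.exists(path)) utils::read.csv(path) else NULL
  base_Ecl <- if (is.null(E_cl)) material_params(orientation)[["E_cl"]]
  else E_cl
  need <- expand.grid(G = G_grid, eps_cl = eps_grid)
  if (!is.null(done)) {
    have <- done[done$orientation == orientation &
                   abs(done$E_cl - base_Ecl) < 1, ]
    need <- need[!paste(need$G, need$eps_cl) %in%
                   paste(have$G, have$eps_cl), , drop = FALSE]
  }
  new_rows <- NULL
  for (i in seq_len(nrow(need)))
    new_rows <- rbind(new_rows,
                      sweep_scores(orientation, need$G[i], need$eps_cl[i],
                                   E_cl = E_cl, spec = spec))
  all_rows <- rbind(done, new_rows)
  utils::write.csv(all_rows, path, row.names = FALSE)
  sel <- all_rows[all_rows$orientation == orientation &
                    abs(all_rows$E_cl - base_Ecl) < 1 &
                    all_rows$G %in% G_grid & all_rows$eps_cl %in% eps_grid, ]
  class(sel) <- c("region_map", class(sel))
  sel
}

#' Read a study configuration from a YAML file
#'
#' Accepts the fields of [study_config()] as top-level YAML keys; missing
#' keys take the defaults. Unknown keys are an error, so typos do not pass
#' silently. Requires the yaml package.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(study_config, raw)
}
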