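# Experiment design generators: two-level resolution IV fractional factorial
# screening and three-level Box-Behnken response surface designs.

new_doe_design <- function(matrix, class, resolution = NA_integer_,
                           n_center = 0L) {
  structure(list(matrix = matrix, design_class = class,
                 resolution = resolution, n_center = n_center),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("doe_design (%s): %d runs x %d factors%s\n", x$design_class,
              nrow(x$matrix), ncol(x$matrix),
              if (!is.na(x$resolution)) sprintf(", resolution %s", x$resolution)
              else ""))
  invisible(x)
}

#' Two-level resolution IV screening design
#'
#' Builds the smallest standard two-level resolution IV design for up to 15
#' factors by fold-over: factors are assigned to distinct interaction columns
#' of a full 2^4 factorial (16 runs), and the mirrored (sign-reversed) runs
#' are appended. Fold-over guarantees that no main effect is aliased with any
#' two-factor interaction. For the study's 14 factors this gives 32 runs with
#' all columns balanced and mutually orthogonal. The construction is
#' deterministic: same factors, same array.
#'
#' @param factors character vector of factor names (or a count), at most 15.
#' @return a `doe_design` with a coded matrix in \{-1, +1\}.
#' @export
screening_design <- function(factors = factor_names("screening")) {
  if (is.numeric(factors)) factors <- paste0("X", seq_len(factors))
  k <- length(factors)
  if (k < 2) stop("need at least 2 factors")
  if (k > 15) stop("fold-over construction supports at most 15 factors")
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  colnames(base) <- NULL
  subsets <- list(1L, 2L, 3L, 4L,
                  c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L),
                  c(3L, 4L),
                  c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L),
                  c(1L, 2L, 3L, 4L))
  X <- vapply(subsets[seq_len(k)], function(s)
    apply(base[, s, drop = FALSE], 1, prod), numeric(16))
  X <- rbind(X, -X)
  colnames(X) <- factors
  rownames(X) <- NULL
  new_doe_design(X, "fractional_factorial", resolution = 4L)
}

# classical Box-Behnken block systems (balanced incomplete blocks)
bb_blocks <- function(k) {
  switch(as.character(k),
         "3" = list(c(1, 2), c(1, 3), c(2, 3)),
         "4" = list(c(1, 2), c(3, 4), c(1, 4), c(2, 3), c(1, 3), c(2, 4)),
         "5" = list(c(1, 2), c(3, 4), c(2, 5), c(1, 3), c(4, 5),
                    c(2, 3), c(1, 4), c(3, 5), c(1, 5), c(2, 4)),
         "7" = list(c(1, 2, 3), c(1, 4, 5), c(1, 6, 7), c(2, 4, 6),
                    c(2, 5, 7), c(3, 4, 7), c(3, 5, 6)),
         stop("no standard Box-Behnken construction implemented for ",
              k, " factors"))
}

#' Box-Behnken response surface design
#'
#' Standard three-level Box-Behnken construction: balanced incomplete blocks
#' of factors crossed with all +/-1 sign patterns, plus conventional
#' all-zero centre replicates. For 7 factors the blocks are the 7 triples of
#' a Steiner triple system (each factor pair appears exactly once), giving
#' 7 x 2^3 = 56 edge runs and 6 centre runs: 62 treatment conditions; every
#' non-centre run has exactly 3 factors at +/-1 and 4 at 0.
#'
#' @param factors character vector of factor names (or a count); supported
#'   sizes 3, 4, 5 and 7.
#' @param n_center number of centre replicates; `NULL` selects the
#'   conventional count (3 for 3-4 factors, 6 for 5 and 7).
#' @return a `doe_design` with a coded matrix in \{-1, 0, +1\}.
#' @export
box_behnken_design <- function(factors = factor_names("box_behnken"),
                               n_center = NULL) {
  if (is.numeric(factors)) factors <- paste0("X", seq_len(factors))
  k <- length(factors)
  if (k < 3) stop("Box-Behnken designs need at least 3 factors")
  blocks <- bb_blocks(k)
  if (is.null(n_center)) n_center <- if (k <= 4) 3L else 6L
  rows <- lapply(blocks, function(b) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(b))))
    X <- matrix(0, nrow(signs), k)
    X[, b] <- as.matrix(signs)
    X
  })
  X <- do.call(rbind, rows)
  X <- rbind(X, matrix(0, n_center, k))
  colnames(X) <- factors
  rownames(X) <- NULL
  new_doe_design(X, "box_behnken", n_center = as.integer(n_center))
}

#' Write / read a coded design as CSV
#'
#' Coded matrices are integer-valued, so the round trip is bit-identical.
#'
#' @param design a `doe_design`.
#' @param path file path.
#' @return `path` invisibly; `read_design_csv` returns a `doe_design`.
#' @export
write_design_csv <- function(design, path) {
  df <- as.data.frame(design$matrix)
  df <- cbind(run = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param design_class design class to stamp on the object read back.
#' @export
read_design_csv <- function(path, design_class = "fractional_factorial") {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, setdiff(names(df), "run"), drop = FALSE])
  storage.mode(X) <- "double"
  new_doe_design(X, design_class)
}
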