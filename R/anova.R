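# Variance-based sensitivity analysis: per-factor sums of squares and %TSS,
# the factor-importance measure of the parameter study.

#' Total sum of squares about the mean
#'
#' `SS_T = sum_i (y_i - ybar)^2` over the N treatment conditions.
#'
#' @param y numeric response vector (one outcome value per run), N >= 2.
#' @return `SS_T`.
#' @export
total_ss <- function(y) {
  stopifnot(length(y) >= 2)
  sum((y - mean(y))^2)
}

#' Factor sum of squares from level means
#'
#' `SS_F = sum_{i=1}^{n} N_{F,i} (ybar_{F,i} - ybar)^2`, where `n` is the
#' number of levels of the factor column, `N_{F,i}` the number of runs at
#' level i and `ybar_{F,i}` the mean outcome at that level. Applied to a
#' coded main-effect column this is the classical one-way decomposition; the
#' same formula applied to a product or squared coded column gives the
#' interaction or quadratic contribution.
#'
#' @param y numeric response vector.
#' @param column coded design column (same length), any number of levels.
#' @return `SS_F`.
#' @export
factor_ss <- function(y, column) {
  stopifnot(length(y) == length(column))
  ybar <- mean(y)
  lv <- unique(column)
  sum(vapply(lv, function(l) {
    idx <- column == l
    sum(idx) * (mean(y[idx]) - ybar)^2
  }, numeric(1)))
}

#' Percent of total sum of squares
#'
#' `%TSS = 100 * SS_F / SS_T`: the contribution of a factor to the response
#' variance, used as the importance measure of each material parameter.
#'
#' @param ss_f factor sum of squares.
#' @param ss_t total sum of squares, > 0.
#' @return percentage in [0, 100] for nested decompositions.
#' @export
percent_tss <- function(ss_f, ss_t) {
  if (ss_t <= 0) stop("%TSS undefined: total sum of squares is zero")
  100 * ss_f / ss_t
}

# build the coded term columns of a term set
term_columns <- function(design, terms = c("main", "quadratic")) {
  terms <- match.arg(terms)
  X <- design$matrix
  fns <- colnames(X)
  cols <- lapply(fns, function(f) X[, f])
  names(cols) <- fns
  type <- stats::setNames(rep("main", length(fns)), fns)
  if (terms == "quadratic") {
    for (i in seq_along(fns)) for (j in seq_along(fns)) {
      if (i < j) {
        nm <- paste0(fns[i], ":", fns[j])
        cols[[nm]] <- X[, i] * X[, j]
        type[nm] <- "interaction"
      }
    }
    for (f in fns) {
      nm <- paste0(f, "^2")
      cols[[nm]] <- X[, f]^2
      type[nm] <- "quadratic"
    }
  }
  list(cols = cols, type = type)
}

#' ANOVA table with %TSS and significance
#'
#' Computes, for every term of the chosen term set, the level-mean sum of
#' squares [factor_ss()], its share of the total [percent_tss()], and an F
#' test against the residual of the fitted model. Term sets: `"main"` (the
#' screening analysis: one term per factor; on the 32-run design the
#' residual has 32 - 1 - 14 = 17 degrees of freedom) and `"quadratic"` (the
#' response-surface analysis: main effects, all pairwise interactions and
#' squared terms, with product/squared coded columns entering the same
#' level-mean formula). The residual sum of squares is `SS_T` minus the
#' least-squares model sum of squares of the corresponding
#' linear/full-quadratic regression, with `df_res = N - 1 - p` for `p`
#' regression columns.
#'
#' @param y numeric response vector (one value per design run).
#' @param design a `doe_design`.
#' @param terms `"main"` or `"quadratic"`.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with columns `term, type, df, ss, pct_tss, F, p,
#'   significant`; attributes `ss_total`, `ss_residual`, `df_residual`.
#' @export
anova_table <- function(y, design, terms = c("main", "quadratic"),
                        alpha = 0.05) {
  terms <- match.arg(terms)
  stopifnot(inherits(design, "doe_design"))
  N <- nrow(design$matrix)
  stopifnot(length(y) == N)
  ss_t <- total_ss(y)
  if (ss_t == 0) stop("constant responses: ANOVA undefined (SS_T = 0)")
  tc <- term_columns(design, terms)
  Xmod <- do.call(cbind, tc$cols)
  qrX <- qr(cbind(1, Xmod))
  p <- qrX$rank - 1L
  df_res <- N - 1L - p
  if (df_res <= 0) stop("no residual degrees of freedom")
  fitted <- qr.fitted(qrX, y)
  ss_model <- sum((fitted - mean(y))^2)
  ss_res <- ss_t - ss_model
  out <- do.call(rbind, lapply(names(tc$cols), function(nm) {
    col <- tc$cols[[nm]]
    ss <- factor_ss(y, col)
    df <- length(unique(col)) - 1L
    Fv <- (ss / df) / (ss_res / df_res)
    pv <- stats::pf(Fv, df, df_res, lower.tail = FALSE)
    data.frame(term = nm, type = tc$type[[nm]], df = df, ss = ss,
               pct_tss = percent_tss(ss, ss_t), F = Fv, p = pv,
               significant = pv < alpha)
  }))
  rownames(out) <- NULL
  attr(out, "ss_total") <- ss_t
  attr(out, "ss_residual") <- ss_res
  attr(out, "df_residual") <- df_res
  out
}

#' Write an ANOVA table (per-outcome %TSS with significance stars) to CSV
#'
#' Lays out one column pair per outcome, mirroring the published importance
#' tables: `%TSS` and a star for `p < 0.05`.
#'
#' @param tables named list of [anova_table()] results (one per outcome).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(tables, path) {
  tables <- Filter(Negate(is.null), tables)
  if (!length(tables)) {
    utils::write.csv(data.frame(term = character(0)), path, row.names = FALSE)
    return(invisible(path))
  }
  terms <- tables[[1]]$term
  df <- data.frame(term = terms)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    stopifnot(identical(tb$term, terms))
    df[[paste0(nm, "_pct_tss")]] <- round(tb$pct_tss, 1)
    df[[paste0(nm, "_sig")]] <- ifelse(tb$significant, "*", "")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
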