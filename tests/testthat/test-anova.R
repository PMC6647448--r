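test_that("total and factor sums of squares match hand computations", {
  expect_equal(total_ss(c(0, 2)), 2)
  expect_equal(total_ss(rep(3, 5)), 0)
  expect_equal(total_ss(c(-3, 1, -1, 3)), 20)  # 9 + 1 + 1 + 9

  # full 2^2 factorial with y = x1 + 2 x2: level means +/-1 and +/-2
  X <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1)))
  y <- X[, 1] + 2 * X[, 2]
  expect_equal(factor_ss(y, X[, 1]), 4)
  expect_equal(factor_ss(y, X[, 2]), 16)
  expect_equal(total_ss(y), 20)
  expect_equal(percent_tss(factor_ss(y, X[, 1]), total_ss(y)), 20)
  expect_equal(percent_tss(factor_ss(y, X[, 2]), total_ss(y)), 80)

  # no-effect factor on a balanced design
  expect_equal(factor_ss(y, c(1, 1, -1, -1) * c(1, -1, 1, -1)), 0)
  # saturated single-factor case: SS_F = SS_T
  expect_equal(factor_ss(c(0, 0, 2, 2), c(-1, -1, 1, 1)), 4)
  expect_equal(percent_tss(100, 100), 100)
  expect_equal(percent_tss(0, 5), 0)
  expect_error(percent_tss(1, 0), "undefined")
})

test_that("factor_ss equals the regression sum of squares on balanced
           two-level designs", {
  d <- screening_design()
  X <- d$matrix
  set.seed(99)
  for (rep in 1:50) {
    y <- rnorm(32)
    f <- sample(colnames(X), 1)
    ssr <- sum((stats::fitted(stats::lm(y ~ X[, f])) - mean(y))^2)
    expect_equal(factor_ss(y, X[, f]), ssr, tolerance = 1e-9)
  }
})

test_that("%TSS is invariant to affine response transformations", {
  d <- screening_design()
  set.seed(3)
  y <- rnorm(32)
  t1 <- anova_table(y, d, "main")
  t2 <- anova_table(5 - 3.2 * y, d, "main")
  expect_equal(t1$pct_tss, t2$pct_tss, tolerance = 1e-9)
  expect_equal(t1$p, t2$p, tolerance = 1e-9)
})

test_that("screening ANOVA: 14 terms, df 17 residual, exact decomposition", {
  d <- screening_design()
  spec <- surrogate_spec(main = c(E_mat = 2, G_cl = 1), sigma = 0.5, seed = 8)
  y <- surrogate_response(d, spec)$y
  tab <- anova_table(y, d, "main")
  expect_equal(nrow(tab), 14)
  expect_equal(attr(tab, "df_residual"), 17)
  # orthogonal decomposition: sum of term SS + residual = SS_T
  expect_equal(sum(tab$ss) + attr(tab, "ss_residual"), attr(tab, "ss_total"),
               tolerance = 1e-9)
  expect_true(all(tab$ss >= 0))
})

test_that("a planted dominant effect is detected with top %TSS", {
  d <- screening_design()
  spec <- surrogate_spec(main = c(eps0_cl = 10), sigma = 1, seed = 21)
  y <- surrogate_response(d, spec)$y
  tab <- anova_table(y, d, "main")
  expect_equal(tab$term[which.max(tab$pct_tss)], "eps0_cl")
  expect_lt(tab$p[tab$term == "eps0_cl"], 1e-6)
})

test_that("exactly linear noiseless response gives 100% to its factor", {
  d <- screening_design()
  y <- 3 * d$matrix[, "G_mat"]
  tab <- anova_table(y, d, "main")
  expect_equal(tab$pct_tss[tab$term == "G_mat"], 100, tolerance = 1e-12)
  expect_equal(sum(tab$pct_tss) - 100, 0, tolerance = 1e-9)
})

test_that("null responses produce the nominal false-positive rate", {
  d <- screening_design()
  set.seed(2024)
  hits <- 0; total <- 0
  for (rep in 1:500) {
    y <- rnorm(32)
    tab <- anova_table(y, d, "main")
    hits <- hits + sum(tab$p < 0.05)
    total <- total + nrow(tab)
  }
  # binomial 99% band around 0.05
  phat <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(phat - 0.05), 2.6 * se)
})

test_that("full-quadratic term set covers interactions and squares on the
           Box-Behnken design", {
  d <- box_behnken_design()
  spec <- surrogate_spec(main = c(E_cl = 4), interaction = c("E_ost:E_cl" = 2),
                         quadratic = c("G_mat^2" = 3), sigma = 0.1, seed = 5)
  y <- surrogate_response(d, spec)$y
  tab <- anova_table(y, d, "quadratic")
  expect_equal(nrow(tab), 7 + choose(7, 2) + 7)
  expect_equal(attr(tab, "df_residual"), 62 - 1 - 35)
  expect_true(tab$significant[tab$term == "E_cl"])
  expect_true(tab$significant[tab$term == "E_ost:E_cl"])
  expect_true(tab$significant[tab$term == "G_mat^2"])
  # planted terms dominate the %TSS ranking; the three-level G_mat main
  # column legitimately absorbs its own quadratic contrast, so it ranks too
  top5 <- tab$term[order(-tab$pct_tss)][1:5]
  expect_true(all(c("E_cl", "E_ost:E_cl", "G_mat^2") %in% top5))
  # unplanted terms stay quiet
  expect_lt(tab$pct_tss[tab$term == "eps_cl"], 5)
})

test_that("degenerate inputs error clearly", {
  d <- screening_design()
  expect_error(anova_table(rep(1, 32), d), "constant")
  expect_error(anova_table(rnorm(10), d), "length")
})
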