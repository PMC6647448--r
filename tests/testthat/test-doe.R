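test_that("screening design: 32 runs, balance, orthogonality, resolution IV", {
  d <- screening_design()
  X <- d$matrix
  expect_equal(dim(X), c(32L, 14L))
  expect_equal(d$design_class, "fractional_factorial")
  expect_equal(d$resolution, 4L)
  expect_true(all(X %in% c(-1, 1)))
  # every column balanced: 16 runs at each level
  expect_true(all(colSums(X == 1) == 16))
  # main-effect columns mutually orthogonal: X'X = 32 I
  expect_equal(unname(crossprod(X)), diag(32, 14))
  # resolution IV: every main effect orthogonal to every 2-factor interaction
  for (i in 1:14) for (a in 1:13) for (b in (a + 1):14)
    expect_identical(sum(X[, i] * X[, a] * X[, b]), 0)
})

test_that("screening design is deterministic and respects capacity", {
  expect_identical(screening_design()$matrix, screening_design()$matrix)
  expect_equal(nrow(screening_design(8)$matrix), 32)
  expect_error(screening_design(16), "at most 15")
})

test_that("Box-Behnken design: 62 runs, block structure, symmetry", {
  d <- box_behnken_design()
  X <- d$matrix
  expect_equal(dim(X), c(62L, 7L))
  expect_equal(d$design_class, "box_behnken")
  nz <- rowSums(X != 0)
  expect_equal(sum(nz == 0), 6)          # centre replicates
  expect_true(all(nz[nz != 0] == 3))     # 3 factors at +/-1, 4 at 0
  expect_equal(colMeans(X), stats::setNames(rep(0, 7), colnames(X)))
  # each factor pair appears together in exactly one block:
  # sum over runs of x_i^2 x_j^2 = 8 for all pairs
  for (i in 1:6) for (j in (i + 1):7)
    expect_equal(sum(X[, i]^2 * X[, j]^2), 8)
  expect_error(box_behnken_design(6), "no standard")
})

test_that("level mapping reproduces the +/-20% factor table exactly", {
  lv <- factor_levels("longitudinal", "screening")
  expect_equal(lv$baseline[lv$factor == "E_mat"], 15e9)
  expect_equal(lv$low[lv$factor == "E_mat"], 12e9)
  expect_equal(lv$high[lv$factor == "E_mat"], 18e9)
  expect_equal(lv$high[lv$factor == "E_ost"], 14.4e9)
  expect_equal(lv$high[lv$factor == "epsn_cl"], 0.00126)
  expect_equal(lv$low[lv$factor == "epsn_cl"], 0.00084)
  expect_equal(factor_levels("radial")$high[10], 0.0018)
  expect_equal(factor_levels("transversal")$baseline[11], 0.0035)
  expect_equal(factor_levels("transversal")$high[11], 0.0042)

  d <- screening_design()
  mats <- map_levels(d, lv, "longitudinal")
  expect_length(mats, 32)
  i <- which(d$matrix[, "E_mat"] == 1)[1]
  expect_equal(mats[[i]][["E_mat"]], 18e9)
  j <- which(d$matrix[, "epsn_cl"] == -1)[1]
  expect_equal(mats[[j]][["epsn_cl"]], 0.00084)

  # Box-Behnken: combined eps_cl factor writes both interface strains;
  # coded 0 is the baseline
  bb <- box_behnken_design()
  lv2 <- factor_levels("longitudinal", "box_behnken")
  mats2 <- map_levels(bb, lv2, "longitudinal")
  k <- which(bb$matrix[, "eps_cl"] == 1)[1]
  expect_equal(mats2[[k]][["epsn_cl"]], 0.00126)
  expect_equal(mats2[[k]][["epss_cl"]], 0.00126)
  ctr <- which(rowSums(bb$matrix != 0) == 0)[1]
  expect_equal(mats2[[ctr]], material_params("longitudinal"))
})

test_that("level mapping is invertible and the CSV round trip is exact", {
  d <- screening_design()
  lv <- factor_levels("radial")
  mats <- map_levels(d, lv, "radial")
  decoded <- t(vapply(mats, function(p)
    vapply(lv$factor, function(f)
      (p[[f]] - lv$baseline[lv$factor == f]) /
        (0.2 * lv$baseline[lv$factor == f]), numeric(1)),
    numeric(14)))
  expect_equal(unname(decoded), unname(d$matrix), tolerance = 1e-9)

  f <- tempfile(fileext = ".csv")
  write_design_csv(d, f)
  d2 <- read_design_csv(f)
  expect_identical(unname(d2$matrix), unname(d$matrix))
  expect_identical(colnames(d2$matrix), colnames(d$matrix))
  unlink(f)
})
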