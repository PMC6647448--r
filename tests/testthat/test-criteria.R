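test_that("MAXPE criterion: threshold, ratio, compression cut-off", {
  expect_equal(f_maxpe(0.004, 0.004), 1)
  expect_equal(f_maxpe(0.0048, 0.004), 1.2)
  expect_equal(f_maxpe(-0.002, 0.004), 0)   # positive part: no compressive initiation
  expect_equal(f_maxpe(c(0.004, -1), 0.004), c(1, 0))
})

test_that("QUADE criterion: pure modes, mixed mode, compression", {
  expect_equal(f_quade(0.00105, 0, 0.00105, 0.00105), 1)
  expect_equal(f_quade(0, 0.00105, 0.00105, 0.00105), 1)
  expect_equal(f_quade(0, -0.00105, 0.00105, 0.00105), 1)  # shear sign-free
  expect_equal(f_quade(-0.01, 0, 0.00105, 0.00105), 0)
  # mixed-mode worked example: (0.0006/0.00105)^2 + (0.0009/0.00105)^2
  expect_equal(f_quade(0.0006, 0.0009, 0.00105, 0.00105),
               (0.0006 / 0.00105)^2 + (0.0009 / 0.00105)^2)
  expect_equal(f_quade(0.0006, 0.0009, 0.00105, 0.00105), 1.061224,
               tolerance = 1e-6)
})

test_that("3D QUADE adds the second shear and reduces to 2D", {
  expect_equal(f_quade_3d(0.002, 0, 0, 0.002, 0.001, 0.003), 1)
  expect_equal(f_quade_3d(0, 0.001 / sqrt(2), 0.003 / sqrt(2),
                          0.002, 0.001, 0.003), 1)
  # eps_t = 0 reduces exactly to the 2D criterion over a strain sweep
  en <- seq(-0.002, 0.004, length.out = 13)
  es <- seq(-0.003, 0.003, length.out = 13)
  expect_equal(f_quade_3d(en, es, 0, 0.0015, 0.002, 0.01),
               f_quade(en, es, 0.0015, 0.002))
})

test_that("initiation check applies the phase rule and first-crossing
           competition", {
  mat <- material_params("longitudinal")
  st <- function(eps1, dir1 = c(0, 1), eps_n = NA, eps_s = NA,
                 normal = c(1, 0))
    list(eps1 = eps1, dir1 = dir1, eps_n = eps_n, eps_s = eps_s,
         normal = normal)

  # bulk phases: MAXPE only
  expect_null(initiation_check(st(0.9 * 0.004), "matrix", mat))
  chk <- initiation_check(st(1.2 * 0.004), "osteon", mat)
  expect_equal(chk$criterion, "MAXPE")
  expect_equal(chk$f, 1.2)
  expect_equal(chk$normal, c(0, 1))

  # cement line: QUADE wins at baseline interface strains
  chk <- initiation_check(st(0.0042, eps_n = 0.0040, eps_s = 0), "cement_line",
                          mat)
  expect_equal(chk$criterion, "QUADE")
  expect_equal(chk$normal, c(1, 0))

  # strong interface: MAXPE crosses first even though f_QUADE is larger
  mat2 <- mat
  mat2[c("epsn_cl", "epss_cl")] <- 0.0045
  chk <- initiation_check(st(0.006, eps_n = 0.006, eps_s = 0), "cement_line",
                          mat2)
  expect_equal(f_quade(0.006, 0, 0.0045, 0.0045), (0.006 / 0.0045)^2)
  expect_gt(f_quade(0.006, 0, 0.0045, 0.0045), f_maxpe(0.006, 0.004))
  expect_equal(chk$criterion, "MAXPE")

  # exact tie in crossing load goes to MAXPE (penetration)
  mat3 <- mat
  mat3[c("epsn_cl", "epss_cl")] <- 0.004
  chk <- initiation_check(st(0.008, eps_n = 0.008, eps_s = 0), "cement_line",
                          mat3)
  expect_equal(chk$criterion, "MAXPE")

  # below both thresholds: no initiation
  expect_null(initiation_check(st(0.003, eps_n = 0.0005, eps_s = 0),
                               "cement_line", mat))
})

test_that("cohesive law: linear softening, secant unloading, energy", {
  T0 <- 60e6; G <- 200
  law0 <- cohesive_traction(0, T0, G)
  expect_equal(law0$traction, T0)
  expect_equal(law0$damage, 0)
  expect_equal(law0$delta_f, 2 * G / T0)
  expect_equal(law0$delta_f, 6.666667e-6, tolerance = 1e-6)

  lawf <- cohesive_traction(2 * G / T0, T0, G)
  expect_equal(lawf$traction, 0)
  expect_equal(lawf$damage, 1)
  expect_equal(lawf$dissipated, G)   # triangle area = G exactly

  # half-way softening then unload to 40%: secant through the origin
  dh <- G / T0                       # = delta_f / 2
  env <- cohesive_traction(dh, T0, G)
  expect_equal(env$traction, T0 / 2)
  expect_equal(env$damage, 0.5)
  un <- cohesive_traction(0.4 * dh, T0, G, delta_hist = dh)
  expect_equal(un$traction, 0.4 * env$traction)
  expect_equal(un$damage, 0.5)       # irreversible
  expect_equal(un$dissipated, env$dissipated)

  # regularized bilinear variant keeps the fracture energy exact
  d0 <- 0.01 * 2 * G / T0
  lawr <- cohesive_traction(2 * G / T0, T0, G, delta0 = d0)
  expect_equal(lawr$dissipated, G, tolerance = 1e-12)
  expect_equal(cohesive_traction(d0, T0, G, delta0 = d0)$traction, T0)
})
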