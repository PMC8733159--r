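# Passive energies, membrane reduction, activation driver.

test_that("green strain handles identity, simple shear, and stays symmetric", {
  s <- green_strain(diag(3))
  expect_equal(max(abs(s$E)), 0)
  expect_equal(s$J, 1)
  # simple shear F12 = 0.2: E12 = E21 = 0.1, E22 = 0.02
  F <- diag(3); F[1, 2] <- 0.2
  s <- green_strain(F)
  expect_equal(s$E[1, 2], 0.1)
  expect_equal(s$E[2, 1], 0.1)
  expect_equal(s$E[2, 2], 0.02)
  expect_equal(s$E[1, 1], 0)
  # symmetry property over random deformations with positive det
  set.seed(5)
  for (i in 1:25) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.15), 3, 3)
    if (det(F) <= 0) next
    E <- green_strain(F)$E
    expect_lt(max(abs(E - t(E))), 1e-12)
  }
  expect_error(green_strain(diag(c(-1, 1, 1))), "determinant")
})

test_that("strain energies reproduce hand-evaluated cases", {
  # reference state: both laws vanish
  ref <- green_strain(diag(3))
  expect_equal(guccione_energy(ref), 0, ignore_attr = TRUE)
  expect_equal(neo_hooke_energy(ref), 0)
  # pure fiber strain with the ventricular parameter row
  E <- matrix(0, 3, 3); E[1, 1] <- 0.1
  W <- guccione_energy(list(E = E, J = 1))
  expect_equal(as.numeric(W), 278 / 2 * (exp(12 * 0.01) - 1),
               tolerance = 1e-12)
  expect_equal(as.numeric(W), 17.72, tolerance = 1e-3)
  # pure volumetric penalty
  Wv <- guccione_energy(list(E = matrix(0, 3, 3), J = 1.01),
                        material_presets("ventricle"))
  expect_equal(as.numeric(Wv), 200e3 / 2 * 0.01^2)  # 10 Pa
  # incompressible uniaxial Neo-Hooke with the atrial stiffness
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  Wnh <- neo_hooke_energy(green_strain(F))
  expect_equal(Wnh, 7450 / 2 * (lam^2 + 2 / lam - 3), tolerance = 1e-10)
  expect_equal(Wnh, 104.9, tolerance = 1e-3)
})

test_that("neo-hooke energy is non-negative for isochoric deformations", {
  set.seed(7)
  for (i in 1:200) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(F) <= 0.1) next
    F <- F / det(F)^(1 / 3)          # isochoric
    expect_gte(neo_hooke_energy(green_strain(F)), -1e-12)
  }
})

test_that("table parameter presets carry the published rows", {
  v <- material_presets("ventricle")
  expect_equal(v[c("C", "b_f", "b_t", "b_ft", "K", "rho0")],
               list(C = 278, b_f = 12.0, b_t = 4.8, b_ft = 8.4,
                    K = 200e3, rho0 = 1082))
  expect_equal(material_presets("atrium")$C, 7450)
  expect_equal(material_presets("valve_plane")$C, 200000)
  expect_equal(material_presets("fat")$K, 1000e3)
})

test_that("membrane tension is zero at reference and matches a finite
          difference of the energy", {
  expect_identical(membrane_tension(1), 0)
  p <- material_presets("ventricle")
  h0 <- 0.01
  W_of_lambda <- function(l) {
    E <- matrix(0, 3, 3)
    E[1, 1] <- (l^2 - 1) / 2
    E[3, 3] <- (l^-2 - 1) / 2
    as.numeric(guccione_energy(list(E = E, J = 1), p))
  }
  for (lam in seq(0.8, 1.4, by = 0.05)) {
    h <- 1e-6
    fd <- h0 * lam * (W_of_lambda(lam + h) - W_of_lambda(lam - h)) / (2 * h)
    Tn <- membrane_tension(lam, p, h0)
    expect_equal(Tn, fd, tolerance = 1e-5)
  }
  # strictly increasing on the physiological stretch range
  Tvals <- membrane_tension(seq(1, 1.3, by = 0.01), p, h0)
  expect_true(all(diff(Tvals) > 0))
  expect_error(membrane_tension(-0.1), "positive")
})

test_that("double-Hill activation is periodic, zero at onset, and its peak
          matches a dense grid search", {
  p <- activation_params()
  expect_equal(p$T_cycle, 1.247)
  t <- c(0.2, 0.5, 0.9)
  expect_equal(active_tension(t, p), active_tension(t + 1.247, p),
               tolerance = 1e-10)
  expect_identical(active_tension(p$t_onset, p), 0)
  # dense-grid oracle for the peak of g1 * g2
  tau <- seq(0, 1, length.out = 10001)[-10001]
  g1 <- (tau / p$alpha1)^p$n1; g1 <- g1 / (1 + g1)
  g2 <- 1 / (1 + (tau / p$alpha2)^p$n2)
  tt <- p$t_onset + tau * p$T_cycle
  a <- active_tension(tt, p)
  expect_equal(max(a), p$T_peak * max(g1 * g2), tolerance = 1e-12)
  expect_equal(tt[which.max(a)], tt[which.max(g1 * g2)])
})
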