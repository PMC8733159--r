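# Pressure-factor machinery and the identity behavior of the loop.

test_that("chamber statistics are exact and order-invariant", {
  pw <- list(times = c(0, 1), p = rbind(c(10e3, 10e3, 10e3, 10e3),
                                        c(1e3, 2e3, 3e3, 6e3)))
  st <- chamber_stats(pw)
  expect_equal(st$p_min, c(10e3, 1e3))
  expect_equal(st$p_max, c(10e3, 6e3))
  expect_equal(st$p_mean, c(10e3, 3e3))
  perm <- list(times = pw$times, p = pw$p[, c(3, 1, 4, 2)])
  st2 <- chamber_stats(perm)
  expect_equal(st2$p_min, st$p_min)
  expect_equal(st2$p_max, st$p_max)
  expect_equal(st2$p_mean, st$p_mean)
  expect_error(chamber_stats(pw, integer(0)), "empty")
})

test_that("scaling factor follows its definition and the clip", {
  expect_equal(scaling_factor(list(p_max = 10e3, p_mean = 10e3)), 0)
  expect_equal(scaling_factor(list(p_max = 2e3, p_mean = 1e3)), 1)
  # degenerate inputs: clipped to +/- 3, zero maximum maps to zero
  expect_equal(scaling_factor(list(p_max = 0.1, p_mean = -10e3)), 3)
  expect_equal(scaling_factor(list(p_max = -0.1, p_mean = -10e3)), -3)
  expect_equal(scaling_factor(list(p_max = 0, p_mean = 5e3)), 0)
})

test_that("pressure factor is mean-free, bounded for unit scaling, and
          handles uniform fields", {
  # hand case: p = {0, 1, 2} kPa with y_s = 1: x at the maximum is 1.5
  pw <- list(times = 0, p = matrix(c(0, 1e3, 2e3), 1))
  pf <- pressure_factor(pw, y_s = 1)
  expect_equal(pf$x[1, 3], 1.5)
  expect_equal(rowMeans(pf$x), 1)
  # uniform field: x identically one with a notice
  pwu <- list(times = c(0, 1), p = matrix(5e3, 2, 8))
  expect_message(pfu <- pressure_factor(pwu), "uniform")
  expect_true(all(pfu$x == 1))
  # random fields: normalization to 1e-12, and x in [0, 2] at y_s = 1
  set.seed(31)
  for (i in 1:20) {
    p <- matrix(rnorm(40 * 25, 1e4, 3e3), 40, 25)
    pf <- pressure_factor(list(times = seq_len(40), p = p))
    expect_lt(max(abs(rowMeans(pf$x) - 1)), 1e-12)
    pf1 <- pressure_factor(list(times = seq_len(40), p = p),
                           y_s = rep(1, 40))
    expect_true(all(pf1$x >= 0 & pf1$x <= 2))
  }
})

test_that("adapted pressure is the factor times the chamber pressure and
          preserves the spatial mean", {
  expect_equal(adapted_pressure(10e3, 1), 10e3)
  expect_equal(adapted_pressure(10e3, 1.2), 12e3)
  set.seed(13)
  p <- matrix(rnorm(10 * 64, 8e3, 2e3), 10, 64)
  pf <- pressure_factor(list(times = 1:10, p = p))
  ps <- adapted_pressure(9500, pf$x)
  expect_lt(max(abs(rowMeans(ps) - 9500)), 1e-9 * 9500)
})

test_that("phase alignment interpolates periodically and exactly at nodes", {
  times <- seq(0, 1.2, by = 0.3)
  x <- matrix(as.numeric(seq_len(5 * 3)), 5, 3)
  pf <- structure(list(times = times, x = x), class = "pressure_factor_field")
  Tc <- 1.5
  # stored time: exact row
  expect_identical(phase_align(pf, 0.6, Tc), x[3, ])
  # periodicity
  expect_equal(phase_align(pf, 0.6 + Tc, Tc), x[3, ])
  expect_equal(phase_align(pf, 0.6 + 5 * Tc, Tc), x[3, ])
  # midpoint between two samples: arithmetic mean
  expect_equal(phase_align(pf, 0.45, Tc), (x[2, ] + x[3, ]) / 2)
  # wrap segment between the last and first sample
  expect_equal(phase_align(pf, 1.35, Tc), (x[5, ] + x[1, ]) / 2)
  expect_error(phase_align(list(times = numeric(0), x = x), 1, Tc),
               "empty")
})

test_that("wall-pressure smoothing preserves the mean and uniform fields", {
  pw <- make_synthetic_pressure_field(32, n_times = 100, seed = 4)
  sm <- smooth_wall_pressure(pw, 0.125)
  expect_equal(mean(sm$p), mean(pw$p), tolerance = 1e-12)
  expect_lt(max(abs(diff(sm$p[, 1]))), max(abs(diff(pw$p[, 1]))))
  pwu <- list(times = pw$times, p = matrix(3e3, 100, 5))
  expect_equal(smooth_wall_pressure(pwu, 0.1)$p, pwu$p)
})

test_that("a uniform-pressure fluid stage makes iteration one the fixed
          point of the coupling loop", {
  cfg <- default_config()
  cfg$coupling$n_mech_cycles <- 3   # identity holds for any cycle count
  stub <- function(mech, geom, cfg2) {
    list(wall_pressure = structure(
      list(times = mech$times,
           p = matrix(8e3, length(mech$times), geom$n_seg)),
      class = "wall_pressure_field"))
  }
  rep <- suppressMessages(
    run_coupled(cfg, fluid_backend = stub, quiet = TRUE))
  expect_true(rep$converged)
  expect_identical(rep$n_iterations, 1L)
  expect_equal(unname(rep$ed[1, "max"]), 0)
  expect_identical(rep$mech_results[[1]]$node_x,
                   rep$mech_results[[2]]$node_x)
  expect_true(all(rep$pressure_factors[[1]]$x == 1))
})
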