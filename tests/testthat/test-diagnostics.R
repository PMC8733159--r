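# Euclidean-distance fields, quantile bands, PV loops.

mech_stub <- function(node_x, node_y, times = seq_len(nrow(node_x)),
                      V = NULL, p = NULL) {
  nt <- length(times)
  structure(list(times = times, node_x = node_x, node_y = node_y,
                 p_chamber = if (is.null(p)) rep(1e3, nt) else p,
                 V = if (is.null(V)) rep(1e-4, nt) else V,
                 cycle_index = rep(1L, nt), T_cycle = 1.247),
            class = "mech_result")
}

test_that("euclidean distance is zero on identity, exact on a 3-4-5
          displacement, and matches a brute-force oracle", {
  set.seed(17)
  nx <- matrix(rnorm(20 * 8, sd = 1e-3), 20, 8)
  ny <- matrix(rnorm(20 * 8, sd = 1e-3), 20, 8)
  a <- mech_stub(nx, ny)
  expect_true(all(euclidean_distance(a, a)$d == 0))
  b <- mech_stub(nx, ny)
  b$node_x[5, 3] <- b$node_x[5, 3] + 3e-3
  b$node_y[5, 3] <- b$node_y[5, 3] + 4e-3
  ed <- euclidean_distance(a, b)
  expect_equal(ed$d[5, 3], 5)        # mm
  expect_equal(unname(ed$summary["max"]), 5)
  # brute-force recomputation over random displacements
  b2 <- mech_stub(nx + matrix(rnorm(160, sd = 1e-4), 20, 8),
                  ny + matrix(rnorm(160, sd = 1e-4), 20, 8))
  ed2 <- euclidean_distance(a, b2)
  oracle <- matrix(0, 20, 8)
  for (i in 1:20) for (j in 1:8) {
    oracle[i, j] <- sqrt((a$node_x[i, j] - b2$node_x[i, j])^2 +
                           (a$node_y[i, j] - b2$node_y[i, j])^2) * 1e3
  }
  expect_equal(ed2$d, oracle)
  # symmetry
  expect_equal(euclidean_distance(b2, a)$d, ed2$d)
  # mismatched grids are a comparison error
  cshort <- mech_stub(nx[, 1:5], ny[, 1:5])
  expect_error(euclidean_distance(a, cshort), "mismatch")
})

test_that("grouped distance summaries reproduce the table layout", {
  nx <- matrix(0, 4, 6); ny <- matrix(0, 4, 6)
  a <- mech_stub(nx, ny)
  b <- mech_stub(nx, ny)
  b$node_x[2, 5] <- 2.07e-3
  ed <- euclidean_distance(a, b)
  tab <- ed_summary(ed, list(free_wall = 1:3, outflow = 4:6))
  expect_identical(tab$group, c("free_wall", "outflow", "Overall"))
  expect_equal(tab$max, c(0, 2.07, 2.07))
  expect_equal(tab$mean[3], mean(ed$d))
  zero <- euclidean_distance(a, a)
  expect_true(all(ed_summary(zero, list(all = 1:6))[, c("min", "max",
                                                        "mean")] == 0))
  expect_error(ed_summary(ed, list(bad = integer(0))), "empty")
})

test_that("factor quantile bands are ordered, collapse for uniform fields,
          and match sort-based order statistics", {
  pfu <- structure(list(times = 1:3, x = matrix(1, 3, 8)),
                   class = "pressure_factor_field")
  b <- pf_band_stats(pfu)
  expect_true(all(b[, c("min", "q05", "q25", "q75", "q95", "max")] == 1))
  x <- matrix(c(0, 1, 2, 3), 1, 4)
  pf <- structure(list(times = 0, x = x), class = "pressure_factor_field")
  b <- pf_band_stats(pf)
  expect_equal(b$q25, as.numeric(quantile(c(0, 1, 2, 3), 0.25, type = 7)))
  expect_equal(b$q75, 2.25)
  set.seed(23)
  xr <- matrix(rnorm(50 * 40, 1, 0.2), 50, 40)
  pfr <- structure(list(times = 1:50, x = xr),
                   class = "pressure_factor_field")
  br <- pf_band_stats(pfr)
  expect_true(all(br$min <= br$q05 & br$q05 <= br$q25 &
                    br$q25 <= br$q75 & br$q75 <= br$q95 &
                    br$q95 <= br$max))
  expect_error(pf_band_stats(structure(list(times = 0,
                                            x = matrix(1, 1, 3)),
                                       class = "pressure_factor_field")),
               "at least 4")
})

test_that("pv loop converts units and its area matches a trapezoid oracle", {
  t <- seq(0, 1, length.out = 100)
  V <- 1e-4 + 2e-5 * sin(2 * pi * t)
  p <- 5e3 + 3e3 * cos(2 * pi * t)
  m <- mech_stub(matrix(0, 100, 4), matrix(0, 100, 4), times = t,
                 V = V, p = p)
  loop <- pv_loop(m)
  expect_equal(loop$V_ml, V * 1e6)
  expect_equal(loop$p_mmHg, p / 133.322)
  # shoelace area vs trapezoid integration of p dV around the loop
  Vc <- c(V, V[1]); pc <- c(p, p[1])
  trap <- abs(sum((pc[-1] + pc[-length(pc)]) / 2 * diff(Vc)))
  expect_equal(attr(loop, "area_J"), trap, tolerance = 1e-10)
  expect_error(pv_loop(mech_stub(matrix(0, 1, 2), matrix(0, 1, 2))),
               "full stored cycle")
})
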