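# Cycle-to-cycle coupling core: spatial pressure statistics per chamber,
# the time-resolved scaling factor with its (-3, 3) clip, the mean-free
# pressure factor, the adapted mechanical pressure, and the iteration
# loop that alternates mechanics and fluid stages until the wall
# deformation stops changing between iterations.

#' Spatial chamber pressure statistics
#'
#' Unweighted minimum, maximum and arithmetic mean of the wall-element
#' pressures of one chamber at every stored time.
#'
#' @param p_wall a `wall_pressure_field`: list with `times` (cycle
#'   phase, s) and `p` (time-by-element pressure matrix, Pa); see
#'   [run_fluid()] and [make_synthetic_pressure_field()].
#' @param elements optional integer vector restricting the statistics to
#'   an element subset (a chamber); default: all elements.
#' @return List with class `"chamber_stats"`: `times`, `p_min`, `p_max`,
#'   `p_mean` (Pa).
#' @export
chamber_stats <- function(p_wall, elements = NULL) {
  p <- p_wall$p
  if (!is.null(elements)) {
    if (length(elements) == 0) stop("domain error: empty element set")
    p <- p[, elements, drop = FALSE]
  }
  if (ncol(p) == 0) stop("domain error: empty element set")
  structure(list(times = p_wall$times,
                 p_min = apply(p, 1, min),
                 p_max = apply(p, 1, max),
                 p_mean = rowMeans(p)),
            class = "chamber_stats")
}

#' Time-resolved scaling factor
#'
#' y_s = 2 (p_max - p_mean) / p_max, clipped to `[-3, 3]`. A degenerate
#' spatial maximum of exactly zero yields y_s = 0 (the field then
#' carries no usable amplitude information).
#'
#' @param stats a [chamber_stats()] object (vectorized over its times),
#'   or a list with `p_max` and `p_mean`.
#' @return Clipped scaling factor, one value per time.
#' @export
scaling_factor <- function(stats) {
  y <- ifelse(stats$p_max == 0, 0,
              2 * (stats$p_max - stats$p_mean) / stats$p_max)
  pmin(pmax(y, -3), 3)
}

#' Spatially resolved, mean-free pressure factor
#'
#' x_i = y_s (p_i - p_mean) / (p_max - p_min) + 1 per element and time.
#' The subtraction of the spatial mean makes the element average of x
#' exactly one at every time, so the mean chamber pressure seen by the
#' circulation is preserved; the residual floating-point mean offset is
#' removed before the field is returned and the normalization is
#' asserted to 1e-12. A spatially uniform field (p_max = p_min) carries
#' no spatial information and maps to x = 1 everywhere.
#'
#' @inheritParams chamber_stats
#' @param stats optional precomputed [chamber_stats()]; computed from
#'   `p_wall` (restricted to `elements`) when missing.
#' @param y_s optional scaling-factor vector; defaults to
#'   `scaling_factor(stats)`.
#' @return A `pressure_factor_field`: list with `times` (cycle phase,
#'   s), `x` (time-by-element factor matrix, element mean 1) and `y_s`.
#' @export
pressure_factor <- function(p_wall, elements = NULL, stats = NULL,
                            y_s = NULL) {
  p <- p_wall$p
  if (!is.null(elements)) p <- p[, elements, drop = FALSE]
  if (ncol(p) == 0) stop("domain error: empty element set")
  if (is.null(stats)) {
    stats <- chamber_stats(list(times = p_wall$times, p = p))
  }
  if (is.null(y_s)) y_s <- scaling_factor(stats)
  rng <- stats$p_max - stats$p_min
  x <- matrix(1, nrow(p), ncol(p))
  nd <- rng > 0
  if (any(nd)) {
    dev <- sweep(p[nd, , drop = FALSE], 1, stats$p_mean[nd])
    xs <- sweep(dev, 1, y_s[nd] / rng[nd], `*`) + 1
    xs <- sweep(xs, 1, rowMeans(xs) - 1)      # remove FP mean residue
    x[nd, ] <- xs
  }
  if (any(!nd)) {
    message("pressure_factor: ", sum(!nd),
            " time slice(s) with uniform pressure mapped to x = 1")
  }
  stopifnot(max(abs(rowMeans(x) - 1)) < 1e-12)
  structure(list(times = p_wall$times, x = x, y_s = y_s),
            class = "pressure_factor_field")
}

#' Adapted mechanical pressure
#'
#' p* = p_mech_c * x: the mean chamber pressure delivered by the
#' circulation, redistributed spatially by the pressure factor. Because
#' the factor is mean-free (element average one), the element mean of
#' p* equals p_mech_c.
#'
#' @param p_mech_c mean chamber pressure in Pa (scalar or per-time
#'   vector).
#' @param x dimensionless pressure factor (scalar, vector or matrix).
#' @return Adapted pressure, same shape as `x`.
#' @export
adapted_pressure <- function(p_mech_c, x) {
  stopifnot(all(is.finite(p_mech_c)), all(is.finite(x)))
  if (is.matrix(x)) p_mech_c * x else p_mech_c * x
}

#' Interpolate a pressure-factor field at an arbitrary time
#'
#' Linear interpolation in cycle phase (`t mod T_cycle`) with periodic
#' wrap-around between the last and first stored samples. Queries at a
#' stored time return the stored slice exactly, and a constant field
#' interpolates bitwise exactly.
#'
#' @param pf a `pressure_factor_field`.
#' @param t_query query time in s.
#' @param T_cycle cycle period in s.
#' @return Factor vector x (one value per element) at the query phase.
#' @export
phase_align <- function(pf, t_query, T_cycle) {
  if (is.null(pf$times) || length(pf$times) == 0) {
    stop("domain error: empty pressure-factor field")
  }
  tx <- pf$times
  nt <- length(tx)
  ph <- t_query %% T_cycle
  if (ph < tx[1] || ph >= tx[nt]) {
    # wrap segment between the last and the first stored sample
    i <- nt; i2 <- 1L
    dt <- (T_cycle - tx[nt]) + tx[1]
    dphi <- if (ph >= tx[nt]) ph - tx[nt] else ph + (T_cycle - tx[nt])
  } else {
    i <- findInterval(ph, tx)
    i2 <- i + 1L
    dt <- tx[i2] - tx[i]
    dphi <- ph - tx[i]
  }
  w <- if (dt > 0) dphi / dt else 0
  a <- pf$x[i, ]
  a + w * (pf$x[i2, ] - a)
}

#' Smooth a wall-pressure field in cycle phase
#'
#' Periodic moving average of each element's pressure trace over a
#' phase window. Used as the determination window for the scaling and
#' pressure factors: it removes the sharp systolic pressure transients
#' that would otherwise kick the wall solver impulsively and can make
#' the sequential coupling loop amplify instead of contract.
#'
#' @param pwf a `wall_pressure_field`.
#' @param width_s window width in s (0 disables smoothing).
#' @return The smoothed `wall_pressure_field`.
#' @export
smooth_wall_pressure <- function(pwf, width_s) {
  if (width_s <= 0) return(pwf)
  nt <- length(pwf$times)
  dt <- mean(diff(pwf$times))
  k <- max(1L, round(width_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  half <- k %/% 2L
  idx <- outer(seq_len(nt), -half:half, `+`)
  idx <- ((idx - 1L) %% nt) + 1L
  p <- pwf$p
  for (j in seq_len(ncol(p))) {
    p[, j] <- rowMeans(matrix(pwf$p[idx, j], nt))
  }
  pwf$p <- p
  pwf
}

#' Run the sequential cycle-to-cycle coupling loop
#'
#' Iteration 0 runs the uncoupled mechanics stage (default ten cycles)
#' and feeds the last-cycle wall motion and boundary pressures to the
#' fluid stage (default four cycles); the wall pressure field extracted
#' from the fluid limit cycle yields the pressure factor for the next
#' mechanics iteration. After every coupled mechanics run the Euclidean
#' distance to the previous iteration's last cycle is evaluated; the
#' loop stops when the maximum distance falls below `tol_mm` or after
#' `max_iter` coupled iterations.
#'
#' @param config a [default_config()]-style configuration list.
#' @param outdir optional directory; when given, the exchange files
#'   (wall motion, boundary pressure, wall pressure, pressure factor,
#'   report) of every iteration are written there.
#' @param fluid_backend function `(mech, geom, config)` returning a
#'   `wall_pressure_field` plus diagnostics, defaulting to the built-in
#'   ALE solver ([run_fluid()]). Supplying a stub (e.g. uniform
#'   pressure) short-circuits the fluid stage, which is useful for
#'   verifying the identity behavior of the coupling chain.
#' @param quiet suppress progress messages.
#' @return A `coupling_report`: per-iteration Euclidean-distance
#'   summaries (mm), pressure-factor extrema, residual-volume traces,
#'   pressure-volume loops, the convergence flag and iteration count.
#' @export
run_coupled <- function(config = default_config(), outdir = NULL,
                        fluid_backend = NULL, quiet = FALSE) {
  cfg <- validate_config(config)
  geom <- config_geometry(cfg)
  params <- config_mech_params(cfg)
  if (is.null(fluid_backend)) {
    fluid_backend <- function(mech, geom, cfg) {
      run_fluid(mech, geom = geom, n_cycles = cfg$coupling$n_fluid_cycles,
                params = config_fluid_params(cfg),
                valve = config_valve(cfg), n_r = cfg$grid$n_r,
                quiet = TRUE)
    }
  }
  say <- function(...) if (!quiet) message(...)
  n_mech <- cfg$coupling$n_mech_cycles
  max_iter <- cfg$coupling$max_iter
  tol_mm <- cfg$coupling$tol_mm
  pf_window <- cfg$coupling$pf_window

  say("iteration 0: mechanics (", n_mech, " cycles, uncoupled)")
  mech <- run_mechanics(geom, params, n_cycles = n_mech)
  mechs <- list(mech)
  pfs <- list()
  eds <- list()
  residuals <- list()
  pv <- list(pv_loop(mech))
  converged <- FALSE
  j <- 0L
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_wall_motion(mech, file.path(outdir, "wall_motion_iter0.csv"))
    write_boundary_pressure(mech,
      file.path(outdir, "boundary_pressure_iter0.csv"))
  }
  while (j < max_iter) {
    say("iteration ", j, ": fluid stage")
    fl <- fluid_backend(mech, geom, cfg)
    pwf <- if (!is.null(fl$wall_pressure)) fl$wall_pressure else fl
    pf <- pressure_factor(smooth_wall_pressure(pwf,
                                               cfg$coupling$pf_time_window))
    pfs[[j + 1L]] <- pf
    if (!is.null(fl$residual)) residuals[[j + 1L]] <- fl$residual
    if (!is.null(outdir)) {
      write_wall_pressure(pwf,
        file.path(outdir, sprintf("wall_pressure_iter%d.csv", j)))
      write_pressure_factor(pf,
        file.path(outdir, sprintf("pressure_factor_iter%d.csv", j)))
    }
    j <- j + 1L
    say("iteration ", j, ": mechanics (pressure factor applied, window = ",
        pf_window, ")")
    mech_new <- run_mechanics(geom, params, n_cycles = n_mech, pf = pf,
                              pf_window = pf_window)
    mechs[[j + 1L]] <- mech_new
    ed <- euclidean_distance(mech, mech_new)
    eds[[j]] <- ed$summary
    pv[[j + 1L]] <- pv_loop(mech_new)
    say(sprintf("  max ED = %.3f mm, mean ED = %.4f mm",
                ed$summary["max"], ed$summary["mean"]))
    if (j >= 2 && eds[[j]]["max"] >= eds[[j - 1]]["max"]) {
      warning("coupling not contracting: max ED did not decrease ",
              "between iterations ", j - 1, " and ", j)
    }
    mech <- mech_new
    if (!is.null(outdir)) {
      write_wall_motion(mech,
        file.path(outdir, sprintf("wall_motion_iter%d.csv", j)))
    }
    if (ed$summary["max"] < tol_mm) {
      converged <- TRUE
      break
    }
  }
  ed_mat <- do.call(rbind, eds)
  pf_extrema <- t(vapply(pfs, function(p) range(p$x), numeric(2)))
  colnames(pf_extrema) <- c("min", "max")
  report <- structure(list(
    ed = ed_mat, pf_extrema = pf_extrema,
    residual = residuals, pv_loops = pv,
    converged = converged, n_iterations = j,
    tol_mm = tol_mm, mech_results = mechs,
    pressure_factors = pfs
  ), class = "coupling_report")
  if (!is.null(outdir)) {
    write_coupling_report(report, file.path(outdir,
                                            "coupling_report.json"))
  }
  report
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("coupling_report:", x$n_iterations, "coupled iteration(s),",
      if (x$converged) "converged" else "not converged",
      sprintf("(tol %.2f mm)\n", x$tol_mm))
  if (!is.null(x$ed)) {
    for (i in seq_len(nrow(x$ed))) {
      cat(sprintf("  ED iteration %d -> %d: min %.3f, max %.3f, mean %.4f mm\n",
                  i - 1, i, x$ed[i, "min"], x$ed[i, "max"],
                  x$ed[i, "mean"]))
    }
  }
  invisible(x)
}
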