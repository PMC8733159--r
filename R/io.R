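# Configuration handling, exchange-file readers/writers (the CSV
# hand-off files between the mechanics and fluid stages), legacy ASCII
# VTK snapshots and the synthetic fixture generators.

#' Default run configuration
#'
#' Nested list of every tunable parameter with its default: geometry
#' preset, material/activation/circulation parameters, fluid and valve
#' settings, grid resolution and the coupling protocol (ten mechanics
#' cycles, four fluid cycles, up to three coupled iterations, 0.1 mm
#' tolerance on the maximum Euclidean distance). Pressure entries accept
#' strings with an explicit unit suffix (`"7.5 mmHg"` or `"1000 Pa"`).
#'
#' @return Configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(n_seg = 64, radius = 0.025, length = 0.07,
                    h0 = 0.01, inlet_span = c(-0.0185, -0.0035),
                    outlet_span = c(0.0035, 0.0135),
                    valve_zone_depth = 0.005, ports = TRUE),
    material = list(preset = "ventricle"),
    activation = list(T_peak = 80e3, alpha1 = 0.303, alpha2 = 0.508,
                      n1 = 1.32, n2 = 21.9, T_cycle = 1.247,
                      t_onset = 0.15),
    circulation = list(R_mv = 4e5, R_ao = 2e5, R_sys = 2.4e7,
                       C_art = 6e-8, p_atrium = "7.5 mmHg",
                       p_art0 = "80 mmHg", K_c = 1e8),
    mechanics = list(kappa = 2e7, c_damp = 3e3, p_ext = 0,
                     fiber_blend = 1, dt_mech = 1e-3, n_out = 250),
    fluid = list(rho = 1055, mu = 0.004, D = 1e-10, cfl_max = 0.7,
                 dt0 = 0.001, dt_min = 1e-6, dt_max = 2.5e-3),
    valve = list(q_lo = 20, q_hi = 160, k_min = 1e-7, phi = 1),
    grid = list(n_r = 8, port_ax_coarsen = 2, motion_taper = pi / 16),
    coupling = list(n_mech_cycles = 10, n_fluid_cycles = 4,
                    max_iter = 3, tol_mm = 0.1, pf_window = "last",
                    pf_time_window = 0.125),
    output = list(vtk_every = 0),
    rng_seed = 1
  )
}

parse_pressure <- function(x, key) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec(
    "^\\s*([-0-9.eE+]+)\\s*(Pa|kPa|mmHg)\\s*$", as.character(x)))[[1]]
  if (length(m) != 3) {
    stop("validation error: `", key, "` must be numeric (Pa) or a ",
         "string with unit suffix Pa, kPa or mmHg, got '", x, "'")
  }
  v <- as.numeric(m[2])
  switch(m[3], Pa = v, kPa = 1e3 * v, mmHg = mmhg_to_pa(v))
}

#' Validate and complete a configuration
#'
#' Merges the user configuration over [default_config()], rejects
#' unknown keys, converts pressure strings to Pa and checks sign and
#' range constraints; every offending key is reported.
#'
#' @param config (partial) configuration list.
#' @return The completed configuration with all pressures in Pa.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  bad <- character(0)
  merge <- function(d, u, prefix = "") {
    for (k in names(u)) {
      if (!k %in% names(d)) {
        bad <<- c(bad, paste0(prefix, k))
      } else if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        if (!is.list(u[[k]])) {
          bad <<- c(bad, paste0(prefix, k))
        } else {
          d[[k]] <- merge(d[[k]], u[[k]], paste0(prefix, k, "."))
        }
      } else {
        d[[k]] <- u[[k]]
      }
    }
    d
  }
  cfg <- merge(def, config)
  if (length(bad)) {
    stop("validation error: unknown configuration key(s): ",
         paste(bad, collapse = ", "))
  }
  for (k in c("p_atrium", "p_art0")) {
    cfg$circulation[[k]] <- parse_pressure(cfg$circulation[[k]],
                                           paste0("circulation.", k))
  }
  cfg$mechanics$p_ext <- parse_pressure(cfg$mechanics$p_ext,
                                        "mechanics.p_ext")
  pos <- c("geometry.radius", "geometry.length", "geometry.h0",
           "geometry.valve_zone_depth", "fluid.rho", "fluid.mu",
           "fluid.cfl_max", "fluid.dt0", "valve.q_lo", "valve.q_hi",
           "valve.k_min", "valve.phi", "circulation.R_mv",
           "circulation.R_ao", "circulation.R_sys", "circulation.C_art",
           "circulation.K_c", "activation.T_cycle",
           "coupling.tol_mm", "mechanics.dt_mech")
  viol <- character(0)
  for (p in pos) {
    kk <- strsplit(p, ".", fixed = TRUE)[[1]]
    v <- cfg[[kk[1]]][[kk[2]]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      viol <- c(viol, p)
    }
  }
  if (cfg$fluid$D < 0) viol <- c(viol, "fluid.D")
  if (!cfg$coupling$pf_window %in% c("last", "all")) {
    viol <- c(viol, "coupling.pf_window")
  }
  if (length(viol)) {
    stop("validation error: invalid value for key(s): ",
         paste(viol, collapse = ", "))
  }
  cfg
}

#' Load / save a run configuration (YAML)
#'
#' @param path file path.
#' @return `load_config()`: a validated configuration list (an empty
#'   file yields all defaults).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param config configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

# Constructors from a validated configuration.
config_geometry <- function(cfg) {
  g <- cfg$geometry
  make_chamber(n_seg = g$n_seg, radius = g$radius, length = g$length,
               h0 = g$h0, inlet_span = g$inlet_span,
               outlet_span = g$outlet_span,
               valve_zone_depth = g$valve_zone_depth, ports = g$ports)
}

config_mech_params <- function(cfg) {
  mat <- material_presets(cfg$material$preset)
  ov <- cfg$material[setdiff(names(cfg$material), "preset")]
  for (k in names(ov)) mat[[k]] <- ov[[k]]
  a <- cfg$activation
  mech_params(
    material = mat,
    activation = activation_params(T_peak = a$T_peak, alpha1 = a$alpha1,
                                   alpha2 = a$alpha2, n1 = a$n1,
                                   n2 = a$n2, T_cycle = a$T_cycle,
                                   t_onset = a$t_onset),
    circulation = do.call(circulation_params, cfg$circulation),
    kappa = cfg$mechanics$kappa, c_damp = cfg$mechanics$c_damp,
    p_ext = cfg$mechanics$p_ext, fiber_blend = cfg$mechanics$fiber_blend)
}

config_fluid_params <- function(cfg) do.call(fluid_params, cfg$fluid)

config_valve <- function(cfg) do.call(valve_config, cfg$valve)

# --- exchange files --------------------------------------------------------

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

write_exchange_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (k in which(num)) {
    out[[k]] <- ifelse(out[[k]] == round(out[[k]]) &
                         abs(out[[k]]) < 2^53,
                       format(out[[k]], scientific = FALSE,
                              trim = TRUE),
                       fmt17(out[[k]]))
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_exchange_csv <- function(path, required) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), " (line 1)")
  }
  df
}

# Long (time, id, value...) table checks: duplicates and coverage.
check_long_table <- function(df, path, time_col, id_col) {
  key <- paste(df[[time_col]], df[[id_col]])
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("format error in ", basename(path), ": duplicate (",
         time_col, ", ", id_col, ") pair at line ", dup[1] + 1L)
  }
  ids <- sort(unique(df[[id_col]]))
  times <- sort(unique(df[[time_col]]))
  if (nrow(df) != length(ids) * length(times)) {
    stop("format error in ", basename(path), ": incomplete coverage (",
         nrow(df), " rows, expected ", length(ids) * length(times),
         " for ", length(ids), " ids x ", length(times), " times)")
  }
  ord <- order(df[[time_col]], df[[id_col]])
  df[ord, , drop = FALSE]
}

#' Write / read the wall-motion exchange file
#'
#' Long CSV with columns `cycle_time_s`, `node_id`, `x_m`, `y_m` (one
#' cycle of wall node coordinates), doubles written with 17 significant
#' digits so the round trip is bit-faithful. Readers normalize row
#' order by (time, id) and raise format errors for missing columns,
#' duplicate (time, id) pairs or gaps in node coverage.
#'
#' @param mech a `mech_result` (or for the reader: the file path).
#' @param path file path.
#' @return `read_wall_motion()` returns the long data frame, normalized.
#' @export
write_wall_motion <- function(mech, path) {
  nt <- length(mech$times); nn <- ncol(mech$node_x)
  df <- data.frame(
    cycle_time_s = rep(mech$times, each = nn),
    node_id = rep(seq_len(nn), times = nt),
    x_m = as.vector(t(mech$node_x)),
    y_m = as.vector(t(mech$node_y)))
  write_exchange_csv(df, path)
}

#' @rdname write_wall_motion
#' @export
read_wall_motion <- function(path) {
  df <- read_exchange_csv(path, c("cycle_time_s", "node_id", "x_m",
                                  "y_m"))
  check_long_table(df, path, "cycle_time_s", "node_id")
}

# wide (times, x, y) matrices from a long wall-motion table
normalize_wall_motion <- function(df, nn = NULL) {
  if (is.character(df)) df <- read_wall_motion(df)
  df <- check_long_table(df, "wall_motion", "cycle_time_s", "node_id")
  ids <- sort(unique(df$node_id))
  if (!is.null(nn) && length(ids) != nn) {
    stop("format error: wall motion has ", length(ids),
         " nodes, expected ", nn)
  }
  times <- sort(unique(df$cycle_time_s))
  nt <- length(times)
  list(times = times,
       x = matrix(df$x_m, nt, length(ids), byrow = TRUE),
       y = matrix(df$y_m, nt, length(ids), byrow = TRUE))
}

#' Write / read the boundary-pressure exchange file
#'
#' CSV with columns `cycle_time_s`, `p_inlet_Pa`, `p_outlet_Pa`,
#' `p_chamber_Pa` for one cycle.
#'
#' @param mech a `mech_result` or a data frame with those columns.
#' @param path file path.
#' @export
write_boundary_pressure <- function(mech, path) {
  df <- if (inherits(mech, "mech_result")) {
    data.frame(cycle_time_s = mech$times, p_inlet_Pa = mech$p_inlet,
               p_outlet_Pa = mech$p_outlet,
               p_chamber_Pa = mech$p_chamber)
  } else as.data.frame(mech)
  write_exchange_csv(df, path)
}

#' @rdname write_boundary_pressure
#' @export
read_boundary_pressure <- function(path) {
  df <- read_exchange_csv(path, c("cycle_time_s", "p_inlet_Pa",
                                  "p_outlet_Pa", "p_chamber_Pa"))
  if (any(duplicated(df$cycle_time_s))) {
    stop("format error in ", basename(path), ": duplicate time at line ",
         which(duplicated(df$cycle_time_s))[1] + 1L)
  }
  df[order(df$cycle_time_s), , drop = FALSE]
}

#' Write / read the wall-pressure exchange file
#'
#' Long CSV with columns `cycle_time_s`, `element_id`, `p_Pa`: the
#' per-wall-segment fluid pressure samples of the last fluid cycle.
#'
#' @param pwf a `wall_pressure_field` (lists `times`, `p`).
#' @param path file path.
#' @return `read_wall_pressure()` returns a `wall_pressure_field`.
#' @export
write_wall_pressure <- function(pwf, path) {
  nt <- length(pwf$times); ne <- ncol(pwf$p)
  df <- data.frame(cycle_time_s = rep(pwf$times, each = ne),
                   element_id = rep(seq_len(ne), times = nt),
                   p_Pa = as.vector(t(pwf$p)))
  write_exchange_csv(df, path)
}

#' @rdname write_wall_pressure
#' @export
read_wall_pressure <- function(path) {
  df <- read_exchange_csv(path, c("cycle_time_s", "element_id", "p_Pa"))
  df <- check_long_table(df, path, "cycle_time_s", "element_id")
  times <- sort(unique(df$cycle_time_s))
  ne <- length(unique(df$element_id))
  structure(list(times = times,
                 p = matrix(df$p_Pa, length(times), ne, byrow = TRUE)),
            class = "wall_pressure_field")
}

#' Write / read the pressure-factor exchange file
#'
#' Long CSV with columns `cycle_time_s`, `element_id`, `x`; the
#' companion scaling-factor file has columns `cycle_time_s`, `y_s`.
#' The mean-free normalization (element mean of x equal to one) is
#' asserted at write time.
#'
#' @param pf a `pressure_factor_field`.
#' @param path file path.
#' @return `read_pressure_factor()` returns a `pressure_factor_field`.
#' @export
write_pressure_factor <- function(pf, path) {
  stopifnot(max(abs(rowMeans(pf$x) - 1)) < 1e-12,
            all(abs(pf$y_s) <= 3))
  nt <- length(pf$times); ne <- ncol(pf$x)
  df <- data.frame(cycle_time_s = rep(pf$times, each = ne),
                   element_id = rep(seq_len(ne), times = nt),
                   x = as.vector(t(pf$x)))
  write_exchange_csv(df, path)
}

#' @rdname write_pressure_factor
#' @export
read_pressure_factor <- function(path) {
  df <- read_exchange_csv(path, c("cycle_time_s", "element_id", "x"))
  df <- check_long_table(df, path, "cycle_time_s", "element_id")
  times <- sort(unique(df$cycle_time_s))
  ne <- length(unique(df$element_id))
  structure(list(times = times,
                 x = matrix(df$x, length(times), ne, byrow = TRUE),
                 y_s = NULL),
            class = "pressure_factor_field")
}

#' @rdname write_pressure_factor
#' @export
write_scaling_factor <- function(pf, path) {
  write_exchange_csv(data.frame(cycle_time_s = pf$times, y_s = pf$y_s),
                     path)
}

#' Write a coupling report as JSON
#'
#' Euclidean-distance summaries (mm), pressure-factor extrema,
#' convergence flag and iteration count.
#'
#' @param report a `coupling_report` from [run_coupled()].
#' @param path file path.
#' @export
write_coupling_report <- function(report, path) {
  out <- list(
    converged = report$converged,
    n_iterations = report$n_iterations,
    tol_mm = report$tol_mm,
    ed_mm = if (!is.null(report$ed)) {
      lapply(seq_len(nrow(report$ed)), function(i)
        as.list(report$ed[i, ]))
    } else list(),
    pf_range = lapply(seq_len(nrow(report$pf_extrema)), function(i)
      as.list(report$pf_extrema[i, ]))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a legacy ASCII VTK snapshot
#'
#' Unstructured-grid VTK file (triangles, quads, general polygons) with
#' optional cell data scalars/vectors, readable by ParaView.
#'
#' @param mesh a `fluid_mesh`.
#' @param path output file.
#' @param nodes node coordinates (default: reference configuration).
#' @param cell_data named list of numeric vectors (length ncell) or
#'   two-column matrices (written as 3D vectors with z = 0).
#' @export
write_vtk <- function(mesh, path, nodes = mesh$nodes0,
                      cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(nodes)
  writeLines(c("# vtk DataFile Version 3.0",
               "cardioloop snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nn, "double")), con)
  writeLines(paste(fmt17(nodes[, 1]), fmt17(nodes[, 2]), "0"), con)
  sizes <- lengths(mesh$cells)
  writeLines(paste("CELLS", mesh$ncell, sum(sizes + 1)), con)
  writeLines(vapply(mesh$cells, function(v)
    paste(c(length(v), v - 1L), collapse = " "), character(1)), con)
  writeLines(paste("CELL_TYPES", mesh$ncell), con)
  writeLines(as.character(ifelse(sizes == 3, 5L,
                                 ifelse(sizes == 4, 9L, 7L))), con)
  if (length(cell_data)) {
    writeLines(paste("CELL_DATA", mesh$ncell), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.matrix(v)) {
        writeLines(paste("VECTORS", nm, "double"), con)
        writeLines(paste(fmt17(v[, 1]), fmt17(v[, 2]), "0"), con)
      } else {
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(fmt17(v), con)
      }
    }
  }
  invisible(path)
}

# --- synthetic fixtures ----------------------------------------------------

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Generate a synthetic endocardial wall-pressure field
#'
#' Reproducible (seeded) per-element pressure samples over one cycle:
#' a smooth mean chamber-pressure trace (diastolic baseline with a
#' systolic rise), plus profile-dependent structure emulating what a
#' ventricular flow simulation produces at the wall - localized
#' systolic overpressure next to the outflow tract (`"outlet-jet"`), a
#' diastolic filling-jet bump near the apex (`"apex-jet"`), plain
#' Gaussian disturbances (`"noise"`), or a spatially uniform field
#' (`"uniform"`).
#'
#' @param n_elements number of wall elements (>= 4).
#' @param n_times samples over the cycle.
#' @param profile one of `"outlet-jet"`, `"apex-jet"`, `"noise"`,
#'   `"uniform"`.
#' @param seed RNG seed; identical seeds give identical fields.
#' @param T_cycle cycle period in s.
#' @param p_dia,p_sys diastolic / systolic mean pressure levels in Pa.
#' @param jet_amp amplitude of the localized pressure bump in Pa.
#' @param noise_sd Gaussian noise standard deviation in Pa (ignored for
#'   `"uniform"`).
#' @return A `wall_pressure_field` with attributes `outlet_elements`
#'   and `apex_elements` (the designated element sets) and `profile`.
#' @export
make_synthetic_pressure_field <- function(n_elements, n_times = 250,
                                          profile = c("outlet-jet",
                                                      "apex-jet",
                                                      "noise",
                                                      "uniform"),
                                          seed = 1, T_cycle = 1.247,
                                          p_dia = 1000, p_sys = 16000,
                                          jet_amp = 2500,
                                          noise_sd = 100) {
  if (n_elements < 4) stop("domain error: need at least 4 elements")
  profile <- match.arg(profile)
  times <- seq(0, T_cycle, length.out = n_times + 1)[seq_len(n_times)]
  tau <- times / T_cycle
  sysw <- exp(-((tau - 0.55) / 0.12)^2)          # systolic window
  diaw <- exp(-((tau - 0.08) / 0.06)^2)          # early filling window
  m <- p_dia + (p_sys - p_dia) * sysw
  n_out <- max(2L, round(0.1 * n_elements))
  outlet_elements <- (n_elements - n_out + 1L):n_elements
  apex_elements <- seq(floor(n_elements * 0.4), ceiling(n_elements * 0.6))
  e <- seq_len(n_elements)
  p <- matrix(rep(m, n_elements), n_times, n_elements)
  if (profile != "uniform") {
    shape <- switch(profile,
      "outlet-jet" = exp(-((e - n_elements) / (0.06 * n_elements))^2),
      "apex-jet" = exp(-((e - (n_elements + 1) / 2) /
                           (0.08 * n_elements))^2),
      "noise" = rep(0, n_elements))
    tw <- if (profile == "apex-jet") diaw else sysw
    p <- p + jet_amp * outer(tw, shape)
    p <- p + with_seed(seed,
                       matrix(stats::rnorm(n_times * n_elements, 0,
                                           noise_sd),
                              n_times, n_elements))
  }
  structure(list(times = times, p = p),
            class = "wall_pressure_field",
            outlet_elements = outlet_elements,
            apex_elements = apex_elements,
            profile = profile, seed = seed)
}

#' Generate synthetic periodic wall motion of a contracting chamber
#'
#' Analytic radial contraction: every wall node moves along its radial
#' direction with stretch `1 - amplitude * w(t)`, where `w` is a smooth
#' periodic systolic waveform vanishing at the cycle start, blended to
#' zero at the base corners. Includes matching synthetic boundary
#' pressure traces so the result can drive the fluid stage
#' stand-alone.
#'
#' @param geom a [make_chamber()] geometry.
#' @param amplitude peak fractional radial contraction (default 0.12).
#' @param n_times samples over the cycle.
#' @param T_cycle cycle period in s.
#' @param p_dia,p_sys diastolic / systolic chamber pressure in Pa.
#' @return A `mech_result`-compatible object (wall motion plus
#'   boundary-pressure traces).
#' @export
make_synthetic_wall_motion <- function(geom, amplitude = 0.12,
                                       n_times = 250, T_cycle = 1.247,
                                       p_dia = 1000, p_sys = 14000) {
  times <- seq(0, T_cycle, length.out = n_times + 1)[seq_len(n_times)]
  tau <- times / T_cycle
  w <- exp(-((tau - 0.55) / 0.14)^2)      # smooth systolic contraction
  w <- w - min(w)                          # zero at cycle start
  w <- w / max(w)
  scale <- 1 - amplitude * w
  r <- outer(scale, geom$r0)
  node_x <- sweep(r, 2, geom$e_r[, 1], `*`)
  node_y <- sweep(r, 2, geom$e_r[, 2], `*`)
  p_ch <- p_dia + (p_sys - p_dia) * w
  structure(list(
    times = times, node_x = node_x, node_y = node_y,
    p_chamber = p_ch,
    p_inlet = rep(mmhg_to_pa(7.5), n_times),
    p_outlet = mmhg_to_pa(80) + 0.15 * (p_ch - p_dia),
    V = vapply(seq_len(n_times), function(i)
      chamber_volume(cbind(node_x[i, ], node_y[i, ]), check = FALSE),
      numeric(1)),
    cycle_index = rep(1L, n_times),
    cycle_conv = numeric(0),
    T_cycle = T_cycle, geom = geom
  ), class = "mech_result")
}
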