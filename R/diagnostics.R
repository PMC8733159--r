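# Evaluation criteria: Euclidean-distance convergence fields and
# summaries, pressure-factor quantile bands, residual-volume (washout)
# traces and pressure-volume loops.

#' Euclidean distance between two mechanics iterations
#'
#' Per-node, per-time displacement magnitude
#' d_i = sqrt(dx^2 + dy^2 + dz^2) between corresponding wall nodes of
#' two mechanics runs (z = 0 in the planar model), reported in mm. Both
#' runs must share the node indexing and sampling grid; this is
#' guaranteed for results produced from the same configuration.
#'
#' @param run_a,run_b `mech_result` objects (see [run_mechanics()]).
#' @return An `ed_field`: list with `times`, matrix `d` (time by node,
#'   mm) and `summary` (min/max/mean over all nodes and times, mm).
#' @export
euclidean_distance <- function(run_a, run_b) {
  if (!identical(dim(run_a$node_x), dim(run_b$node_x)) ||
      max(abs(run_a$times - run_b$times)) > 1e-12) {
    stop("comparison error: mechanics results have mismatched node or ",
         "time grids")
  }
  d <- sqrt((run_a$node_x - run_b$node_x)^2 +
              (run_a$node_y - run_b$node_y)^2) * 1e3
  structure(list(times = run_a$times, d = d,
                 summary = c(min = min(d), max = max(d), mean = mean(d))),
            class = "ed_field")
}

#' Tabulate Euclidean-distance summaries per node group
#'
#' One row of min/max/mean (mm, rounded to two decimals in the printed
#' table) per named node group plus an `Overall` row.
#'
#' @param ed an `ed_field` from [euclidean_distance()].
#' @param node_sets named list of node index vectors (may overlap or
#'   subset the nodes); empty groups are an error.
#' @return Data frame with columns `group`, `min`, `max`, `mean` (mm).
#' @export
ed_summary <- function(ed, node_sets = list()) {
  rows <- lapply(names(node_sets), function(nm) {
    idx <- node_sets[[nm]]
    if (length(idx) == 0) stop("domain error: empty node group '", nm, "'")
    di <- ed$d[, idx, drop = FALSE]
    data.frame(group = nm, min = min(di), max = max(di), mean = mean(di))
  })
  rows <- c(rows, list(data.frame(group = "Overall", min = min(ed$d),
                                  max = max(ed$d), mean = mean(ed$d))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pressure-factor quantile bands
#'
#' Per-time envelopes of the spatial factor distribution: extrema, the
#' central 50% band `[q25, q75]` and the central 90% band `[q05, q95]`.
#' Quantiles use linear interpolation of order statistics (type 7).
#'
#' @param pf a `pressure_factor_field` (see [pressure_factor()]) with
#'   at least 4 elements.
#' @return Data frame with columns `time`, `min`, `q05`, `q25`, `q75`,
#'   `q95`, `max`.
#' @export
pf_band_stats <- function(pf) {
  if (ncol(pf$x) < 4) {
    stop("domain error: quantile bands need at least 4 elements")
  }
  q <- t(apply(pf$x, 1, stats::quantile,
               probs = c(0, 0.05, 0.25, 0.75, 0.95, 1), type = 7,
               names = FALSE))
  out <- data.frame(time = pf$times, min = q[, 1], q05 = q[, 2],
                    q25 = q[, 3], q75 = q[, 4], q95 = q[, 5],
                    max = q[, 6])
  rownames(out) <- NULL
  out
}

#' Residual volume of initial chamber blood
#'
#' Integrates the passive scalar over the chamber:
#' V_res = sum_c psi_c * V_c, reported in ml. With psi initialized to 1
#' in the chamber this is the initial blood volume still residing there.
#'
#' @param psi cell scalar concentrations in `[0, 1]`.
#' @param mesh a `fluid_mesh`.
#' @param vol optional current cell volumes (defaults to the reference
#'   metric).
#' @return Residual volume in ml (area times unit depth).
#' @export
residual_volume <- function(psi, mesh, vol = NULL) {
  if (is.null(vol)) vol <- mesh_geometry(mesh)$vol
  cc <- mesh$chamber_cells
  sum(psi[cc] * vol[cc]) * 1e6
}

#' Pressure-volume loop of the last mechanics cycle
#'
#' @param mech a `mech_result`.
#' @return Data frame with `time` (s), `V_ml` (chamber volume, ml) and
#'   `p_mmHg` (mean chamber pressure, mmHg), plus attribute `"area_J"`,
#'   the loop area (stroke work per unit depth, J) from the shoelace
#'   formula.
#' @export
pv_loop <- function(mech) {
  if (length(mech$times) < 2) {
    stop("domain error: pressure-volume loop needs a full stored cycle")
  }
  V <- mech$V; p <- mech$p_chamber
  out <- data.frame(time = mech$times, V_ml = V * 1e6,
                    p_mmHg = pa_to_mmhg(p))
  area <- abs(shoelace_area(cbind(V, p)))
  attr(out, "area_J") <- area
  out
}

#' Womersley number
#'
#' alpha = d sqrt(omega rho / mu): the ratio of pulsatile inertial to
#' viscous effects for a vessel of diameter `d` at angular frequency
#' `omega`.
#'
#' @param d diameter in m.
#' @param omega angular frequency in rad/s.
#' @param rho fluid density in kg/m^3.
#' @param mu dynamic viscosity in kg/(m s).
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(d, omega, rho = 1055, mu = 0.004) {
  d * sqrt(omega * rho / mu)
}
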