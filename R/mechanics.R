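# Reduced spatially resolved wall mechanics: each wall node moves
# radially (about the base center) under the local transmural pressure,
# passive + active membrane tension converted by Laplace's law, a
# neighbor regularization and viscous damping. The chamber is closed by
# a lumped circulation (preload source, diode valves, two-element
# Windkessel afterload) supplying the mean chamber pressure.

#' Lumped circulation parameters
#'
#' Diode valve resistances `R_mv`, `R_ao` (Pa s / m^3), systemic
#' Windkessel resistance `R_sys` and compliance `C_art`, constant atrial
#' preload `p_atrium` (Pa; default 7.5 mmHg, the diastatic left-heart
#' filling pressure), initial arterial pressure `p_art0`, and the stiff
#' artificial chamber compliance `K_c` (Pa) that enforces the
#' volume-flow balance. These are reduced stand-ins for a full
#' closed-loop circulation; defaults are tuned to yield a classical
#' pressure-volume loop on the default chamber preset.
#'
#' @param R_mv,R_ao mitral / aortic valve resistance in Pa s / m^3.
#' @param R_sys systemic resistance in Pa s / m^3.
#' @param C_art arterial compliance in m^3 / Pa.
#' @param p_atrium atrial (preload) pressure in Pa.
#' @param p_art0 initial arterial pressure in Pa.
#' @param K_c artificial chamber stiffness in Pa.
#' @return List with class `"circulation_params"`.
#' @export
circulation_params <- function(R_mv = 4e5, R_ao = 2e5, R_sys = 2.4e7,
                               C_art = 6e-8,
                               p_atrium = mmhg_to_pa(7.5),
                               p_art0 = mmhg_to_pa(80),
                               K_c = 1e8) {
  stopifnot(R_mv > 0, R_ao > 0, R_sys > 0, C_art > 0, K_c > 0)
  structure(as.list(environment()), class = "circulation_params")
}

#' Wall mechanics parameter bundle
#'
#' @param material passive Guccione parameters
#'   (see [material_presets()]).
#' @param activation [activation_params()] for the active driver.
#' @param circulation [circulation_params()] for the lumped circuit.
#' @param kappa neighbor regularization stiffness in Pa/m.
#' @param c_damp wall damping in Pa s / m.
#' @param p_ext external (pericardial) pressure in Pa.
#' @param fiber_blend fiber-exponent blend passed to
#'   [membrane_tension()].
#' @param thickness_grading if `TRUE` (default), the local wall
#'   thickness is graded with the reference radius,
#'   `h_i = h0 * r0_i / mean(r0)`. Under the Laplace law this makes the
#'   pressure a node's tension can carry independent of its reference
#'   radius, so the chamber responds to the (spatially mean) pressure
#'   with a coherent, nearly uniform stretch instead of ballooning at
#'   the apex - the membrane analogue of the curvature compensation a
#'   doubly curved shell provides.
#' @return List with class `"mech_params"`.
#' @export
mech_params <- function(material = material_presets("ventricle"),
                        activation = activation_params(),
                        circulation = circulation_params(),
                        kappa = 2e7, c_damp = 3e3, p_ext = 0,
                        fiber_blend = 1, thickness_grading = TRUE) {
  structure(as.list(environment()), class = "mech_params")
}

# Per-node wall thickness (m).
node_thickness <- function(geom, params) {
  if (isTRUE(params$thickness_grading)) {
    geom$h0 * geom$r0 / mean(geom$r0)
  } else {
    rep(geom$h0, length(geom$r0))
  }
}

# d(area)/d(r_i) for the radial wall polygon (closed across the base):
# with node positions p_i = r_i e_i, dA/dr_i =
# (cross(e_i, p_{i+1}) + cross(p_{i-1}, e_i)) / 2, indices cyclic.
area_gradient_r <- function(r, e_r) {
  px <- r * e_r[, 1]; py <- r * e_r[, 2]
  nxt <- c(2:length(r), 1L); prv <- c(length(r), 1:(length(r) - 1L))
  0.5 * (e_r[, 1] * py[nxt] - e_r[, 2] * px[nxt] +
           px[prv] * e_r[, 2] - py[prv] * e_r[, 1])
}

# Passive equilibrium stretch per node under a transmural pressure:
# solves T_pass(lambda) / (lambda r0) = p (Laplace law) by bisection.
# Used as the diastatic initial condition of the wall solver.
equilibrium_stretch <- function(geom, params, p) {
  p_net <- p - params$p_ext
  if (p_net <= 0) return(rep(1, geom$n_seg + 1L))
  h_n <- node_thickness(geom, params)
  vapply(seq_along(geom$r0), function(i) {
    f <- function(l) {
      membrane_tension(l, params$material, h_n[i],
                       params$fiber_blend) / (l * geom$r0[i]) - p_net
    }
    stats::uniroot(f, c(1 + 1e-9, 3), tol = 1e-10)$root
  }, numeric(1))
}

# Map per-segment values to nodes by adjacent-segment averaging.
segment_to_node <- function(x_seg) {
  n <- length(x_seg)
  c(x_seg[1], (x_seg[-n] + x_seg[-1]) / 2, x_seg[n])
}

#' Radial wall accelerations
#'
#' Force balance per wall node: the areal mass `rho0 * h0` times the
#' radial acceleration equals the transmural pressure load minus the
#' Laplace-law tension term `(T_pass(lambda) + T_act(t)) / r`, plus a
#' neighbor regularization `kappa * (r[i+1] - 2 r[i] + r[i-1])` (one-sided
#' at the apex-side and base-side end nodes) minus viscous damping.
#'
#' @param state list with radii `r` (m), radial velocities `v` (m/s) and
#'   time `t` (s).
#' @param p_local local pressure per wall node in Pa (one value per node;
#'   per-segment fields are mapped to nodes by adjacent-segment
#'   averaging upstream).
#' @param t time in s (for the activation driver).
#' @param geom chamber geometry.
#' @param params a [mech_params()] bundle.
#' @return Radial accelerations in m/s^2.
#' @export
wall_rhs <- function(state, p_local, t, geom, params) {
  r <- state$r; v <- state$v
  n <- length(r)
  lam <- r / geom$r0
  h_n <- node_thickness(geom, params)
  Tp <- membrane_tension(lam, params$material, h_n,
                         params$fiber_blend)
  Ta <- active_tension(t, params$activation, h_n)
  # neighbor regularization on the stretch field (scaled back to a
  # radial force): vanishes for any uniform stretch, in particular at
  # the non-circular reference shape
  lap <- c(lam[2] - lam[1],
           lam[-c(1, 2)] - 2 * lam[-c(1, n)] + lam[-c(n - 1, n)],
           lam[n - 1] - lam[n]) * geom$r0
  f <- (p_local - params$p_ext) - (Tp + Ta) / r +
    params$kappa * lap - params$c_damp * v
  if (any(!is.finite(f))) {
    stop("numerical error: non-finite wall force at node ",
         which(!is.finite(f))[1])
  }
  f / (params$material$rho0 * geom$h0)
}

#' Advance the lumped circulation by one time step
#'
#' Diode valve flows `Q_mv = max(p_atrium - p_chamber, 0)/R_mv` and
#' `Q_ao = max(p_chamber - p_art, 0)/R_ao`, an explicit two-element
#' Windkessel update for the arterial pressure, and a backward
#' (semi-implicit) update of the chamber pressure through the stiff
#' artificial compliance
#' `dp_chamber/dt = K_c (Q_mv - Q_ao - dV_wall/dt) / V`.
#' The piecewise-linear implicit equation for the new chamber pressure
#' is monotone and solved exactly by regime enumeration.
#'
#' @param circ list with `p_chamber`, `p_art`, `V` (and optionally
#'   `Q_mv`, `Q_ao`), see [run_mechanics()].
#' @param dV_wall_dt wall volume rate of change in m^3/s.
#' @param dt time step in s (> 0).
#' @param params a [circulation_params()] list.
#' @param alpha wall pressure admittance in m^3/(s Pa): the linearized
#'   sensitivity of the wall volume rate to a chamber-pressure change
#'   within the step. The wall solver passes its value to damp the
#'   stiff pressure-wall mode implicitly; the default 0 gives the plain
#'   backward compliance update.
#' @return Updated circulation state (list with `p_chamber`, `p_art`,
#'   `Q_mv`, `Q_ao`, `V`).
#' @export
circulation_step <- function(circ, dV_wall_dt, dt, params, alpha = 0) {
  stopifnot(dt > 0)
  p <- circ$p_chamber; pa <- params$p_atrium; part <- circ$p_art
  V <- circ$V
  c0 <- dt * params$K_c / V
  # backward update per valve regime, including the wall admittance:
  # p' = p + c0 [ Q_mv(p') - Q_ao(p') - dVdt* - alpha (p' - p) ]
  solve_regime <- function(g_mv, g_ao) {
    (p + c0 * (g_mv * pa + g_ao * part - dV_wall_dt + alpha * p)) /
      (1 + c0 * (g_mv + g_ao + alpha))
  }
  g1 <- 1 / params$R_mv; g2 <- 1 / params$R_ao
  cand <- c(closed = solve_regime(0, 0), mv = solve_regime(g1, 0),
            ao = solve_regime(0, g2), both = solve_regime(g1, g2))
  ok <- c(
    cand[1] >= pa && cand[1] <= part,
    cand[2] < pa && cand[2] <= part,
    cand[3] > part && cand[3] >= pa,
    cand[4] < pa && cand[4] > part)
  pn <- cand[which(ok)[1]]
  if (is.na(pn)) pn <- cand[1]
  if (abs(pn - p) > mmhg_to_pa(50)) {
    stop("stability error: chamber pressure step ",
         sprintf("%.1f", pa_to_mmhg(abs(pn - p))),
         " mmHg exceeds 50 mmHg; reduce dt")
  }
  Q_mv <- max(pa - pn, 0) / params$R_mv
  Q_ao <- max(pn - part, 0) / params$R_ao
  part_n <- part + dt * (Q_ao - part / params$R_sys) / params$C_art
  list(p_chamber = as.numeric(pn), p_art = part_n,
       Q_mv = Q_mv, Q_ao = Q_ao, V = V + dt * dV_wall_dt)
}

#' Run the wall mechanics stage
#'
#' Integrates the radial wall dynamics (explicit RK4, fixed step
#' `dt_mech`) interleaved with the semi-implicit lumped-circulation
#' update. When a pressure-factor field `pf` is supplied, the local
#' pressure at node i becomes `p_chamber(t) * x_i(phase(t))` (the
#' element factors are phase-interpolated and mapped to nodes by
#' adjacent-segment averaging); by default the factor is applied only
#' during the final cycle. The last cycle is resampled onto `n_out`
#' equidistant phase points.
#'
#' @param geom a [make_chamber()] geometry.
#' @param params a [mech_params()] bundle.
#' @param n_cycles number of heart cycles (>= 1; default 10, enough to
#'   reach a limit cycle).
#' @param pf optional `pressure_factor_field` (see [pressure_factor()]);
#'   element indexing must match `geom`.
#' @param pf_window `"last"` (default) applies the factor only in the
#'   final cycle; `"all"` applies it throughout.
#' @param dt_mech integration step in s (default 1 ms).
#' @param n_out samples per cycle in the result (default 250, a 4.988 ms
#'   output grid over the 1.247 s cycle).
#' @return A `mech_result`: output times (cycle phase, s), wall node
#'   coordinates, chamber/inlet/outlet pressures (Pa), chamber volume
#'   (m^3) for the last cycle, the cycle index, and per-cycle
#'   self-convergence displacements.
#' @export
run_mechanics <- function(geom, params = mech_params(), n_cycles = 10,
                          pf = NULL, pf_window = c("last", "all"),
                          dt_mech = 1e-3, n_out = 250) {
  pf_window <- match.arg(pf_window)
  stopifnot(n_cycles >= 1)
  if (!is.null(pf) && ncol(pf$x) != geom$n_seg) {
    stop("pressure-factor field has ", ncol(pf$x),
         " elements but geometry has ", geom$n_seg, " segments")
  }
  Tc <- params$activation$T_cycle
  n_step <- round(Tc / dt_mech)
  nn <- geom$n_seg + 1L
  r <- geom$r0 * equilibrium_stretch(geom, params,
                                     params$circulation$p_atrium)
  v <- numeric(nn)
  circ <- list(p_chamber = params$circulation$p_atrium,
               p_art = params$circulation$p_art0,
               Q_mv = 0, Q_ao = 0,
               V = chamber_volume(r * geom$e_r, check = FALSE))
  V_old <- circ$V
  # last-cycle storage (per integration step)
  st_r <- matrix(NA_real_, n_step + 1, nn)
  st_p <- st_pi <- st_po <- st_V <- numeric(n_step + 1)
  prev_cycle_r <- NULL
  last_full_r <- NULL
  cycle_conv <- numeric(0)
  for (cyc in seq_len(n_cycles)) {
    is_last <- cyc == n_cycles
    use_pf <- !is.null(pf) && (pf_window == "all" || is_last)
    cyc_r <- matrix(NA_real_, n_step + 1, nn)
    cyc_r[1, ] <- r
    if (is_last) {
      st_r[1, ] <- r
      st_p[1] <- circ$p_chamber; st_pi[1] <- params$circulation$p_atrium
      st_po[1] <- circ$p_art; st_V[1] <- circ$V
    }
    for (k in seq_len(n_step)) {
      t0 <- (cyc - 1) * Tc + (k - 1) * dt_mech
      p_frozen <- circ$p_chamber
      if (use_pf) {
        x_seg <- phase_align(pf, t0, Tc)
        x_node <- segment_to_node(x_seg)
        p_loc <- p_frozen * x_node
      } else {
        x_node <- rep(1, nn)
        p_loc <- rep(p_frozen, nn)
      }
      # RK4 on (r, v) with frozen pressure
      acc <- function(rr, vv, tt) {
        wall_rhs(list(r = rr, v = vv), p_loc, tt, geom, params)
      }
      h <- dt_mech
      k1v <- acc(r, v, t0);                 k1r <- v
      k2v <- acc(r + h / 2 * k1r, v + h / 2 * k1v, t0 + h / 2)
      k2r <- v + h / 2 * k1v
      k3v <- acc(r + h / 2 * k2r, v + h / 2 * k2v, t0 + h / 2)
      k3r <- v + h / 2 * k2v
      k4v <- acc(r + h * k3r, v + h * k3v, t0 + h)
      k4r <- v + h * k3v
      r <- r + h / 6 * (k1r + 2 * k2r + 2 * k3r + k4r)
      v <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      if (any(r < 0.2 * geom$r0) || any(r > 3 * geom$r0)) {
        bad <- which(r < 0.2 * geom$r0 | r > 3 * geom$r0)[1]
        stop("solver failure: wall radius diverged at node ", bad,
             " (t = ", sprintf("%.3f", t0), " s, lambda = ",
             sprintf("%.2f", r[bad] / geom$r0[bad]), ")")
      }
      V_new <- chamber_volume(r * geom$e_r, check = FALSE)
      # implicit pressure-wall coupling: admittance of the wall volume
      # rate to a pressure change applied over the remaining half step
      m_eff <- params$material$rho0 * geom$h0
      dA <- area_gradient_r(r, geom$e_r)
      alpha <- 2 * dt_mech * sum(dA * x_node) / m_eff
      circ <- circulation_step(circ, (V_new - V_old) / dt_mech,
                               dt_mech, params$circulation,
                               alpha = alpha)
      # feed the implicit pressure increment back into the wall motion
      v <- v + dt_mech * (circ$p_chamber - p_frozen) * x_node / m_eff
      circ$V <- V_new
      V_old <- V_new
      cyc_r[k + 1, ] <- r
      if (is_last) {
        st_r[k + 1, ] <- r
        st_p[k + 1] <- circ$p_chamber
        st_pi[k + 1] <- params$circulation$p_atrium
        st_po[k + 1] <- circ$p_art
        st_V[k + 1] <- V_new
      }
    }
    if (!is.null(prev_cycle_r)) {
      cycle_conv <- c(cycle_conv, max(abs(cyc_r - prev_cycle_r)))
    }
    prev_cycle_r <- cyc_r
  }
  # resample the last cycle onto the n_out-point phase grid
  t_step <- seq(0, Tc, length.out = n_step + 1)
  t_out <- seq(0, Tc, length.out = n_out + 1)[seq_len(n_out)]
  interp_mat <- function(M) {
    apply(M, 2, function(col) approx_periodic(t_step, col, t_out))
  }
  r_out <- interp_mat(st_r)
  node_x <- sweep(r_out, 2, geom$e_r[, 1], `*`)
  node_y <- sweep(r_out, 2, geom$e_r[, 2], `*`)
  structure(list(
    times = t_out,
    node_x = node_x, node_y = node_y,
    p_chamber = approx_periodic(t_step, st_p, t_out),
    p_inlet = approx_periodic(t_step, st_pi, t_out),
    p_outlet = approx_periodic(t_step, st_po, t_out),
    V = approx_periodic(t_step, st_V, t_out),
    cycle_index = rep(n_cycles, n_out),
    cycle_conv = cycle_conv,
    T_cycle = Tc, geom = geom
  ), class = "mech_result")
}

# Linear interpolation on an increasing grid; query times are clamped
# into the grid range. Formulated as a + w*(b - a) so that constant
# fields interpolate bitwise exactly.
approx_periodic <- function(tx, y, tq) {
  idx <- findInterval(tq, tx, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(tx) - 1L)
  w <- (tq - tx[idx]) / (tx[idx + 1L] - tx[idx])
  a <- y[idx]
  a + w * (y[idx + 1L] - a)
}

#' @export
print.mech_result <- function(x, ...) {
  cat("mech_result: cycle", x$cycle_index[1], "of the wall solver,",
      length(x$times), "samples,",
      ncol(x$node_x), "wall nodes\n")
  cat(sprintf("  volume %.1f .. %.1f ml, chamber pressure %.1f .. %.1f mmHg\n",
              min(x$V) * 1e6, max(x$V) * 1e6,
              pa_to_mmhg(min(x$p_chamber)), pa_to_mmhg(max(x$p_chamber))))
  invisible(x)
}
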