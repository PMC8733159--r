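# Incompressible ALE finite-volume solver on the moving chamber grid.
#
# Collocated cell-centered velocity/pressure with a Chorin-type
# pressure projection: explicit upwind ALE convection (relative face
# fluxes use exact per-face swept volumes, which gives a discrete
# geometric conservation law and machine-accurate free-stream
# preservation), explicit viscous fluxes, a pointwise semi-implicit
# Darcy-Forchheimer valve forcing, and a compact-stencil pressure
# Poisson equation whose corrected face fluxes transport both momentum
# and the washout scalar.

#' Fluid solver parameters
#'
#' @param rho blood density in kg/m^3.
#' @param mu dynamic viscosity in kg/(m s).
#' @param D scalar diffusivity in m^2/s (numerical-stability value).
#' @param cfl_max Courant bound (<= 1).
#' @param dt0 initial time step in s.
#' @param dt_min smallest admissible step in s.
#' @param dt_max largest admissible step in s.
#' @return List with class `"fluid_params"`.
#' @export
fluid_params <- function(rho = 1055, mu = 0.004, D = 1e-10,
                         cfl_max = 0.7, dt0 = 0.001, dt_min = 1e-6,
                         dt_max = 2.5e-3) {
  stopifnot(rho > 0, mu > 0, D >= 0, cfl_max > 0, cfl_max <= 1,
            dt0 > 0, dt_min > 0)
  structure(as.list(environment()), class = "fluid_params")
}

#' Valve (porous zone) configuration
#'
#' Flux-dependent permeability ramp: the valve plane is blocked
#' (`k_min`) below `q_lo` ml/s, fully permeable (k = 1) above `q_hi`
#' ml/s and linear in between; opening and closing traverse the same
#' curve. `L_ref` converts the dimensionless permeability into a
#' dimensional one (k * L_ref^2, m^2); it defaults to the geometry's
#' valve-zone depth.
#'
#' @param q_lo blocking flux threshold in ml/s.
#' @param q_hi full-open flux threshold in ml/s.
#' @param k_min blocked (dimensionless) permeability.
#' @param phi porosity (kept at 1).
#' @param L_ref reference length in m (NULL: use the valve-zone depth).
#' @return List with class `"valve_config"`.
#' @export
valve_config <- function(q_lo = 20, q_hi = 160, k_min = 1e-7, phi = 1,
                         L_ref = NULL) {
  stopifnot(q_lo > 0, q_hi > q_lo, k_min > 0, k_min < 1, phi > 0)
  structure(as.list(environment()), class = "valve_config")
}

#' Flux-dependent valve plane permeability
#'
#' @param q_abs volume-flux magnitude in ml/s (>= 0, vectorized).
#' @param cfg a [valve_config()].
#' @return Dimensionless permeability in `[k_min, 1]`: `k_min` below
#'   `q_lo`, 1 above `q_hi`, linear in between (continuous at both
#'   thresholds).
#' @export
valve_permeability <- function(q_abs, cfg = valve_config()) {
  if (any(q_abs < 0)) stop("domain error: flux magnitude must be >= 0")
  k <- cfg$k_min + (1 - cfg$k_min) * (q_abs - cfg$q_lo) /
    (cfg$q_hi - cfg$q_lo)
  pmin(pmax(k, cfg$k_min), 1)
}

#' Darcy-Forchheimer valve forcing
#'
#' Body force per unit mass opposing the velocity relative to the valve
#' plane motion:
#' F = -(phi mu)/(rho k L^2) u_rel - (1.75 phi)/sqrt(150 k L^2) |u_rel| u_rel.
#' With a blocked permeability this pins the fluid in the porous zone to
#' the plane motion.
#'
#' @param u_rel relative velocity, a length-2 vector or an (n x 2)
#'   matrix in m/s.
#' @param k_p dimensionless permeability in `(0, 1]`.
#' @param cfg a [valve_config()] (porosity, reference length).
#' @param params a [fluid_params()] (rho, mu).
#' @param L_ref reference length in m, overriding `cfg$L_ref`.
#' @return Force per unit mass (same shape as `u_rel`, m/s^2).
#' @export
valve_forcing <- function(u_rel, k_p, cfg = valve_config(),
                          params = fluid_params(), L_ref = NULL) {
  if (any(k_p <= 0)) stop("domain error: permeability must be positive")
  L <- if (!is.null(L_ref)) L_ref else
    if (!is.null(cfg$L_ref)) cfg$L_ref else 1
  u <- if (is.matrix(u_rel)) u_rel else matrix(u_rel, ncol = 2)
  speed <- sqrt(rowSums(u^2))
  a <- cfg$phi * params$mu / (params$rho * k_p * L^2)
  b <- 1.75 * cfg$phi / sqrt(150 * k_p * L^2)
  f <- -(a + b * speed) * u
  if (!is.matrix(u_rel)) f <- drop(f)
  f
}

#' Initialize the washout scalar
#'
#' psi = 1 in chamber cells, 0 in port-tube cells.
#'
#' @param mesh a `fluid_mesh` with cell region labels.
#' @return Scalar vector over cells.
#' @export
init_scalar <- function(mesh) {
  if (is.null(mesh$cell_region) ||
      length(mesh$cell_region) != mesh$ncell) {
    stop("configuration error: mesh cells are not labeled chamber/port")
  }
  as.numeric(mesh$cell_region == 0L)
}

#' Fresh fluid state at rest
#'
#' @param mesh a `fluid_mesh`.
#' @return A `fluid_state`: cell velocities `u`, pressure `p`, scalar
#'   `psi`, face fluxes `phi` (m^3/s), current nodes, cell volumes,
#'   cell mesh velocity `c_mesh`, time `t` and previous step `dt_prev`.
#' @export
new_fluid_state <- function(mesh) {
  gm <- mesh_geometry(mesh)
  structure(list(
    u = matrix(0, mesh$ncell, 2), p = numeric(mesh$ncell),
    psi = init_scalar(mesh), phi = numeric(mesh$nface),
    nodes = mesh$nodes0, vol = gm$vol,
    c_mesh = matrix(0, mesh$ncell, 2),
    t = 0, dt_prev = NA_real_
  ), class = "fluid_state")
}

#' Uniform-velocity fluid state
#'
#' State with spatially uniform velocity and consistent face fluxes,
#' used for free-stream preservation checks.
#'
#' @param mesh a `fluid_mesh`.
#' @param u0 length-2 velocity in m/s.
#' @return A `fluid_state`.
#' @export
uniform_fluid_state <- function(mesh, u0) {
  st <- new_fluid_state(mesh)
  st$u[, 1] <- u0[1]; st$u[, 2] <- u0[2]
  gm <- mesh_geometry(mesh)
  st$phi <- u0[1] * gm$Sx + u0[2] * gm$Sy
  st
}

#' CFL-limited time step
#'
#' Convective limit dt = cfl_max * min_c(dx_c / |u - c_mesh|_c) with
#' dx_c = sqrt(V_c), combined with the explicit-diffusion stability
#' limit of the viscous term, dt <= 0.5 min_c(V_c / sum_f nu |S|/d),
#' clamped to `[dt_min, 1.2 dt_prev]` (and `dt_max`); the first step
#' returns `dt0` (capped by the diffusive limit).
#'
#' @param state a `fluid_state`.
#' @param mesh a `fluid_mesh`.
#' @param params a [fluid_params()].
#' @return Time step in s; a collapse below `dt_min` is a blow-up error.
#' @export
cfl_timestep <- function(state, mesh, params = fluid_params()) {
  gm <- mesh_geometry(mesh, state$nodes)
  smag <- sqrt(gm$Sx^2 + gm$Sy^2)
  acc_faces <- function(v) {
    out <- numeric(mesh$ncell)
    ow <- rowsum(v, mesh$f_owner, reorder = FALSE)
    out[as.integer(rownames(ow))] <- ow
    int <- mesh$f_neigh > 0L
    nb <- rowsum(v[int], mesh$f_neigh[int], reorder = FALSE)
    idx <- as.integer(rownames(nb))
    out[idx] <- out[idx] + nb
    out
  }
  csum <- acc_faces(params$mu / params$rho * smag / gm$dPN)
  dt_diff <- 0.5 * min(gm$vol / pmax(csum, 1e-300))
  if (is.na(state$dt_prev)) return(min(params$dt0, dt_diff))
  perim <- acc_faces(smag)
  dx <- 2 * gm$vol / perim                 # inradius-like cell size
  rel <- sqrt(rowSums((state$u - state$c_mesh)^2))
  dt <- params$cfl_max * suppressWarnings(min(dx / pmax(rel, 1e-300)))
  dt <- min(dt, 1.2 * state$dt_prev, params$dt_max, dt_diff)
  if (dt < params$dt_min) {
    stop("blow-up error: CFL time step collapsed below dt_min at t = ",
         sprintf("%.4f", state$t), " s")
  }
  dt
}

# Weighted least-squares cell gradient. Fits grad p to the compact
# pressure differences toward the face neighbours (boundary faces use
# the face-center value), with per-face weights: faces the projection
# treats as (nearly) closed - walls, blocked porous faces - are
# down-weighted to zero-gradient behavior. Exact for linear fields on
# arbitrarily anisotropic cells, which keeps the cell pressure force
# consistent with the compact face fluxes (unlike Green-Gauss on the
# high-aspect wedge cells at the web center).
lsq_gradient <- function(mesh, gm, p_face, p_cell, facew) {
  cc <- mesh$ce_cell; ff <- mesh$ce_face
  o <- mesh$f_owner[ff]; nb <- mesh$f_neigh[ff]
  oth <- ifelse(cc == o, nb, o)
  bnd <- oth == 0L
  othx <- pmax(oth, 1L)
  dx <- ifelse(bnd, gm$fx[ff], gm$cx[othx]) - gm$cx[cc]
  dy <- ifelse(bnd, gm$fy[ff], gm$cy[othx]) - gm$cy[cc]
  dp <- ifelse(bnd, p_face[ff], p_cell[othx]) - p_cell[cc]
  w <- facew[ff] / pmax(dx^2 + dy^2, 1e-300)
  sxx <- as.numeric(rowsum(w * dx * dx, cc))
  sxy <- as.numeric(rowsum(w * dx * dy, cc))
  syy <- as.numeric(rowsum(w * dy * dy, cc))
  bx <- as.numeric(rowsum(w * dx * dp, cc))
  by <- as.numeric(rowsum(w * dy * dp, cc))
  det <- pmax(sxx * syy - sxy^2, 1e-300)
  cbind((syy * bx - sxy * by) / det, (sxx * by - sxy * bx) / det)
}

# Pressure Poisson solve with cached symbolic factorization.
solve_pressure <- function(mesh, coef, o, n, int, dir, p_dir, divstar) {
  nc <- mesh$ncell
  has_dir <- length(dir) > 0
  i <- c(o[int], n[int], o[int], n[int], o[dir])
  j <- c(o[int], n[int], n[int], o[int], o[dir])
  x <- c(coef[int], coef[int], -coef[int], -coef[int], coef[dir])
  if (!has_dir) {  # pure Neumann: pin the pressure level
    i <- c(i, 1L); j <- c(j, 1L); x <- c(x, mean(coef[int]))
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nc, nc))
  b <- -divstar
  if (has_dir) {
    add <- coef[dir] * p_dir
    bb <- rowsum(add, o[dir], reorder = FALSE)
    idx <- as.integer(rownames(bb))
    b[idx] <- b[idx] + bb
  }
  cache <- mesh$cache
  A <- Matrix::forceSymmetric(A)
  if (is.null(cache$pchol)) {
    cache$pchol <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  } else {
    cache$pchol <- Matrix::update(cache$pchol, A)
  }
  as.numeric(Matrix::solve(cache$pchol, b, system = "A"))
}

#' Advance the ALE fluid state by one step
#'
#' Explicit upwind ALE convection with swept-volume-consistent mesh
#' fluxes, explicit viscous diffusion, pointwise semi-implicit porous
#' valve forcing, pressure projection enforcing a divergence-free
#' absolute face flux on the new mesh, and a bounded, conservative
#' first-order upwind update of the washout scalar using the corrected
#' relative fluxes.
#'
#' @param state a `fluid_state`.
#' @param mesh a `fluid_mesh`.
#' @param motion list with `nodes` (node coordinates at the new time
#'   level) and optionally `velocity` (node velocities, m/s; derived
#'   from the displacement increment when missing).
#' @param dt time step in s.
#' @param bcs list with Dirichlet pressures `p_inlet`, `p_outlet` (Pa)
#'   and scalar inflow values `psi_inlet`, `psi_outlet` (default 0).
#' @param params a [fluid_params()].
#' @param valve optional list with `cfg` (a [valve_config()]),
#'   dimensionless permeabilities `k_mitral`, `k_aortic` and `L_ref`;
#'   omitted = no porous forcing.
#' @param gm optional precomputed [mesh_geometry()] of `motion$nodes`.
#' @return The advanced `fluid_state`. The post-projection divergence of
#'   the face fluxes is stored in field `div_max` (m^3/s, scaled by
#'   cell volume over dt it is dimensionless and held below 1e-8).
#' @export
ale_step <- function(state, mesh, motion, dt, bcs, params = fluid_params(),
                     valve = NULL, gm = NULL) {
  nodes0 <- state$nodes
  nodes1 <- motion$nodes
  if (is.null(gm)) gm <- mesh_geometry(mesh, nodes1)
  vol0 <- state$vol; vol1 <- gm$vol
  if (any(vol1 <= 0)) {
    stop("mesh error: non-positive cell volume at cell ",
         which(vol1 <= 0)[1])
  }
  sflux <- face_swept_volume(mesh, nodes0, nodes1) / dt
  node_vel <- if (!is.null(motion$velocity)) motion$velocity else
    (nodes1 - nodes0) / dt
  bt <- mesh$f_btype
  is_int <- bt == 0L
  is_wall <- bt == BTYPE[["wall"]] | bt == BTYPE[["port_wall"]]
  is_slip <- bt == BTYPE[["base"]]
  is_in <- bt == BTYPE[["inlet"]]
  is_out <- bt == BTYPE[["outlet"]]
  o <- mesh$f_owner; nb <- mesh$f_neigh

  # --- explicit convection (relative flux = old face flux - mesh flux)
  phi0 <- state$phi
  phi0[is_wall | is_slip] <- sflux[is_wall | is_slip]
  Frel <- phi0 - sflux
  nbx <- pmax(nb, 1L)
  upw_o <- Frel >= 0
  ux_don <- ifelse(upw_o, state$u[o, 1],
                   ifelse(nb > 0L, state$u[nbx, 1], state$u[o, 1]))
  uy_don <- ifelse(upw_o, state$u[o, 2],
                   ifelse(nb > 0L, state$u[nbx, 2], state$u[o, 2]))
  conv_x <- cell_div(mesh, Frel * ux_don)
  conv_y <- cell_div(mesh, Frel * uy_don)

  # --- explicit viscous fluxes (no drag on slip faces)
  nu_coef <- params$mu / params$rho * sqrt(gm$Sx^2 + gm$Sy^2) / gm$dPN
  uwx <- (node_vel[mesh$f_n1, 1] + node_vel[mesh$f_n2, 1]) / 2
  uwy <- (node_vel[mesh$f_n1, 2] + node_vel[mesh$f_n2, 2]) / 2
  dux <- ifelse(is_int, state$u[nbx, 1] - state$u[o, 1],
                ifelse(is_wall, uwx - state$u[o, 1], 0))
  duy <- ifelse(is_int, state$u[nbx, 2] - state$u[o, 2],
                ifelse(is_wall, uwy - state$u[o, 2], 0))
  visc_x <- -cell_div(mesh, -nu_coef * dux)
  visc_y <- -cell_div(mesh, -nu_coef * duy)

  # --- predictor (no pressure: the projection determines the full
  # pressure field each step)
  ux <- (vol0 * state$u[, 1] + dt * (-conv_x + visc_x)) / vol1
  uy <- (vol0 * state$u[, 2] + dt * (-conv_y + visc_y)) / vol1

  # cell mesh velocity (node average) for forcing and CFL
  nv_per_cell <- tabulate(mesh$ce_cell, nbins = mesh$ncell)
  cmx <- as.numeric(rowsum(node_vel[mesh$ce_a, 1], mesh$ce_cell)) /
    nv_per_cell
  cmy <- as.numeric(rowsum(node_vel[mesh$ce_a, 2], mesh$ce_cell)) /
    nv_per_cell

  # --- semi-implicit Darcy-Forchheimer valve forcing; the relaxation
  # factor also scales the pressure-correction coefficients below so
  # that a blocked zone is impermeable to the projection fluxes too
  # (the porous drag enters the momentum diagonal, and the projection
  # uses its inverse).
  cellw <- rep(1, mesh$ncell)
  if (!is.null(valve)) {
    L <- valve$L_ref
    for (zone in list(list(cells = mesh$mitral_cells, k = valve$k_mitral),
                      list(cells = mesh$aortic_cells, k = valve$k_aortic))) {
      cc <- zone$cells
      if (!length(cc)) next
      relx <- ux[cc] - cmx[cc]; rely <- uy[cc] - cmy[cc]
      speed <- sqrt(relx^2 + rely^2)
      a <- valve$cfg$phi * params$mu / (params$rho * zone$k * L^2)
      b <- 1.75 * valve$cfg$phi / sqrt(150 * zone$k * L^2)
      fac <- dt * (a + b * speed)
      ux[cc] <- (ux[cc] + fac * cmx[cc]) / (1 + fac)
      uy[cc] <- (uy[cc] + fac * cmy[cc]) / (1 + fac)
      cellw[cc] <- 1 / (1 + fac)
    }
  }

  # --- projection
  facew <- 2 * cellw[o] * cellw[nbx] / (cellw[o] + cellw[nbx])
  facew[mesh$f_neigh == 0L] <- cellw[o[mesh$f_neigh == 0L]]
  # a (nearly) blocked porous face fluxes like a moving wall: blend the
  # interpolated predictor flux with the swept flux by the face weight
  phistar <- sflux + facew *
    (0.5 * ((ux[o] + ux[nbx]) * gm$Sx + (uy[o] + uy[nbx]) * gm$Sy) -
       sflux)
  phistar[is_wall | is_slip] <- sflux[is_wall | is_slip]
  dirf <- which(is_in | is_out)
  phistar[dirf] <- ux[o[dirf]] * gm$Sx[dirf] + uy[o[dirf]] * gm$Sy[dirf]
  # over-relaxed non-orthogonality treatment: |S|^2 / (S . d) reduces
  # to |S|/d on orthogonal faces and keeps the compact flux response
  # consistent on the skewed web cells
  bndf <- mesh$f_neigh == 0L
  ddx <- ifelse(bndf, gm$fx, gm$cx[nbx]) - gm$cx[o]
  ddy <- ifelse(bndf, gm$fy, gm$cy[nbx]) - gm$cy[o]
  Smag <- sqrt(gm$Sx^2 + gm$Sy^2)
  Sd <- pmax(gm$Sx * ddx + gm$Sy * ddy,
             0.05 * Smag * sqrt(ddx^2 + ddy^2))
  coef <- dt / params$rho * Smag^2 / Sd * facew
  p_dir <- ifelse(is_in[dirf], bcs$p_inlet, bcs$p_outlet)
  ii <- which(is_int)
  divstar <- cell_div(mesh, phistar)
  p <- solve_pressure(mesh, coef, o, nb, ii, dirf, p_dir, divstar)

  phi1 <- phistar
  phi1[ii] <- phistar[ii] - coef[ii] * (p[nb[ii]] - p[o[ii]])
  phi1[dirf] <- phistar[dirf] - coef[dirf] * (p_dir - p[o[dirf]])
  div1 <- cell_div(mesh, phi1)
  div_max <- max(abs(div1) * dt / vol1)

  # --- cell velocity correction (face-weighted least-squares gradient)
  gradw <- facew
  gradw[is_wall | is_slip] <- 0          # walls: zero-gradient faces
  p_face <- numeric(mesh$nface)
  p_face[dirf] <- p_dir
  gd <- lsq_gradient(mesh, gm, p_face, p, gradw)
  ux <- ux - dt / params$rho * cellw * gd[, 1]
  uy <- uy - dt / params$rho * cellw * gd[, 2]

  # --- washout scalar: upwind on corrected relative fluxes
  Frel1 <- phi1 - sflux
  psi_bc <- numeric(mesh$nface)
  psi_bc[is_in] <- if (!is.null(bcs$psi_inlet)) bcs$psi_inlet else 0
  psi_bc[is_out] <- if (!is.null(bcs$psi_outlet)) bcs$psi_outlet else 0
  upw1 <- Frel1 >= 0
  psi_don <- ifelse(upw1, state$psi[o],
                    ifelse(nb > 0L, state$psi[nbx], psi_bc))
  adv <- cell_div(mesh, Frel1 * psi_don)
  dpsi <- ifelse(is_int, state$psi[nbx] - state$psi[o], 0)
  Dcoef <- params$D * sqrt(gm$Sx^2 + gm$Sy^2) / gm$dPN
  diff <- -cell_div(mesh, -Dcoef * dpsi)
  psi <- (vol0 * state$psi + dt * (-adv + diff)) / vol1

  structure(list(
    u = cbind(ux, uy), p = p, psi = psi, phi = phi1,
    nodes = nodes1, vol = vol1, c_mesh = cbind(cmx, cmy),
    t = state$t + dt, dt_prev = dt, div_max = div_max,
    sflux = sflux
  ), class = "fluid_state")
}

#' Advance the washout scalar only
#'
#' Convenience wrapper applying the scalar transport of [ale_step()]
#' with the state's stored face fluxes on a static mesh: a bounded,
#' conservative first-order upwind ALE update.
#'
#' @param state a `fluid_state`.
#' @param mesh a `fluid_mesh`.
#' @param dt time step in s.
#' @param params a [fluid_params()].
#' @param psi_in scalar value carried by boundary inflow.
#' @return The state with updated `psi` and advanced time.
#' @export
scalar_step <- function(state, mesh, dt, params = fluid_params(),
                        psi_in = 0) {
  gm <- mesh_geometry(mesh, state$nodes)
  o <- mesh$f_owner; nb <- mesh$f_neigh
  nbx <- pmax(nb, 1L)
  bt <- mesh$f_btype
  is_int <- bt == 0L
  Frel <- state$phi            # static mesh: no swept flux
  Frel[bt == BTYPE[["wall"]] | bt == BTYPE[["base"]]] <- 0
  upw <- Frel >= 0
  psi_don <- ifelse(upw, state$psi[o],
                    ifelse(nb > 0L, state$psi[nbx], psi_in))
  adv <- cell_div(mesh, Frel * psi_don)
  dpsi <- ifelse(is_int, state$psi[nbx] - state$psi[o], 0)
  Dcoef <- params$D * sqrt(gm$Sx^2 + gm$Sy^2) / gm$dPN
  diff <- -cell_div(mesh, -Dcoef * dpsi)
  state$psi <- state$psi + dt * (-adv + diff) / state$vol
  state$t <- state$t + dt
  state
}

# Periodic linear interpolation of a (time x k) matrix at scalar time.
periodic_interp <- function(tx, M, tq, T_cycle) {
  nt <- length(tx)
  ph <- tq %% T_cycle
  if (ph < tx[1] || ph >= tx[nt]) {
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
  a <- M[i, ]
  a + w * (M[i2, ] - a)
}

#' Run the fluid stage
#'
#' Replays one cycle of wall motion periodically over `n_cycles` heart
#' cycles (default four, enough to approach a periodic limit cycle),
#' starting from rest. Valve permeabilities follow the chamber
#' volume-flux magnitude each step (mitral during filling, aortic
#' during ejection). The wall-adjacent cell pressure is sampled per
#' wall segment throughout and the last cycle is returned as the
#' `wall_pressure_field` for the coupling, together with the
#' residual-volume (washout) trace and bookkeeping diagnostics.
#'
#' @param wall_motion a `mech_result` or a data frame in
#'   `wall_motion.csv` layout (columns cycle_time_s, node_id, x_m, y_m).
#' @param geom the chamber geometry (required when `wall_motion` is a
#'   data frame; taken from the `mech_result` otherwise).
#' @param boundary_pressure optional data frame (cycle_time_s,
#'   p_inlet_Pa, p_outlet_Pa, p_chamber_Pa); defaults to the traces
#'   stored in the `mech_result`.
#' @param n_cycles number of heart cycles (>= 1).
#' @param params a [fluid_params()].
#' @param valve a [valve_config()].
#' @param n_r radial rings for [build_grid()] (ignored when `mesh`
#'   given).
#' @param mesh optional prebuilt `fluid_mesh`.
#' @param motion_taper angular width (radians) over which the
#'   prescribed wall displacement is blended to zero at the two base
#'   corners, keeping the fluid mesh anchored at the valve plane.
#' @param n_out samples per cycle of the returned wall-pressure field.
#' @param quiet suppress progress messages.
#' @return List with `wall_pressure` (a `wall_pressure_field`),
#'   `residual` (data frame time_s, V_res_ml), `state` (final
#'   `fluid_state`), `mesh`, `mass_err` (max relative mismatch between
#'   boundary volume flux and mesh volume change), `div_max`,
#'   `cycle_l2` (L2 distance of successive per-cycle wall-pressure
#'   traces) and `n_steps`.
#' @export
run_fluid <- function(wall_motion, geom = NULL, boundary_pressure = NULL,
                      n_cycles = 4, params = fluid_params(),
                      valve = valve_config(), n_r = 8, mesh = NULL,
                      motion_taper = pi / 16, n_out = 250,
                      quiet = FALSE) {
  stopifnot(n_cycles >= 1)
  if (inherits(wall_motion, "mech_result")) {
    mech <- wall_motion
    if (is.null(geom)) geom <- mech$geom
    Tc <- mech$T_cycle
    wm_t <- mech$times
    wm_x <- mech$node_x; wm_y <- mech$node_y
    if (is.null(boundary_pressure)) {
      boundary_pressure <- data.frame(
        cycle_time_s = mech$times, p_inlet_Pa = mech$p_inlet,
        p_outlet_Pa = mech$p_outlet, p_chamber_Pa = mech$p_chamber)
    }
  } else {
    if (is.null(geom)) stop("geom is required with a wall-motion table")
    wm <- normalize_wall_motion(wall_motion, geom$n_seg + 1L)
    wm_t <- wm$times; wm_x <- wm$x; wm_y <- wm$y
    Tc <- attr(wm, "T_cycle")
    if (is.null(Tc)) Tc <- 1.247
    if (is.null(boundary_pressure)) {
      stop("boundary_pressure is required with a wall-motion table")
    }
  }
  bp_t <- boundary_pressure$cycle_time_s
  bp <- as.matrix(boundary_pressure[, c("p_inlet_Pa", "p_outlet_Pa")])
  if (is.null(mesh)) mesh <- build_grid(geom, n_r = n_r)
  nn <- length(mesh$wall_nodes)
  stopifnot(ncol(wm_x) == nn)
  # blend displacement to zero at the base corners
  taper <- pmin(1, geom$theta / motion_taper,
                (pi - geom$theta) / motion_taper)
  ref_x <- geom$nodes[, 1]; ref_y <- geom$nodes[, 2]
  wall_disp_at <- function(t) {
    xy <- periodic_interp(wm_t, cbind(wm_x, wm_y), t, Tc)
    cbind((xy[seq_len(nn)] - ref_x) * taper,
          (xy[nn + seq_len(nn)] - ref_y) * taper)
  }

  state <- new_fluid_state(mesh)
  disp0 <- solve_mesh_motion(mesh, wall_disp_at(0))
  state$nodes <- disp0$nodes
  state$vol <- mesh_geometry(mesh, state$nodes)$vol
  prev_disp <- disp0$displacement
  L_ref <- if (!is.null(valve$L_ref)) valve$L_ref else
    geom$valve_zone_depth

  t_end <- n_cycles * Tc
  cc <- mesh$chamber_cells
  V_ch <- sum(state$vol[cc])
  hist_t <- list()
  hist_res <- list()
  rec_t <- list()              # wall-pressure history (all cycles)
  rec_p <- list()
  wall_faces <- which(mesh$f_btype == BTYPE[["wall"]] &
                        mesh$f_wallseg > 0L)
  wall_faces <- wall_faces[order(mesh$f_wallseg[wall_faces])]
  wall_own <- mesh$f_owner[wall_faces]
  io_faces <- which(mesh$f_btype %in% BTYPE[c("inlet", "outlet")])
  mass_err <- 0
  div_max <- 0
  nstep <- 0L
  while (state$t < t_end - 1e-12) {
    dt <- cfl_timestep(state, mesh, params)
    if (state$t + dt > t_end) dt <- t_end - state$t
    t1 <- state$t + dt
    sm <- solve_mesh_motion(mesh, wall_disp_at(t1),
                            prev_displacement = prev_disp, dt = dt,
                            check_tangle = FALSE)
    gm1 <- mesh_geometry(mesh, sm$nodes)
    V_new <- sum(gm1$vol[cc])
    Vdot <- (V_new - V_ch) / dt
    q_ml <- abs(Vdot) * 1e6
    kv <- list(cfg = valve, L_ref = L_ref,
               k_mitral = if (Vdot > 0) valve_permeability(q_ml, valve)
                          else valve$k_min,
               k_aortic = if (Vdot < 0) valve_permeability(q_ml, valve)
                          else valve$k_min)
    pio <- periodic_interp(bp_t, bp, t1, Tc)
    bcs <- list(p_inlet = pio[1], p_outlet = pio[2],
                psi_inlet = 0, psi_outlet = 0)
    state <- ale_step(state, mesh, list(nodes = sm$nodes,
                                        velocity = sm$velocity),
                      dt, bcs, params, valve = kv, gm = gm1)
    prev_disp <- sm$displacement
    # global mass balance: net port outflow must equal -dV/dt of the
    # mesh; the defect is reported relative to the larger of the
    # instantaneous and the cycle-scale volume flux
    outflow <- sum(state$phi[io_faces])
    dVdt_mesh <- sum(state$sflux[mesh$f_neigh == 0L])
    flux_scale <- max(abs(dVdt_mesh), sum(state$vol[cc]) / Tc)
    mass_err <- max(mass_err, abs(outflow + dVdt_mesh) / flux_scale)
    div_max <- max(div_max, state$div_max)
    V_ch <- V_new
    nstep <- nstep + 1L
    hist_t[[nstep]] <- state$t
    hist_res[[nstep]] <- residual_volume(state$psi, mesh, state$vol)
    rec_t[[nstep]] <- state$t
    rec_p[[nstep]] <- state$p[wall_own]
    if (!quiet && nstep %% 500L == 0L) {
      message(sprintf("  fluid t = %.3f / %.3f s (%d steps)",
                      state$t, t_end, nstep))
    }
  }
  # per-cycle wall-pressure traces on the output phase grid
  rec_t <- unlist(rec_t)
  rec_p <- do.call(rbind, rec_p)
  hist_t <- unlist(hist_t)
  hist_res <- unlist(hist_res)
  t_out <- seq(0, Tc, length.out = n_out + 1)[seq_len(n_out)]
  cyc_field <- function(cyc) {
    tt <- t_out + (cyc - 1) * Tc
    apply(rec_p, 2, function(col)
      stats::approx(rec_t, col, xout = pmax(tt, rec_t[1]), rule = 2)$y)
  }
  fields <- lapply(seq_len(n_cycles), cyc_field)
  cycle_l2 <- if (n_cycles >= 2) {
    vapply(seq_len(n_cycles - 1), function(i)
      sqrt(mean((fields[[i + 1]] - fields[[i]])^2)), numeric(1))
  } else numeric(0)
  wall_pressure <- structure(
    list(times = t_out, p = fields[[n_cycles]]),
    class = "wall_pressure_field")
  list(wall_pressure = wall_pressure,
       residual = data.frame(time_s = hist_t, V_res_ml = hist_res),
       state = state, mesh = mesh, mass_err = mass_err,
       div_max = div_max, cycle_l2 = cycle_l2, n_steps = nstep)
}
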