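# ALE flow solver: valve law, forcing, time stepping, transport.

test_that("valve permeability follows the piecewise-linear opening law", {
  cfg <- valve_config()
  expect_equal(valve_permeability(10, cfg), cfg$k_min)    # blocked
  expect_equal(valve_permeability(200, cfg), 1)           # fully open
  expect_equal(valve_permeability(90, cfg), 0.5, tolerance = 1e-6)
  # continuity at both thresholds and linearity between them
  q <- seq(0, 300, by = 0.5)
  k <- valve_permeability(q, cfg)
  expect_true(all(diff(k) >= 0))
  expect_lt(max(abs(diff(k)[q[-1] > 21 & q[-1] < 159] -
                      (1 - cfg$k_min) / 140 * 0.5)), 1e-9)
  expect_equal(valve_permeability(20, cfg), cfg$k_min, tolerance = 1e-9)
  expect_equal(valve_permeability(160, cfg), 1, tolerance = 1e-9)
  expect_error(valve_permeability(-1, cfg), "domain")
})

test_that("valve forcing vanishes with the plane motion, opposes the flow,
          and matches a hand-evaluated magnitude", {
  cfg <- valve_config(L_ref = 1)
  expect_equal(valve_forcing(c(0, 0), 1, cfg), c(0, 0))
  set.seed(9)
  u <- matrix(rnorm(40), ncol = 2)
  f <- valve_forcing(u, 0.3, cfg)
  expect_true(all(rowSums(f * u) <= 0))
  # k = 1, phi = 1, L = 1 m, |u| = 1: |F| = mu/rho + 1.75/sqrt(150)
  f1 <- valve_forcing(c(1, 0), 1, cfg, fluid_params())
  expect_equal(-f1[1], 0.004 / 1055 + 1.75 / sqrt(150), tolerance = 1e-6)
  expect_equal(abs(f1[1]), 0.14289, tolerance = 1e-4)
  expect_error(valve_forcing(c(1, 0), 0, cfg), "domain")
})

test_that("scalar init marks chamber cells and residual volume matches", {
  mesh <- build_grid(fix_geom(), n_r = 6)
  psi <- init_scalar(mesh)
  expect_true(all(psi[mesh$chamber_cells] == 1))
  expect_true(all(psi[mesh$port_cells] == 0))
  vol <- mesh_geometry(mesh)$vol
  expect_equal(residual_volume(psi, mesh),
               sum(vol[mesh$chamber_cells]) * 1e6)
  expect_equal(residual_volume(numeric(mesh$ncell), mesh), 0)
  expect_equal(residual_volume(0.5 * psi, mesh),
               0.5 * residual_volume(psi, mesh))
})

test_that("cfl stepping honors the initial step, the Courant bound and the
          growth clamp", {
  mesh <- build_channel_mesh(10, 10, 0.01, 0.01)
  st <- new_fluid_state(mesh)
  expect_equal(cfl_timestep(st, mesh), 0.001)   # first call
  st$dt_prev <- 1e-3
  st$u[, 1] <- 1                                 # 1 m/s, 1 mm cells
  expect_lte(cfl_timestep(st, mesh), 0.7e-3)
  st$u[, 1] <- 0                                 # u = c: growth-limited
  st$dt_prev <- 5e-4
  pr <- fluid_params(mu = 1e-6)                  # diffusion not limiting
  expect_equal(cfl_timestep(st, mesh, pr), 6e-4)
  st$dt_prev <- 1e-7
  st$u[, 1] <- 1e6
  expect_error(cfl_timestep(st, mesh), "blow-up")
})

test_that("uniform flow survives arbitrary interior mesh motion", {
  mesh <- build_channel_mesh(12, 10, 0.012, 0.01, slip_walls = TRUE)
  st <- uniform_fluid_state(mesh, c(0.3, 0))
  bcs <- list(p_inlet = 0, p_outlet = 0)
  nodes <- mesh$nodes0
  for (k in 1:20) {
    nn2 <- wiggled_nodes(mesh, 2e-4, phase = k)
    st <- ale_step(st, mesh, list(nodes = nn2), 5e-4, bcs)
    nodes <- nn2
  }
  expect_lt(max(abs(st$u[, 1] - 0.3)), 1e-10)
  expect_lt(max(abs(st$u[, 2])), 1e-10)
  expect_lt(st$div_max, 1e-8)
})

test_that("pressure-driven channel flow converges to the Poiseuille profile", {
  h <- 0.008; L <- 0.016
  mesh <- build_channel_mesh(16, 32, L, h)
  pr <- fluid_params(mu = 0.04)   # viscous fluid: fast approach to steady state
  dp <- 20
  st <- new_fluid_state(mesh)
  bcs <- list(p_inlet = dp, p_outlet = 0)
  for (k in 1:3000) {
    st <- ale_step(st, mesh, list(nodes = mesh$nodes0), 3e-4, bcs, pr)
  }
  umax <- dp * h^2 / (8 * pr$mu * L)
  expect_equal(max(st$u[, 1]), umax, tolerance = 0.02)
  # full mid-channel profile against the parabola
  gm <- mesh_geometry(mesh)
  mid <- which(abs(gm$cx - (L / 2 + L / 64)) < L / 64)
  y <- gm$cy[mid]
  uex <- dp / (2 * pr$mu * L) * y * (h - y)
  expect_lt(max(abs(st$u[mid, 1] - uex)) / umax, 0.02)
})

test_that("a blocked valve plane passes less than a thousandth of the open
          flow", {
  mesh <- build_channel_mesh(24, 6, 0.06, 0.015,
                             porous = list(x0 = 0.045, x1 = 0.05))
  pr <- fluid_params()
  bcs <- list(p_inlet = 1000, p_outlet = 10665)
  run_plug <- function(k_p, nstep = 250) {
    st <- new_fluid_state(mesh)
    kv <- list(cfg = valve_config(), L_ref = 0.005,
               k_mitral = k_p, k_aortic = k_p)
    for (k in seq_len(nstep)) {
      dt <- cfl_timestep(st, mesh, pr)
      st <- ale_step(st, mesh, list(nodes = mesh$nodes0), dt, bcs, pr,
                     valve = kv)
    }
    abs(sum(st$phi[mesh$f_btype == 4L]))  # through-plane flux
  }
  q_blocked <- run_plug(valve_config()$k_min)
  q_open <- run_plug(1)
  expect_lt(q_blocked / q_open, 1e-3)
})

test_that("scalar transport is bounded, conservative on a sealed box, and
          frozen when the fluid moves with the mesh", {
  mesh <- build_channel_mesh(12, 12, 0.012, 0.012, closed = TRUE)
  pr <- fluid_params(D = 0)
  st <- new_fluid_state(mesh)
  set.seed(21)
  st$psi <- runif(mesh$ncell)
  psi_init <- st$psi
  # redistribute the scalar by stirring the interior mesh
  tot0 <- sum(st$psi * st$vol)
  bcs <- list(p_inlet = 0, p_outlet = 0)
  for (k in 1:40) {
    nn2 <- wiggled_nodes(mesh, 3e-4, phase = 2 * k)
    st <- ale_step(st, mesh, list(nodes = nn2), 4e-4, bcs, pr)
  }
  expect_true(all(st$psi >= -1e-12 & st$psi <= 1 + 1e-12))
  expect_lt(abs(sum(st$psi * st$vol) - tot0) / tot0, 1e-10)
  # the scalar really was redistributed across the moving mesh
  expect_false(isTRUE(all.equal(st$psi, psi_init)))
  # u identical to the mesh velocity and no diffusion: psi unchanged
  st2 <- new_fluid_state(mesh)
  st2$psi <- runif(mesh$ncell)
  psi0 <- st2$psi
  st2 <- scalar_step(st2, mesh, 1e-3, pr)   # phi = 0: u = c_mesh = 0
  expect_identical(st2$psi, psi0)
})

test_that("upwind advection shifts a step profile while conserving mass", {
  mesh <- build_channel_mesh(60, 4, 0.06, 0.004, slip_walls = TRUE)
  pr <- fluid_params(D = 0)
  st <- uniform_fluid_state(mesh, c(0.1, 0))
  gm <- mesh_geometry(mesh)
  st$psi <- as.numeric(gm$cx < 0.02)
  mass0 <- sum(st$psi * st$vol)
  dt <- 5e-3  # CFL = 0.5 at 1 mm cells
  nstep <- 40
  for (k in seq_len(nstep)) st <- scalar_step(st, mesh, dt, pr)
  # method of characteristics: the front moves u * t = 2 cm and stays
  # inside the channel (inflow carries psi = 0, nothing leaves), so the
  # total mass is exactly conserved
  shift <- 0.1 * dt * nstep
  exact <- as.numeric(gm$cx < 0.02 + shift)
  expect_lt(abs(sum(st$psi * st$vol) - mass0) / mass0, 1e-10)
  expect_true(all(st$psi >= -1e-12 & st$psi <= 1 + 1e-12))
  # the numerical front (psi = 0.5 crossing) sits at the exact position
  # within the upwind smearing width
  front_num <- max(gm$cx[st$psi > 0.5])
  expect_lt(abs(front_num - (0.02 + shift)), 0.006)
})

test_that("the fluid stage reaches a periodic limit cycle with global mass
          balance on the moving chamber", {
  g <- fix_geom()
  wm <- make_synthetic_wall_motion(g)
  fl <- run_fluid(wm, n_cycles = 4, quiet = TRUE)
  # net port outflow equals the mesh volume change each step
  expect_lt(fl$mass_err, 1e-6)
  # post-projection divergence of the ALE fluxes
  expect_lt(fl$div_max, 1e-8)
  # cycle-to-cycle periodicity: later cycles differ less than early ones
  expect_lt(fl$cycle_l2[3], fl$cycle_l2[1])
  # washout: residual volume decays from the initial chamber volume
  expect_lt(tail(fl$residual$V_res_ml, 1), fl$residual$V_res_ml[1])
  expect_true(all(fl$state$psi >= -1e-9 & fl$state$psi <= 1 + 1e-9))
  # wall pressure field covers every segment at every stored time
  expect_identical(dim(fl$wall_pressure$p),
                   c(length(fl$wall_pressure$times), g$n_seg))
  fixture_env$fluid4 <- fl
})

test_that("zero wall motion with matched port pressures stays quiescent", {
  g <- fix_geom()
  wm <- make_synthetic_wall_motion(g, amplitude = 0)
  wm$p_inlet[] <- 1000; wm$p_outlet[] <- 1000; wm$p_chamber[] <- 1000
  fl <- run_fluid(wm, n_cycles = 1, quiet = TRUE)
  expect_lt(max(abs(fl$state$u)), 1e-3)
  v0 <- fl$residual$V_res_ml[1]
  expect_lt(max(abs(fl$residual$V_res_ml - v0)) / v0, 0.005)
})

test_that("womersley number reproduces the printed pulsatility value", {
  expect_equal(round(womersley_number(0.015, 2 * pi, 1055, 0.004), 1),
               19.3)
})
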