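# Shared fixtures for the test suite. Everything is generated in code;
# heavier simulation results are cached per test session.

fixture_env <- new.env(parent = emptyenv())

# default chamber geometry
fix_geom <- function() {
  if (is.null(fixture_env$geom)) fixture_env$geom <- make_chamber()
  fixture_env$geom
}

# a converged uncoupled 10-cycle mechanics run on the default preset
fix_mech10 <- function() {
  if (is.null(fixture_env$mech10)) {
    fixture_env$mech10 <- run_mechanics(fix_geom(), n_cycles = 10)
  }
  fixture_env$mech10
}

# a unit-amplitude pressure-factor field (x identically one)
pf_identity <- function(geom, n_times = 250, T_cycle = 1.247) {
  times <- seq(0, T_cycle, length.out = n_times + 1)[seq_len(n_times)]
  structure(list(times = times,
                 x = matrix(1, n_times, geom$n_seg),
                 y_s = rep(0, n_times)),
            class = "pressure_factor_field")
}

# wiggle interior nodes of a mesh (boundary fixed), for ALE/GCL checks
wiggled_nodes <- function(mesh, amp, phase = 0) {
  bnd <- unique(c(mesh$f_n1[mesh$f_btype != 0L],
                  mesh$f_n2[mesh$f_btype != 0L]))
  interior <- setdiff(seq_len(nrow(mesh$nodes0)), bnd)
  nodes <- mesh$nodes0
  k <- seq_len(2 * length(interior))
  nodes[interior, ] <- nodes[interior, ] +
    amp * matrix(sin(phase + k), ncol = 2)
  nodes
}
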