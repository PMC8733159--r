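# Boundary-fitted finite-volume grid for the chamber and its port tubes.
#
# The chamber interior is meshed by a "spider-web" grid: rays from an
# interior center node to every node of the closed boundary loop (wall
# nodes plus base nodes), with n_r rings. The innermost ring consists of
# triangles sharing the center node; all other cells are quadrilaterals.
# Port tubes carry structured quad grids glued node-to-node onto the
# base. Cells are stored as counter-clockwise node loops, faces as node
# pairs with owner/neighbour cells, which keeps all finite-volume
# machinery agnostic of the cell shape.

BTYPE <- c(interior = 0L, wall = 1L, base = 2L, port_wall = 3L,
           inlet = 4L, outlet = 5L)

# Subdivide [a, b] into at least n_min segments of target size h.
seg_breaks <- function(a, b, h, n_min = 1L) {
  n <- max(n_min, ceiling(abs(b - a) / h))
  seq(a, b, length.out = n + 1)
}

#' Build the boundary-fitted fluid grid
#'
#' Generates the chamber spider-web grid (`n_r` rings by `n_theta`
#' boundary-loop segments, where `n_theta` counts wall plus base
#' segments) and, if the geometry has ports, structured grids for the
#' two port tubes, glued to the base with matching nodes. Cells inside
#' each port within `valve_zone_depth` of the base are marked as the
#' mitral / aortic porous valve zones.
#'
#' @param geom a [make_chamber()] geometry.
#' @param n_r number of radial rings (>= 4).
#' @param port_ax_coarsen axial cell-size factor for the port tubes
#'   relative to the wall segment length (default 2).
#' @param grade_exp radial grading exponent: ring k sits at fraction
#'   `(k/n_r)^grade_exp` of the boundary distance. Values below 1
#'   enlarge the innermost (wedge) cells, which relaxes the explicit
#'   diffusion time-step limit at the web center.
#' @return An object of class `"fluid_mesh"`; see Details.
#' @details The mesh stores reference node coordinates `nodes0`, cells as
#'   ccw node loops, a face table (`f_n1`, `f_n2`, `f_owner`, `f_neigh`,
#'   `f_btype`, `f_wallseg`), cell groups (`chamber_cells`, `port_cells`,
#'   `mitral_cells`, `aortic_cells`), the wall boundary nodes in
#'   one-to-one correspondence with the geometry's wall nodes, and a
#'   cache environment for factorized operators. Every wall boundary
#'   face maps to exactly one geometry wall segment.
#' @export
build_grid <- function(geom, n_r = 8, port_ax_coarsen = 2,
                       grade_exp = 0.7) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (n_r < 4) stop("mesh error: n_r must be >= 4")
  R <- geom$radius
  wall <- geom$nodes                      # (-R,0) .. apex .. (R,0)
  n_wall <- nrow(wall)
  h_wall <- mean(sqrt(rowSums(diff(wall)^2)))

  # Base breakpoints from +R back to -R (ccw continuation of the loop).
  if (geom$ports) {
    o <- geom$outlet_span; i <- geom$inlet_span
    marks <- sort(unique(c(R, o[2], o[1], i[2], i[1], -R)),
                  decreasing = TRUE)
  } else {
    marks <- c(R, -R)
  }
  bx <- numeric(0)
  for (k in seq_len(length(marks) - 1)) {
    s <- seg_breaks(marks[k], marks[k + 1], h_wall, n_min = 2L)
    bx <- c(bx, s[-length(s)])
  }
  bx <- c(bx, -R)                          # closing breakpoint
  base_nodes <- cbind(x = bx[-c(1, length(bx))], y = 0)  # interior only

  # Closed boundary loop: wall nodes then base interior nodes (ccw).
  loop <- rbind(wall, base_nodes)
  n_loop <- nrow(loop)                     # == n_theta
  # polygon centroid (area-weighted) as the web center
  x <- loop[, 1]; y <- loop[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  A <- 0.5 * sum(cr)
  ctr <- c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * A)

  # Node table: center, rings 1..n_r (ring n_r is the boundary loop).
  nid <- function(k, l) 1L + (k - 1L) * n_loop + ((l - 1L) %% n_loop) + 1L
  nodes <- matrix(0, nrow = 1 + n_r * n_loop, ncol = 2)
  nodes[1, ] <- ctr
  for (k in seq_len(n_r)) {
    f <- (k / n_r)^grade_exp
    idx <- nid(k, seq_len(n_loop))
    nodes[idx, 1] <- ctr[1] + f * (loop[, 1] - ctr[1])
    nodes[idx, 2] <- ctr[2] + f * (loop[, 2] - ctr[2])
  }

  cells <- vector("list", n_r * n_loop)
  ci <- 0L
  for (l in seq_len(n_loop)) {           # innermost triangle ring
    ci <- ci + 1L
    cells[[ci]] <- c(1L, nid(1, l), nid(1, l + 1))
  }
  for (k in 2:n_r) {
    for (l in seq_len(n_loop)) {
      ci <- ci + 1L
      cells[[ci]] <- c(nid(k - 1, l), nid(k, l), nid(k, l + 1),
                       nid(k - 1, l + 1))
    }
  }
  chamber_cells <- seq_len(ci)

  # Boundary classification by construction: outer-ring loop edges.
  loop_edge_key <- function(l) {
    p <- sort(c(nid(n_r, l), nid(n_r, l + 1)))
    paste(p[1], p[2])
  }
  bnd_type <- new.env(parent = emptyenv())
  bnd_seg <- new.env(parent = emptyenv())
  for (l in seq_len(n_loop)) {
    ty <- if (l <= geom$n_seg) "wall" else "base"
    assign(loop_edge_key(l), ty, envir = bnd_type)
    if (ty == "wall") assign(loop_edge_key(l), l, envir = bnd_seg)
  }

  # Port tubes.
  port_cells <- integer(0)
  mitral_cells <- integer(0)
  aortic_cells <- integer(0)
  cell_region <- rep(0L, length(cells))   # 0 chamber, 1 inlet, 2 outlet
  if (geom$ports) {
    base_ids <- nid(n_r, n_wall:(n_loop + 1L))  # +R corner .. base .. -R corner
    base_x <- nodes[base_ids, 1]
    for (which_port in 1:2) {
      span <- if (which_port == 1) geom$inlet_span else geom$outlet_span
      width <- diff(span)
      tube_len <- 4 * width
      sel <- which(base_x >= span[1] - 1e-12 & base_x <= span[2] + 1e-12)
      cols <- base_ids[sel][order(base_x[sel])]     # bottom row, x ascending
      ncol_p <- length(cols)
      ys <- seg_breaks(0, tube_len, port_ax_coarsen * h_wall, n_min = 4L)
      n_ax <- length(ys) - 1
      colx <- nodes[cols, 1]
      # new nodes for rows 1..n_ax
      newid <- matrix(0L, nrow = n_ax + 1, ncol = ncol_p)
      newid[1, ] <- cols
      for (j in seq_len(n_ax)) {
        ids <- nrow(nodes) + seq_len(ncol_p)
        nodes <- rbind(nodes, cbind(colx, ys[j + 1]))
        newid[j + 1, ] <- ids
      }
      zone <- integer(0)
      for (j in seq_len(n_ax)) {
        for (c2 in seq_len(ncol_p - 1)) {
          ci <- ci + 1L
          cells[[ci]] <- c(newid[j, c2], newid[j, c2 + 1],
                           newid[j + 1, c2 + 1], newid[j + 1, c2])
          port_cells <- c(port_cells, ci)
          cell_region[ci] <- which_port
          ymid <- (ys[j] + ys[j + 1]) / 2
          if (ymid <= geom$valve_zone_depth) zone <- c(zone, ci)
        }
      }
      if (which_port == 1) mitral_cells <- zone else aortic_cells <- zone
      # classify tube boundary edges
      topty <- if (which_port == 1) "inlet" else "outlet"
      for (c2 in seq_len(ncol_p - 1)) {
        p <- sort(c(newid[n_ax + 1, c2], newid[n_ax + 1, c2 + 1]))
        assign(paste(p[1], p[2]), topty, envir = bnd_type)
      }
      for (j in seq_len(n_ax)) {
        for (cc in c(1L, ncol_p)) {
          p <- sort(c(newid[j, cc], newid[j + 1, cc]))
          assign(paste(p[1], p[2]), "port_wall", envir = bnd_type)
        }
      }
    }
  }
  cell_region <- cell_region[seq_along(cells)]

  mesh <- finalize_mesh(nodes, cells, bnd_type, bnd_seg)
  mesh$n_r <- as.integer(n_r)
  mesh$n_theta <- as.integer(n_loop)
  mesh$chamber_cells <- chamber_cells
  mesh$port_cells <- port_cells
  mesh$mitral_cells <- mitral_cells
  mesh$aortic_cells <- aortic_cells
  mesh$cell_region <- cell_region
  mesh$wall_nodes <- nid(n_r, seq_len(n_wall))  # matches geometry nodes
  mesh$geom <- geom
  gm <- mesh_geometry(mesh, mesh$nodes0)
  if (any(gm$vol <= 0)) {
    stop("mesh error: non-positive cell volume at cell ",
         which(gm$vol <= 0)[1])
  }
  mesh
}

# Assemble face tables from cell node loops; classify boundary faces
# from the `bnd_type` environment (keyed by sorted node pairs).
finalize_mesh <- function(nodes, cells, bnd_type, bnd_seg) {
  ncell <- length(cells)
  ce_cell <- integer(0); ce_a <- integer(0); ce_b <- integer(0)
  nv <- lengths(cells)
  ce_cell <- rep.int(seq_len(ncell), nv)
  ce_a <- unlist(cells, use.names = FALSE)
  ce_b <- unlist(lapply(cells, function(v) c(v[-1], v[1])),
                 use.names = FALSE)
  key <- paste(pmin(ce_a, ce_b), pmax(ce_a, ce_b))
  first <- !duplicated(key)
  fidx <- match(key, key[first])          # face id per cell-edge
  nface <- sum(first)
  f_n1 <- ce_a[first]; f_n2 <- ce_b[first]
  f_owner <- ce_cell[first]
  f_neigh <- integer(nface)
  dup <- which(!first)
  f_neigh[fidx[dup]] <- ce_cell[dup]
  f_btype <- rep(BTYPE[["interior"]], nface)
  f_wallseg <- integer(nface)
  bnd <- which(f_neigh == 0L)
  for (fi in bnd) {
    k <- paste(min(f_n1[fi], f_n2[fi]), max(f_n1[fi], f_n2[fi]))
    ty <- if (exists(k, envir = bnd_type, inherits = FALSE)) {
      get(k, envir = bnd_type)
    } else "wall"
    f_btype[fi] <- BTYPE[[ty]]
    if (ty == "wall" && exists(k, envir = bnd_seg, inherits = FALSE)) {
      f_wallseg[fi] <- get(k, envir = bnd_seg)
    }
  }
  structure(list(
    nodes0 = nodes, cells = cells, ncell = ncell, nface = nface,
    ce_cell = ce_cell, ce_a = ce_a, ce_b = ce_b, ce_face = fidx,
    ce_sign = ifelse(first, 1, -1),
    f_n1 = f_n1, f_n2 = f_n2, f_owner = f_owner, f_neigh = f_neigh,
    f_btype = f_btype, f_wallseg = f_wallseg,
    cache = new.env(parent = emptyenv())
  ), class = "fluid_mesh")
}

#' @export
print.fluid_mesh <- function(x, ...) {
  cat("fluid_mesh:", x$ncell, "cells,", x$nface, "faces",
      if (length(x$port_cells)) sprintf("(%d chamber, %d port)",
                                        length(x$chamber_cells),
                                        length(x$port_cells)) else "",
      "\n")
  invisible(x)
}

#' Metric quantities of a (possibly deformed) mesh
#'
#' @param mesh a `fluid_mesh`.
#' @param nodes node coordinate matrix (defaults to the reference
#'   configuration `mesh$nodes0`).
#' @return List with cell volumes `vol` (m^3 per unit depth), cell
#'   centroids `cx`, `cy`, face area vectors `Sx`, `Sy` (outward from the
#'   owner, |S| = face length), face centers `fx`, `fy`, and
#'   owner-to-neighbour distances `dPN`.
#' @export
mesh_geometry <- function(mesh, nodes = mesh$nodes0) {
  xa <- nodes[mesh$ce_a, 1]; ya <- nodes[mesh$ce_a, 2]
  xb <- nodes[mesh$ce_b, 1]; yb <- nodes[mesh$ce_b, 2]
  cr <- xa * yb - xb * ya
  vol <- 0.5 * as.numeric(rowsum(cr, mesh$ce_cell))
  cx <- as.numeric(rowsum((xa + xb) * cr, mesh$ce_cell)) / (6 * vol)
  cy <- as.numeric(rowsum((ya + yb) * cr, mesh$ce_cell)) / (6 * vol)
  x1 <- nodes[mesh$f_n1, 1]; y1 <- nodes[mesh$f_n1, 2]
  x2 <- nodes[mesh$f_n2, 1]; y2 <- nodes[mesh$f_n2, 2]
  Sx <- y2 - y1; Sy <- -(x2 - x1)
  fx <- (x1 + x2) / 2; fy <- (y1 + y2) / 2
  bnd <- mesh$f_neigh == 0L
  nx <- ifelse(bnd, fx, cx[pmax(mesh$f_neigh, 1L)])
  ny <- ifelse(bnd, fy, cy[pmax(mesh$f_neigh, 1L)])
  dPN <- sqrt((nx - cx[mesh$f_owner])^2 + (ny - cy[mesh$f_owner])^2)
  list(vol = vol, cx = cx, cy = cy, Sx = Sx, Sy = Sy, fx = fx, fy = fy,
       dPN = dPN)
}

# Outward swept volume per face between two node configurations,
# divided by dt this is the mesh-flux entering the ALE convective term.
# Summed over the faces of a cell it reproduces the cell volume change
# exactly (discrete geometric conservation law).
face_swept_volume <- function(mesh, nodes_old, nodes_new) {
  a0x <- nodes_old[mesh$f_n1, 1]; a0y <- nodes_old[mesh$f_n1, 2]
  b0x <- nodes_old[mesh$f_n2, 1]; b0y <- nodes_old[mesh$f_n2, 2]
  a1x <- nodes_new[mesh$f_n1, 1]; a1y <- nodes_new[mesh$f_n1, 2]
  b1x <- nodes_new[mesh$f_n2, 1]; b1y <- nodes_new[mesh$f_n2, 2]
  q <- 0.5 * ((a0x * b0y - b0x * a0y) + (b0x * b1y - b1x * b0y) +
              (b1x * a1y - a1x * b1y) + (a1x * a0y - a0x * a1y))
  -q
}

# Divergence accumulator: sum over each cell of signed face values.
cell_div <- function(mesh, face_vals) {
  out <- numeric(mesh$ncell)
  o <- rowsum(face_vals, mesh$f_owner, reorder = FALSE)
  out[as.integer(rownames(o))] <- o
  int <- mesh$f_neigh > 0L
  if (any(int)) {
    nb <- rowsum(face_vals[int], mesh$f_neigh[int], reorder = FALSE)
    idx <- as.integer(rownames(nb))
    out[idx] <- out[idx] - nb
  }
  out
}

# --- mesh motion -----------------------------------------------------------

mesh_motion_operator <- function(mesh, delta_floor = 1e-3) {
  cache <- mesh$cache
  if (!is.null(cache$motion)) return(cache$motion)
  nn <- nrow(mesh$nodes0)
  wall <- mesh$wall_nodes
  # Dirichlet set: every boundary node plus all port-tube nodes (rigid
  # tubes); wall nodes receive the prescribed displacement, the rest 0.
  bnd_nodes <- unique(c(mesh$f_n1[mesh$f_btype != 0L],
                        mesh$f_n2[mesh$f_btype != 0L]))
  port_nodes <- unique(unlist(mesh$cells[mesh$port_cells],
                              use.names = FALSE))
  dir_nodes <- sort(unique(c(bnd_nodes, port_nodes)))
  interior <- setdiff(seq_len(nn), dir_nodes)
  # inverse-squared wall distance diffusivity with a floor
  d2wall <- function(p) {
    w <- mesh$nodes0[wall, , drop = FALSE]
    apply(p, 1, function(q) sqrt(min((w[, 1] - q[1])^2 +
                                       (w[, 2] - q[2])^2)))
  }
  delta <- d2wall(mesh$nodes0)
  gam <- 1 / pmax(delta, delta_floor)^2
  e1 <- mesh$f_n1; e2 <- mesh$f_n2
  w <- (gam[e1] + gam[e2]) / 2
  L <- Matrix::sparseMatrix(
    i = c(e1, e2, e1, e2), j = c(e2, e1, e1, e2),
    x = c(-w, -w, w, w), dims = c(nn, nn))
  Lii <- L[interior, interior, drop = FALSE]
  Lib <- L[interior, dir_nodes, drop = FALSE]
  op <- list(interior = interior, dir_nodes = dir_nodes,
             chol = Matrix::Cholesky(Matrix::forceSymmetric(Lii)),
             Lib = Lib, nn = nn)
  cache$motion <- op
  op
}

#' Solve the mesh-motion Laplace problem
#'
#' Interior node displacement solves a graph Laplace equation with
#' diffusivity `gamma = max(delta, delta_floor)^-2`, where `delta` is
#' the reference distance to the moving endocardial wall; this stiffens
#' the near-wall region so that cells next to the wall translate almost
#' rigidly. All boundary nodes and all port-tube nodes are Dirichlet:
#' wall nodes take the prescribed displacement, every other constrained
#' node is held fixed. The operator is factorized once per mesh and
#' reused, so the solve is a pair of triangular substitutions and is
#' exactly linear in the boundary data.
#'
#' @param mesh a `fluid_mesh` from [build_grid()].
#' @param wall_displacement matrix `(n_wall_nodes x 2)` of wall node
#'   displacements in m (same order as the geometry wall nodes).
#' @param prev_displacement optional previous full displacement field;
#'   with `dt` it yields the node velocity.
#' @param dt time increment in s for the velocity (optional).
#' @param delta_floor distance floor in m for the diffusivity (default
#'   1 mm).
#' @return List with `displacement` (n_nodes x 2), `nodes` (displaced
#'   coordinates) and, if `prev_displacement` and `dt` are given,
#'   `velocity` (n_nodes x 2, m/s). A tangled result (non-positive cell
#'   volume) raises a mesh error naming the first offending cell.
#' @export
solve_mesh_motion <- function(mesh, wall_displacement,
                              prev_displacement = NULL, dt = NULL,
                              delta_floor = 1e-3, check_tangle = TRUE) {
  wall_displacement <- as.matrix(wall_displacement)
  stopifnot(nrow(wall_displacement) == length(mesh$wall_nodes),
            all(is.finite(wall_displacement)))
  op <- mesh_motion_operator(mesh, delta_floor)
  nn <- op$nn
  disp <- matrix(0, nn, 2)
  disp[mesh$wall_nodes, ] <- wall_displacement
  db <- disp[op$dir_nodes, , drop = FALSE]
  rhs <- -op$Lib %*% db
  di <- Matrix::solve(op$chol, rhs, system = "A")
  disp[op$interior, ] <- as.matrix(di)
  nodes <- mesh$nodes0 + disp
  if (check_tangle) {
    vol <- mesh_geometry(mesh, nodes)$vol
    if (any(vol <= 0)) {
      stop("mesh error: motion tangles the mesh at cell ",
           which(vol <= 0)[1])
    }
  }
  out <- list(displacement = disp, nodes = nodes)
  if (!is.null(prev_displacement) && !is.null(dt)) {
    out$velocity <- (disp - prev_displacement) / dt
  }
  out
}

#' Build a rectangular channel mesh
#'
#' Structured quad grid on `[0, Lx] x [0, Ly]` used for solver
#' verification (Poiseuille flow, free-stream preservation, scalar
#' transport). The `x = 0` side is an `inlet` boundary, `x = Lx` an
#' `outlet`; the lateral sides are `wall` by default or slip-free
#' `base`-tagged boundaries with `slip_walls = TRUE` (the solver applies
#' no viscous drag on `base` faces).
#'
#' @param nx,ny number of cells along / across the channel.
#' @param Lx,Ly channel length / height in m.
#' @param slip_walls logical; tag lateral boundaries as frictionless.
#' @param closed logical; tag the two ends as walls instead of
#'   inlet/outlet (a sealed box, used for conservation checks).
#' @param porous optional list `list(x0=, x1=)` marking cells with
#'   centroid x in `[x0, x1]` as a porous valve zone (`mitral_cells`).
#' @return A `fluid_mesh`.
#' @export
build_channel_mesh <- function(nx, ny, Lx, Ly, slip_walls = FALSE,
                               closed = FALSE, porous = NULL) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  cells <- vector("list", nx * ny)
  ci <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      ci <- ci + 1L
      cells[[ci]] <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1),
                       nid(i, j + 1))
    }
  }
  bnd_type <- new.env(parent = emptyenv())
  bnd_seg <- new.env(parent = emptyenv())
  side <- if (slip_walls) "base" else "wall"
  for (i in seq_len(nx)) {
    p <- sort(c(nid(i, 1), nid(i + 1, 1)))
    assign(paste(p[1], p[2]), side, envir = bnd_type)
    p <- sort(c(nid(i, ny + 1), nid(i + 1, ny + 1)))
    assign(paste(p[1], p[2]), side, envir = bnd_type)
  }
  endty <- c(if (closed) "wall" else "inlet",
             if (closed) "wall" else "outlet")
  for (j in seq_len(ny)) {
    p <- sort(c(nid(1, j), nid(1, j + 1)))
    assign(paste(p[1], p[2]), endty[1], envir = bnd_type)
    p <- sort(c(nid(nx + 1, j), nid(nx + 1, j + 1)))
    assign(paste(p[1], p[2]), endty[2], envir = bnd_type)
  }
  mesh <- finalize_mesh(nodes, cells, bnd_type, bnd_seg)
  mesh$n_r <- as.integer(ny); mesh$n_theta <- as.integer(nx)
  mesh$chamber_cells <- seq_len(mesh$ncell)
  mesh$port_cells <- integer(0)
  mesh$mitral_cells <- integer(0)
  mesh$aortic_cells <- integer(0)
  if (!is.null(porous)) {
    gm <- mesh_geometry(mesh)
    mesh$mitral_cells <- which(gm$cx >= porous$x0 & gm$cx <= porous$x1)
  }
  mesh$cell_region <- rep(0L, mesh$ncell)
  mesh$wall_nodes <- integer(0)
  mesh
}
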