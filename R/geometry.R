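# Idealized 2D chamber geometry: a half-ellipse left ventricle (base at
# y = 0, apex at y = -L) with two straight port tubes (mitral inlet,
# aortic outlet) attached at the base. All lengths in m; "volumes" are
# areas times a unit depth of 1 m.

#' Create an idealized chamber geometry
#'
#' The endocardial wall is a half-ellipse parameterized by `theta` in
#' `[0, pi]`: node positions are `(-R cos(theta), -L sin(theta))`, so the
#' wall runs from the left base corner `(-R, 0)` through the apex
#' `(0, -L)` to the right base corner `(R, 0)`. Each wall node carries a
#' reference radius `r0` (distance from the base center) and a fixed unit
#' radial direction; wall kinematics are radial about the base center,
#' which keeps the two base corners on the base plane. Two straight port
#' tubes (length four times their width) extend upward from the base
#' over the `inlet_span` (mitral) and `outlet_span` (aortic) intervals.
#'
#' @param n_seg number of wall segments (>= 16); the wall has
#'   `n_seg + 1` nodes.
#' @param radius base half-width R in m.
#' @param length apex depth L in m.
#' @param h0 reference wall thickness in m.
#' @param inlet_span,outlet_span disjoint x-intervals on the base
#'   (length-2 vectors, m) where the mitral / aortic port tubes attach.
#' @param valve_zone_depth extent of the porous valve zone into each
#'   port tube, in m.
#' @param ports logical; `FALSE` builds a closed chamber without port
#'   tubes (used for closed-form volume checks).
#' @return An object of class `"chamber_geometry"`.
#' @export
make_chamber <- function(n_seg = 64, radius = 0.025, length = 0.07,
                         h0 = 0.01,
                         inlet_span = c(-0.0185, -0.0035),
                         outlet_span = c(0.0035, 0.0135),
                         valve_zone_depth = 0.005,
                         ports = TRUE) {
  if (n_seg < 16) stop("configuration error: n_seg must be >= 16")
  stopifnot(radius > 0, length > 0, h0 > 0, valve_zone_depth > 0)
  theta <- seq(0, pi, length.out = n_seg + 1)
  nodes <- cbind(x = -radius * cos(theta), y = -length * sin(theta))
  r0 <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  e_r <- nodes / r0  # unit radial direction about the base center
  if (ports) {
    inlet_span <- sort(as.numeric(inlet_span))
    outlet_span <- sort(as.numeric(outlet_span))
    spans <- rbind(inlet_span, outlet_span)
    if (any(spans <= -radius) || any(spans >= radius)) {
      stop("configuration error: port spans must lie inside (-R, R)")
    }
    if (max(inlet_span[1], outlet_span[1]) <
        min(inlet_span[2], outlet_span[2])) {
      stop("configuration error: inlet and outlet port spans overlap")
    }
  } else {
    inlet_span <- outlet_span <- NULL
  }
  structure(list(
    n_seg = as.integer(n_seg), theta = theta, r0 = r0, e_r = e_r,
    nodes = nodes, h0 = h0, base_y = 0,
    radius = radius, length = length,
    inlet_span = inlet_span, outlet_span = outlet_span,
    valve_zone_depth = valve_zone_depth, ports = ports
  ), class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("chamber_geometry: half-ellipse R =", x$radius, "m, L =", x$length,
      "m,", x$n_seg, "wall segments,",
      if (x$ports) "with port tubes\n" else "no ports\n")
  invisible(x)
}

# Signed shoelace area of an (n x 2) coordinate matrix (closed implicitly).
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  0.5 * sum(x * ys - xs * y)
}

# O(n^2) proper-crossing test between non-adjacent polygon edges.
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip adjacent (wrap) edge
    if (!length(j)) next
    d1 <- cross2(b[i, 1] - a[i, 1], b[i, 2] - a[i, 2],
                 a[j, 1] - a[i, 1], a[j, 2] - a[i, 2])
    d2 <- cross2(b[i, 1] - a[i, 1], b[i, 2] - a[i, 2],
                 b[j, 1] - a[i, 1], b[j, 2] - a[i, 2])
    d3 <- cross2(b[j, 1] - a[j, 1], b[j, 2] - a[j, 2],
                 a[i, 1] - a[j, 1], a[i, 2] - a[j, 2])
    d4 <- cross2(b[j, 1] - a[j, 1], b[j, 2] - a[j, 2],
                 b[i, 1] - a[j, 1], b[i, 2] - a[j, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Enclosed chamber volume from wall node coordinates
#'
#' Shoelace area of the wall polygon (closed by the straight base
#' segment between its two end nodes) times a unit depth of 1 m.
#'
#' @param node_xy (n x 2) matrix of wall node coordinates in m, ordered
#'   along the wall.
#' @param check if `TRUE`, raise a geometry error for a self-intersecting
#'   polygon (skipped in solver inner loops).
#' @return Enclosed volume in m^3 (per metre depth).
#' @export
chamber_volume <- function(node_xy, check = TRUE) {
  node_xy <- as.matrix(node_xy)
  if (check && polygon_self_intersects(node_xy)) {
    stop("geometry error: wall polygon is self-intersecting")
  }
  a <- shoelace_area(node_xy)
  if (check && a <= 0) stop("geometry error: non-positive enclosed area")
  a
}
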