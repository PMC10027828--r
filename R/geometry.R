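# Idealized 2D aneurysm geometry and triangulation.
#
# The domain is a straight parent-vessel channel of height D (the vessel
# diameter) with a circular-bulge side-wall sac attached to the upper
# wall through a neck.  The sac is the major segment of a circle of
# diameter `dome_diameter` cut by the neck chord of width `neck_width`
# lying on the vessel wall.  The channel is meshed with a graded
# structured grid (boundary-layer rows at both walls); the sac with
# concentric rings shrunk toward the circle center, graded the same way
# at the sac wall, conforming with the channel nodes along the neck.

#' Geometry parameters for the idealized aneurysm
#'
#' All lengths in meters.
#'
#' @param vessel_diameter Parent-vessel (channel) height, m.
#' @param vessel_length Channel length, m.
#' @param dome_diameter Diameter of the sac circle, m; must exceed
#'   `neck_width`.
#' @param neck_width Width of the neck chord on the vessel wall, m.
#' @param sac_stand_off Position of the neck center along the vessel, m.
#' @param mesh_size Target element edge length, m.
#' @param boundary_layer_layers Number of graded wall-adjacent element
#'   rows on vessel and sac walls.
#' @param boundary_layer_growth Growth ratio between successive
#'   boundary-layer rows (`>= 1`).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(vessel_diameter = 3e-3,
                            vessel_length = 20e-3,
                            dome_diameter = 5e-3,
                            neck_width = 2.5e-3,
                            sac_stand_off = 10e-3,
                            mesh_size = 2e-4,
                            boundary_layer_layers = 3L,
                            boundary_layer_growth = 1.3) {
  lens <- c(vessel_diameter = vessel_diameter, vessel_length = vessel_length,
            dome_diameter = dome_diameter, neck_width = neck_width,
            sac_stand_off = sac_stand_off, mesh_size = mesh_size)
  bad <- names(lens)[!(is.finite(lens) & lens > 0)]
  if (length(bad))
    stop("geometry lengths must be positive: ", paste(bad, collapse = ", "))
  if (neck_width >= dome_diameter)
    stop(sprintf("neck_width (%.3g m) must be smaller than dome_diameter (%.3g m)",
                 neck_width, dome_diameter))
  if (neck_width >= vessel_length)
    stop("neck_width must be smaller than vessel_length")
  if (boundary_layer_growth < 1)
    stop("boundary_layer_growth must be >= 1")
  if (sac_stand_off - neck_width / 2 <= 0 ||
      sac_stand_off + neck_width / 2 >= vessel_length)
    stop("neck chord must lie strictly inside the vessel length")
  structure(list(vessel_diameter = vessel_diameter,
                 vessel_length = vessel_length,
                 dome_diameter = dome_diameter,
                 neck_width = neck_width,
                 sac_stand_off = sac_stand_off,
                 mesh_size = mesh_size,
                 boundary_layer_layers = as.integer(boundary_layer_layers),
                 boundary_layer_growth = boundary_layer_growth),
            class = "geometry_params")
}

# 1D grid over [0, len] with boundary-layer grading at one or both ends.
# Wall-adjacent spacing is mesh_size / growth^layers, growing geometrically
# to ~mesh_size, then uniform cells of ~mesh_size in the interior.
.graded_grid <- function(len, mesh_size, layers, growth,
                         bl_start = TRUE, bl_end = TRUE) {
  bl <- if (layers > 0 && growth > 1)
    mesh_size * growth^(seq_len(layers) - layers) else numeric(0)
  # shrink boundary layers if they would consume the interval
  while (length(bl) && (sum(bl) * (bl_start + bl_end)) > 0.45 * len)
    bl <- bl[-1L]
  start_off <- if (bl_start) cumsum(bl) else numeric(0)
  end_off <- if (bl_end) cumsum(bl) else numeric(0)
  inner <- len - sum(start_off[length(start_off)], 0) -
    sum(end_off[length(end_off)], 0)
  lo <- if (length(start_off)) max(start_off) else 0
  hi <- len - (if (length(end_off)) max(end_off) else 0)
  n_mid <- max(1L, round((hi - lo) / mesh_size))
  mid <- seq(lo, hi, length.out = n_mid + 1L)
  sort(unique(c(0, start_off, mid, len - end_off, len)))
}

# Structured triangulation of [0,len] x [0,height] given explicit grid
# lines.  Returns nodes, triangles (CCW).
.channel_triangulation <- function(xg, yg) {
  nx <- length(xg); ny <- length(yg)
  nodes <- cbind(rep(xg, times = ny), rep(yg, each = nx))
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      k <- k + 1L
      # union-jack alternation for isotropy
      tris[[k]] <- if ((i + j) %% 2L == 0L)
        rbind(c(a, b, c), c(a, c, d)) else rbind(c(a, b, d), c(b, c, d))
    }
  }
  list(nodes = nodes, tri = do.call(rbind, tris))
}

#' Build the idealized aneurysm mesh
#'
#' Triangulates the channel-plus-sac domain described by
#' [geometry_params()].  Cell regions are tagged `LUMEN` (vessel) and
#' `SAC` (bulge beyond the neck line); boundary edges are tagged `INLET`
#' (x = 0), `OUTLET` (x = vessel_length), `WALL_VESSEL` and `WALL_SAC`.
#'
#' @param params A [geometry_params()] object.
#' @return An object of class `aneu_mesh`: list with `nodes` (n x 2
#'   matrix, m), `tri` (m x 3 connectivity, counterclockwise), `region`
#'   (character per triangle), `boundary` (data frame `n1`, `n2`, `tri`,
#'   `tag`; edge directed as in the owning triangle so the outward normal
#'   is `(dy, -dx)`).
#' @export
build_idealized_geometry <- function(params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  p <- params
  D <- p$vessel_diameter; L <- p$vessel_length
  R <- p$dome_diameter / 2; w <- p$neck_width / 2
  x0 <- p$sac_stand_off
  d0 <- sqrt(R^2 - w^2)            # center height above the wall
  C <- c(x0, D + d0)
  hs <- p$mesh_size

  xL <- x0 - w; xR <- x0 + w
  n_seg <- function(len) max(1L, round(len / hs))
  xg <- sort(unique(c(
    seq(0, xL, length.out = n_seg(xL) + 1L),
    seq(xL, xR, length.out = max(4L, n_seg(2 * w)) + 1L),
    seq(xR, L, length.out = n_seg(L - xR) + 1L))))
  yg <- .graded_grid(D, hs, p$boundary_layer_layers, p$boundary_layer_growth)

  ch <- .channel_triangulation(xg, yg)
  nodes <- ch$nodes; tri <- ch$tri
  region <- rep("LUMEN", nrow(tri))

  ## ---- sac: boundary loop = chord nodes (shared) + arc nodes ----
  top_row <- which(abs(nodes[, 2] - D) < 1e-12 * max(D, 1e-9))
  chord_sel <- top_row[nodes[top_row, 1] >= xL - 1e-15 &
                         nodes[top_row, 1] <= xR + 1e-15]
  chord_idx <- chord_sel[order(nodes[chord_sel, 1])]  # left -> right
  if (length(chord_idx) < 3L)
    stop("degenerate neck discretization; decrease mesh_size")

  thR <- atan2(-d0, w)              # angle of right neck endpoint
  thL <- atan2(-d0, -w) + 2 * pi    # left endpoint, reached CCW over the top
  n_arc <- max(8L, round(R * (thL - thR) / hs))
  th <- seq(thR, thL, length.out = n_arc + 1L)
  arc_int <- th[-c(1L, length(th))]          # interior arc nodes
  arc_xy <- cbind(C[1] + R * cos(arc_int), C[2] + R * sin(arc_int))

  n0 <- nrow(nodes)
  nodes <- rbind(nodes, arc_xy)
  loop <- c(chord_idx, n0 + seq_len(nrow(arc_xy)))  # CCW closed loop
  N <- length(loop)

  ## radial ring fractions (1 = boundary, toward 0 = center)
  bl <- if (p$boundary_layer_layers > 0 && p$boundary_layer_growth > 1)
    hs * p$boundary_layer_growth^(seq_len(p$boundary_layer_layers) -
                                    p$boundary_layer_layers) else numeric(0)
  while (length(bl) && sum(bl) > 0.4 * d0) bl <- bl[-1L]
  rho_bl <- 1 - cumsum(bl) / R
  rho_in <- min(rho_bl, 1)
  rho_stop <- max(0.9 * hs / R, 0.05)
  n_mid <- max(1L, round((rho_in - rho_stop) * R / hs))
  rho <- c(1, rho_bl, seq(rho_in, rho_stop, length.out = n_mid + 1L)[-1L])
  rho <- rho[rho > 0]

  ring_prev <- loop
  sac_tri <- list()
  for (k in seq_along(rho)[-1L]) {
    new_xy <- cbind(C[1] + rho[k] * (nodes[loop, 1] - C[1]),
                    C[2] + rho[k] * (nodes[loop, 2] - C[2]))
    base <- nrow(nodes)
    nodes <- rbind(nodes, new_xy)
    ring_new <- base + seq_len(N)
    ip1 <- c(seq_len(N)[-1L], 1L)
    sac_tri[[length(sac_tri) + 1L]] <-
      rbind(cbind(ring_prev, ring_prev[ip1], ring_new),
            cbind(ring_prev[ip1], ring_new[ip1], ring_new))
    ring_prev <- ring_new
  }
  cbase <- nrow(nodes)
  nodes <- rbind(nodes, matrix(C, 1L))
  ip1 <- c(seq_len(N)[-1L], 1L)
  sac_tri[[length(sac_tri) + 1L]] <-
    cbind(ring_prev, ring_prev[ip1], rep(cbase + 1L, N))
  sac_tri <- do.call(rbind, sac_tri)

  tri <- rbind(tri, sac_tri)
  region <- c(region, rep("SAC", nrow(sac_tri)))

  ## enforce CCW orientation
  a <- .tri_signed_area(nodes, tri)
  if (any(abs(a) < 1e-18))
    stop("meshing failure: degenerate (zero-area) triangle produced; ",
         "adjust mesh_size relative to the geometry")
  flip <- a < 0
  tri[flip, ] <- tri[flip, c(1L, 3L, 2L)]

  mesh <- .finalize_mesh(nodes, tri, region, function(mx, my) {
    tol <- 1e-9 * max(L, D)
    ifelse(mx < tol, "INLET",
      ifelse(mx > L - tol, "OUTLET",
        ifelse(my > D + tol, "WALL_SAC", "WALL_VESSEL")))
  })
  attr(mesh, "params") <- p
  attr(mesh, "sac_area_analytic") <- pi * R^2 - (R^2 * acos(d0 / R) - d0 * w)
  mesh
}

#' Build a plain channel mesh
#'
#' Straight 2D channel without a sac, used for verification against
#' closed-form channel flows (Poiseuille, Casson, porous slab).  Walls
#' are tagged `WALL_VESSEL`; set `region` to `"SAC"` to make the whole
#' channel a porous slab.
#'
#' @param length,height Channel dimensions, m.
#' @param mesh_size Target element size, m.
#' @param boundary_layer_layers,boundary_layer_growth Wall grading as in
#'   [geometry_params()].
#' @param region Region tag applied to every cell, `"LUMEN"` or `"SAC"`.
#' @return An `aneu_mesh`.
#' @export
build_channel_mesh <- function(length, height, mesh_size,
                               boundary_layer_layers = 0L,
                               boundary_layer_growth = 1.3,
                               region = "LUMEN") {
  stopifnot(length > 0, height > 0, mesh_size > 0,
            region %in% c("LUMEN", "SAC"))
  xg <- seq(0, length, length.out = max(1L, round(length / mesh_size)) + 1L)
  yg <- .graded_grid(height, mesh_size, boundary_layer_layers,
                     boundary_layer_growth)
  ch <- .channel_triangulation(xg, yg)
  a <- .tri_signed_area(ch$nodes, ch$tri)
  tri <- ch$tri
  tri[a < 0, ] <- tri[a < 0, c(1L, 3L, 2L)]
  .finalize_mesh(ch$nodes, tri, rep(region, nrow(tri)), function(mx, my) {
    tol <- 1e-9 * max(length, height)
    ifelse(mx < tol, "INLET", ifelse(mx > length - tol, "OUTLET",
                                     "WALL_VESSEL"))
  })
}

.tri_signed_area <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# Identify boundary edges (undirected edges in exactly one triangle),
# keep the direction they have in the owning CCW triangle, tag by a
# midpoint classifier, and assemble the aneu_mesh object.
.finalize_mesh <- function(nodes, tri, region, classify) {
  m <- nrow(tri)
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  owner <- rep.int(seq_len(m), 3L)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two triangles")
  is_b <- cnt[key] == 1L
  be <- e[is_b, , drop = FALSE]
  bo <- owner[is_b]
  mx <- (nodes[be[, 1], 1] + nodes[be[, 2], 1]) / 2
  my <- (nodes[be[, 1], 2] + nodes[be[, 2], 2]) / 2
  tags <- classify(mx, my)
  boundary <- data.frame(n1 = be[, 1], n2 = be[, 2], tri = bo, tag = tags,
                         stringsAsFactors = FALSE)
  structure(list(nodes = unname(nodes), tri = unname(tri),
                 region = region, boundary = boundary),
            class = "aneu_mesh")
}

#' Validate mesh structural invariants
#'
#' Checks positive orientation, that every boundary edge belongs to
#' exactly one triangle (by construction), that boundary tags partition
#' the boundary, that `SAC` cells form a single edge-connected component
#' touching `WALL_SAC`, and that all required tags are present.
#'
#' @param mesh An `aneu_mesh`.
#' @param require_sac Require a SAC region and WALL_SAC tag.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_mesh <- function(mesh, require_sac = TRUE) {
  stopifnot(inherits(mesh, "aneu_mesh"))
  if (any(.tri_signed_area(mesh$nodes, mesh$tri) <= 0))
    stop("mesh has non-positively-oriented triangles")
  tags <- unique(mesh$boundary$tag)
  need <- c("INLET", "OUTLET", "WALL_VESSEL", if (require_sac) "WALL_SAC")
  miss <- setdiff(need, tags)
  if (length(miss))
    stop("mesh is missing boundary tags: ", paste(miss, collapse = ", "))
  unknown <- setdiff(tags, c("INLET", "OUTLET", "WALL_VESSEL", "WALL_SAC"))
  if (length(unknown))
    stop("unknown boundary tags: ", paste(unknown, collapse = ", "))
  if (require_sac) {
    sac <- which(mesh$region == "SAC")
    if (!length(sac)) stop("mesh has no SAC cells")
    # edge-connectivity of the SAC subdomain
    ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
    e <- rbind(mesh$tri[sac, c(1L, 2L)], mesh$tri[sac, c(2L, 3L)],
               mesh$tri[sac, c(3L, 1L)])
    keys <- ekey(e[, 1], e[, 2])
    owner <- rep.int(seq_along(sac), 3L)
    sp <- split(owner, keys)
    adj <- lapply(seq_along(sac), function(i) integer(0))
    for (o in sp[lengths(sp) == 2L]) {
      adj[[o[1]]] <- c(adj[[o[1]]], o[2]); adj[[o[2]]] <- c(adj[[o[2]]], o[1])
    }
    seen <- logical(length(sac)); stack <- 1L; seen[1L] <- TRUE
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      nb <- adj[[cur]][!seen[adj[[cur]]]]
      seen[nb] <- TRUE; stack <- c(stack, nb)
    }
    if (!all(seen)) stop("SAC region is not edge-connected")
    sac_wall_tris <- mesh$boundary$tri[mesh$boundary$tag == "WALL_SAC"]
    if (!any(sac_wall_tris %in% sac))
      stop("SAC region is not adjacent to WALL_SAC")
  }
  invisible(TRUE)
}

#' Measured area of a tagged cell region
#'
#' @param mesh An `aneu_mesh`.
#' @param region Region tag, `"SAC"` or `"LUMEN"`.
#' @return Total area of the region's triangles, m^2.
#' @export
region_area <- function(mesh, region = "SAC") {
  sel <- mesh$region == region
  if (!any(sel)) stop("region not present: ", region)
  sum(.tri_signed_area(mesh$nodes, mesh$tri[sel, , drop = FALSE]))
}

#' @export
print.aneu_mesh <- function(x, ...) {
  cat(sprintf("aneu_mesh: %d nodes, %d triangles (%d SAC), %d boundary edges\n",
              nrow(x$nodes), nrow(x$tri), sum(x$region == "SAC"),
              nrow(x$boundary)))
  tb <- table(x$boundary$tag)
  cat("  boundary:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.aneu_mesh <- function(x, ...) {
  graphics::plot(x$nodes, type = "n", asp = 1, xlab = "x (m)", ylab = "y (m)",
                 ...)
  for (r in unique(x$region)) {
    sel <- x$region == r
    col <- if (r == "SAC") grDevices::adjustcolor("tomato", 0.3) else
      grDevices::adjustcolor("steelblue", 0.15)
    tt <- x$tri[sel, , drop = FALSE]
    graphics::polygon(
      x = as.vector(t(cbind(matrix(x$nodes[t(tt), 1], ncol = 3, byrow = TRUE), NA))),
      y = as.vector(t(cbind(matrix(x$nodes[t(tt), 2], ncol = 3, byrow = TRUE), NA))),
      col = col, border = "grey60", lwd = 0.3)
  }
  invisible(x)
}
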