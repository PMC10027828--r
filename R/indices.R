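# Hemodynamic wall indices: WSS, TAWSS, OSI, wall pressure statistics.
#
# Wall shear is the tangential part of the viscous traction
# mu_app (grad u + grad u^T) n on each wall facet, evaluated from the
# P1 element gradient of the facet's owning triangle (consistent with
# the discretization).  TAWSS = (1/T) int ||tau|| dt and
# OSI = 1/2 (1 - ||int tau dt|| / int ||tau|| dt), both by trapezoidal
# quadrature over the stored final cycle.

# Precompute wall-facet data: owning triangle, outward normal, length,
# region and midpoint, in a fixed facet order.
.wall_setup <- function(mesh) {
  bnd <- mesh$boundary
  sel <- grepl("^WALL", bnd$tag)
  w <- bnd[sel, , drop = FALSE]
  ex <- mesh$nodes[w$n2, 1] - mesh$nodes[w$n1, 1]
  ey <- mesh$nodes[w$n2, 2] - mesh$nodes[w$n1, 2]
  len <- sqrt(ex^2 + ey^2)
  data.frame(facet_id = seq_len(nrow(w)), n1 = w$n1, n2 = w$n2, tri = w$tri,
             tag = w$tag, length = len, nx = ey / len, ny = -ex / len,
             x = (mesh$nodes[w$n1, 1] + mesh$nodes[w$n2, 1]) / 2,
             y = (mesh$nodes[w$n1, 2] + mesh$nodes[w$n2, 2]) / 2)
}

# Fast path used inside the time loop: returns n_facets x 2 matrix of
# tangential traction.
.wall_shear_values <- function(wall, fem, u, v, rheology) {
  t_ <- wall$tri
  uE <- matrix(u[fem$mesh$tri[t_, ]], ncol = 3L)
  vE <- matrix(v[fem$mesh$tri[t_, ]], ncol = 3L)
  b <- fem$b[t_, , drop = FALSE]; cc <- fem$c[t_, , drop = FALSE]
  ux <- rowSums(b * uE); uy <- rowSums(cc * uE)
  vx <- rowSums(b * vE); vy <- rowSums(cc * vE)
  mu <- apparent_viscosity(shear_rate_components(ux, uy, vx, vy), rheology)
  nx <- wall$nx; ny <- wall$ny
  tx <- mu * (2 * ux * nx + (uy + vx) * ny)
  ty <- mu * ((uy + vx) * nx + 2 * vy * ny)
  tn <- tx * nx + ty * ny
  # sign: traction exerted by the blood on the wall (for channel flow
  # the bottom-wall shear then points downstream)
  cbind(tn * nx - tx, tn * ny - ty)
}

#' Wall shear stress of a flow state
#'
#' Tangential viscous traction on every wall facet (tags `WALL_VESSEL`
#' and `WALL_SAC`), with the normal component projected out.  The sign
#' convention is the traction exerted by the blood on the wall, so in
#' forward channel flow the wall shear vector points downstream.
#'
#' @param state A `flow_state`.
#' @param mesh The mesh the state lives on.
#' @param rheology A [casson_params()] object.
#' @return Data frame with one row per wall facet: position, region tag,
#'   facet length, shear vector (`tau_x`, `tau_y`, Pa) and magnitude
#'   `wss`.
#' @export
wall_shear <- function(state, mesh, rheology) {
  fem <- .fem_setup(mesh)
  wall <- .wall_setup(mesh)
  tau <- .wall_shear_values(wall, fem, state$u, state$v, rheology)
  cbind(wall[, c("facet_id", "x", "y", "tag", "length", "nx", "ny")],
        data.frame(tau_x = tau[, 1], tau_y = tau[, 2],
                   wss = sqrt(tau[, 1]^2 + tau[, 2]^2)))
}

.trapz_weights <- function(times) {
  nt <- length(times)
  w <- numeric(nt)
  dt <- diff(times)
  w[1] <- dt[1] / 2; w[nt] <- dt[nt - 1] / 2
  if (nt > 2) w[2:(nt - 1)] <- (dt[-1] + dt[-(nt - 1)]) / 2
  w
}

#' Oscillatory shear index of a shear time series
#'
#' \deqn{OSI = \tfrac12\left(1 - \frac{\lVert\int \tau\,dt\rVert}
#'   {\int \lVert\tau\rVert\,dt}\right) \in [0, 0.5]}
#' by trapezoidal quadrature over one cycle.  An identically zero series
#' (stagnant facet) is defined as OSI 0.
#'
#' @param times Sample times, s, strictly increasing, spanning the
#'   cycle.
#' @param tau_x,tau_y Shear vector components at the sample times, Pa.
#'   Matrices (time x facet) are accepted and processed columnwise.
#' @return OSI per facet, dimensionless.
#' @export
osi <- function(times, tau_x, tau_y) {
  tau_x <- as.matrix(tau_x); tau_y <- as.matrix(tau_y)
  stopifnot(length(times) == nrow(tau_x), all(diff(times) > 0),
            all(dim(tau_x) == dim(tau_y)))
  w <- .trapz_weights(times)
  ix <- colSums(w * tau_x); iy <- colSums(w * tau_y)
  imag <- colSums(w * sqrt(tau_x^2 + tau_y^2))
  out <- numeric(ncol(tau_x))
  pos <- imag > 0
  out[pos] <- 0.5 * (1 - sqrt(ix[pos]^2 + iy[pos]^2) / imag[pos])
  pmin(pmax(out, 0), 0.5)
}

#' Time-averaged wall shear stress of a shear series
#'
#' \eqn{TAWSS = (1/T) \int \lVert\tau\rVert dt} by trapezoidal
#' quadrature; always at least the magnitude of the mean shear vector.
#'
#' @inheritParams osi
#' @return TAWSS per facet, Pa.
#' @export
tawss <- function(times, tau_x, tau_y) {
  tau_x <- as.matrix(tau_x); tau_y <- as.matrix(tau_y)
  stopifnot(length(times) == nrow(tau_x), all(diff(times) > 0))
  w <- .trapz_weights(times)
  colSums(w * sqrt(tau_x^2 + tau_y^2)) / (times[length(times)] - times[1])
}

#' Aggregate a per-facet field over a wall region
#'
#' @param values Per-facet values, aligned with `wall_shear()` facet
#'   order.
#' @param mesh The mesh.
#' @param region `"WALL_SAC"` or `"WALL_VESSEL"`.
#' @return Named vector `c(max =, avg =)`; the average is weighted by
#'   facet length (the 2D surrogate of facet area).
#' @export
aggregate_wall <- function(values, mesh, region) {
  wall <- .wall_setup(mesh)
  stopifnot(length(values) == nrow(wall))
  sel <- wall$tag == region
  if (!any(sel)) stop("empty wall region: ", region)
  c(max = max(values[sel]),
    avg = sum(values[sel] * wall$length[sel]) / sum(wall$length[sel]))
}

# Length-weighted pressure statistics on a wall region for one state.
.wall_pressure_stats <- function(state, mesh, region) {
  wall <- .wall_setup(mesh)
  sel <- wall$tag == region
  if (!any(sel)) stop("empty wall region: ", region)
  pf <- (state$p[wall$n1[sel]] + state$p[wall$n2[sel]]) / 2
  len <- wall$length[sel]
  c(max = max(pf), avg = sum(pf * len) / sum(len))
}

#' Hemodynamic indices report of a transient run
#'
#' Computes per-facet TAWSS and OSI from the stored final-cycle shear
#' series, aggregates them over the sac and vessel walls, and extracts
#' wall-pressure statistics at the peak-systole and early-diastole
#' snapshots of the final cycle.
#'
#' @param flow An [run_transient()] result.
#' @return An object of class `aneu_indices`: list with `per_facet`
#'   (data frame), `regions` (data frame of max/avg TAWSS and OSI per
#'   wall region), `pressure` (data frame of wall-pressure stats per
#'   region and phase) and `stagnant_facets` (facet ids with an all-zero
#'   shear series, where OSI defaults to 0).
#' @export
indices_report <- function(flow) {
  stopifnot(inherits(flow, "aneu_flow"))
  if (!isTRUE(flow$complete)) stop("flow trajectory is incomplete")
  ws <- flow$wall
  mesh <- flow$mesh
  per_tawss <- tawss(ws$times, ws$tau_x, ws$tau_y)
  per_osi <- osi(ws$times, ws$tau_x, ws$tau_y)
  w <- .trapz_weights(ws$times)
  stagnant <- which(colSums(w * sqrt(ws$tau_x^2 + ws$tau_y^2)) == 0)
  Tcyc <- ws$times[length(ws$times)] - ws$times[1]
  mean_tau_mag <- sqrt(colSums(w * ws$tau_x)^2 +
                         colSums(w * ws$tau_y)^2) / Tcyc
  per_facet <- cbind(ws$facets[, c("facet_id", "x", "y", "tag", "length")],
                     data.frame(tawss = per_tawss, osi = per_osi,
                                mean_tau_mag = mean_tau_mag))

  regions <- do.call(rbind, lapply(c("WALL_SAC", "WALL_VESSEL"), function(rg) {
    tw <- aggregate_wall(per_tawss, mesh, rg)
    os <- aggregate_wall(per_osi, mesh, rg)
    data.frame(region = rg, max_tawss = tw[["max"]], avg_tawss = tw[["avg"]],
               max_osi = os[["max"]], avg_osi = os[["avg"]])
  }))

  phases <- flow$phase_index[flow$phase_index$cycle == flow$case$solver$cycles, ]
  if (!all(c("systole", "diastole") %in% phases$phase))
    stop("final-cycle phase snapshots missing from trajectory")
  pressure <- do.call(rbind, lapply(seq_len(nrow(phases)), function(i) {
    st <- flow$snapshots[[phases$snap[i]]]
    do.call(rbind, lapply(c("WALL_SAC", "WALL_VESSEL"), function(rg) {
      ps <- .wall_pressure_stats(st, mesh, rg)
      data.frame(phase = phases$phase[i], time = phases$time[i], region = rg,
                 max_pressure = ps[["max"]], avg_pressure = ps[["avg"]])
    }))
  }))
  structure(list(per_facet = per_facet, regions = regions,
                 pressure = pressure, stagnant_facets = stagnant),
            class = "aneu_indices")
}

#' @export
print.aneu_indices <- function(x, ...) {
  cat("Hemodynamic indices (final cardiac cycle)\n")
  print(x$regions, row.names = FALSE, digits = 4)
  cat("\nWall pressure at sampled phases:\n")
  print(x$pressure, row.names = FALSE, digits = 4)
  if (length(x$stagnant_facets))
    cat(sprintf("\nNote: %d stagnant facet(s) with zero shear history (OSI = 0).\n",
                length(x$stagnant_facets)))
  invisible(x)
}

#' Write per-facet and region-summary CSV files
#'
#' @param report An [indices_report()] result.
#' @param facet_path,region_path Output CSV paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_indices_csv <- function(report, facet_path = NULL, region_path = NULL) {
  stopifnot(inherits(report, "aneu_indices"))
  if (!is.null(facet_path))
    utils::write.csv(report$per_facet, facet_path, row.names = FALSE)
  if (!is.null(region_path))
    utils::write.csv(report$regions, region_path, row.names = FALSE)
  invisible(c(facet_path, region_path))
}
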