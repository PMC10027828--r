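# Transient incompressible Casson flow solver.
#
# Each time step solves the implicitly discretized momentum/continuity
# system by Picard outer iterations: convection and apparent viscosity
# are lagged to the previous iterate, the pressure-velocity coupling is
# solved monolithically (sparse LU) with SUPG/PSPG stabilization, and
# the step is accepted once momentum and continuity residuals fall under
# their tolerances.  The Darcy coil sink is treated implicitly.

#' Solver configuration
#'
#' @param dt Time-step size, s.  The default (0.002 s) gives 400 steps
#'   per 0.8 s cardiac cycle and lands exactly on the peak-systole and
#'   early-diastole sample times.
#' @param cycles Number of cardiac cycles to integrate; only the final
#'   cycle feeds the hemodynamic indices.
#' @param outer_iterations_max Maximum Picard iterations per step.
#' @param continuity_tolerance,momentum_tolerance Relative residual
#'   targets for step acceptance.
#' @param under_relaxation_u,under_relaxation_p Iterate under-relaxation
#'   factors in `(0, 1]`.
#' @param time_scheme `"implicit_euler"` or `"bdf2"`.
#' @param density Blood density, kg/m^3.
#' @param snapshot_stride Save a full flow state every this many steps.
#' @param periodicity_stride Stride (steps) for the phase-matched states
#'   kept over the last two cycles for the periodicity diagnostic; must
#'   divide the steps per cycle.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.002, cycles = 3L,
                          outer_iterations_max = 40L,
                          continuity_tolerance = 1e-5,
                          momentum_tolerance = 1e-5,
                          under_relaxation_u = 1,
                          under_relaxation_p = 1,
                          time_scheme = c("implicit_euler", "bdf2"),
                          density = 1060,
                          snapshot_stride = 40L,
                          periodicity_stride = 10L) {
  time_scheme <- match.arg(time_scheme)
  stopifnot(dt > 0, cycles >= 1, outer_iterations_max >= 1,
            continuity_tolerance > 0, momentum_tolerance > 0,
            under_relaxation_u > 0, under_relaxation_u <= 1,
            under_relaxation_p > 0, under_relaxation_p <= 1,
            density > 0)
  structure(list(dt = dt, cycles = as.integer(cycles),
                 outer_iterations_max = as.integer(outer_iterations_max),
                 continuity_tolerance = continuity_tolerance,
                 momentum_tolerance = momentum_tolerance,
                 under_relaxation_u = under_relaxation_u,
                 under_relaxation_p = under_relaxation_p,
                 time_scheme = time_scheme, density = density,
                 snapshot_stride = as.integer(snapshot_stride),
                 periodicity_stride = as.integer(periodicity_stride)),
            class = "solver_config")
}

#' Boundary-condition specification
#'
#' @param inlet `"velocity"` (Dirichlet profile scaled by the waveform)
#'   or `"traction"` (prescribed normal traction, i.e. pressure).
#' @param inlet_profile Spatial shape of the velocity inlet:
#'   `"parabolic"` (fully developed, centerline 1.5x mean) or
#'   `"uniform"`.
#' @param inlet_pressure Inlet pressure for `inlet = "traction"`, Pa.
#' @param outlet_pressure Outlet pressure (zero = classical do-nothing
#'   traction-free outlet), Pa.
#' @param walls `"noslip"` (both velocity components zero) or `"slip"`
#'   (impermeable but stress-free: only the wall-normal component is
#'   constrained; wall segments must be axis-aligned).
#' @return An object of class `bc_spec`.
#' @export
bc_spec <- function(inlet = c("velocity", "traction"),
                    inlet_profile = c("parabolic", "uniform"),
                    inlet_pressure = 0, outlet_pressure = 0,
                    walls = c("noslip", "slip")) {
  structure(list(inlet = match.arg(inlet),
                 inlet_profile = match.arg(inlet_profile),
                 inlet_pressure = inlet_pressure,
                 outlet_pressure = outlet_pressure,
                 walls = match.arg(walls)),
            class = "bc_spec")
}

#' Case configuration
#'
#' Bundles everything one transient run needs.  The mesh may be supplied
#' (e.g. read from a file) or is built from `geometry` on first use.
#'
#' @param geometry A [geometry_params()] object.
#' @param mesh Optional pre-built [build_idealized_geometry()] mesh.
#' @param waveform An [generate_waveform()] pulsatile inflow.
#' @param rheology A [casson_params()] object.
#' @param porous A [porous_props()] coil model (`porosity = 1` for the
#'   uncoiled case), or `NULL` to leave the coil model out entirely;
#'   the two are numerically identical.
#' @param solver A [solver_config()].
#' @param bc A [bc_spec()].
#' @return An object of class `case_config`.
#' @export
case_config <- function(geometry = geometry_params(), mesh = NULL,
                        waveform = generate_waveform(),
                        rheology = params_from_hematocrit(0.4),
                        porous = porous_props(1),
                        solver = solver_config(), bc = bc_spec()) {
  stopifnot(inherits(geometry, "geometry_params") || is.null(geometry),
            is.null(mesh) || inherits(mesh, "aneu_mesh"),
            inherits(waveform, "aneu_waveform"),
            inherits(rheology, "casson_params"),
            is.null(porous) || inherits(porous, "porous_props"),
            inherits(solver, "solver_config"),
            inherits(bc, "bc_spec"))
  structure(list(geometry = geometry, mesh = mesh, waveform = waveform,
                 rheology = rheology, porous = porous, solver = solver,
                 bc = bc),
            class = "case_config")
}

case_mesh <- function(case) {
  if (!is.null(case$mesh)) case$mesh else build_idealized_geometry(case$geometry)
}

# Dirichlet dof list for the current bc at inlet speed `vin` (section
# mean).  Returns integer dofs and values; dof order [u, v, p].
.dirichlet_dofs <- function(fem, bc, vin) {
  mesh <- fem$mesh; n <- fem$n
  bnd <- mesh$boundary
  wall_nodes <- unique(c(bnd$n1[grepl("^WALL", bnd$tag)],
                         bnd$n2[grepl("^WALL", bnd$tag)]))
  inlet_nodes <- unique(c(bnd$n1[bnd$tag == "INLET"],
                          bnd$n2[bnd$tag == "INLET"]))
  dofs <- integer(0); vals <- numeric(0)
  if (bc$walls == "noslip") {
    dofs <- c(dofs, wall_nodes, wall_nodes + n)
    vals <- c(vals, numeric(2L * length(wall_nodes)))
  } else {                       # slip: constrain wall-normal (y) only
    dofs <- c(dofs, wall_nodes + n)
    vals <- c(vals, numeric(length(wall_nodes)))
  }
  if (bc$inlet == "velocity") {
    y <- mesh$nodes[inlet_nodes, 2]
    ylo <- min(y); yhi <- max(y)
    D <- yhi - ylo
    prof <- if (bc$inlet_profile == "parabolic") {
      s <- 2 * (y - ylo) / D - 1
      1.5 * vin * (1 - s^2)
    } else rep(vin, length(y))
    dofs <- c(dofs, inlet_nodes, inlet_nodes + n)
    vals <- c(vals, prof, numeric(length(inlet_nodes)))
  }
  # last occurrence wins: inlet values override wall zeros at corners;
  # for the parabolic profile both are zero there anyway
  dup <- duplicated(dofs, fromLast = TRUE)
  list(dofs = dofs[!dup], vals = vals[!dup])
}

# Traction boundary contributions to the RHS (inlet/outlet pressures).
.traction_rhs <- function(fem, bc) {
  n <- fem$n; bnd <- fem$mesh$boundary
  rhs <- numeric(3L * n)
  add_edge_load <- function(rhs, sel, p_val) {
    if (!any(sel) || p_val == 0) return(rhs)
    # traction t = -p n on the boundary; integrate t * phi over edges
    tx <- -p_val * fem$edge_nx[sel]; ty <- -p_val * fem$edge_ny[sel]
    l2 <- fem$edge_len[sel] / 2
    nd <- c(bnd$n1[sel], bnd$n2[sel])
    rhs + .accumulate(c(nd, nd + n),
                      c(tx * l2, tx * l2, ty * l2, ty * l2), 3L * n)
  }
  if (bc$inlet == "traction")
    rhs <- add_edge_load(rhs, bnd$tag == "INLET", bc$inlet_pressure)
  rhs <- add_edge_load(rhs, bnd$tag == "OUTLET", bc$outlet_pressure)
  rhs
}

# Impose Dirichlet rows: zero them with a diagonal mask and put 1 on
# the diagonal (sparse algebra; no subassignment on the sparse matrix).
.apply_dirichlet <- function(Amat, rhs, dir) {
  if (length(dir$dofs)) {
    nd <- nrow(Amat)
    keep <- rep.int(1, nd); keep[dir$dofs] <- 0
    one <- numeric(nd); one[dir$dofs] <- 1
    Amat <- Matrix::Diagonal(nd, keep) %*% Amat + Matrix::Diagonal(nd, one)
    rhs[dir$dofs] <- dir$vals
  }
  list(A = Amat, rhs = rhs)
}

# Residual norms of the nonlinear system at iterate x, Dirichlet rows
# excluded.  Each block is scaled by the cancellation-free magnitude
# |A| |x| + |rhs| of its own equations, so the measure is meaningful for
# homogeneous RHS (traction-driven and zero-inflow cases) and reports 0
# for the all-zero trivial solution.
.residual_norms <- function(sys, x, dir, n) {
  r <- as.numeric(sys$A %*% x - sys$rhs)
  if (length(dir$dofs)) r[dir$dofs] <- 0
  mag <- as.numeric(abs(sys$A) %*% abs(x)) + abs(sys$rhs)
  mom_i <- seq_len(2L * n); cont_i <- 2L * n + seq_len(n)
  rel <- function(idx) {
    num <- sqrt(sum(r[idx]^2)); den <- sqrt(sum(mag[idx]^2))
    if (num == 0) 0 else num / max(den, 1e-300)
  }
  c(momentum = rel(mom_i), continuity = rel(cont_i))
}

#' Flow state
#'
#' Nodal velocity and pressure at one time.
#'
#' @param time Time, s.
#' @param u,v Velocity components per node, m/s.
#' @param p Pressure per node, Pa.
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(time, u, v, p) {
  structure(list(time = time, u = u, v = v, p = p), class = "flow_state")
}

# Picard loop shared by steady solves and time steps.  dti = 0 for
# steady; hist_* is the time-discretization history field.
.picard_solve <- function(fem, x0, dir, tr_rhs, rheology, porous, cfg,
                          dti, hist_u = NULL, hist_v = NULL,
                          context = "solve") {
  n <- fem$n
  x <- x0
  x[dir$dofs] <- dir$vals
  alpha_u <- cfg$under_relaxation_u; alpha_p <- cfg$under_relaxation_p
  res <- c(momentum = Inf, continuity = Inf)
  for (it in seq_len(cfg$outer_iterations_max + 1L)) {
    sys <- .fem_assemble(fem, x[seq_len(n)], x[n + seq_len(n)],
                         rheology, porous, cfg$density, dti, hist_u, hist_v)
    sys$rhs <- sys$rhs + tr_rhs
    sys <- .apply_dirichlet(sys$A, sys$rhs, dir)
    res <- .residual_norms(sys, x, dir, n)
    # the initial iterate (old state under new boundary data) is only
    # accepted when its residual vanishes identically (true fixed point);
    # otherwise at least one linear solve happens per step
    if ((it > 1L || all(res == 0)) &&
        res[["momentum"]] < cfg$momentum_tolerance &&
        res[["continuity"]] < cfg$continuity_tolerance)
      return(list(x = x, iterations = it - 1L, residuals = res))
    if (it > cfg$outer_iterations_max) break
    xs <- as.numeric(Matrix::solve(sys$A, sys$rhs))
    uv <- seq_len(2L * n); pp <- 2L * n + seq_len(n)
    x[uv] <- x[uv] + alpha_u * (xs[uv] - x[uv])
    x[pp] <- x[pp] + alpha_p * (xs[pp] - x[pp])
    x[dir$dofs] <- dir$vals
  }
  stop(structure(class = c("aneuflow_divergence", "error", "condition"),
                 list(message = sprintf(
                   paste0("%s: outer iterations exceeded %d ",
                          "(momentum residual %.3g, continuity residual %.3g)"),
                   context, cfg$outer_iterations_max,
                   res[["momentum"]], res[["continuity"]]),
                   call = NULL, residuals = res)))
}

#' Advance the flow by one time step
#'
#' One implicit step of the transient solver: Picard iterations with the
#' apparent viscosity and convection lagged to the previous iterate and
#' the Darcy sink implicit, accepted when momentum and continuity
#' residuals are below their tolerances.
#'
#' @param state A [flow_state()] at time t (used as history and initial
#'   iterate).
#' @param dt Step size, s.
#' @param fem Assembly data from the internal setup (pass a mesh to have
#'   it built).
#' @param rheology,porous,bc,config Model components, see
#'   [case_config()].
#' @param inlet_velocity Section-mean inlet velocity at time t + dt, m/s
#'   (ignored for traction inlets).
#' @param prev_state Optional state at t - dt for BDF2.
#' @return A `flow_state` at t + dt with attributes `iterations` and
#'   `residuals`.
#' @export
advance_state <- function(state, dt, fem, rheology, porous, bc, config,
                          inlet_velocity, prev_state = NULL) {
  if (inherits(fem, "aneu_mesh")) fem <- .fem_setup(fem)
  n <- fem$n
  use_bdf2 <- config$time_scheme == "bdf2" && !is.null(prev_state)
  if (use_bdf2) {
    dti <- 1.5 / dt
    hist_u <- (4 * state$u - prev_state$u) / 3
    hist_v <- (4 * state$v - prev_state$v) / 3
  } else {
    dti <- 1 / dt
    hist_u <- state$u; hist_v <- state$v
  }
  dir <- .dirichlet_dofs(fem, bc, inlet_velocity)
  tr_rhs <- .traction_rhs(fem, bc)
  x0 <- c(state$u, state$v, state$p)
  sol <- .picard_solve(fem, x0, dir, tr_rhs, rheology, porous, config, dti,
                       hist_u, hist_v,
                       context = sprintf("advance to t=%.4g", state$time + dt))
  out <- flow_state(state$time + dt, sol$x[seq_len(n)],
                    sol$x[n + seq_len(n)], sol$x[2L * n + seq_len(n)])
  attr(out, "iterations") <- sol$iterations
  attr(out, "residuals") <- sol$residuals
  out
}

#' Steady flow solve
#'
#' Solves the stationary problem (no time derivative) by Picard
#' iteration; used for the closed-form channel verifications and as the
#' initial state of steady-inflow control runs.
#'
#' @param mesh An `aneu_mesh`.
#' @param rheology,porous,bc Model components.
#' @param config A [solver_config()]; under-relaxation applies to the
#'   Picard update.
#' @param inlet_velocity Section-mean inlet velocity, m/s (velocity
#'   inlets).
#' @return A `flow_state` with `time = 0`.
#' @export
solve_steady <- function(mesh, rheology, porous = porous_props(1),
                         bc = bc_spec(), config = solver_config(),
                         inlet_velocity = 0) {
  fem <- .fem_setup(mesh)
  n <- fem$n
  dir <- .dirichlet_dofs(fem, bc, inlet_velocity)
  tr_rhs <- .traction_rhs(fem, bc)
  sol <- .picard_solve(fem, numeric(3L * n), dir, tr_rhs, rheology, porous,
                       config, dti = 0, context = "steady solve")
  out <- flow_state(0, sol$x[seq_len(n)], sol$x[n + seq_len(n)],
                    sol$x[2L * n + seq_len(n)])
  attr(out, "iterations") <- sol$iterations
  attr(out, "residuals") <- sol$residuals
  out
}

#' Boundary flux of a flow state
#'
#' Integral of u . n over the edges with a given tag (2D: per unit
#' depth, m^2/s).  Outward positive.
#'
#' @param state A `flow_state`.
#' @param mesh The mesh the state lives on.
#' @param tag Boundary tag.
#' @return Signed flux, m^2/s.
#' @export
boundary_flux <- function(state, mesh, tag) {
  bnd <- mesh$boundary[mesh$boundary$tag == tag, , drop = FALSE]
  if (!nrow(bnd)) stop("no boundary edges tagged ", tag)
  ex <- mesh$nodes[bnd$n2, 1] - mesh$nodes[bnd$n1, 1]
  ey <- mesh$nodes[bnd$n2, 2] - mesh$nodes[bnd$n1, 2]
  len <- sqrt(ex^2 + ey^2)
  nx <- ey / len; ny <- -ex / len
  un1 <- state$u[bnd$n1] * nx + state$v[bnd$n1] * ny
  un2 <- state$u[bnd$n2] * nx + state$v[bnd$n2] * ny
  sum(len * (un1 + un2) / 2)
}
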