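# Transient cardiac-cycle integration, trajectory recording and
# checkpointing.

.transient_setup <- function(case, mesh) {
  cfg <- case$solver; wf <- case$waveform
  n_per <- round(wf$period / cfg$dt)
  if (abs(n_per * cfg$dt - wf$period) > 1e-9 * wf$period)
    stop("dt must divide the cardiac period; got dt = ", cfg$dt,
         " for period ", wf$period)
  if (n_per %% cfg$periodicity_stride != 0L)
    stop("periodicity_stride must divide the steps per cycle (",
         n_per, ")")
  k_sys <- round(wf$t_peak_systole / cfg$dt)
  k_dia <- round(wf$t_early_diastole / cfg$dt)
  if (max(abs(c(k_sys * cfg$dt - wf$t_peak_systole,
                k_dia * cfg$dt - wf$t_early_diastole))) > 1e-9)
    stop("dt must land on the peak-systole and early-diastole phase times; ",
         "got dt = ", cfg$dt)
  fem <- .fem_setup(mesh)
  wall <- .wall_setup(mesh)
  list(fem = fem, wall = wall, n_per = n_per,
       n_steps = cfg$cycles * n_per, k_sys = k_sys, k_dia = k_dia)
}

.new_progress <- function(S, case, initial_state) {
  n <- S$fem$n
  state0 <- if (is.null(initial_state))
    flow_state(0, numeric(n), numeric(n), numeric(n)) else initial_state
  nf <- nrow(S$wall)
  nt <- S$n_per + 1L
  P <- list(step = 0L, state = state0, prev_state = NULL,
            snapshots = list(), snap_times = numeric(0),
            snap_steps = integer(0),
            phase_index = data.frame(cycle = integer(0),
                                     phase = character(0),
                                     time = numeric(0), snap = integer(0)),
            tau_x = matrix(NA_real_, nt, nf),
            tau_y = matrix(NA_real_, nt, nf),
            pstates = list(),
            log = list())
  P <- .record_step(P, S, case, 0L)
  P
}

# Record snapshots/series owed at completed step k (state already in P).
.record_step <- function(P, S, case, k) {
  cfg <- case$solver
  t <- k * cfg$dt
  cyc <- (k - 1L) %/% S$n_per + 1L          # cycle this step belongs to
  kin <- k - (cyc - 1L) * S$n_per           # phase step within that cycle
  is_phase <- k > 0L && (kin == S$k_sys || kin == S$k_dia)
  want_snap <- k == 0L || k == S$n_steps || is_phase ||
    (k %% cfg$snapshot_stride == 0L)
  if (want_snap) {
    P$snapshots[[length(P$snapshots) + 1L]] <- P$state
    P$snap_times <- c(P$snap_times, t)
    P$snap_steps <- c(P$snap_steps, k)
    if (is_phase)
      P$phase_index <- rbind(P$phase_index, data.frame(
        cycle = cyc, phase = if (kin == S$k_sys) "systole" else "diastole",
        time = t, snap = length(P$snapshots)))
  }
  k0 <- (cfg$cycles - 1L) * S$n_per
  if (k >= k0) {
    tau <- .wall_shear_values(S$wall, S$fem, P$state$u, P$state$v,
                              case$rheology)
    P$tau_x[k - k0 + 1L, ] <- tau[, 1]
    P$tau_y[k - k0 + 1L, ] <- tau[, 2]
  }
  if (cfg$cycles >= 2L && k %% cfg$periodicity_stride == 0L &&
      k >= (cfg$cycles - 2L) * S$n_per)
    P$pstates[[as.character(k)]] <- c(P$state$u, P$state$v)
  P
}

.transient_loop <- function(case, mesh, S, P, halt_at_step = NULL) {
  cfg <- case$solver; wf <- case$waveform
  tr_rhs <- .traction_rhs(S$fem, case$bc)
  last <- if (is.null(halt_at_step)) S$n_steps else
    min(halt_at_step, S$n_steps)
  while (P$step < last) {
    k <- P$step + 1L
    t_new <- k * cfg$dt
    vin <- waveform_velocity(wf, t_new)
    use_bdf2 <- cfg$time_scheme == "bdf2" && !is.null(P$prev_state)
    if (use_bdf2) {
      dti <- 1.5 / cfg$dt
      hist_u <- (4 * P$state$u - P$prev_state$u) / 3
      hist_v <- (4 * P$state$v - P$prev_state$v) / 3
    } else {
      dti <- 1 / cfg$dt
      hist_u <- P$state$u; hist_v <- P$state$v
    }
    dir <- .dirichlet_dofs(S$fem, case$bc, vin)
    x0 <- c(P$state$u, P$state$v, P$state$p)
    sol <- tryCatch(
      .picard_solve(S$fem, x0, dir, tr_rhs, case$rheology, case$porous,
                    cfg, dti, hist_u, hist_v,
                    context = sprintf("step %d (t = %.4g s)", k, t_new)),
      aneuflow_divergence = function(e) {
        e$message <- paste0(e$message, " [time step failed at t = ",
                            format(t_new), " s]")
        stop(e)
      })
    n <- S$fem$n
    P$prev_state <- P$state
    P$state <- flow_state(t_new, sol$x[seq_len(n)], sol$x[n + seq_len(n)],
                          sol$x[2L * n + seq_len(n)])
    P$step <- k
    P$log[[k]] <- c(step = k, time = t_new, iterations = sol$iterations,
                    momentum = sol$residuals[["momentum"]],
                    continuity = sol$residuals[["continuity"]])
    P <- .record_step(P, S, case, k)
  }
  .as_flow(case, mesh, S, P, complete = P$step >= S$n_steps)
}

.as_flow <- function(case, mesh, S, P, complete) {
  log <- as.data.frame(do.call(rbind, P$log))
  structure(list(case = case, mesh = mesh, complete = complete,
                 n_per_cycle = S$n_per, dt = case$solver$dt,
                 snapshots = P$snapshots, snap_times = P$snap_times,
                 snap_steps = P$snap_steps, phase_index = P$phase_index,
                 wall = list(facets = S$wall,
                             times = ((case$solver$cycles - 1L) * S$n_per +
                                        0:S$n_per) * case$solver$dt,
                             tau_x = P$tau_x, tau_y = P$tau_y),
                 pstates = P$pstates, residual_log = log,
                 progress = if (complete) NULL else P),
            class = "aneu_flow")
}

#' Run a transient cardiac-cycle simulation
#'
#' Integrates the case over `cycles` cardiac periods from rest (or a
#' supplied initial state), recording full flow snapshots on a stride
#' and exactly at the peak-systole and early-diastole phases of every
#' cycle, the wall-shear time series over the final cycle (which feeds
#' [indices_report()]), and phase-matched velocity states of the last
#' two cycles for the periodicity diagnostic.  The run is fully
#' deterministic.
#'
#' @param case A [case_config()].
#' @param initial_state Optional `flow_state` to start from (default:
#'   fluid at rest; the early cycles then act as washout).
#' @param halt_at_step Stop after this completed step and return an
#'   incomplete trajectory that [resume_transient()] can continue;
#'   intended for checkpointing.
#' @return An object of class `aneu_flow`.
#' @export
run_transient <- function(case, initial_state = NULL, halt_at_step = NULL) {
  stopifnot(inherits(case, "case_config"))
  mesh <- case_mesh(case)
  S <- .transient_setup(case, mesh)
  P <- .new_progress(S, case, initial_state)
  .transient_loop(case, mesh, S, P, halt_at_step)
}

#' Resume an incomplete transient run
#'
#' Continues a trajectory produced with `halt_at_step` (possibly after a
#' [checkpoint_write()]/[checkpoint_read()] round trip) to completion.
#' The result is identical to an uninterrupted run.
#'
#' @param flow An incomplete `aneu_flow`.
#' @param halt_at_step Optionally halt again at a later step.
#' @return An `aneu_flow`.
#' @export
resume_transient <- function(flow, halt_at_step = NULL) {
  stopifnot(inherits(flow, "aneu_flow"))
  if (isTRUE(flow$complete)) return(flow)
  S <- .transient_setup(flow$case, flow$mesh)
  .transient_loop(flow$case, flow$mesh, S, flow$progress, halt_at_step)
}

#' Write / read a trajectory checkpoint
#'
#' Serializes a trajectory (complete or halted mid-run) with a format
#' version stamp.  Reading validates the stamp and fails loudly on a
#' truncated or foreign file.
#'
#' @param flow An `aneu_flow`.
#' @param path Checkpoint file path.
#' @return `checkpoint_write`: `path` invisibly. `checkpoint_read`: the
#'   stored `aneu_flow`.
#' @export
checkpoint_write <- function(flow, path) {
  stopifnot(inherits(flow, "aneu_flow"))
  saveRDS(list(format = "aneuflow-checkpoint", version = 1L, flow = flow),
          path)
  invisible(path)
}

#' @rdname checkpoint_write
#' @export
checkpoint_read <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable or truncated checkpoint file: ", path,
         " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, "aneuflow-checkpoint"))
    stop("not an aneuflow checkpoint: ", path)
  if (!identical(obj$version, 1L))
    stop("checkpoint version mismatch: found ", obj$version,
         ", supported 1")
  obj$flow
}

#' Cycle-to-cycle periodicity error
#'
#' Relative L2 difference of the velocity field between the last two
#' cycles at matching phases:
#' \deqn{\sqrt{\sum_k \lVert u(t_k) - u(t_k - T)\rVert^2 /
#'   \sum_k \lVert u(t_k)\rVert^2}}
#' over the stored phase-matched states of the final cycle.  Small
#' values indicate the pulsatile solution has converged to its periodic
#' state, the rationale for integrating several cycles and analyzing
#' only the last.
#'
#' @param flow A complete `aneu_flow` with at least two cycles.
#' @return Relative difference, dimensionless.
#' @export
periodicity_error <- function(flow) {
  stopifnot(inherits(flow, "aneu_flow"), isTRUE(flow$complete))
  cfg <- flow$case$solver
  if (cfg$cycles < 2L) return(NA_real_)
  n_per <- flow$n_per_cycle
  ks <- as.integer(names(flow$pstates))
  num <- 0; den <- 0
  for (k in ks[ks > (cfg$cycles - 1L) * n_per]) {
    prev <- as.character(k - n_per)
    if (!prev %in% names(flow$pstates)) next
    d <- flow$pstates[[as.character(k)]] - flow$pstates[[prev]]
    num <- num + sum(d^2)
    den <- den + sum(flow$pstates[[as.character(k)]]^2)
  }
  if (den == 0) return(0)
  sqrt(num / den)
}

#' Mass-balance error of saved snapshots
#'
#' Relative mismatch between inflow and outflow flux for every saved
#' snapshot, `|influx + outflux| / max(|influx|)`.
#'
#' @param flow An `aneu_flow`.
#' @return Numeric vector, one entry per snapshot.
#' @export
mass_balance_error <- function(flow) {
  vapply(flow$snapshots, function(st) {
    fin <- boundary_flux(st, flow$mesh, "INLET")
    fout <- boundary_flux(st, flow$mesh, "OUTLET")
    if (fin == 0 && fout == 0) 0 else abs(fin + fout) / max(abs(fin), 1e-300)
  }, numeric(1))
}

#' @export
print.aneu_flow <- function(x, ...) {
  cfg <- x$case$solver
  cat(sprintf("aneu_flow: %s run, %d cycle(s) x %d steps (dt = %g s)\n",
              if (isTRUE(x$complete)) "complete" else "PARTIAL",
              cfg$cycles, x$n_per_cycle, x$dt))
  cat(sprintf("  mesh: %d nodes, %d triangles; porosity %.2f, %s\n",
              nrow(x$mesh$nodes), nrow(x$mesh$tri),
              if (is.null(x$case$porous)) 1 else x$case$porous$porosity,
              if (!is.na(x$case$rheology$hematocrit))
                sprintf("HCT %.2f", x$case$rheology$hematocrit) else
                  "explicit rheology"))
  if (nrow(x$residual_log))
    cat(sprintf("  Picard iterations/step: median %g, max %g\n",
                stats::median(x$residual_log$iterations),
                max(x$residual_log$iterations)))
  cat(sprintf("  %d snapshots", length(x$snapshots)))
  if (isTRUE(x$complete) && cfg$cycles >= 2L)
    cat(sprintf("; cycle-to-cycle periodicity error %.3g",
                periodicity_error(x)))
  cat("\n")
  invisible(x)
}

#' @export
summary.aneu_flow <- function(object, ...) {
  out <- list(flow = object,
              indices = if (isTRUE(object$complete))
                indices_report(object) else NULL,
              mass_balance = max(mass_balance_error(object)),
              periodicity = if (isTRUE(object$complete))
                periodicity_error(object) else NA_real_)
  class(out) <- "summary.aneu_flow"
  out
}

#' @export
print.summary.aneu_flow <- function(x, ...) {
  print(x$flow)
  cat(sprintf("  max snapshot mass-balance error: %.3g\n", x$mass_balance))
  if (!is.null(x$indices)) { cat("\n"); print(x$indices) }
  invisible(x)
}

#' @export
plot.aneu_flow <- function(x, snapshot = length(x$snapshots), ...) {
  st <- x$snapshots[[snapshot]]
  sp <- sqrt(st$u^2 + st$v^2)
  tr <- x$mesh$tri
  val <- (sp[tr[, 1]] + sp[tr[, 2]] + sp[tr[, 3]]) / 3
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[pmin(64L, 1L + floor(63 * val / max(val, 1e-300)))]
  graphics::plot(x$mesh$nodes, type = "n", asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("|u| (m/s) at t = %.3f s",
                                x$snap_times[snapshot]), ...)
  graphics::polygon(
    x = as.vector(t(cbind(matrix(x$mesh$nodes[t(tr), 1], ncol = 3,
                                 byrow = TRUE), NA))),
    y = as.vector(t(cbind(matrix(x$mesh$nodes[t(tr), 2], ncol = 3,
                                 byrow = TRUE), NA))),
    col = col, border = NA)
  invisible(x)
}
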