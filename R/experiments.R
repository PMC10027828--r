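# Experiment drivers: grid-refinement study, hematocrit x porosity
# sweeps, coil-table consistency checks and the qualitative trend
# report.

#' Percent change between successive grid-study rows
#'
#' `100 (current - previous) / previous`, truncated (not rounded) toward
#' zero at two decimals -- the convention under which the reference
#' grid-study change column is self-consistent.
#'
#' @param previous,current Sac-averaged WSS of the coarser and finer
#'   grid, Pa.
#' @return Percent change, truncated to two decimals.
#' @export
percent_change <- function(previous, current) {
  if (any(previous <= 0)) stop("previous value must be positive")
  trunc(100 * (current - previous) / previous * 100) / 100
}

#' Grid-refinement study
#'
#' Runs the case on a sequence of decreasing element sizes and reports
#' the sac-averaged TAWSS with the percent change between successive
#' grids; the selected grid is the first whose change falls under
#' `threshold`.  Supplying `values` bypasses the simulations and only
#' exercises the reporting arithmetic (useful to audit a printed table).
#'
#' @param case A [case_config()]; its geometry is re-meshed per size.
#' @param element_sizes Strictly decreasing element sizes, m.
#' @param values Optional precomputed sac-averaged WSS values, Pa (one
#'   per size), bypassing simulation.
#' @param threshold Acceptance threshold on the change column, percent.
#' @return A data frame of class `grid_study` with columns
#'   `element_size`, `n_elements`, `avg_wss_sac`, `change_pct` (NA for
#'   the first row) and attribute `selected` (row index), plus `error`
#'   messages for sizes whose run failed.
#' @export
run_grid_study <- function(case, element_sizes, values = NULL,
                           threshold = 1) {
  stopifnot(length(element_sizes) >= 2L, all(diff(element_sizes) < 0))
  n_sz <- length(element_sizes)
  n_el <- rep(NA_integer_, n_sz)
  wss <- rep(NA_real_, n_sz)
  errs <- rep(NA_character_, n_sz)
  if (!is.null(values)) {
    stopifnot(length(values) == n_sz)
    wss <- values
  } else {
    stopifnot(inherits(case, "case_config"))
    for (i in seq_len(n_sz)) {
      g <- case$geometry; g$mesh_size <- element_sizes[i]
      ci <- case; ci$geometry <- g; ci$mesh <- NULL
      res <- tryCatch({
        mesh <- build_idealized_geometry(g)
        fl <- run_transient(ci)
        rep_ <- indices_report(fl)
        list(n = nrow(mesh$tri),
             w = rep_$regions$avg_tawss[rep_$regions$region == "WALL_SAC"])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errs[i] <- conditionMessage(res)
      } else {
        n_el[i] <- res$n; wss[i] <- res$w
      }
    }
  }
  change <- c(NA_real_, percent_change(wss[-n_sz], wss[-1L]))
  out <- data.frame(element_size = element_sizes, n_elements = n_el,
                    avg_wss_sac = wss, change_pct = change,
                    error = errs)
  ok <- which(!is.na(change) & abs(change) < threshold)
  attr(out, "selected") <- if (length(ok)) min(ok) else NA_integer_
  class(out) <- c("grid_study", "data.frame")
  if (any(!is.na(errs)))
    stop(structure(class = c("aneuflow_partial_gridstudy", "error",
                             "condition"),
                   list(message = paste("grid study failed for size(s):",
                                        paste(element_sizes[!is.na(errs)],
                                              collapse = ", ")),
                        call = NULL, partial = out)))
  out
}

#' Sweep specification
#'
#' @param hematocrits Hematocrit fractions to sweep.
#' @param porosities Coil porosities in `(0, 1]` (1 = uncoiled).
#' @param base_case The [case_config()] every cell starts from.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(hematocrits = c(0.35, 0.40, 0.45),
                       porosities = c(0.75, 0.85, 1.0),
                       base_case = case_config()) {
  stopifnot(length(hematocrits) >= 1L, length(porosities) >= 1L,
            all(hematocrits > 0 & hematocrits < 1),
            all(porosities > 0 & porosities <= 1),
            inherits(base_case, "case_config"))
  structure(list(hematocrits = hematocrits, porosities = porosities,
                 base_case = base_case),
            class = "sweep_spec")
}

#' Run a hematocrit x porosity sweep
#'
#' One full transient run and indices report per (HCT, porosity) cell,
#' in deterministic (row-major: hematocrit outer, porosity inner)
#' order.  Failing cells are recorded and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param keep_reports Keep each cell's full [indices_report()] as an
#'   attribute.
#' @return A long-format data frame of class `aneu_sweep`: one row per
#'   cell with sac-region summaries (`max_osi_sac`, `avg_osi_sac`,
#'   `avg_tawss_sac`, `max_tawss_sac`, `max_pressure_sac_systole`) and
#'   an `error` column (NA on success).
#' @export
run_sweep <- function(spec, keep_reports = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  mesh <- case_mesh(spec$base_case)   # mesh shared by all cells
  grid <- expand.grid(porosity = spec$porosities, hct = spec$hematocrits,
                      KEEP.OUT.ATTRS = FALSE)[, c("hct", "porosity")]
  reports <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    H <- grid$hct[i]; eps <- grid$porosity[i]
    res <- tryCatch({
      ci <- spec$base_case
      ci$mesh <- mesh
      ci$rheology <- params_from_hematocrit(
        H, plasma_viscosity = spec$base_case$rheology$plasma_viscosity,
        gamma_dot_min = spec$base_case$rheology$gamma_dot_min)
      ci$porous <- porous_props(eps)
      fl <- run_transient(ci)
      indices_report(fl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(hct = H, porosity = eps,
                              max_osi_sac = NA_real_, avg_osi_sac = NA_real_,
                              avg_tawss_sac = NA_real_,
                              max_tawss_sac = NA_real_,
                              max_pressure_sac_systole = NA_real_,
                              error = conditionMessage(res))
    } else {
      sac <- res$regions[res$regions$region == "WALL_SAC", ]
      psys <- res$pressure[res$pressure$region == "WALL_SAC" &
                             res$pressure$phase == "systole", ]
      rows[[i]] <- data.frame(hct = H, porosity = eps,
                              max_osi_sac = sac$max_osi,
                              avg_osi_sac = sac$avg_osi,
                              avg_tawss_sac = sac$avg_tawss,
                              max_tawss_sac = sac$max_tawss,
                              max_pressure_sac_systole = psys$max_pressure,
                              error = NA_character_)
      if (keep_reports) reports[[i]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aneu_sweep", "data.frame")
  if (keep_reports) attr(out, "reports") <- reports
  out
}

#' Qualitative trend report for a sweep
#'
#' Checks, as soft expectations with `pass`/`warn` status (never an
#' error), the directional findings the coiling study is known for: at
#' fixed hematocrit, lowering the coil porosity should raise the average
#' sac OSI, and should lower the average sac WSS.  A 2D idealized
#' geometry cannot guarantee the directionality seen on a 3D
#' patient-specific case, hence soft status rather than hard failure.
#'
#' @param sweep An [run_sweep()] result containing porosities below 1
#'   and 1.
#' @return Data frame with one row per (hematocrit, expectation) and a
#'   `status` column (`"pass"` or `"warn"`).
#' @export
trend_report <- function(sweep) {
  stopifnot(inherits(sweep, "aneu_sweep"))
  ok <- is.na(sweep$error)
  sweep <- sweep[ok, , drop = FALSE]
  eps_lo <- min(sweep$porosity)
  if (!any(sweep$porosity == 1) || eps_lo == 1)
    stop("trend report needs both a coiled (porosity < 1) and an uncoiled cell")
  rows <- list()
  for (H in unique(sweep$hct)) {
    lo <- sweep[sweep$hct == H & sweep$porosity == eps_lo, ]
    un <- sweep[sweep$hct == H & sweep$porosity == 1, ]
    if (!nrow(lo) || !nrow(un)) next
    rows[[length(rows) + 1L]] <- data.frame(
      hct = H,
      expectation = sprintf("avg sac OSI rises under coiling (eps %.2f vs 1)",
                            eps_lo),
      coiled = lo$avg_osi_sac, uncoiled = un$avg_osi_sac,
      status = if (lo$avg_osi_sac >= un$avg_osi_sac) "pass" else "warn")
    rows[[length(rows) + 1L]] <- data.frame(
      hct = H,
      expectation = sprintf("avg sac WSS falls under coiling (eps %.2f vs 1)",
                            eps_lo),
      coiled = lo$avg_tawss_sac, uncoiled = un$avg_tawss_sac,
      status = if (lo$avg_tawss_sac <= un$avg_tawss_sac) "pass" else "warn")
  }
  do.call(rbind, rows)
}

#' Consistency checks of the coil porosity/permeability table
#'
#' Recomputes the reciprocal permeabilities of the two tabulated
#' porosity rows and the porosity of the reference coil (0.254 mm wire,
#' 30 cm long, 103.87 mm^3 sac), and compares them with their tabulated
#' 3-significant-figure reciprocals (2.70e7, 1.85e7 1/m^2) and
#' 2-decimal porosity (0.85).
#'
#' @return Data frame with columns `quantity`, `computed`, `expected`,
#'   `agree`.
#' @export
table1_consistency <- function() {
  k75 <- permeability_for_porosity(0.75)
  k85 <- permeability_for_porosity(0.85)
  eps <- porosity_from_coil(coil_spec(0.254e-3, 0.30, 103.87e-9))
  data.frame(
    quantity = c("1/k at porosity 0.75 (1/m^2)",
                 "1/k at porosity 0.85 (1/m^2)",
                 "porosity of reference coil"),
    computed = c(signif(1 / k75, 3), signif(1 / k85, 3), round(eps, 2)),
    expected = c(2.70e7, 1.85e7, 0.85),
    agree = c(signif(1 / k75, 3) == 2.70e7,
              signif(1 / k85, 3) == 1.85e7,
              round(eps, 2) == 0.85))
}

#' @export
print.grid_study <- function(x, ...) {
  cat("Grid-refinement study (sac-averaged WSS)\n")
  print.data.frame(x[, c("element_size", "n_elements", "avg_wss_sac",
                         "change_pct")], row.names = FALSE, digits = 4)
  sel <- attr(x, "selected")
  if (!is.na(sel))
    cat(sprintf("selected grid: element size %g m (change %.2f%%)\n",
                x$element_size[sel], x$change_pct[sel]))
  invisible(x)
}
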