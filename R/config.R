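# Case configuration files (YAML).  Internally everything is SI (m, s,
# Pa); config values may be plain numbers (already SI) or strings with
# an explicit unit suffix ("3 mm", "30 cm", "103.87 mm^3", "2 ms").

.unit_factors <- c("m" = 1, "cm" = 1e-2, "mm" = 1e-3,
                   "m^3" = 1, "cm^3" = 1e-6, "mm^3" = 1e-9,
                   "s" = 1, "ms" = 1e-3, "m/s" = 1, "cm/s" = 1e-2)

.parse_quantity <- function(x, what = "value") {
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[1])))
        && parts[2] %in% names(.unit_factors))
      return(as.numeric(parts[1]) * .unit_factors[[parts[2]]])
  }
  stop("cannot parse ", what, ": ", deparse(x),
       " (use a number in SI units or \"<number> <unit>\" with unit one of ",
       paste(names(.unit_factors), collapse = ", "), ")")
}

.build_from_block <- function(block, builder, defaults_ok = TRUE) {
  if (is.null(block)) {
    if (defaults_ok) return(builder())
    stop("required config block missing")
  }
  args <- lapply(names(block), function(nm) .parse_quantity(block[[nm]], nm))
  names(args) <- names(block)
  do.call(builder, args)
}

#' Read a case configuration from YAML
#'
#' Builds a [case_config()] from a YAML file with optional blocks
#' `geometry`, `waveform`, `rheology`, `porous`, `solver`, `bc` and
#' `mesh` (a path to an MSH file, resolved relative to the config file).
#' Length/time quantities accept unit suffixes (`"3 mm"`, `"30 cm"`,
#' `"103.87 mm^3"`); bare numbers are SI.  The rheology block takes
#' either `hematocrit` or explicit `tau_y`/`mu_inf`; the porous block
#' takes `porosity` (number, or `"from_coil"` together with a `coil`
#' sub-block) and optionally an explicit `permeability`.
#'
#' @param path Path to the YAML file.
#' @return A [case_config()].
#' @export
read_case_config <- function(path) {
  y <- yaml::read_yaml(path)
  geometry <- .build_from_block(y$geometry, geometry_params)

  waveform <- if (is.null(y$waveform)) generate_waveform() else
    generate_waveform(
      profile = y$waveform$profile %||% "default_mca",
      period = .parse_quantity(y$waveform$period %||% 0.8, "period"),
      mean_velocity = .parse_quantity(y$waveform$mean_velocity %||% 0.25,
                                      "mean_velocity"),
      rel_amplitudes = unlist(y$waveform$rel_amplitudes %||% c(0.8, 0.2)))

  rb <- y$rheology
  rheology <- if (is.null(rb) || !is.null(rb$hematocrit)) {
    params_from_hematocrit(
      rb$hematocrit %||% 0.4,
      plasma_viscosity = rb$plasma_viscosity %||% 0.00145,
      gamma_dot_min = rb$gamma_dot_min %||% 1e-3)
  } else {
    casson_params(tau_y = rb$tau_y, mu_inf = rb$mu_inf,
                  gamma_dot_min = rb$gamma_dot_min %||% 1e-3)
  }

  pb <- y$porous
  porous <- if (is.null(pb)) porous_props(1) else {
    eps <- if (identical(pb$porosity, "from_coil")) {
      cb <- pb$coil
      if (is.null(cb)) stop("porosity: from_coil requires a coil block")
      porosity_from_coil(coil_spec(
        .parse_quantity(cb$wire_diameter, "wire_diameter"),
        .parse_quantity(cb$length, "coil length"),
        .parse_quantity(cb$sac_volume, "sac_volume")))
    } else .parse_quantity(pb$porosity %||% 1, "porosity")
    if (!is.null(pb$permeability) && !identical(pb$permeability, "table"))
      porous_props(eps, permeability = pb$permeability)
    else porous_props(eps)
  }

  solver <- .build_from_block(y$solver, solver_config)
  bc <- if (is.null(y$bc)) bc_spec() else
    do.call(bc_spec, y$bc)
  mesh <- if (!is.null(y$mesh)) {
    mp <- if (file.exists(y$mesh)) y$mesh else file.path(dirname(path), y$mesh)
    read_mesh(mp)
  }
  case_config(geometry = geometry, mesh = mesh, waveform = waveform,
              rheology = rheology, porous = porous, solver = solver, bc = bc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
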