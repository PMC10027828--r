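# Endovascular coil as a Darcy porous medium.
#
# A packed coil is characterized by the fluid volume fraction (porosity)
# of the occupied sac and an equivalent permeability; flow through the
# pack feels a momentum sink -(mu/k) u per unit volume over the sac.

# Anchor points relating porosity to permeability (m^2) for coiled sacs;
# intermediate porosities are interpolated linearly between them.
.coil_perm_table <- data.frame(
  porosity     = c(0.75, 0.85),
  permeability = c(3.7e-8, 5.4e-8)
)

#' Coil specification
#'
#' Geometry of a detachable coil packed into an aneurysm sac: wire
#' diameter, deployed wire length, and the sac volume it occupies.  All in
#' SI units (m, m, m^3).
#'
#' @param wire_diameter Coil wire diameter, m.
#' @param length Total deployed coil length, m.
#' @param sac_volume Aneurysm sac volume, m^3.
#' @return An object of class `coil_spec`.
#' @examples
#' # a 0.254 mm wire, 30 cm long, in a 103.87 mm^3 sac
#' coil_spec(0.254e-3, 0.30, 103.87e-9)
#' @export
coil_spec <- function(wire_diameter, length, sac_volume) {
  stopifnot(wire_diameter > 0, length > 0, sac_volume > 0)
  structure(list(wire_diameter = wire_diameter, length = length,
                 sac_volume = sac_volume),
            class = "coil_spec")
}

#' Porosity of a coiled sac
#'
#' The coil occupies a cylinder volume `pi d_w^2 L / 4`; porosity is the
#' remaining fluid fraction `1 - V_coil / V_sac`.
#'
#' @param spec A [coil_spec()].
#' @return Porosity in `(0, 1)`.
#' @export
porosity_from_coil <- function(spec) {
  stopifnot(inherits(spec, "coil_spec"))
  v_coil <- pi * spec$wire_diameter^2 * spec$length / 4
  if (v_coil >= spec$sac_volume)
    stop(sprintf(
      "coil volume %.4g m^3 is not smaller than sac volume %.4g m^3 (overpacked)",
      v_coil, spec$sac_volume))
  1 - v_coil / spec$sac_volume
}

#' Permeability for a given coil-pack porosity
#'
#' Interpolates/extrapolates permeability linearly against porosity
#' through the two tabulated anchor points (0.75, 3.7e-8 m^2) and
#' (0.85, 5.4e-8 m^2), clamped positive.  `porosity = 1` means no coil:
#' the sink is disabled and `Inf` is returned so that `mu/k` is exactly
#' zero.
#'
#' @param porosity Fluid volume fraction in `(0, 1]`.
#' @return Permeability, m^2 (`Inf` for porosity 1).
#' @export
permeability_for_porosity <- function(porosity) {
  stopifnot(is.numeric(porosity), length(porosity) == 1L)
  if (porosity <= 0) stop("porosity must be positive, got ", porosity)
  if (porosity > 1) stop("porosity cannot exceed 1, got ", porosity)
  if (porosity == 1) return(Inf)
  tb <- .coil_perm_table
  slope <- diff(tb$permeability) / diff(tb$porosity)
  k <- tb$permeability[1L] + slope * (porosity - tb$porosity[1L])
  max(k, 1e-12)  # clamp: extrapolation must stay positive
}

#' Porous-medium properties of the coiled sac
#'
#' @param porosity Fluid volume fraction in `(0, 1]`; 1 disables the sink.
#' @param permeability Permeability, m^2.  Defaults to
#'   [permeability_for_porosity()] of `porosity`.
#' @return An object of class `porous_props`.
#' @export
porous_props <- function(porosity = 1,
                         permeability = permeability_for_porosity(porosity)) {
  stopifnot(porosity > 0, porosity <= 1, permeability > 0)
  structure(list(porosity = porosity, permeability = permeability),
            class = "porous_props")
}

#' Darcy momentum sink
#'
#' Momentum source per unit volume exerted by the coil pack on the fluid:
#' \eqn{-(\mu_{app}/k)\,u} (Pa/m).  Identically zero when the porosity is
#' 1 (permeability `Inf`).  Applied by the solver on sac cells only.
#'
#' @param u Velocity, m/s; a length-2 vector or an n x 2 matrix.
#' @param mu_app Apparent viscosity, Pa s (scalar or length n).
#' @param props A [porous_props()] object.
#' @return Momentum source with the shape of `u`, Pa/m.
#' @export
darcy_sink <- function(u, mu_app, props) {
  stopifnot(inherits(props, "porous_props"))
  -(mu_app / props$permeability) * u
}

#' @export
print.porous_props <- function(x, ...) {
  cat(sprintf("Porous coil pack: porosity %.3f, permeability %s\n",
              x$porosity,
              if (is.finite(x$permeability))
                sprintf("%.3g m^2", x$permeability) else "Inf (sink off)"))
  invisible(x)
}
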