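# Casson blood rheology with hematocrit-dependent coefficients.
#
# Apparent viscosity follows the Casson law
#   mu(gdot) = (sqrt(tau_y / gdot) + sqrt(mu_inf))^2
# regularized by a shear-rate floor gdot_min so the stagnant limit stays
# finite.  tau_y is the yield stress (Pa), mu_inf the asymptotic
# (high-shear) Casson viscosity (Pa s).

#' Casson rheology parameters
#'
#' Container for the coefficients of the regularized Casson constitutive
#' law.  Either construct directly or derive from hematocrit with
#' [params_from_hematocrit()].
#'
#' @param tau_y Yield stress, Pa (`>= 0`; `0` gives a Newtonian fluid with
#'   viscosity `mu_inf`).
#' @param mu_inf Asymptotic high-shear viscosity, Pa s (`> 0`).
#' @param hematocrit Red-cell volume fraction in `(0, 1)`, or `NA` when the
#'   coefficients were given explicitly.
#' @param plasma_viscosity Plasma viscosity, Pa s; only used by the
#'   hematocrit correlation.
#' @param gamma_dot_min Regularization floor for the shear rate, 1/s.
#'   Shear rates below this value are clamped before evaluating the Casson
#'   law, bounding the apparent viscosity.
#' @return An object of class `casson_params`.
#' @seealso [apparent_viscosity()], [params_from_hematocrit()],
#'   [newtonian_params()]
#' @export
casson_params <- function(tau_y, mu_inf, hematocrit = NA_real_,
                          plasma_viscosity = 0.00145,
                          gamma_dot_min = 1e-3) {
  stopifnot(is.numeric(tau_y), length(tau_y) == 1L, tau_y >= 0,
            is.numeric(mu_inf), length(mu_inf) == 1L, mu_inf > 0,
            is.numeric(gamma_dot_min), gamma_dot_min > 0)
  if (!is.na(hematocrit) && (hematocrit <= 0 || hematocrit >= 1))
    stop("hematocrit must lie strictly between 0 and 1, got ", hematocrit)
  structure(
    list(tau_y = tau_y, mu_inf = mu_inf, hematocrit = hematocrit,
         plasma_viscosity = plasma_viscosity,
         gamma_dot_min = gamma_dot_min),
    class = "casson_params"
  )
}

#' Newtonian fluid as a degenerate Casson law
#'
#' Convenience constructor for a constant-viscosity fluid: a
#' `casson_params` object with zero yield stress, for which
#' [apparent_viscosity()] returns `mu` identically.
#'
#' @param mu Dynamic viscosity, Pa s.
#' @inheritParams casson_params
#' @return A `casson_params` object with `tau_y = 0`.
#' @export
newtonian_params <- function(mu, gamma_dot_min = 1e-3) {
  casson_params(tau_y = 0, mu_inf = mu, gamma_dot_min = gamma_dot_min)
}

#' Derive Casson coefficients from hematocrit
#'
#' Maps the red-cell volume fraction H to Casson coefficients with a
#' Merrill/Einstein-type parameterization:
#' \deqn{\tau_y(H) = 0.1\,(0.625\,H)^3 \;\mathrm{Pa}, \qquad
#'       \mu_\infty(H) = \eta_p (1-H)^{-2.5},}
#' where \eqn{\eta_p} is the plasma viscosity.  Both coefficients increase
#' strictly with H, so hematocrit sweeps move yield stress and viscosity
#' together, as they do in whole blood.
#'
#' @param H Hematocrit, volume fraction strictly inside `(0, 1)`.
#' @inheritParams casson_params
#' @return A `casson_params` object.
#' @examples
#' params_from_hematocrit(0.40)  # normal hematocrit
#' @export
params_from_hematocrit <- function(H, plasma_viscosity = 0.00145,
                                   gamma_dot_min = 1e-3) {
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0 || H >= 1)
    stop("hematocrit must lie strictly between 0 and 1, got ", H)
  casson_params(
    tau_y = 0.1 * (0.625 * H)^3,
    mu_inf = plasma_viscosity * (1 - H)^(-2.5),
    hematocrit = H,
    plasma_viscosity = plasma_viscosity,
    gamma_dot_min = gamma_dot_min
  )
}

#' Casson apparent viscosity
#'
#' Evaluates the regularized Casson law
#' \deqn{\mu(\dot\gamma) = \left(\sqrt{\tau_y / \max(\dot\gamma,
#'   \dot\gamma_{\min})} + \sqrt{\mu_\infty}\right)^2.}
#' Vectorized over `gamma_dot`.  For `tau_y = 0` the result is exactly
#' `mu_inf` (bitwise), so a zero-yield Casson fluid and an explicit
#' Newtonian fluid follow identical code paths in the solver.
#'
#' @param gamma_dot Shear rate(s), 1/s, `>= 0`.
#' @param params A [casson_params()] object.
#' @return Apparent viscosity, Pa s, same length as `gamma_dot`.
#' @examples
#' p <- casson_params(tau_y = 0.01, mu_inf = 0.0035)
#' apparent_viscosity(1, p)      # 0.0253...
#' apparent_viscosity(1e6, p)    # ~ mu_inf
#' @export
apparent_viscosity <- function(gamma_dot, params) {
  stopifnot(inherits(params, "casson_params"), all(gamma_dot >= 0))
  if (params$tau_y == 0) return(rep(params$mu_inf, length(gamma_dot)))
  g <- pmax(gamma_dot, params$gamma_dot_min)
  (sqrt(params$tau_y / g) + sqrt(params$mu_inf))^2
}

#' Shear rate from a velocity gradient tensor
#'
#' Second-invariant shear rate \eqn{\dot\gamma = \sqrt{2\,D : D}} with
#' \eqn{D = \tfrac12(\nabla u + \nabla u^T)} the rate-of-strain tensor.
#'
#' @param grad 2x2 velocity-gradient matrix (entries `du_i/dx_j`), 1/s.
#' @return Scalar shear rate, 1/s, `>= 0`.
#' @export
shear_rate <- function(grad) {
  stopifnot(is.matrix(grad), all(dim(grad) == c(2L, 2L)), all(is.finite(grad)))
  D <- 0.5 * (grad + t(grad))
  sqrt(2 * sum(D * D))
}

# Vectorized shear rate for the assembly loop: element-constant gradient
# components as vectors.  gdot = sqrt(2 ux^2 + 2 vy^2 + (uy + vx)^2).
shear_rate_components <- function(ux, uy, vx, vy) {
  sqrt(2 * ux^2 + 2 * vy^2 + (uy + vx)^2)
}

#' @export
print.casson_params <- function(x, ...) {
  cat("Casson rheology\n")
  if (!is.na(x$hematocrit))
    cat(sprintf("  hematocrit      : %.3f\n", x$hematocrit))
  cat(sprintf("  yield stress    : %.6g Pa\n", x$tau_y))
  cat(sprintf("  mu_inf          : %.6g Pa s\n", x$mu_inf))
  cat(sprintf("  shear-rate floor: %.3g 1/s\n", x$gamma_dot_min))
  invisible(x)
}
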