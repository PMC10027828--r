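# Pulsatile inflow waveform for the cardiac cycle.
#
# The section-mean inlet velocity over one cycle is modeled as a mean
# plus a small number of cosine harmonics phased so that the maximum
# falls at peak systole.  The default MCA profile peaks at t = 0.24 s and
# is decelerating ("early diastole") at t = 0.54 s of a 0.8 s cycle; for
# other periods both phase times scale proportionally.

#' Generate a pulsatile inflow waveform
#'
#' Builds the periodic section-mean inlet velocity
#' \deqn{v(t) = \bar v \Big(1 + \sum_n a_n \cos\big(2\pi n (t -
#'   t_{sys})/T\big)\Big)}
#' whose unique maximum over one period lies at peak systole
#' \eqn{t_{sys}}.  The harmonic amplitudes keep the waveform strictly
#' positive (no inflow reversal) and leave the period mean exactly
#' \eqn{\bar v}.
#'
#' The `default_mca` profile uses relative amplitudes (0.8, 0.2): with the
#' default mean of 0.25 m/s the peak is 0.5 m/s at t = 0.24 s and the
#' minimum 0.1 m/s, a plausible middle-cerebral-artery envelope.
#'
#' @param profile Waveform family; only `"default_mca"` is defined.
#' @param period Cardiac period T, s.
#' @param mean_velocity Cycle-mean section velocity, m/s.
#' @param rel_amplitudes Harmonic amplitudes relative to the mean; must
#'   keep the waveform positive.
#' @return An object of class `aneu_waveform` with fields `period`,
#'   `mean_velocity`, `harmonics` (amplitude m/s, phase rad),
#'   `t_peak_systole` and `t_early_diastole` (s).
#' @examples
#' w <- generate_waveform()
#' waveform_velocity(w, w$t_peak_systole)  # 0.5 m/s
#' @export
generate_waveform <- function(profile = "default_mca", period = 0.8,
                              mean_velocity = 0.25,
                              rel_amplitudes = c(0.8, 0.2)) {
  if (!identical(profile, "default_mca"))
    stop("unknown waveform profile: ", profile)
  stopifnot(period > 0, mean_velocity > 0)
  amps <- mean_velocity * rel_amplitudes
  # positivity: worst case is all harmonics at their trough simultaneously
  if (mean_velocity - sum(abs(amps)) <= 0 &&
      min(vapply(seq_len(2048L),
                 function(i) {
                   th <- 2 * pi * (i - 1) / 2048
                   mean_velocity + sum(amps * cos(seq_along(amps) * th))
                 }, numeric(1))) <= 0)
    stop("harmonic amplitudes produce a non-positive waveform")
  structure(
    list(period = period,
         mean_velocity = mean_velocity,
         harmonics = data.frame(amplitude = amps,
                                phase = rep(0, length(amps))),
         t_peak_systole = 0.24 * period / 0.8,
         t_early_diastole = 0.54 * period / 0.8),
    class = "aneu_waveform"
  )
}

#' Evaluate a waveform
#'
#' Periodic in `t` with period `w$period`; vectorized.
#'
#' @param w An [generate_waveform()] object.
#' @param t Time(s), s.
#' @return Section-mean velocity, m/s.
#' @export
waveform_velocity <- function(w, t) {
  stopifnot(inherits(w, "aneu_waveform"))
  theta <- 2 * pi * (t - w$t_peak_systole) / w$period
  v <- rep(w$mean_velocity, length(t))
  for (n in seq_len(nrow(w$harmonics)))
    v <- v + w$harmonics$amplitude[n] * cos(n * theta + w$harmonics$phase[n])
  v
}

#' Export a waveform as a two-column CSV
#'
#' Writes `time,velocity` samples of one period.
#'
#' @param w An `aneu_waveform`.
#' @param path Output file path.
#' @param n Number of samples over one period.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path, n = 200L) {
  t <- seq(0, w$period, length.out = n)
  utils::write.csv(data.frame(time = t, velocity = waveform_velocity(w, t)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.aneu_waveform <- function(x, ...) {
  cat(sprintf(
    "Pulsatile waveform: period %.3g s, mean %.3g m/s, peak %.3g m/s\n",
    x$period, x$mean_velocity,
    x$mean_velocity + sum(x$harmonics$amplitude)))
  cat(sprintf("  peak systole at t = %.3g s, early diastole at t = %.3g s\n",
              x$t_peak_systole, x$t_early_diastole))
  invisible(x)
}

#' @export
plot.aneu_waveform <- function(x, n = 400L, ...) {
  t <- seq(0, x$period, length.out = n)
  graphics::plot(t, waveform_velocity(x, t), type = "l",
                 xlab = "time (s)", ylab = "inlet mean velocity (m/s)", ...)
  graphics::abline(v = c(x$t_peak_systole, x$t_early_diastole),
                   lty = 3, col = "grey40")
  invisible(x)
}
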