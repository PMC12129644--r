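#' Pulse-sequence parameters for a stimulated-echo diffusion experiment
#'
#' Bundles the timing and gradient constants of a pulsed-field-gradient
#' stimulated-echo (PFG-STE) experiment. The echo amplitude follows
#' \deqn{A(\tau, \tau_1, g, \delta) \propto
#'   \exp(-2\tau/T_2 - \tau_1/T_1)\,\exp(-\gamma^2 g^2 \delta^2 D t_d),}
#' where \eqn{t_d = \Delta - \delta/3} is the diffusion time for rectangular
#' gradient pulses and \eqn{\Delta = \tau + \tau_1} the gradient pulse
#' separation.
#'
#' Exactly one of `Delta`, `t_d`, or the pair `tau`/`tau1` must determine the
#' pulse separation. When `tau`/`tau1` are not supplied they default to
#' `tau = delta` and `tau1 = Delta - tau`; they only enter through the
#' (gradient-independent) relaxation prefactor, so this convention does not
#' affect diffusion coefficients.
#'
#' @param delta Gradient pulse duration, s.
#' @param Delta Gradient pulse separation, s (optional; see Details).
#' @param t_d Diffusion time, s. For rectangular pulses
#'   `Delta = t_d + delta/3`; for sine-shaped pulses `Delta = t_d + delta/4`.
#' @param tau First echo interval, s.
#' @param tau1 Longitudinal storage interval, s.
#' @param gamma Gyromagnetic ratio, rad s\eqn{^{-1}} T\eqn{^{-1}}. Default is
#'   the proton value 2.6752e8.
#' @param T1,T2 Spin-lattice and spin-spin relaxation times, s. Default `Inf`
#'   (no relaxation attenuation).
#' @param shape Gradient pulse shape, `"rectangular"` or `"sine"`.
#'
#' @return An object of class `pulse_params`.
#' @seealso [b_factor()], [relaxation_prefactor()]
#' @examples
#' pp <- pulse_params(delta = 1e-3, t_d = 0.05)
#' b_factor(pp, g = 1)
#' @export
pulse_params <- function(delta, Delta = NULL, t_d = NULL, tau = NULL, tau1 = NULL,
                         gamma = 2.6752e8, T1 = Inf, T2 = Inf,
                         shape = c("rectangular", "sine")) {
  shape <- match.arg(shape)
  if (!is_number(delta) || delta <= 0) {
    stop_soludiff("'delta' must be a single positive number (s)", "parameter_error")
  }
  if (!is_number(gamma) || gamma <= 0) {
    stop_soludiff("'gamma' must be a single positive number", "parameter_error")
  }
  if (!is.null(tau) && !is.null(tau1)) {
    if (!is_number(tau) || tau <= 0 || !is_number(tau1) || tau1 <= 0) {
      stop_soludiff("'tau' and 'tau1' must be positive numbers (s)", "parameter_error")
    }
    Delta_from_tau <- tau + tau1
    if (!is.null(Delta) && abs(Delta - Delta_from_tau) > 1e-12) {
      stop_soludiff("'Delta' inconsistent with tau + tau1", "parameter_error")
    }
    Delta <- Delta_from_tau
  }
  if (is.null(Delta)) {
    if (is.null(t_d)) {
      stop_soludiff("supply 'Delta', 't_d', or both 'tau' and 'tau1'", "parameter_error")
    }
    if (!is_number(t_d) || t_d <= 0) {
      stop_soludiff("'t_d' must be a single positive number (s)", "parameter_error")
    }
    Delta <- if (shape == "rectangular") t_d + delta / 3 else t_d + delta / 4
  }
  if (!is_number(Delta) || Delta <= 0) {
    stop_soludiff("'Delta' must be a single positive number (s)", "parameter_error")
  }
  if (delta >= Delta) {
    stop_soludiff("'delta' must be smaller than 'Delta'", "parameter_error")
  }
  if (Delta - delta / 3 <= 0) {
    stop_soludiff("diffusion time Delta - delta/3 must be positive", "parameter_error")
  }
  if (is.null(tau)) tau <- delta
  if (is.null(tau1)) tau1 <- Delta - tau
  if (tau <= 0 || tau1 <= 0 || abs(tau + tau1 - Delta) > 1e-12) {
    stop_soludiff("'tau' and 'tau1' must be positive and sum to 'Delta'",
                  "parameter_error")
  }
  if (!(is_number(T1) || identical(T1, Inf)) || T1 <= 0 ||
      !(is_number(T2) || identical(T2, Inf)) || T2 <= 0) {
    stop_soludiff("'T1' and 'T2' must be positive (possibly Inf)", "parameter_error")
  }
  structure(
    list(gamma = gamma, delta = delta, Delta = Delta, tau = tau, tau1 = tau1,
         T1 = T1, T2 = T2, shape = shape),
    class = "pulse_params"
  )
}

#' @export
print.pulse_params <- function(x, ...) {
  cat("PFG stimulated-echo parameters (", x$shape, " gradients)\n", sep = "")
  cat(sprintf("  delta = %g ms, Delta = %g ms, t_d = %g ms\n",
              x$delta * 1e3, x$Delta * 1e3, (x$Delta - x$delta / 3) * 1e3))
  cat(sprintf("  tau = %g ms, tau1 = %g ms, T1 = %g s, T2 = %g s\n",
              x$tau * 1e3, x$tau1 * 1e3, x$T1, x$T2))
  cat(sprintf("  gamma = %g rad/s/T\n", x$gamma))
  invisible(x)
}

#' Gradient attenuation factor of the stimulated echo
#'
#' Computes the diffusion-weighting factor \eqn{b} such that a species with
#' self-diffusion coefficient \eqn{D} attenuates as \eqn{\exp(-bD)}:
#' \deqn{b = (\gamma g \delta)^2 (\Delta - \delta/3)} for rectangular
#' gradient pulses and
#' \deqn{b = (\gamma g \delta)^2 \frac{4}{\pi^2} (\Delta - \delta/4)}
#' for sine-shaped (half-sine-lobe) pulses.
#'
#' @param params A [pulse_params()] object.
#' @param g Gradient amplitude(s), T/m; non-negative, vectorised.
#' @return Attenuation factor(s), s m\eqn{^{-2}}; 0 where `g = 0`.
#' @examples
#' pp <- pulse_params(delta = 1e-3, t_d = 0.05)
#' b_factor(pp, c(0, 0.5, 1))
#' @export
b_factor <- function(params, g) {
  stopifnot(inherits(params, "pulse_params"))
  if (!is.numeric(g) || any(!is.finite(g)) || any(g < 0)) {
    stop_soludiff("'g' must be non-negative finite gradient amplitudes (T/m)",
                  "parameter_error")
  }
  base <- (params$gamma * g * params$delta)^2
  switch(params$shape,
    rectangular = base * (params$Delta - params$delta / 3),
    sine        = base * (4 / pi^2) * (params$Delta - params$delta / 4)
  )
}

#' Relaxation prefactor of the stimulated echo
#'
#' The gradient-independent amplitude scale
#' \eqn{\exp(-2\tau/T_2 - \tau_1/T_1)}. Because \eqn{\tau} and \eqn{\tau_1}
#' are held fixed along a gradient ramp, this factor only rescales the
#' zero-gradient amplitude and cancels from diffusion-coefficient estimates.
#'
#' @param params A [pulse_params()] object.
#' @return A dimensionless scale in (0, 1].
#' @export
relaxation_prefactor <- function(params) {
  stopifnot(inherits(params, "pulse_params"))
  exp(-2 * params$tau / params$T2 - params$tau1 / params$T1)
}

#' Exponential decay components
#'
#' Represents a population of molecules as `(fraction, D)` pairs; a decay with
#' components \eqn{(p_i, D_i)} has amplitude
#' \eqn{A(b) = A_0 \sum_i p_i e^{-b D_i}}.
#'
#' @param fraction Population weights in \[0, 1\]; must sum to 1 within 1e-9.
#' @param D Self-diffusion coefficients, m\eqn{^2}/s; positive.
#' @return A data frame with columns `fraction` and `D`.
#' @examples
#' exp_components(c(0.12, 0.88), c(7.6e-11, 2.9e-11))
#' @export
exp_components <- function(fraction, D) {
  if (length(fraction) != length(D) || length(fraction) < 1L) {
    stop_soludiff("'fraction' and 'D' must have equal positive length",
                  "parameter_error")
  }
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop_soludiff("fractions must lie in [0, 1]", "parameter_error")
  }
  if (abs(sum(fraction) - 1) > 1e-9) {
    stop_soludiff("fractions must sum to 1 (within 1e-9)", "validation_error")
  }
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop_soludiff("diffusion coefficients must be positive", "parameter_error")
  }
  data.frame(fraction = as.numeric(fraction), D = as.numeric(D))
}

#' Multi-component echo amplitude
#'
#' Evaluates \eqn{A(b) = A_0 \sum_i p_i e^{-b D_i}} for validated
#' components. Monotonically non-increasing in `b`; equals `A0` at `b = 0`.
#'
#' @param A0 Zero-gradient amplitude (> 0), arbitrary units.
#' @param components A component table from [exp_components()] (or a data
#'   frame with columns `fraction`, `D`).
#' @param b Attenuation factor(s) from [b_factor()], s m\eqn{^{-2}}.
#' @return Echo amplitude(s), same length as `b`.
#' @export
echo_amplitude <- function(A0, components, b) {
  if (!is_number(A0) || A0 <= 0) {
    stop_soludiff("'A0' must be a single positive number", "parameter_error")
  }
  components <- exp_components(components$fraction, components$D)
  if (!is.numeric(b) || any(!is.finite(b)) || any(b < 0)) {
    stop_soludiff("'b' must be non-negative and finite", "parameter_error")
  }
  A0 * as.numeric(exp(-outer(b, components$D)) %*% components$fraction)
}

#' A measured or simulated diffusion decay
#'
#' One gradient ramp: strictly increasing gradient amplitudes with the echo
#' amplitudes recorded at each, plus the pulse-sequence parameters needed to
#' convert gradients to attenuation factors.
#'
#' @param g Gradient amplitudes, T/m; non-negative, strictly increasing,
#'   length >= 4.
#' @param A Echo amplitudes, arbitrary units; `A[1]` must be positive.
#' @param params A [pulse_params()] object.
#' @param label Species name (optional).
#' @param concentration Surfactant concentration, g/L (optional).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(g, A, params, label = NA_character_,
                        concentration = NA_real_) {
  stopifnot(inherits(params, "pulse_params"))
  if (!is.numeric(g) || !is.numeric(A) || length(g) != length(A)) {
    stop_soludiff("'g' and 'A' must be numeric vectors of equal length",
                  "data_error")
  }
  if (length(g) < 4L) {
    stop_soludiff("a decay curve needs at least 4 points", "data_error")
  }
  if (any(!is.finite(g)) || any(!is.finite(A))) {
    stop_soludiff("'g' and 'A' must be finite", "data_error")
  }
  if (g[1] < 0 || any(diff(g) <= 0)) {
    stop_soludiff("'g' must be non-negative and strictly increasing", "data_error")
  }
  if (A[1] <= 0) {
    stop_soludiff("the zero/lowest-gradient amplitude must be positive", "data_error")
  }
  structure(
    list(g = as.numeric(g), A = as.numeric(A), params = params,
         label = label, concentration = concentration),
    class = "decay_curve"
  )
}

#' Attenuation factors of a decay curve
#'
#' @param decay A [decay_curve()].
#' @return The vector `b_factor(decay$params, decay$g)`.
#' @export
decay_b <- function(decay) {
  stopifnot(inherits(decay, "decay_curve"))
  b_factor(decay$params, decay$g)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("Diffusion decay: %d points, g in [%g, %g] T/m",
              length(x$g), min(x$g), max(x$g)))
  if (!is.na(x$label)) cat(", species ", x$label, sep = "")
  if (!is.na(x$concentration)) cat(sprintf(" at %g g/L", x$concentration))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.decay_curve <- function(x, ...) {
  data.frame(g_T_per_m = x$g, b_s_per_m2 = decay_b(x), amplitude = x$A)
}

#' Semi-logarithmic plot of a diffusion decay
#'
#' @param x A [decay_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.decay_curve <- function(x, ...) {
  graphics::plot(decay_b(x), log(x$A),
                 xlab = expression(b ~ (s ~ m^-2)), ylab = "ln A", ...)
}
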