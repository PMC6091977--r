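#' Activity-coefficient parameters for a 1:1 electrolyte
#'
#' Bundles the constants of the Debye-Hueckel and Davies equations used to
#' convert DMACl concentrations into ionic activities. Defaults are the
#' standard 25 degC aqueous values: the Debye-Hueckel slope A = 0.509, the
#' distance-of-closest-approach term B = 3.28 nm^-1 M^-1/2 with an ion size
#' d = 0.35 nm for dimethylammonium, and the Davies linear coefficient 0.3.
#' `switch_conc` is the concentration (mol/L) at which the conversion
#' switches from the Debye-Hueckel branch (below) to the Davies branch
#' (at and above).
#'
#' @param debye_A Debye-Hueckel limiting slope (dimensionless, base-10).
#' @param charge_z Integer ion charge (+1 for DMA).
#' @param ion_size_d Ion size parameter in nm.
#' @param size_B Size coefficient in nm^-1 M^-1/2.
#' @param davies_C Davies linear coefficient (dimensionless).
#' @param switch_conc Branch-switch concentration in mol/L.
#' @return An object of class `activity_params`.
#' @export
#' @examples
#' p <- activity_params()
#' activity(0.110, p)  # ~0.085 M
activity_params <- function(debye_A = 0.509, charge_z = 1L, ion_size_d = 0.35,
                            size_B = 3.28, davies_C = 0.3, switch_conc = 0.100) {
  stopifnot(debye_A > 0, ion_size_d > 0, size_B > 0, davies_C > 0,
            switch_conc > 0, charge_z == as.integer(charge_z))
  structure(list(debye_A = debye_A, charge_z = as.integer(charge_z),
                 ion_size_d = ion_size_d, size_B = size_B,
                 davies_C = davies_C, switch_conc = switch_conc),
            class = "activity_params")
}

#' Ionic strength of a fully dissociated 1:1 salt
#'
#' For a 1:1 salt at concentration c, I = (1/2) sum c_i z_i^2 = c.
#'
#' @param conc Salt concentration in mol/L (vectorized, non-negative).
#' @return Ionic strength in mol/L.
#' @export
ionic_strength <- function(conc) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be finite and non-negative", call. = FALSE)
  }
  conc
}

#' Debye-Hueckel activity coefficient (base-10 logarithm)
#'
#' log10 gamma = -A z^2 sqrt(I) / (1 + B d sqrt(I)), the extended
#' Debye-Hueckel form appropriate for DMACl below ~100 mM.
#'
#' @param Ic Ionic strength in mol/L (vectorized, non-negative).
#' @param params An [activity_params()] object.
#' @return log10 of the activity coefficient (<= 0).
#' @export
debye_huckel_log_gamma <- function(Ic, params = activity_params()) {
  if (any(!is.finite(Ic)) || any(Ic < 0)) {
    stop("`Ic` must be finite and non-negative", call. = FALSE)
  }
  s <- sqrt(Ic)
  -params$debye_A * params$charge_z^2 * s / (1 + params$size_B * params$ion_size_d * s)
}

#' Davies activity coefficient (base-10 logarithm)
#'
#' log10 gamma = -A z^2 (sqrt(I)/(1 + sqrt(I)) - C I), used for DMACl at and
#' above 100 mM where the extended Debye-Hueckel form underestimates gamma.
#'
#' @inheritParams debye_huckel_log_gamma
#' @return log10 of the activity coefficient.
#' @export
davies_log_gamma <- function(Ic, params = activity_params()) {
  if (any(!is.finite(Ic)) || any(Ic < 0)) {
    stop("`Ic` must be finite and non-negative", call. = FALSE)
  }
  s <- sqrt(Ic)
  -params$debye_A * params$charge_z^2 * (s / (1 + s) - params$davies_C * Ic)
}

#' Ionic activity of a 1:1 salt
#'
#' Converts concentration to thermodynamic activity, a = gamma(I) * c, using
#' the Debye-Hueckel branch for `conc < switch_conc` and the Davies branch at
#' and above it.
#'
#' @param conc Salt concentration in mol/L (vectorized, non-negative).
#' @param params An [activity_params()] object.
#' @return Activity in mol/L.
#' @export
activity <- function(conc, params = activity_params()) {
  Ic <- ionic_strength(conc)
  log_g <- ifelse(conc < params$switch_conc,
                  debye_huckel_log_gamma(Ic, params),
                  davies_log_gamma(Ic, params))
  conc * 10^log_g
}

#' Concentration whose activity equals a given value
#'
#' Numerical inverse of [activity()]; used to report fitted half-activation
#' constants on the concentration scale the conductance data were recorded
#' on. The activity map is strictly increasing on the relevant range, so the
#' root is unique.
#'
#' @param a Target activity in mol/L (scalar, non-negative).
#' @param params An [activity_params()] object.
#' @return Concentration in mol/L.
#' @export
inverse_activity <- function(a, params = activity_params()) {
  stopifnot(length(a) == 1L, is.finite(a), a >= 0)
  if (a == 0) return(0)
  upper <- max(1, 4 * a)
  while (activity(upper, params) < a) upper <- upper * 2
  stats::uniroot(function(c) activity(c, params) - a,
                 lower = a, upper = upper, tol = 1e-12)$root
}

#' @export
print.activity_params <- function(x, ...) {
  cat("Activity-coefficient parameters (1:1 salt)\n")
  cat(sprintf("  A = %.3f, z = %+d, d = %.2f nm, B = %.2f, C = %.2f\n",
              x$debye_A, x$charge_z, x$ion_size_d, x$size_B, x$davies_C))
  cat(sprintf("  Debye-Hueckel below %.0f mM, Davies at/above\n",
              1000 * x$switch_conc))
  invisible(x)
}
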