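#' Boltzmann factor kT in kJ/mol
#'
#' @param temperature Temperature in K.
#' @return R * T in kJ/mol (2.494 kJ/mol at 300 K).
#' @export
kT_kJmol <- function(temperature = 300) 8.314462618e-3 * temperature

#' Rate constants of the two-site single-file permeation model
#'
#' The four-state hopping scheme has states E (empty), L (ion in the left,
#' intracellular-facing site), R (ion in the right site) and D (both sites
#' occupied), with transitions E->L (kL * X), L->R (k+), R->L (k-),
#' R->E (kR), R->D (kL * X) and D->L (kRtilde). All rates are dimensionless
#' multiples of a common kinetic prefactor; kL carries prefactor * M^-1 and
#' defaults to 1 (barrierless entry from the intracellular bulk). Backward
#' crossing from the extracellular side is neglected.
#'
#' Defaults are the Arrhenius estimates from the one- and two-ion
#' free-energy profiles: k+ = exp(-0.5), k- = exp(-1.5), kR = exp(-15) and,
#' with a second ion destabilizing the bound one, kRtilde = exp(-7.5).
#'
#' @param kL Entry rate constant (prefactor * M^-1).
#' @param kplus Left-to-right hop rate (prefactor units).
#' @param kminus Right-to-left hop rate (prefactor units).
#' @param kR Right-exit rate from single occupancy (prefactor units).
#' @param kRtilde Right-exit rate from double occupancy (prefactor units).
#' @return An object of class `two_site_rates`.
#' @export
two_site_rates <- function(kL = 1, kplus = exp(-0.5), kminus = exp(-1.5),
                           kR = exp(-15), kRtilde = exp(-7.5)) {
  r <- c(kL = kL, kplus = kplus, kminus = kminus, kR = kR, kRtilde = kRtilde)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(r), class = "two_site_rates")
}

#' @export
print.two_site_rates <- function(x, ...) {
  cat("Two-site single-file permeation rates (prefactor units)\n")
  cat(sprintf("  kL = %.4g M^-1, k+ = %.4g, k- = %.4g, kR = %.4g, kR~ = %.4g\n",
              x$kL, x$kplus, x$kminus, x$kR, x$kRtilde))
  invisible(x)
}

#' Arrhenius rate from a dimensionless barrier
#'
#' With a common kinetic prefactor for all transitions, a barrier of height
#' b (in kT) gives a rate exp(-b) in prefactor units.
#'
#' @param barrier Barrier height in kT units (dimensionless, vectorized).
#' @return Rate in prefactor units.
#' @export
arrhenius_rate <- function(barrier) {
  if (any(!is.finite(barrier))) stop("`barrier` must be finite", call. = FALSE)
  exp(-barrier)
}

#' Extract two-site hopping rates from free-energy profiles
#'
#' Arrhenius rates from barrier heights on the profiles, with a common
#' kinetic prefactor and barriers in units of kT at the profile temperature:
#' `kR` from the full escape barrier of the right (bound) site on the
#' single-ion profile toward the bulk, `kRtilde` from the escape barrier of
#' the bound well on the two-ion profile, and `k+`/`k-` from the inter-site
#' barrier between the two binding sites measured from each side (so that
#' detailed balance k+/k- = exp((G_L - G_R)/kT) holds by construction).
#' `kL` is not derivable from a profile (entry is barrierless) and is kept
#' at the supplied value.
#'
#' @param single Single-ion [free_energy_profile()].
#' @param double Two-ion [free_energy_profile()].
#' @param site_L,site_R One-row data.frames from [find_minima()] on
#'   `single`: the left (larger z, intracellular-facing) and right (smaller
#'   z, bound) sites.
#' @param kL Entry rate constant to carry through (default 1).
#' @return A [two_site_rates()] object.
#' @export
rates_from_profiles <- function(single, double, site_L, site_R, kL = 1) {
  stopifnot(inherits(single, "fe_profile"), inherits(double, "fe_profile"))
  site_L <- .resolve_minimum(single, site_L)
  site_R <- .resolve_minimum(single, site_R)
  kT1 <- kT_kJmol(single$temperature)
  kT2 <- kT_kJmol(double$temperature)
  kR <- exp(-barrier_height(single, site_R, "increasing") / kT1)
  gm2 <- global_minimum(double)
  kRtilde <- exp(-barrier_height(double, gm2, "increasing") / kT2)
  lo <- min(site_L$z_min, site_R$z_min)
  hi <- max(site_L$z_min, site_R$z_min)
  Gbar <- max(single$G[single$z >= lo & single$z <= hi])
  kplus <- exp(-(Gbar - site_L$G_min) / kT1)
  kminus <- exp(-(Gbar - site_R$G_min) / kT1)
  two_site_rates(kL = kL, kplus = kplus, kminus = kminus,
                 kR = kR, kRtilde = kRtilde)
}

#' Single-site Michaelis-Menten flux
#'
#' The one-site, two-state (empty/occupied) model with entry rate kL * X and
#' exit rate kR gives the stationary flux J = kL X / (X kL / kR + 1): the
#' Michaelis-Menten form with half-activation X = kR / kL and saturation at
#' kR.
#'
#' @param kL Entry rate constant (prefactor * M^-1).
#' @param kR Exit rate (prefactor units).
#' @param X Intracellular permeant concentration, mol/L (vectorized).
#' @return Flux in prefactor units.
#' @export
single_site_flux <- function(kL, kR, X) {
  stopifnot(kL >= 0, kR >= 0, all(X >= 0))
  if (kR == 0) return(rep(0, length(X)))
  kL * X / (X * kL / kR + 1)
}

#' Closed-form stationary flux of the two-site model
#'
#' The analytic solution of the four-state master equation:
#' \deqn{J = \frac{X k_L k^+ \tilde k_R (X k_L + k_R)}
#'   {(k^+ + \tilde k_R) X^2 k_L^2 + \tilde k_R (k_R + k^- + k^+) X k_L +
#'    k_R k^+ \tilde k_R}}
#'
#' @param rates A [two_site_rates()] object.
#' @param X Intracellular permeant concentration, mol/L (vectorized).
#' @return Flux in prefactor units.
#' @export
two_site_flux <- function(rates, X) {
  stopifnot(inherits(rates, "two_site_rates"), all(X >= 0))
  with(rates, {
    num <- X * kL * kplus * kRtilde * (X * kL + kR)
    den <- (kplus + kRtilde) * X^2 * kL^2 +
      kRtilde * (kR + kminus + kplus) * X * kL +
      kR * kplus * kRtilde
    ifelse(X == 0, 0, ifelse(den == 0, 0, num / den))
  })
}

#' Stationary state of the two-site master equation
#'
#' Solves the four balance equations plus normalization by a linear solve
#' (one balance row is replaced by the normalization constraint, since the
#' generator matrix is rank-deficient by construction). The flux is
#' J = kR * pR + kRtilde * pD.
#'
#' @param rates A [two_site_rates()] object.
#' @param X Intracellular permeant concentration, mol/L (scalar).
#' @return An object of class `stationary_state`: list with `pE`, `pL`,
#'   `pR`, `pD`, `J`, `X`.
#' @export
two_site_stationary <- function(rates, X) {
  stopifnot(inherits(rates, "two_site_rates"), length(X) == 1L, X >= 0)
  if (X > 0 && rates$kR == 0 && rates$kRtilde == 0) {
    stop("degenerate model: no exit pathway (kR = kRtilde = 0) with X > 0",
         call. = FALSE)
  }
  a <- rates$kL * X
  # generator Q[i, j] = rate i -> j, states (E, L, R, D)
  Q <- matrix(0, 4, 4, dimnames = list(c("E", "L", "R", "D"),
                                       c("E", "L", "R", "D")))
  Q["E", "L"] <- a
  Q["L", "R"] <- rates$kplus
  Q["R", "L"] <- rates$kminus
  Q["R", "E"] <- rates$kR
  Q["R", "D"] <- a
  Q["D", "L"] <- rates$kRtilde
  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[4, ] <- 1                       # replace one balance row by normalization
  b <- c(0, 0, 0, 1)
  p <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate model: stationary state is not unique", call. = FALSE)
  })
  p <- unname(pmin(pmax(p, 0), 1))
  structure(list(pE = p[1], pL = p[2], pR = p[3], pD = p[4],
                 J = rates$kR * p[3] + rates$kRtilde * p[4], X = X),
            class = "stationary_state")
}

#' @export
print.stationary_state <- function(x, ...) {
  cat(sprintf("Stationary state at X = %g M:\n", x$X))
  cat(sprintf("  pE = %.4g  pL = %.4g  pR = %.4g  pD = %.4g\n",
              x$pE, x$pL, x$pR, x$pD))
  cat(sprintf("  flux J = %.6g (prefactor units)\n", x$J))
  invisible(x)
}

#' Two-site flux in the negligible-kR limit
#'
#' Dropping the terms proportional to kR (the single-occupancy exit, slower
#' than every other rate by orders of magnitude) reduces the two-site flux
#' to a Michaelis-Menten form:
#' \deqn{J = \frac{k_L k^+/(k^-+k^+)\, X}
#'   {\frac{(k^+ + \tilde k_R) k_L}{(k^-+k^+) \tilde k_R} X + 1}}
#' with saturation at \eqn{k^+ \tilde k_R / (k^+ + \tilde k_R)}.
#'
#' @inheritParams two_site_flux
#' @return Flux in prefactor units.
#' @export
two_site_flux_limit <- function(rates, X) {
  stopifnot(inherits(rates, "two_site_rates"), all(X >= 0))
  with(rates, {
    slope <- kL * kplus / (kminus + kplus)
    inv_K <- (kplus + kRtilde) * kL / ((kminus + kplus) * kRtilde)
    slope * X / (inv_K * X + 1)
  })
}

#' Half-activation concentration of the two-site model
#'
#' The concentration at which the limiting Michaelis-Menten flux reaches
#' half its saturating value:
#' \deqn{X_{1/2} = \frac{(k^- + k^+)\,\tilde k_R}{(k^+ + \tilde k_R)\, k_L}}
#' With the default profile-derived rates and kL = 1 prefactor * M^-1 this
#' evaluates to 7.56e-4 M.
#'
#' @param rates A [two_site_rates()] object.
#' @return Half-activation concentration in mol/L.
#' @export
half_activation <- function(rates) {
  stopifnot(inherits(rates, "two_site_rates"))
  if (rates$kL <= 0 || rates$kRtilde <= 0) {
    stop("`kL` and `kRtilde` must be > 0", call. = FALSE)
  }
  if (rates$kplus + rates$kminus <= 0) {
    stop("`kplus + kminus` must be > 0", call. = FALSE)
  }
  with(rates, (kminus + kplus) * kRtilde / ((kplus + kRtilde) * kL))
}

#' Ion-ion interaction summary
#'
#' Quantifies how the repulsion between two ions in the pore raises the exit
#' rate (kRtilde / kR) and hence shifts the half-activation constant away
#' from the one-site dissociation constant Kd = kR / kL.
#'
#' @param rates A [two_site_rates()] object.
#' @return A list with `kRtilde_over_kR`, `one_site_Kd` (mol/L),
#'   `two_site_Khalf` (mol/L) and `Khalf_over_Kd`.
#' @export
occupancy_ratio_check <- function(rates) {
  stopifnot(inherits(rates, "two_site_rates"))
  Kd <- rates$kR / rates$kL
  Khalf <- half_activation(rates)
  list(kRtilde_over_kR = rates$kRtilde / rates$kR,
       one_site_Kd = Kd,
       two_site_Khalf = Khalf,
       Khalf_over_Kd = Khalf / Kd)
}
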