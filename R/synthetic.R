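#' Specification of a synthetic free-energy profile
#'
#' Describes a profile as a sum of Gaussian wells on a flat baseline,
#' clamped smoothly to the baseline beyond `plateau_start`. Two extras make
#' the generated curves behave like enhanced-sampling output: an optional
#' broad long-range component (a wide, fixed-amplitude Gaussian modelling
#' the slow approach to bulk) and depth calibration — the narrow-well
#' amplitudes are obtained by solving a small linear system so that the
#' realized free energy at each well centre equals exactly `baseline -
#' depth`, even when wells overlap.
#'
#' @param wells Data.frame with columns `label`, `center` (nm), `depth`
#'   (kJ/mol, > 0), `width` (Gaussian sigma, nm, > 0).
#' @param broad Optional data.frame with columns `center`, `amplitude`,
#'   `width` for fixed-amplitude long-range components.
#' @param plateau_start z (nm) beyond which the profile is exactly at
#'   baseline; all well centers must lie below it.
#' @param z_max Grid end (nm), > plateau_start.
#' @param grid_step Grid spacing (nm).
#' @param baseline Plateau free energy (kJ/mol).
#' @param ramp_width Width (nm) of the smoothstep ramp that takes the
#'   profile onto the baseline at `plateau_start`.
#' @param temperature Temperature (K) attached to generated profiles.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(wells, broad = NULL, plateau_start, z_max,
                         grid_step = 0.01, baseline = 0, ramp_width = 0.05,
                         temperature = 300) {
  need <- c("center", "depth", "width")
  if (!is.data.frame(wells) || nrow(wells) > 0 && !all(need %in% names(wells))) {
    stop("`wells` must have columns center, depth, width", call. = FALSE)
  }
  if (nrow(wells) > 0) {
    stopifnot(all(wells$depth > 0), all(wells$width > 0),
              all(wells$center < plateau_start))
    if (is.null(wells$label)) wells$label <- paste0("w", seq_len(nrow(wells)))
  }
  stopifnot(plateau_start < z_max, grid_step > 0, ramp_width > 0,
            temperature > 0)
  if (!is.null(broad)) {
    stopifnot(is.data.frame(broad),
              all(c("center", "amplitude", "width") %in% names(broad)),
              all(broad$amplitude > 0), all(broad$width > 0))
  }
  structure(list(wells = wells, broad = broad, plateau_start = plateau_start,
                 z_max = z_max, grid_step = grid_step, baseline = baseline,
                 ramp_width = ramp_width, temperature = temperature),
            class = "profile_spec")
}

#' Default one-ion profile specification
#'
#' Emulates the free-energy landscape of a single DMA leaving the
#' selectivity filter: four minima (S3 the global one at 37.4 kJ/mol =
#' 15 kT, S4 3 kJ/mol shallower, the off-axis SX and the intracellular S0
#' much shallower), with the profile reaching the bulk plateau at 2 nm.
#' Positions and widths are design choices — only the depth relations and
#' the unbinding distance carry physical meaning.
#'
#' @return A [profile_spec()] object.
#' @export
profile_spec_single_ion <- function() {
  profile_spec(
    wells = data.frame(
      label = c("S3", "S4", "SX", "S0"),
      center = c(0.25, 0.55, 0.90, 1.30),
      depth = c(37.4, 34.4, 8.0, 12.0),
      width = c(0.05, 0.05, 0.06, 0.09),
      stringsAsFactors = FALSE),
    broad = data.frame(center = 1.30, amplitude = 4.0, width = 0.45),
    plateau_start = 2.0, z_max = 3.0, grid_step = 0.01
  )
}

#' Default two-ion profile specification
#'
#' Emulates the landscape of the bound DMA when a second DMA occupies the
#' filter: a single bound well whose depth is reduced by 25 kJ/mol relative
#' to the one-ion global minimum (37.4 - 25.0 = 12.4 kJ/mol), with the ion
#' unbound already at 1 nm.
#'
#' @return A [profile_spec()] object.
#' @export
profile_spec_two_ion <- function() {
  profile_spec(
    wells = data.frame(label = "S3", center = 0.30, depth = 12.4, width = 0.10,
                       stringsAsFactors = FALSE),
    broad = data.frame(center = 0.30, amplitude = 5.0, width = 0.40),
    plateau_start = 1.0, z_max = 2.0, grid_step = 0.01
  )
}

# Sum of Gaussian components (depths positive) at positions z.
.gauss_sum <- function(z, center, amp, width) {
  out <- numeric(length(z))
  for (j in seq_along(center)) {
    out <- out + amp[j] * exp(-(z - center[j])^2 / (2 * width[j]^2))
  }
  out
}

#' Generate a free-energy profile from a specification
#'
#' Deterministic: G(z) = baseline - s(z) * sum of Gaussian wells, where
#' s(z) is a cubic smoothstep that is 1 below `plateau_start - ramp_width`
#' and 0 at `plateau_start`, so the profile sits exactly on the baseline
#' beyond the plateau onset. Narrow-well amplitudes are calibrated (linear
#' solve) so the realized G at each well centre is exactly
#' `baseline - depth`. A warning is raised if overlapping wells merge below
#' a detection prominence of 1 kJ/mol.
#'
#' @param spec A [profile_spec()] object.
#' @return An [free_energy_profile()] object, with the well labels stored in
#'   attribute `well_labels`.
#' @export
make_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  z <- seq(0, spec$z_max, by = spec$grid_step)
  n_wells <- nrow(spec$wells)
  dev <- numeric(length(z))
  broad_at <- function(zz) {
    if (is.null(spec$broad)) return(numeric(length(zz)))
    .gauss_sum(zz, spec$broad$center, spec$broad$amplitude, spec$broad$width)
  }
  if (n_wells > 0) {
    # calibrate amplitudes: realized depth at each centre equals the spec
    A <- outer(seq_len(n_wells), seq_len(n_wells), function(i, j) {
      exp(-(spec$wells$center[i] - spec$wells$center[j])^2 /
            (2 * spec$wells$width[j]^2))
    })
    target <- spec$wells$depth - broad_at(spec$wells$center)
    amp <- tryCatch(solve(A, target), error = function(e) {
      stop("well geometry is degenerate; amplitudes cannot be calibrated",
           call. = FALSE)
    })
    if (any(amp <= 0)) {
      warning("overlapping wells force non-positive amplitudes; ",
              "profile shape may not show all specified minima", call. = FALSE)
    }
    dev <- .gauss_sum(z, spec$wells$center, amp, spec$wells$width)
  }
  dev <- dev + broad_at(z)
  # cubic smoothstep down to the baseline at plateau_start
  ramp0 <- spec$plateau_start - spec$ramp_width
  u <- pmin(pmax((z - ramp0) / spec$ramp_width, 0), 1)
  s <- 1 - (3 * u^2 - 2 * u^3)
  profile <- free_energy_profile(z, spec$baseline - s * dev,
                                 temperature = spec$temperature)
  if (n_wells > 0) {
    found <- find_minima(profile, prominence_min = 1)
    if (nrow(found) < n_wells) {
      warning(sprintf(paste0("only %d of %d wells detected at 1 kJ/mol ",
                             "prominence (wells merged?)"),
                      nrow(found), n_wells), call. = FALSE)
    }
    attr(profile, "well_labels") <- spec$wells$label
  }
  profile
}

#' Specification of a synthetic conductance dataset
#'
#' Describes a dose-response experiment on the normalized-conductance
#' scale: Michaelis-Menten in the ionic activity with a shared
#' half-activation constant (specified on the concentration scale, then
#' converted through the activity map), per-voltage saturating
#' conductances, multiplicative Gaussian replicate noise, and normalization
#' to a reference cell.
#'
#' @param K_half_gen_mM Generating half-activation constant, mM
#'   (concentration scale).
#' @param g_max_per_voltage Named numeric vector, voltage (mV) ->
#'   saturating conductance.
#' @param concentrations_mM Concentrations sampled, mM.
#' @param n_replicates Replicates per (voltage, concentration) cell.
#' @param noise_cv Fractional SD of the multiplicative Gaussian noise.
#' @param seed Integer seed.
#' @param normalization_ref `c(voltage_mV, conc_mM)` of the g = 1 cell.
#' @return An object of class `conductance_spec`.
#' @export
conductance_spec <- function(K_half_gen_mM = 52,
                             g_max_per_voltage = c("140" = 0.7, "160" = 0.8,
                                                   "180" = 0.9, "200" = 1.0),
                             concentrations_mM = c(20, 50, 110, 250),
                             n_replicates = 4L,
                             noise_cv = 0.05,
                             seed = 1234L,
                             normalization_ref = c(voltage_mV = 200, conc_mM = 110)) {
  stopifnot(K_half_gen_mM > 0, noise_cv >= 0, n_replicates >= 1,
            length(g_max_per_voltage) >= 1, !is.null(names(g_max_per_voltage)),
            all(g_max_per_voltage > 0), all(concentrations_mM >= 0))
  structure(list(K_half_gen_mM = K_half_gen_mM,
                 g_max_per_voltage = g_max_per_voltage,
                 concentrations_mM = concentrations_mM,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 normalization_ref = normalization_ref),
            class = "conductance_spec")
}

#' Default conductance-dataset specification
#'
#' The study conditions of the dose-response experiment the fit is tested
#' on: concentrations 20/50/110/250 mM, voltages +140/+160/+180/+200 mV
#' with saturating conductance increasing linearly with voltage, n = 4
#' replicates, 5% multiplicative noise, and a generating half-activation
#' constant of 52 mM (concentration scale) — the apparent Kd of the channel
#' for DMA.
#'
#' @param seed Integer seed (default 1234).
#' @param noise_cv Fractional noise SD (default 0.05).
#' @return A [conductance_spec()] object.
#' @export
conductance_spec_default <- function(seed = 1234L, noise_cv = 0.05) {
  conductance_spec(seed = seed, noise_cv = noise_cv)
}

#' Generate a synthetic conductance dataset
#'
#' For every (voltage, concentration, replicate): g = gmax(V) * a / (a +
#' K_act) * (1 + eps), eps ~ Normal(0, noise_cv), where a is the ionic
#' activity of the concentration and K_act the activity of the generating
#' half-activation constant. The whole table is then rescaled so the mean
#' of the reference cell equals 1, mirroring the experimental
#' normalization. Seeded and reproducible.
#'
#' @param spec A [conductance_spec()] object.
#' @param params An [activity_params()] object.
#' @return A [conductance_dataset()] with activities attached.
#' @export
make_conductance <- function(spec, params = activity_params()) {
  stopifnot(inherits(spec, "conductance_spec"))
  voltages <- as.numeric(names(spec$g_max_per_voltage))
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      conc_mM = spec$concentrations_mM,
                      voltage_mV = voltages)
  grid <- grid[, c("voltage_mV", "conc_mM", "replicate")]
  a <- activity(grid$conc_mM / 1000, params)
  K_act <- activity(spec$K_half_gen_mM / 1000, params)
  gmax <- spec$g_max_per_voltage[as.character(grid$voltage_mV)]
  set.seed(spec$seed)
  eps <- stats::rnorm(nrow(grid), 0, spec$noise_cv)
  g <- unname(gmax * a / (a + K_act) * (1 + eps))
  ref <- grid$voltage_mV == spec$normalization_ref[[1]] &
    grid$conc_mM == spec$normalization_ref[[2]]
  if (any(ref)) g <- g / mean(g[ref])
  conductance_dataset(
    data.frame(grid, g_norm = pmax(g, 0), activity_M = a),
    normalization_ref = spec$normalization_ref
  )
}

#' Seeded AR(1) series
#'
#' First-order autoregressive Gaussian series, x(t+1) = rho * x(t) +
#' Normal(0, sigma), started from the stationary distribution (or a given
#' x0). Used as a correlated-data fixture for block-analysis error
#' estimation.
#'
#' @param n Length (>= 2).
#' @param rho Autocorrelation, |rho| < 1.
#' @param sigma Innovation SD.
#' @param seed Integer seed.
#' @param x0 Optional fixed starting value; by default drawn from the
#'   stationary Normal(0, sigma / sqrt(1 - rho^2)).
#' @return Numeric vector of length `n`.
#' @export
make_ar1_series <- function(n, rho, sigma, seed = 1L, x0 = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2, sigma >= 0)
  if (!is.numeric(rho) || abs(rho) >= 1) {
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (is.null(x0)) {
    x0 <- if (sigma == 0) 0 else stats::rnorm(1, 0, sigma / sqrt(1 - rho^2))
  }
  innov <- stats::rnorm(n - 1L, 0, sigma)
  c(x0, stats::filter(innov, rho, method = "recursive", init = x0))
}
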