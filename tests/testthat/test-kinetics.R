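default_rates <- two_site_rates()

# Residuals of the four stationary balance equations for a solved state.
balance_residuals <- function(rates, st) {
  a <- rates$kL * st$X
  c(E = rates$kR * st$pR - a * st$pE,
    L = a * st$pE + rates$kminus * st$pR + rates$kRtilde * st$pD -
      rates$kplus * st$pL,
    R = rates$kplus * st$pL - (rates$kminus + rates$kR + a) * st$pR,
    D = a * st$pR - rates$kRtilde * st$pD)
}

test_that("arrhenius_rate is exp(-barrier) in kT units", {
  expect_equal(arrhenius_rate(0), 1)
  expect_equal(arrhenius_rate(15), exp(-15))
  expect_equal(arrhenius_rate(7.5), exp(-7.5))
  expect_error(arrhenius_rate(NaN), "finite")
})

test_that("rate extraction from profiles obeys detailed balance and the depth offsets", {
  single <- make_profile(profile_spec_single_ion())
  double <- make_profile(profile_spec_two_ion())
  m <- find_minima(single, 1, labels = attr(single, "well_labels"))
  s3 <- m[m$label == "S3", ]; s4 <- m[m$label == "S4", ]
  r <- rates_from_profiles(single, double, site_L = s4, site_R = s3)
  kT <- kT_kJmol(300)

  # the two-ion well is 25 kJ/mol shallower by construction
  expect_equal(r$kRtilde / r$kR, exp(25 / kT), tolerance = 1e-6)
  # detailed-balance identity of Arrhenius hop rates
  dG_LR <- s4$G_min - s3$G_min
  expect_equal(r$kplus / r$kminus, exp(dG_LR / kT), tolerance = 1e-12)
  # kR from the 15 kT escape barrier of the bound site
  expect_equal(r$kR, exp(-37.4 / kT), tolerance = 1e-6)
  # identical profiles give identical exit rates
  r_same <- rates_from_profiles(single, single, site_L = s4, site_R = s3)
  expect_equal(r_same$kRtilde, r_same$kR)
})

test_that("single-site flux has Michaelis-Menten shape with X1/2 = kR/kL", {
  kL <- 1; kR <- exp(-15)
  expect_equal(single_site_flux(kL, kR, 0), 0)
  expect_equal(single_site_flux(kL, kR, 1e6), kR, tolerance = 1e-6)
  expect_equal(single_site_flux(kL, kR, kR / kL), kR / 2)  # exact half-saturation
  expect_equal(single_site_flux(1, 0, 0.1), 0)             # absorbing site
})

test_that("closed-form flux agrees with the linear solve at default rates", {
  X <- 10^seq(-6, 0, length.out = 40)
  J_closed <- two_site_flux(default_rates, X)
  J_solve <- vapply(X, function(x) two_site_stationary(default_rates, x)$J,
                    numeric(1))
  expect_equal(J_solve, J_closed, tolerance = 1e-12)
})

test_that("stationary solve satisfies balance and normalization, incl. X = 0", {
  st0 <- two_site_stationary(default_rates, 0)
  expect_equal(st0$pE, 1)
  expect_equal(st0$J, 0)
  for (x in c(1e-5, 1e-3, 1e-1)) {
    st <- two_site_stationary(default_rates, x)
    expect_equal(st$pE + st$pL + st$pR + st$pD, 1, tolerance = 1e-10)
    expect_true(all(abs(balance_residuals(default_rates, st)) < 1e-10))
  }
  expect_error(two_site_stationary(two_site_rates(kR = 0, kRtilde = 0), 0.1),
               "degenerate")
})

test_that("closed form and linear solve agree over random rate sets", {
  set.seed(2024)
  for (i in 1:100) {
    r <- two_site_rates(kL = exp(runif(1, -20, 0)),
                        kplus = exp(runif(1, -20, 0)),
                        kminus = exp(runif(1, -20, 0)),
                        kR = exp(runif(1, -20, 0)),
                        kRtilde = exp(runif(1, -20, 0)))
    X <- 10^runif(20, -6, 0)
    J_closed <- two_site_flux(r, X)
    J_solve <- vapply(X, function(x) two_site_stationary(r, x)$J, numeric(1))
    expect_equal(J_solve, J_closed, tolerance = 1e-8)
  }
})

test_that("the negligible-kR limit approximates the full flux and improves as kR shrinks", {
  # the pointwise error of the limit is first order in kR/(kL X): with
  # kR = exp(-15) it is ~0.7% at X = 1e-5 M and below 1e-3 for X >= 1e-3 M
  X <- 10^seq(-5, -1, length.out = 50)
  rel <- abs(two_site_flux(default_rates, X) -
               two_site_flux_limit(default_rates, X)) /
    two_site_flux(default_rates, X)
  expect_lt(max(rel), 1e-2)
  expect_lt(max(rel[X >= 1e-3]), 1e-3)
  # normalized to the saturating flux, the curves agree to ~1e-4 everywhere
  rel_curve <- abs(two_site_flux(default_rates, X) -
                     two_site_flux_limit(default_rates, X)) /
    max(two_site_flux(default_rates, X))
  expect_lt(max(rel_curve), 1e-3)

  worst <- vapply(c(exp(-13), exp(-15), exp(-17), exp(-19)), function(kR) {
    r <- two_site_rates(kR = kR)
    max(abs(two_site_flux(r, X) - two_site_flux_limit(r, X)) /
          two_site_flux(r, X))
  }, numeric(1))
  expect_true(all(diff(worst) < 0))          # shrinking kR tightens the limit
})

test_that("limiting flux saturates at kplus*kRtilde/(kplus+kRtilde)", {
  asym <- with(default_rates, kplus * kRtilde / (kplus + kRtilde))
  expect_equal(two_site_flux_limit(default_rates, 1e6), asym, tolerance = 1e-6)
})

test_that("half-activation matches its closed form and defining property", {
  expect_equal(half_activation(default_rates), 7.5586e-4, tolerance = 1e-4)
  Xh <- half_activation(default_rates)
  asym <- with(default_rates, kplus * kRtilde / (kplus + kRtilde))
  expect_equal(two_site_flux_limit(default_rates, Xh), asym / 2,
               tolerance = 1e-10)
  # kRtilde -> infinity limit
  r_inf <- two_site_rates(kRtilde = 1e12)
  expect_equal(half_activation(r_inf),
               with(default_rates, (kminus + kplus) / kL), tolerance = 1e-6)
  expect_error(half_activation(two_site_rates(kL = 0)), "kL")
  expect_error(half_activation(two_site_rates(kRtilde = 0)), "kRtilde")
})

test_that("ion-ion interaction summary quantifies the exit-rate enhancement", {
  chk <- occupancy_ratio_check(default_rates)
  expect_equal(chk$kRtilde_over_kR, exp(7.5), tolerance = 1e-12)
  expect_equal(chk$one_site_Kd, exp(-15))
  expect_equal(chk$Khalf_over_Kd, 2470.9, tolerance = 1e-3)
  # no-repulsion limit
  r_eq <- two_site_rates(kRtilde = exp(-15))
  chk_eq <- occupancy_ratio_check(r_eq)
  expect_equal(chk_eq$Khalf_over_Kd,
               with(r_eq, (kminus + kplus) / (kplus + kR)), tolerance = 1e-12)
})

test_that("flux is non-negative, bounded, and non-decreasing in X under ion-ion repulsion", {
  set.seed(77)
  for (i in 1:20) {
    kR <- exp(runif(1, -20, -2))
    # repulsive regime: double occupancy speeds up the exit (kRtilde >= kR);
    # with kRtilde << kR a second ion blocks the pore and the flux is
    # genuinely non-monotone in X, so monotonicity is a property of this
    # regime, not of arbitrary rates
    r <- two_site_rates(kL = exp(runif(1, -5, 0)),
                        kplus = exp(runif(1, -10, 0)),
                        kminus = exp(runif(1, -10, 0)),
                        kR = kR,
                        kRtilde = min(kR * exp(runif(1, 0, 10)), 1))
    X <- 10^seq(-6, 1, length.out = 60)
    J <- two_site_flux(r, X)
    expect_true(all(J >= 0))
    expect_true(all(diff(J) >= -1e-13 * max(J)))
    expect_true(all(J <= max(r$kR, r$kRtilde) * (1 + 1e-12)))
  }
})

test_that("slow double-occupancy exit produces self-block: flux peaks then falls", {
  r_block <- two_site_rates(kR = 1e-2, kRtilde = 1e-6)
  X <- 10^seq(-6, 1, length.out = 100)
  J <- two_site_flux(r_block, X)
  expect_gt(max(J), 10 * J[length(J)])   # flux collapses at high X
  expect_true(all(J <= max(r_block$kR, r_block$kRtilde) * (1 + 1e-12)))
})
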