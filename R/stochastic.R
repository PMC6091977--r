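#' Transition labels of the hopping scheme
#' @noRd
.transition_labels <- c("entryL", "hopLR", "hopRL", "exitR_single",
                        "entryD", "exitR_double")
.state_labels <- c("E", "L", "R", "D")

#' Exact stochastic simulation of the two-site hopping scheme
#'
#' Direct Gillespie simulation of the four-state continuous-time Markov
#' chain behind the two-site permeation model: exponential waiting times
#' with total propensity equal to the sum of the allowed transition rates in
#' the current state, and exact transition selection. No tau-leaping is
#' used; the rates span many orders of magnitude and statistical exactness
#' is the point, since the simulation serves as the independent oracle for
#' the analytic stationary state. Randomness comes from R's Mersenne-Twister
#' generator, seeded by `seed`, so trajectories are reproducible across
#' platforms.
#'
#' @param rates A [two_site_rates()] object.
#' @param X Intracellular permeant concentration, mol/L.
#' @param t_max Trajectory length in prefactor-time units; defaults to the
#'   length needed for ~1000 expected permeation events at the analytic
#'   flux.
#' @param seed Integer seed.
#' @param start_state Initial state, one of `"E"`, `"L"`, `"R"`, `"D"`.
#' @param record_events If `TRUE`, keep the full event log (time, label) in
#'   the returned object; off by default since long runs have millions of
#'   events.
#' @param n_slices Number of equal time slices over which per-state dwell
#'   time is accumulated (controls the burn-in resolution of
#'   [empirical_occupancy()]).
#' @return An object of class `trajectory`: dwell-time matrix (slice by
#'   state), transition counts, permeation event times, total time, seed,
#'   and the event log if requested.
#' @export
simulate_trajectory <- function(rates, X, t_max = NULL, seed = 1L,
                                start_state = c("E", "L", "R", "D"),
                                record_events = FALSE, n_slices = 100L) {
  stopifnot(inherits(rates, "two_site_rates"), length(X) == 1L, X >= 0)
  start_state <- match.arg(start_state)
  if (is.null(t_max)) {
    J <- two_site_flux(rates, X)
    if (J <= 0) stop("analytic flux is zero; supply `t_max` explicitly",
                     call. = FALSE)
    t_max <- 1000 / J
  }
  if (!is.numeric(t_max) || t_max <= 0) stop("`t_max` must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  res <- gillespie_core(rates$kL * X, rates$kplus, rates$kminus, rates$kR,
                        rates$kRtilde, t_max,
                        match(start_state, .state_labels) - 1L,
                        record_events, as.integer(n_slices))
  dwell <- res$dwell
  colnames(dwell) <- .state_labels
  counts <- as.integer(res$counts)
  names(counts) <- .transition_labels
  traj <- list(dwell = dwell, counts = counts, exit_times = res$exit_times,
               total_time = res$t_end, n_events = res$n_events,
               early_stop = res$early_stop,
               final_state = .state_labels[res$final_state + 1L],
               seed = as.integer(seed), X = X, rates = rates,
               start_state = start_state)
  if (record_events) {
    traj$events <- data.frame(time = res$event_time,
                              transition = .transition_labels[res$event_code + 1L],
                              stringsAsFactors = FALSE)
  }
  structure(traj, class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Gillespie trajectory: X = %g M, t_max = %g, seed = %d\n",
              x$X, x$total_time, x$seed))
  cat(sprintf("  %d events, %d permeation events%s\n", x$n_events,
              length(x$exit_times),
              if (x$early_stop) " (terminated early: absorbing state)" else ""))
  invisible(x)
}

#' Exact stochastic simulation of the one-site scheme
#'
#' Direct Gillespie simulation of the two-state (empty/occupied) model:
#' entry at kL * X, exit at kR. Small and written in R; it serves as the
#' exact stochastic counterpart of the single-site Michaelis-Menten flux
#' ([single_site_flux()]).
#'
#' @param kL Entry rate constant (prefactor * M^-1).
#' @param kR Exit rate (prefactor units).
#' @param X Permeant concentration, mol/L.
#' @param t_max Trajectory length in prefactor-time units.
#' @param seed Integer seed.
#' @return A list with `exit_times`, `occupied_time`, `total_time`,
#'   `n_events`.
#' @export
simulate_one_site <- function(kL, kR, X, t_max, seed = 1L) {
  stopifnot(kL >= 0, kR >= 0, X >= 0, t_max > 0)
  set.seed(as.integer(seed))
  t <- 0; occupied <- FALSE
  occ_time <- 0; n_events <- 0L
  exit_times <- numeric(0)
  repeat {
    rate <- if (occupied) kR else kL * X
    if (rate <= 0) break
    dt <- stats::rexp(1, rate)
    if (t + dt >= t_max) {
      if (occupied) occ_time <- occ_time + (t_max - t)
      break
    }
    if (occupied) {
      occ_time <- occ_time + dt
      exit_times <- c(exit_times, t + dt)
    }
    t <- t + dt
    occupied <- !occupied
    n_events <- n_events + 1L
  }
  list(exit_times = exit_times, occupied_time = occ_time,
       total_time = t_max, n_events = n_events)
}

#' Empirical permeation flux from a trajectory
#'
#' Counts permeation events (right exits from single and double occupancy)
#' after a burn-in fraction of the trajectory and divides by the remaining
#' time. The Monte-Carlo standard error comes from block analysis of the
#' binned exit counts (see [block_error()]).
#'
#' @param traj A [simulate_trajectory()] result.
#' @param burn_in Fraction of the trajectory discarded from the start,
#'   in [0, 1).
#' @param n_blocks Number of blocks for the error estimate.
#' @return A list with `J` (flux in prefactor units), `se` (Monte-Carlo
#'   standard error), `n_exits`, `time`.
#' @export
empirical_flux <- function(traj, burn_in = 0.1, n_blocks = 20L) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in >= 1) {
    stop("`burn_in` must be in [0, 1)", call. = FALSE)
  }
  t0 <- burn_in * traj$total_time
  T_obs <- traj$total_time - t0
  if (T_obs <= 0) stop("zero post-burn-in time", call. = FALSE)
  ex <- traj$exit_times[traj$exit_times > t0]
  J <- length(ex) / T_obs
  n_bins <- 10L * as.integer(n_blocks)
  edges <- seq(t0, traj$total_time, length.out = n_bins + 1L)
  bin_counts <- as.numeric(table(cut(ex, edges, include.lowest = TRUE)))
  bin_flux <- bin_counts / (T_obs / n_bins)
  se <- block_error(bin_flux, n_blocks)
  list(J = J, se = se, n_exits = length(ex), time = T_obs)
}

#' Empirical state occupancies from a trajectory
#'
#' Dwell-time fractions per state after discarding a burn-in fraction
#' (rounded to the trajectory's dwell-slice resolution). Probabilities sum
#' to one exactly.
#'
#' @inheritParams empirical_flux
#' @return A named numeric vector `c(pE, pL, pR, pD)`.
#' @export
empirical_occupancy <- function(traj, burn_in = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in >= 1) {
    stop("`burn_in` must be in [0, 1)", call. = FALSE)
  }
  n_slices <- nrow(traj$dwell)
  k0 <- floor(burn_in * n_slices)
  d <- colSums(traj$dwell[(k0 + 1L):n_slices, , drop = FALSE])
  if (sum(d) <= 0) stop("zero post-burn-in time", call. = FALSE)
  p <- d / sum(d)
  names(p) <- paste0("p", .state_labels)
  p
}
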