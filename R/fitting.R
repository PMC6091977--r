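#' Normalized-conductance dataset
#'
#' Records of cGMP-gated conductance versus permeant concentration:
#' one row per (voltage, concentration, replicate) with the conductance
#' normalized to a reference cell (by convention the +200 mV / 110 mM
#' condition). Activities are attached separately with
#' [attach_activities()] since the fit is performed against activity, not
#' concentration.
#'
#' @param records A data.frame with columns `voltage_mV`, `conc_mM`,
#'   `replicate`, `g_norm` and optionally `activity_M`.
#' @param normalization_ref Length-2 numeric `c(voltage_mV, conc_mM)`
#'   identifying the g = 1 reference cell.
#' @return An object of class `conductance_dataset` (a data.frame).
#' @export
conductance_dataset <- function(records,
                                normalization_ref = c(voltage_mV = 200, conc_mM = 110)) {
  need <- c("voltage_mV", "conc_mM", "replicate", "g_norm")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$g_norm < 0)) stop("`g_norm` must be >= 0", call. = FALSE)
  if (any(records$conc_mM < 0)) stop("`conc_mM` must be >= 0", call. = FALSE)
  if ("activity_M" %in% names(records)) {
    if (any(records$activity_M > records$conc_mM / 1000 + 1e-12)) {
      stop("activities cannot exceed concentrations", call. = FALSE)
    }
  }
  structure(as.data.frame(records),
            normalization_ref = normalization_ref,
            class = c("conductance_dataset", "data.frame"))
}

#' Attach ionic activities to a conductance dataset
#'
#' Fills (or recomputes) the `activity_M` column from `conc_mM` using the
#' piecewise Debye-Hueckel / Davies conversion of [activity()]. Idempotent.
#'
#' @param dataset A [conductance_dataset()].
#' @param params An [activity_params()] object.
#' @return The dataset with `activity_M` populated.
#' @export
attach_activities <- function(dataset, params = activity_params()) {
  stopifnot(inherits(dataset, "conductance_dataset"))
  dataset$activity_M <- activity(dataset$conc_mM / 1000, params)
  dataset
}

# Variable-projection residual sum of squares: for a fixed K the optimal
# gmax per voltage is linear least squares with a closed form.
.mm_rss <- function(K, a, g, voltage) {
  f <- a / (a + K)
  rss <- 0
  for (v in unique(voltage)) {
    i <- voltage == v
    gmax <- sum(g[i] * f[i]) / sum(f[i]^2)
    rss <- rss + sum((g[i] - gmax * f[i])^2)
  }
  rss
}

.mm_gmax <- function(K, a, g, voltage) {
  vs <- sort(unique(voltage))
  gm <- vapply(vs, function(v) {
    i <- voltage == v
    f <- a[i] / (a[i] + K)
    sum(g[i] * f) / sum(f^2)
  }, numeric(1))
  names(gm) <- as.character(vs)
  gm
}

#' Global Michaelis-Menten fit of conductance versus activity
#'
#' Simultaneously fits g(a, V) = gmax(V) * a / (a + K) to all records, with
#' a single half-activation constant K shared across voltages and one
#' saturating conductance per voltage — the analysis that yields the
#' apparent Kd of the channel for its permeant. The fit is unweighted least
#' squares over replicate-level records. K is optimized on the log scale
#' (guaranteeing positivity) by variable projection: for any K the optimal
#' gmax(V) values are closed-form linear least-squares solutions, leaving a
#' one-dimensional profile objective that is minimized with a coarse
#' log-spaced grid followed by [stats::optimize()].
#'
#' @param dataset A [conductance_dataset()] with activities attached.
#' @param params [activity_params()] used to express K on the concentration
#'   scale (inverse activity transform).
#' @return An object of class `mm_fit`: `K_half` (mol/L, activity scale),
#'   `K_half_conc_mM` (concentration scale), `g_max` (named per-voltage
#'   vector), `rss`, `n_obs`, `converged`, and the fitted data.
#' @export
global_mm_fit <- function(dataset, params = activity_params()) {
  stopifnot(inherits(dataset, "conductance_dataset"))
  if (!"activity_M" %in% names(dataset)) {
    stop("attach activities first (see attach_activities())", call. = FALSE)
  }
  keep <- dataset$activity_M > 0
  d <- dataset[keep, , drop = FALSE]
  if (length(unique(d$voltage_mV)) < 2) {
    stop("need at least 2 voltages to fit a shared K", call. = FALSE)
  }
  if (length(unique(d$activity_M)) < 3) {
    stop("need at least 3 distinct activities", call. = FALSE)
  }
  a <- d$activity_M; g <- d$g_norm; v <- d$voltage_mV
  lo <- log(min(a)) - 8
  hi <- log(max(a)) + 8
  grid <- seq(lo, hi, length.out = 200)
  rss_grid <- vapply(grid, function(lk) .mm_rss(exp(lk), a, g, v), numeric(1))
  i <- which.min(rss_grid)
  bracket <- grid[c(max(1, i - 1), min(length(grid), i + 1))]
  opt <- stats::optimize(function(lk) .mm_rss(exp(lk), a, g, v),
                         interval = bracket, tol = 1e-12)
  K <- exp(opt$minimum)
  converged <- is.finite(opt$objective) && i > 1 && i < length(grid)
  gmax <- .mm_gmax(K, a, g, v)
  structure(list(K_half = K,
                 K_half_conc_mM = 1000 * inverse_activity(K, params),
                 g_max = gmax,
                 rss = opt$objective,
                 n_obs = nrow(d),
                 converged = converged,
                 data = d),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Global Michaelis-Menten fit (shared half-activation constant)\n")
  cat(sprintf("  K_half = %.4g M (activity)  =  %.3g mM (concentration scale)\n",
              x$K_half, x$K_half_conc_mM))
  cat("  g_max per voltage:\n")
  for (v in names(x$g_max)) cat(sprintf("    %s mV: %.4f\n", v, x$g_max[[v]]))
  cat(sprintf("  rss = %.4g over %d records%s\n", x$rss, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Predicted conductance from a fit
#'
#' @param object An `mm_fit` object.
#' @param newdata Data.frame with `voltage_mV` and `activity_M`.
#' @param ... Unused.
#' @return Predicted normalized conductance.
#' @export
predict.mm_fit <- function(object, newdata = object$data, ...) {
  gmax <- object$g_max[as.character(newdata$voltage_mV)]
  unname(gmax * newdata$activity_M / (newdata$activity_M + object$K_half))
}

#' Bootstrap confidence interval for the half-activation constant
#'
#' Case-resampling bootstrap: within each (voltage, concentration) cell the
#' replicate records are resampled with replacement, the global fit is
#' repeated, and a percentile interval for K is formed. Cells with a single
#' replicate cannot be resampled within-cell; in that case all records are
#' resampled jointly, with a warning.
#'
#' With few replicates per cell the plain percentile interval is too narrow
#' (resampling n points from n underestimates the spread by roughly
#' sqrt((n-1)/n)), so by default the quantile levels are widened by
#' Hesterberg's expanded-percentile correction, using the smallest cell
#' size as the resampling unit; set `expand = FALSE` for the plain
#' percentile interval.
#'
#' @param dataset A [conductance_dataset()] with activities attached.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param expand Apply the expanded-percentile small-sample correction
#'   (default `TRUE`).
#' @param params Passed to [global_mm_fit()].
#' @return A list with `lower`, `upper` (mol/L, activity scale),
#'   `lower_conc_mM`, `upper_conc_mM`, `K_boot` (the bootstrap draws) and
#'   `level`.
#' @export
bootstrap_khalf <- function(dataset, n_boot = 200L, seed = 1L, level = 0.95,
                            expand = TRUE, params = activity_params()) {
  stopifnot(inherits(dataset, "conductance_dataset"))
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 100L) {
    stop("`n_boot` must be at least 100", call. = FALSE)
  }
  cells <- interaction(dataset$voltage_mV, dataset$conc_mM, drop = TRUE)
  within_cell <- all(table(cells) >= 2)
  if (!within_cell) {
    warning("cells with a single replicate: resampling over all records",
            call. = FALSE)
  }
  idx_by_cell <- split(seq_len(nrow(dataset)), cells)
  set.seed(as.integer(seed))
  K_boot <- vapply(seq_len(n_boot), function(b) {
    idx <- if (within_cell) {
      unlist(lapply(idx_by_cell, function(i) sample(i, length(i), replace = TRUE)),
             use.names = FALSE)
    } else {
      sample(nrow(dataset), nrow(dataset), replace = TRUE)
    }
    fit <- global_mm_fit(dataset[idx, , drop = FALSE], params = params)
    fit$K_half
  }, numeric(1))
  alpha <- (1 - level) / 2
  if (expand) {
    n_unit <- if (within_cell) min(table(cells)) else nrow(dataset)
    if (n_unit > 1) {
      alpha <- stats::pnorm(-stats::qnorm(1 - alpha) * sqrt(n_unit / (n_unit - 1)))
    }
  }
  q <- stats::quantile(K_boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2],
       lower_conc_mM = 1000 * inverse_activity(q[1], params),
       upper_conc_mM = 1000 * inverse_activity(q[2], params),
       K_boot = K_boot, level = level)
}
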