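#' One-dimensional free-energy profile
#'
#' Container for a tabulated free energy G(z) along a single collective
#' variable: here the distance (nm) of a permeant DMA ion from the centre of
#' mass of the Val64 ring at the intracellular mouth of the selectivity
#' filter. Profiles of this kind are the raw output of enhanced-sampling
#' simulations; this package only analyzes them.
#'
#' @param z Reaction-coordinate grid, nm; strictly increasing, length >= 3.
#' @param G Free energy at each grid point, kJ/mol; finite.
#' @param err Optional per-point standard error, kJ/mol.
#' @param temperature Simulation temperature in K (default 300).
#' @return An object of class `fe_profile` with fields `z`, `G`, `err`,
#'   `temperature`.
#' @export
free_energy_profile <- function(z, G, err = NULL, temperature = 300) {
  z <- as.numeric(z); G <- as.numeric(G)
  if (length(z) != length(G)) stop("`z` and `G` must have equal length", call. = FALSE)
  if (length(z) < 3) stop("a profile needs at least 3 grid points", call. = FALSE)
  if (any(!is.finite(z)) || any(!is.finite(G))) {
    stop("`z` and `G` must be finite", call. = FALSE)
  }
  if (any(diff(z) <= 0)) stop("`z` must be strictly increasing", call. = FALSE)
  if (!is.null(err)) {
    err <- as.numeric(err)
    if (length(err) != length(z) || any(!is.finite(err)) || any(err < 0)) {
      stop("`err` must be non-negative, finite and match `z` in length", call. = FALSE)
    }
  }
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    stop("`temperature` must be a positive scalar (K)", call. = FALSE)
  }
  structure(list(z = z, G = G, err = err, temperature = temperature),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile: %d points, z in [%.3f, %.3f] nm, T = %g K\n",
              length(x$z), min(x$z), max(x$z), x$temperature))
  cat(sprintf("  G range [%.2f, %.2f] kJ/mol%s\n", min(x$G), max(x$G),
              if (is.null(x$err)) "" else ", with error column"))
  invisible(x)
}

#' Read a free-energy profile from whitespace-delimited text
#'
#' Accepts plain two- or three-column files (z in nm, G in kJ/mol, optional
#' standard error) as written by Plumed's FES dumpers; lines starting with
#' `#` or `#!` are ignored. Rows are sorted by z before validation.
#'
#' @param path Path to the text file.
#' @param temperature Temperature (K) to attach to the profile.
#' @return An [free_energy_profile()] object.
#' @export
read_profile <- function(path, temperature = 300) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no data rows in ", path, call. = FALSE)
  rows <- strsplit(trimws(lines[idx]), "\\s+")
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1 || !(ncol %in% c(2L, 3L))) {
    bad <- idx[which(lengths(rows) != lengths(rows)[1])[1]]
    stop(sprintf("expected 2 or 3 numeric columns on every row (line %d)",
                 if (length(ncol) != 1) bad else idx[1]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r), numeric(ncol)))
  vals <- matrix(vals, nrow = ncol)
  bad <- which(apply(vals, 2, function(v) any(is.na(v))))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric value at line %d of %s", idx[bad[1]], path),
         call. = FALSE)
  }
  z <- vals[1, ]; G <- vals[2, ]
  err <- if (ncol == 3L) vals[3, ] else NULL
  if (anyDuplicated(z)) {
    dup <- which(duplicated(z))[1]
    stop(sprintf("duplicate reaction-coordinate value at line %d", idx[dup]),
         call. = FALSE)
  }
  o <- order(z)
  if (length(z) < 3) stop("profile in ", path, " has fewer than 3 points", call. = FALSE)
  free_energy_profile(z[o], G[o], if (is.null(err)) NULL else err[o], temperature)
}

#' Write a free-energy profile as whitespace-delimited text
#'
#' @param profile An [free_energy_profile()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  header <- if (is.null(profile$err)) {
    "#! FIELDS z_nm G_kJmol"
  } else {
    "#! FIELDS z_nm G_kJmol err_kJmol"
  }
  m <- cbind(profile$z, profile$G, profile$err)
  body <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Bulk (unbound) free-energy reference
#'
#' Mean of G over the last `tail_fraction` of the z range; well depths and
#' unbinding distances are measured against this plateau.
#'
#' @param profile An [free_energy_profile()] object.
#' @param tail_fraction Fraction of the z range to average over, in (0, 0.5].
#' @return Reference free energy in kJ/mol.
#' @export
bulk_reference <- function(profile, tail_fraction = 0.1) {
  stopifnot(inherits(profile, "fe_profile"))
  if (!is.numeric(tail_fraction) || length(tail_fraction) != 1L ||
      tail_fraction <= 0 || tail_fraction > 0.5) {
    stop("`tail_fraction` must be in (0, 0.5]", call. = FALSE)
  }
  z0 <- max(profile$z) - tail_fraction * diff(range(profile$z))
  mean(profile$G[profile$z >= z0])
}

# Interior local minima on the grid, with a flat bottom represented by its
# leftmost point. Works on the run-length-collapsed series so plateaus of
# any width are handled uniformly.
.local_min_indices <- function(G) {
  r <- rle(G)
  v <- r$values
  n <- length(v)
  if (n < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-n]))
  is_min <- c(FALSE, v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n], FALSE)
  starts[is_min]
}

# Topographic prominence of the minimum at index i: the lower of the two
# saddle heights that must be climbed before reaching deeper terrain (or the
# profile boundary), minus G[i].
.prominence <- function(G, i) {
  v <- G[i]
  left <- if (i == 1) -Inf else {
    seg <- G[(i - 1):1]
    lower <- which(seg < v)
    if (length(lower) == 0) max(seg) else max(seg[1:lower[1]])
  }
  right <- if (i == length(G)) -Inf else {
    seg <- G[(i + 1):length(G)]
    lower <- which(seg < v)
    if (length(lower) == 0) max(seg) else max(seg[1:lower[1]])
  }
  min(left, right) - v
}

#' Locate free-energy minima
#'
#' Finds interior local minima with topographic prominence at least
#' `prominence_min` (kJ/mol), the same criterion used to pick out the
#' binding sites S4/S3/SX/S0 on a noisy profile. Depths are measured from
#' the bulk plateau (see [bulk_reference()]).
#'
#' @param profile An [free_energy_profile()] object.
#' @param prominence_min Minimum prominence in kJ/mol (> 0, default 1).
#' @param labels Optional character vector of labels assigned in z order;
#'   defaults to `m1`, `m2`, ...
#' @param tail_fraction Passed to [bulk_reference()].
#' @return A data.frame with one row per minimum (ordered by z): `label`,
#'   `z_min` (nm), `G_min` (kJ/mol), `depth` (kJ/mol, >= 0 relative to the
#'   plateau), `prominence` (kJ/mol), `index` (grid index).
#' @export
find_minima <- function(profile, prominence_min = 1, labels = NULL,
                        tail_fraction = 0.1) {
  stopifnot(inherits(profile, "fe_profile"))
  if (!is.numeric(prominence_min) || prominence_min <= 0) {
    stop("`prominence_min` must be > 0", call. = FALSE)
  }
  G <- profile$G
  idx <- .local_min_indices(G)
  if (length(idx) > 0) {
    prom <- vapply(idx, function(i) .prominence(G, i), numeric(1))
    keep <- prom >= prominence_min
    idx <- idx[keep]; prom <- prom[keep]
  } else {
    prom <- numeric(0)
  }
  ref <- bulk_reference(profile, tail_fraction)
  out <- data.frame(
    label = character(length(idx)),
    z_min = profile$z[idx],
    G_min = G[idx],
    depth = pmax(ref - G[idx], 0),
    prominence = prom,
    index = idx,
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0) {
    out <- out[order(out$z_min), , drop = FALSE]
    out$label <- if (!is.null(labels)) {
      if (length(labels) < nrow(out)) {
        stop("fewer labels than minima found", call. = FALSE)
      }
      labels[seq_len(nrow(out))]
    } else {
      paste0("m", seq_len(nrow(out)))
    }
    rownames(out) <- NULL
  }
  out
}

#' Deepest free-energy minimum
#'
#' The minimum with the largest depth relative to the bulk plateau; ties are
#' broken by smaller z. A profile with no detectable minimum (flat or
#' monotonic) returns a degenerate zero-depth minimum at the first interior
#' grid point.
#'
#' @inheritParams find_minima
#' @return A one-row data.frame in the format of [find_minima()].
#' @export
global_minimum <- function(profile, labels = NULL, tail_fraction = 0.1) {
  m <- find_minima(profile, prominence_min = .Machine$double.eps,
                   labels = labels, tail_fraction = tail_fraction)
  if (nrow(m) == 0) {
    ref <- bulk_reference(profile, tail_fraction)
    return(data.frame(label = "degenerate", z_min = profile$z[2],
                      G_min = profile$G[2], depth = max(ref - profile$G[2], 0),
                      prominence = 0, index = 2L, stringsAsFactors = FALSE))
  }
  best <- which(m$depth == max(m$depth))
  m[best[which.min(m$z_min[best])], , drop = FALSE]
}

# Validate a minimum argument: a one-row data.frame from find_minima().
.resolve_minimum <- function(profile, m) {
  if (!is.data.frame(m) || nrow(m) != 1L || !all(c("z_min", "G_min") %in% names(m))) {
    stop("expected a one-row data.frame as returned by find_minima()", call. = FALSE)
  }
  if (m$z_min < min(profile$z) || m$z_min > max(profile$z)) {
    stop("minimum lies outside the profile range", call. = FALSE)
  }
  m
}

#' Signed free-energy difference between two minima
#'
#' Returns G(a) - G(b) in kJ/mol; positive when site `a` is disfavored
#' relative to site `b` (e.g. S4 vs S3 on the single-ion profile).
#'
#' @param profile An [free_energy_profile()] object.
#' @param a,b One-row data.frames as returned by [find_minima()].
#' @return Signed difference in kJ/mol.
#' @export
depth_difference <- function(profile, a, b) {
  a <- .resolve_minimum(profile, a)
  b <- .resolve_minimum(profile, b)
  a$G_min - b$G_min
}

#' Unbinding distance
#'
#' Smallest z beyond the global minimum from which the profile stays within
#' `tol` kJ/mol of the bulk plateau all the way to the end of the grid: the
#' distance at which the ion is effectively free to diffuse in the bulk.
#'
#' @param profile An [free_energy_profile()] object.
#' @param tol Flatness tolerance in kJ/mol (> 0).
#' @param tail_fraction Passed to [bulk_reference()].
#' @return The unbinding distance in nm, with attribute `converged` set to
#'   `FALSE` (and a warning) if the profile never flattens within `tol`, in
#'   which case the profile end is returned.
#' @export
unbinding_distance <- function(profile, tol = 1, tail_fraction = 0.1) {
  stopifnot(inherits(profile, "fe_profile"))
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  ref <- bulk_reference(profile, tail_fraction)
  gm <- global_minimum(profile, tail_fraction = tail_fraction)
  dev <- abs(profile$G - ref)
  # running maximum of the deviation over the suffix starting at each point
  suffix_max <- rev(cummax(rev(dev)))
  cand <- which(profile$z > gm$z_min & suffix_max <= tol)
  if (length(cand) == 0) {
    warning("profile never flattens to within tol of the bulk reference; ",
            "returning the profile end", call. = FALSE)
    return(structure(max(profile$z), converged = FALSE))
  }
  structure(profile$z[cand[1]], converged = TRUE)
}

#' Escape barrier from a minimum
#'
#' Maximum of G on the path from the minimum to the profile boundary in the
#' requested direction, minus G at the minimum. This is the activation
#' free energy entering an Arrhenius rate for escape in that direction.
#'
#' @param profile An [free_energy_profile()] object.
#' @param m A one-row data.frame as returned by [find_minima()].
#' @param direction `"increasing"` (toward larger z) or `"decreasing"`.
#' @return Barrier height in kJ/mol (>= 0).
#' @export
barrier_height <- function(profile, m, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  m <- .resolve_minimum(profile, m)
  sel <- if (direction == "increasing") profile$z >= m$z_min else profile$z <= m$z_min
  max(profile$G[sel]) - m$G_min
}

#' Block-analysis standard error
#'
#' Standard error of the mean of a (possibly correlated) series, estimated
#' by splitting it into `n_blocks` contiguous blocks and taking
#' sd(block means) / sqrt(n_blocks). For correlated data the estimate grows
#' with block size until blocks are longer than the correlation time, the
#' usual block-averaging picture.
#'
#' @param series Numeric vector of samples (length >= 2 * n_blocks).
#' @param n_blocks Number of contiguous blocks (>= 2).
#' @return Standard error estimate (>= 0).
#' @export
block_error <- function(series, n_blocks) {
  if (!is.numeric(series) || any(!is.finite(series))) {
    stop("`series` must be finite numeric", call. = FALSE)
  }
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 2) stop("`n_blocks` must be >= 2", call. = FALSE)
  n <- length(series)
  if (n < 2L * n_blocks) {
    stop("series too short: need at least 2 samples per block", call. = FALSE)
  }
  len <- n %/% n_blocks
  used <- series[seq_len(len * n_blocks)]
  means <- colMeans(matrix(used, nrow = len))
  stats::sd(means) / sqrt(n_blocks)
}
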