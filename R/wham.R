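# Multiple-histogram reweighting: combine per-temperature canonical energy
# histograms into one density-of-states estimate. All arithmetic is in log
# space (log-sum-exp); no bare exponentials of +-E/T ever appear.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(M) {
  m <- apply(M, 1, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(M[ok, , drop = FALSE] - m[ok])))
  out
}

#' Density-of-states estimate
#'
#' `ln g(E)` on a uniform energy-bin grid, defined up to one additive
#' constant (the gauge); finite exactly on the support mask, `NA` elsewhere.
#' Optional per-bin standard errors come from independent runs
#' ([combine_runs()]); errors are absent (`NA`), not zero, when fewer than
#' two runs are available.
#'
#' @param energies uniform grid of bin centers.
#' @param ln_g natural log density of states (NA off support).
#' @param stderr per-bin standard errors (optional).
#' @param state optional fitting state (WHAM bookkeeping, provenance).
#' @export
dos_estimate <- function(energies, ln_g, stderr = NULL, state = NULL) {
  stopifnot(length(energies) == length(ln_g))
  if (is.null(stderr)) stderr <- rep(NA_real_, length(ln_g))
  stopifnot(length(stderr) == length(ln_g))
  structure(list(energies = as.numeric(energies), ln_g = as.numeric(ln_g),
                 stderr = as.numeric(stderr),
                 support = is.finite(ln_g), state = state),
            class = "dos_estimate")
}

#' @export
print.dos_estimate <- function(x, ...) {
  cat(sprintf("Density of states: %d bins, %d on support, E in [%.4g, %.4g]\n",
              length(x$energies), sum(x$support),
              min(x$energies[x$support]), max(x$energies[x$support])))
  if (!is.null(x$state$iterations))
    cat(sprintf("  WHAM: %d iterations, max |d lnZ| = %.3g (%s)\n",
                x$state$iterations, x$state$delta,
                if (isTRUE(x$state$converged)) "converged" else "NOT converged"))
  if (!is.null(x$state$n_runs))
    cat(sprintf("  combined from %d independent runs\n", x$state$n_runs))
  invisible(x)
}

#' @export
as.data.frame.dos_estimate <- function(x, ...) {
  data.frame(E_bin_center = x$energies, ln_g = x$ln_g, stderr = x$stderr,
             support_flag = x$support)
}

#' @export
plot.dos_estimate <- function(x, ...) {
  graphics::plot(x$energies[x$support], x$ln_g[x$support], type = "l",
                 xlab = "E", ylab = "ln g(E)", ...)
  invisible(x)
}

#' Multiple-histogram reweighting (WHAM)
#'
#' Iterates the self-consistent equations
#' `g(E) = sum_k h(E; T_k) / sum_k M_k Z_k^{-1} exp(-E / kB T_k)` and
#' `Z_k = sum_E g(E) exp(-E / kB T_k)` to a fixed point, entirely in log
#' space, with the gauge fixed by `ln Z_1 = 0`. Iteration stops when
#' `max |delta ln Z_k| < tol` or after `max_iter` iterations (then flagged
#' unconverged). Bins with zero total counts inside the support envelope
#' are excluded from `ln g` (no interpolation at this stage; smoothing
#' happens in the microcanonical analysis).
#'
#' @param histograms a [histogram_set()] with at least one nonzero count.
#' @param tol convergence threshold on `max |delta ln Z_k|`.
#' @param max_iter iteration cap.
#' @param kB Boltzmann constant.
#' @return A [dos_estimate()] whose `state` carries the per-thread `ln_z`,
#'   iteration count, final change, convergence and overlap flags, and the
#'   thread temperatures.
#' @export
wham <- function(histograms, tol = 1e-8, max_iter = 1e5, kB = 1) {
  stopifnot(inherits(histograms, "histogram_set"))
  counts <- histograms$counts
  if (sum(counts) == 0) stop("wham: all histograms are empty")
  temps <- histograms$temperatures
  K <- length(temps)
  M <- histograms$totals
  use <- M > 0
  counts <- counts[, use, drop = FALSE]
  temps <- temps[use]
  M <- M[use]
  K <- length(temps)

  # adjacent-histogram overlap diagnostic
  overlap_ok <- TRUE
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      if (!any(counts[, k] > 0 & counts[, k + 1] > 0)) { overlap_ok <- FALSE; break }
    }
    if (!overlap_ok)
      warning("wham: adjacent histograms without overlap; result flagged")
  }

  h_tot <- rowSums(counts)
  env <- range(which(h_tot > 0))
  idx <- env[1]:env[2]                       # trim to support envelope
  E_all <- histograms$bin_centers[idx]
  h_tot <- h_tot[idx]
  sup <- h_tot > 0
  E <- E_all[sup]
  ln_h <- log(h_tot[sup])
  A <- outer(-E, 1 / (kB * temps))           # |support| x K
  ln_M <- log(M)

  ln_z <- numeric(K)
  it <- 0L
  delta <- Inf
  repeat {
    it <- it + 1L
    denom <- row_logsumexp(sweep(A, 2, ln_M - ln_z, `+`))
    ln_g <- ln_h - denom
    ln_z_new <- apply(A + ln_g, 2, logsumexp)
    ln_z_new <- ln_z_new - ln_z_new[1]       # gauge: ln Z_1 = 0
    delta <- max(abs(ln_z_new - ln_z))
    ln_z <- ln_z_new
    if (delta < tol || it >= max_iter) break
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf("wham: not converged after %d iterations (max |d lnZ| = %.3g)",
                    it, delta))

  ln_g_full <- rep(NA_real_, length(E_all))
  ln_g_full[sup] <- ln_g
  dos_estimate(E_all, ln_g_full,
               state = list(ln_z = ln_z, iterations = it, delta = delta,
                            converged = converged, overlap_ok = overlap_ok,
                            temperatures = temps, tol = tol, kB = kB))
}

# align estimate `b` to `a` by the least-squares constant on shared support
gauge_offset <- function(a, b, shared) {
  mean(a[shared] - b[shared])
}

#' Combine independent density-of-states estimates
#'
#' Aligns each replicate to a common gauge by the least-squares constant on
#' the shared support, then reports the per-bin mean `ln g` and the standard
#' error of the mean across runs. These errors propagate into all derivative
#' curves downstream. With fewer than two runs, errors are reported as
#' absent (`NA`), not zero.
#'
#' @param estimates list of [dos_estimate()] objects on identical bin grids.
#' @return A combined [dos_estimate()].
#' @export
combine_runs <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "dos_estimate")))
  if (length(estimates) == 1) {
    e <- estimates[[1]]
    return(dos_estimate(e$energies, e$ln_g,
                        state = list(n_runs = 1L)))
  }
  # intersect the (uniform) grids by energy value
  w <- diff(estimates[[1]]$energies[1:2])
  key <- function(d) round(d$energies / w)
  common <- Reduce(intersect, lapply(estimates, key))
  if (length(common) < 2) stop("combine_runs: no common energy grid")
  mats <- vapply(estimates, function(d) {
    d$ln_g[match(common, key(d))]
  }, numeric(length(common)))
  shared <- rowSums(is.finite(mats)) == ncol(mats)
  if (!any(shared)) stop("combine_runs: no shared support across runs")
  for (r in 2:ncol(mats))
    mats[, r] <- mats[, r] + gauge_offset(mats[, 1], mats[, r], shared)
  n_avail <- rowSums(is.finite(mats))
  ln_g <- ifelse(n_avail > 0, rowMeans(mats, na.rm = TRUE), NA_real_)
  sdv <- apply(mats, 1, stats::sd, na.rm = TRUE)
  stderr <- ifelse(n_avail >= 2, sdv / sqrt(n_avail), NA_real_)
  dos_estimate(common * w, ln_g, stderr,
               state = list(n_runs = length(estimates),
                            n_avail = n_avail))
}

#' WHAM self-consistency check
#'
#' Recomputes `ln Z_k` from a converged estimate and returns the maximum
#' absolute deviation from the stored values (should be below the fitting
#' tolerance).
#'
#' @param dos a [dos_estimate()] produced by [wham()].
#' @export
wham_self_consistency <- function(dos) {
  st <- dos$state
  stopifnot(!is.null(st$ln_z))
  E <- dos$energies[dos$support]
  ln_g <- dos$ln_g[dos$support]
  A <- outer(-E, 1 / (st$kB * st$temperatures))
  ln_z <- apply(A + ln_g, 2, logsumexp)
  ln_z <- ln_z - ln_z[1]
  max(abs(ln_z - st$ln_z))
}
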