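# Canonical-ensemble observables computed by reweighting the density of
# states (mean energy, heat capacity) and from per-thread time series
# (temperature derivatives of structural observables).

canonical_log_weights <- function(dos, T, kB = 1) {
  E <- dos$energies[dos$support]
  lw <- dos$ln_g[dos$support] - E / (kB * T)
  list(E = E, lw = lw - logsumexp(lw))
}

warn_extrapolation <- function(dos, T) {
  temps <- dos$state$temperatures
  if (!is.null(temps) && (any(T < min(temps)) || any(T > max(temps))))
    warning("temperature outside the histogram-supported range; reweighted value is an extrapolation")
}

#' Canonical mean energy from the density of states
#'
#' `<E> = sum_E E g(E) exp(-E/kB T) / sum_E g(E) exp(-E/kB T)`, computed
#' with log-sum-exp weights; invariant under the gauge constant of `ln g`.
#'
#' @param dos a [dos_estimate()].
#' @param T temperature(s), > 0.
#' @param kB Boltzmann constant.
#' @export
canonical_mean_energy <- function(dos, T, kB = 1) {
  stopifnot(all(T > 0))
  warn_extrapolation(dos, T)
  vapply(T, function(Ti) {
    w <- canonical_log_weights(dos, Ti, kB)
    sum(w$E * exp(w$lw))
  }, numeric(1))
}

#' Heat capacity from the density of states
#'
#' Computed as the canonical energy variance,
#' `C_V = (<E^2> - <E>^2) / (kB T^2)`, which equals `d<E>/dT` in the
#' canonical ensemble; non-negative by construction.
#'
#' @inheritParams canonical_mean_energy
#' @export
heat_capacity <- function(dos, T, kB = 1) {
  stopifnot(all(T > 0))
  warn_extrapolation(dos, T)
  vapply(T, function(Ti) {
    w <- canonical_log_weights(dos, Ti, kB)
    p <- exp(w$lw)
    m <- sum(w$E * p)
    (sum(w$E^2 * p) - m^2) / (kB * Ti^2)
  }, numeric(1))
}

#' Temperature derivative of an observable from paired time series
#'
#' Fluctuation formula `d<O>/dT = (<O E> - <O><E>) / (kB T^2)` estimated
#' from a thread's paired (O, E) samples at temperature `T`. With `O = E`
#' this is the time-series heat-capacity estimator; used in particular for
#' the structural fluctuations `d<Rgyr^2>/dT`, whose peak across the ladder
#' signals the collapse transition.
#'
#' @param O observable samples.
#' @param E paired energy samples.
#' @param T sampling temperature of the thread.
#' @param kB Boltzmann constant.
#' @param min_samples minimum sample count required.
#' @export
observable_temperature_derivative <- function(O, E, T, kB = 1,
                                              min_samples = 1000) {
  stopifnot(length(O) == length(E), T > 0)
  if (length(O) < min_samples)
    stop("observable_temperature_derivative: need at least ", min_samples,
         " paired samples")
  (mean(O * E) - mean(O) * mean(E)) / (kB * T^2)
}

#' Canonical observable curves
#'
#' Mean energy and heat capacity reweighted from the density of states on a
#' grid of inverse temperatures, plus (when a run's time series is given)
#' `d<Rgyr^2>/dT` at the ladder temperatures via the covariance formula
#' (the radius of gyration is not a function of E, so it cannot come from
#' the energy-only density of states). With a list of per-run estimates,
#' replicate errors are attached.
#'
#' @param dos a [dos_estimate()] or list of them (independent runs).
#' @param beta_grid inverse-temperature grid for `<E>` and `C_V`.
#' @param histograms optional [histogram_set()] with time series for the
#'   structural fluctuation curve.
#' @param kB Boltzmann constant.
#' @return A `canonical_curves` object.
#' @export
canonical_curves <- function(dos, beta_grid = seq(0.2, 10, length.out = 200),
                             histograms = NULL, kB = 1) {
  stopifnot(all(beta_grid > 0), !is.unsorted(beta_grid, strictly = TRUE))
  doses <- if (is.list(dos) && !inherits(dos, "dos_estimate")) dos else list(dos)
  Tg <- 1 / rev(beta_grid)
  one <- function(d) {
    suppressWarnings(list(E = canonical_mean_energy(d, Tg, kB),
                          CV = heat_capacity(d, Tg, kB)))
  }
  per <- lapply(doses, one)
  Em <- vapply(per, `[[`, numeric(length(Tg)), "E")
  Cm <- vapply(per, `[[`, numeric(length(Tg)), "CV")
  R <- length(doses)
  res <- list(beta = beta_grid,
              mean_energy = rev(rowMeans(Em)),
              heat_capacity = rev(rowMeans(Cm)),
              mean_energy_err = if (R >= 2) rev(apply(Em, 1, stats::sd) / sqrt(R)) else rep(NA_real_, length(Tg)),
              heat_capacity_err = if (R >= 2) rev(apply(Cm, 1, stats::sd) / sqrt(R)) else rep(NA_real_, length(Tg)))
  if (!is.null(histograms) && !is.null(histograms$timeseries)) {
    ts <- histograms$timeseries
    temps <- histograms$temperatures
    drg <- vapply(seq_along(temps), function(k)
      observable_temperature_derivative(ts$rg2[, k], ts$E[, k], temps[k],
                                        kB = kB,
                                        min_samples = min(1000, nrow(ts$E))),
      numeric(1))
    res$ladder_beta <- 1 / temps
    res$drg2_dT <- drg
  }
  structure(res, class = "canonical_curves")
}

#' @export
as.data.frame.canonical_curves <- function(x, ...) {
  data.frame(beta_can = x$beta, mean_energy = x$mean_energy,
             heat_capacity = x$heat_capacity,
             mean_energy_err = x$mean_energy_err,
             heat_capacity_err = x$heat_capacity_err)
}

#' @export
plot.canonical_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$drg2_dT)) 2 else 3),
                      mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$beta, x$mean_energy, type = "l",
                 xlab = expression(beta[can]), ylab = expression(E))
  graphics::plot(x$beta, x$heat_capacity, type = "l",
                 xlab = expression(beta[can]), ylab = expression(C[V]))
  if (!is.null(x$drg2_dT))
    graphics::plot(x$ladder_beta, x$drg2_dT, type = "b",
                   xlab = expression(beta[can]),
                   ylab = expression(d * R[gyr]^2 / dT))
  invisible(x)
}
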