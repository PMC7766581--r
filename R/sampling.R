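#' Temperature ladder for replica exchange
#'
#' Ordered increasing temperatures for the parallel-tempering threads.
#' The production default covers `[0.1, 5.0]` with geometric spacing, which
#' keeps exchange acceptance roughly uniform across a ladder on which the
#' heat capacity varies over decades; an explicit temperature list overrides
#' range, count and spacing.
#'
#' @param t_min,t_max ladder range (both > 0).
#' @param count number of threads K.
#' @param spacing `"geometric"` or `"linear"`.
#' @param temperatures explicit increasing temperature vector (optional).
#' @export
temperature_ladder <- function(t_min = 0.1, t_max = 5.0, count = 48,
                               spacing = c("geometric", "linear"),
                               temperatures = NULL) {
  if (is.null(temperatures)) {
    spacing <- match.arg(spacing)
    stopifnot(t_min > 0, t_max > t_min, count >= 1)
    temperatures <- switch(spacing,
      geometric = exp(seq(log(t_min), log(t_max), length.out = count)),
      linear = seq(t_min, t_max, length.out = count))
  } else {
    temperatures <- as.numeric(temperatures)
    if (any(temperatures <= 0) || is.unsorted(temperatures, strictly = TRUE))
      stop("temperatures must be positive and strictly increasing")
  }
  structure(list(temperatures = temperatures, count = length(temperatures)),
            class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("Temperature ladder: K = %d threads in [%.4g, %.4g]\n",
              x$count, min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Sweep schedule for a parallel-tempering run
#'
#' One sweep is N attempted displacement moves. Every
#' `displacement_sweeps_per_pivot_sweep[k]` sweeps, thread k additionally
#' performs a pivot sweep (N - 2 attempted tail rotations); by default this
#' interval is interpolated linearly from 70 at the coldest thread down to
#' 20 at the hottest (pivots equilibrate extended high-temperature states
#' cheaply, compact low-temperature states need more local moves).
#' Replica exchanges are attempted every `exchange_period` sweeps,
#' alternating even/odd neighbor pairs on successive epochs.
#'
#' @param total_sweeps measurement sweeps per thread (M_k).
#' @param thermalization_sweeps sweeps discarded before measurement.
#' @param exchange_period sweeps between exchange epochs.
#' @param displacement_sweeps_per_pivot_sweep integer (scalar or per-thread
#'   vector, typically in `[20, 70]`), or `NULL` for the default
#'   temperature-dependent interpolation.
#' @param stride record the (E, Rgyr^2) time series every `stride` sweeps.
#' @export
sweep_schedule <- function(total_sweeps, thermalization_sweeps,
                           exchange_period = 1500,
                           displacement_sweeps_per_pivot_sweep = NULL,
                           stride = 1) {
  stopifnot(total_sweeps >= 0, thermalization_sweeps >= 0,
            exchange_period >= 1, stride >= 1)
  structure(list(total_sweeps = as.integer(total_sweeps),
                 thermalization_sweeps = as.integer(thermalization_sweeps),
                 exchange_period = as.integer(exchange_period),
                 displacement_sweeps_per_pivot_sweep =
                   displacement_sweeps_per_pivot_sweep,
                 stride = as.integer(stride)),
            class = "sweep_schedule")
}

pivot_intervals <- function(schedule, count) {
  dpp <- schedule$displacement_sweeps_per_pivot_sweep
  if (is.null(dpp)) dpp <- round(seq(70, 20, length.out = count))
  if (length(dpp) == 1) dpp <- rep(dpp, count)
  stopifnot(length(dpp) == count, all(dpp >= 1))
  as.integer(dpp)
}

#' Metropolis acceptance
#'
#' Accepts iff `u < min(exp(-delta_e / (kB T)), 1)`; the infinite-energy
#' sentinel (`Inf`) is always rejected.
#'
#' @param delta_e proposed energy change.
#' @param T temperature (> 0).
#' @param u uniform random number in `[0, 1)`.
#' @param kB Boltzmann constant.
#' @return logical accept flag (vectorized).
#' @export
metropolis_accept <- function(delta_e, T, u, kB = 1) {
  stopifnot(all(T > 0))
  p <- ifelse(is.finite(delta_e), pmin(exp(-delta_e / (kB * T)), 1), 0)
  u < p
}

#' Replica-exchange acceptance probability
#'
#' `min(exp[(E_k - E_{k+1}) (1/(kB T_k) - 1/(kB T_{k+1}))], 1)` for
#' neighboring threads.
#'
#' @param e_k,e_k1 replica energies in threads k and k+1.
#' @param t_k,t_k1 thread temperatures.
#' @param kB Boltzmann constant.
#' @export
exchange_probability <- function(e_k, e_k1, t_k, t_k1, kB = 1) {
  pmin(exp((e_k - e_k1) * (1 / (kB * t_k) - 1 / (kB * t_k1))), 1)
}

#' One replica-exchange decision
#'
#' Decides whether the conformations in neighboring threads k and k+1 swap,
#' given a uniform random number. Swapping only relabels which thread holds
#' which replica; the multiset of energies is unchanged.
#'
#' @param energies per-thread energy vector.
#' @param temperatures per-thread temperature vector.
#' @param k lower thread index of the pair (1 <= k < K).
#' @param u uniform random number in `[0, 1)`.
#' @param kB Boltzmann constant.
#' @return logical swap flag.
#' @export
replica_exchange_step <- function(energies, temperatures, k, u, kB = 1) {
  stopifnot(k >= 1, k < length(energies))
  u < exchange_probability(energies[k], energies[k + 1],
                           temperatures[k], temperatures[k + 1], kB)
}

#' Propose a displacement move
#'
#' Picks a monomer uniformly and shifts it by a vector with components
#' uniform in `[-rd/2, +rd/2]` (symmetric proposal). Uses R's RNG.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @param rd displacement box edge length.
#' @return list with the `move` and its energy `delta`.
#' @export
displacement_move <- function(conf, params, rd) {
  i <- sample.int(nrow(conf), 1)
  move <- displacement_move_spec(i, stats::runif(3, -rd / 2, rd / 2))
  list(move = move, delta = energy_delta(conf, move, params))
}

#' Propose a pivot move
#'
#' Picks an interior pivot monomer uniformly in 2..N-1, a uniform random
#' rotation axis and an angle uniform in `[0, 2 pi)`, and rotates the chain
#' tail rigidly. All bond lengths are preserved exactly; among local terms
#' only the bend angle at the pivot changes. Uses R's RNG.
#'
#' @inheritParams displacement_move
#' @export
pivot_move <- function(conf, params) {
  n <- nrow(conf)
  stopifnot(n >= 3)
  i <- sample(2:(n - 1), 1)
  z <- stats::runif(1, -1, 1)
  phi_ax <- stats::runif(1, 0, 2 * pi)
  axis <- c(sqrt(1 - z^2) * cos(phi_ax), sqrt(1 - z^2) * sin(phi_ax), z)
  move <- pivot_move_spec(i, axis, stats::runif(1, 0, 2 * pi))
  list(move = move, delta = energy_delta(conf, move, params))
}

#' Adaptive displacement step-size calibration
#'
#' Before measurements, each thread's displacement box edge `rd` is scaled
#' by a constant factor until the measured acceptance rate falls into the
#' target band (about 50%). Threads are calibrated from the coldest up,
#' warm-starting each thread's `rd` and conformation from the previous one.
#'
#' @param ladder a [temperature_ladder()].
#' @param params a [model_params()] object.
#' @param trial_sweeps sweeps per adjustment round.
#' @param target acceptance band (inclusive).
#' @param factor multiplicative adjustment per round.
#' @param rd_init starting step size for the coldest thread.
#' @param max_rounds adjustment rounds before giving up (with a warning).
#' @param seed integer seed (independent of R's RNG).
#' @return list with per-thread `rd`, measured `acceptance`, and a
#'   `converged` flag per thread.
#' @export
calibrate_step_sizes <- function(ladder, params, trial_sweeps = 200,
                                 target = c(0.45, 0.55), factor = 1.1,
                                 rd_init = 0.1, max_rounds = 100, seed = 1) {
  K <- ladder$count
  rd <- numeric(K); acc <- numeric(K); conv <- logical(K)
  pos <- unclass(straight_chain(params))
  r <- rd_init
  for (k in seq_len(K)) {
    res <- cpp_calibrate_rd(pos, unclass(params), ladder$temperatures[k], r,
                            as.integer(trial_sweeps), target[1], target[2],
                            factor, as.integer(max_rounds),
                            seed * 1000 + k)
    rd[k] <- res$rd; acc[k] <- res$acceptance; conv[k] <- res$converged
    pos <- res$pos
    r <- res$rd
  }
  if (!all(conv))
    warning("step-size calibration did not converge for ",
            sum(!conv), " thread(s); using last rd")
  list(rd = rd, acceptance = acc, converged = conv)
}

#' Energy histogram set
#'
#' Per-thread binned energy counts on a shared uniform grid, plus the
#' per-thread (E, Rgyr^2) time series recorded at a stated stride. The
#' column sums are the per-thread measurement totals M_k that enter the
#' multiple-histogram reweighting.
#'
#' @param bin_centers uniform energy-bin centers.
#' @param counts bins x threads count matrix.
#' @param temperatures per-thread temperatures.
#' @param timeseries optional list with matrices `E` and `rg2`
#'   (records x threads).
#' @param stride time-series recording stride in sweeps.
#' @export
histogram_set <- function(bin_centers, counts, temperatures,
                          timeseries = NULL, stride = NA_integer_) {
  counts <- as.matrix(counts)
  stopifnot(length(bin_centers) == nrow(counts),
            length(temperatures) == ncol(counts),
            all(counts >= 0))
  w <- diff(bin_centers)
  if (length(w) > 0 && max(abs(w - w[1])) > 1e-8 * abs(w[1]))
    stop("bin grid must be uniform")
  structure(list(bin_centers = as.numeric(bin_centers), counts = counts,
                 temperatures = as.numeric(temperatures),
                 totals = colSums(counts),
                 bin_width = if (length(w)) w[1] else NA_real_,
                 timeseries = timeseries, stride = stride),
            class = "histogram_set")
}

#' @export
print.histogram_set <- function(x, ...) {
  cat(sprintf("Energy histograms: %d bins (width %.4g) x %d threads, %s measurements\n",
              length(x$bin_centers), x$bin_width, length(x$temperatures),
              format(sum(x$totals), big.mark = ",")))
  invisible(x)
}

#' Run a replica-exchange (parallel tempering) simulation
#'
#' Orchestrates the full sampling stage: straight-chain initialization of
#' every thread, adaptive step-size calibration, thermalization, then
#' measurement sweeps with displacement and pivot updates, periodic replica
#' exchanges, per-sweep energy histogram accumulation, and (E, Rgyr^2) time
#' series. Fully reproducible from the seed (internal per-thread RNG
#' streams; R's RNG is untouched).
#'
#' @param params a [model_params()] object.
#' @param ladder a [temperature_ladder()].
#' @param schedule a [sweep_schedule()].
#' @param seed integer master seed.
#' @param bin_width energy histogram bin width (default 0.5).
#' @param bin_range energy grid range; default `c(-8, 10) * N` comfortably
#'   covers the sampled range (outliers are clamped into edge bins).
#' @param rd per-thread displacement step sizes; calibrated if `NULL`.
#' @param calibration_sweeps trial sweeps per calibration round.
#' @return A `pt_run` object: `histograms` ([histogram_set()]), per-thread
#'   and global minimum-energy conformations, acceptance diagnostics,
#'   replica mixing ranges, and a config echo.
#' @export
run_parallel_tempering <- function(params, ladder, schedule, seed = 1,
                                   bin_width = 0.5, bin_range = NULL,
                                   rd = NULL, calibration_sweeps = 200) {
  stopifnot(inherits(params, "model_params"),
            inherits(ladder, "temperature_ladder"),
            inherits(schedule, "sweep_schedule"))
  N <- params$n_monomers
  if (is.null(bin_range)) bin_range <- c(-8, 10) * N * params$epsilon_lj
  n_bins <- max(1L, ceiling(diff(bin_range) / bin_width))
  bin_lo <- bin_range[1]
  bin_centers <- bin_lo + (seq_len(n_bins) - 0.5) * bin_width

  calib <- NULL
  if (is.null(rd)) {
    calib <- calibrate_step_sizes(ladder, params,
                                  trial_sweeps = calibration_sweeps,
                                  seed = seed)
    rd <- calib$rd
  }
  stopifnot(length(rd) == ladder$count)
  dpp <- pivot_intervals(schedule, ladder$count)

  res <- cpp_pt_run(unclass(straight_chain(params)), unclass(params),
                    ladder$temperatures, rd, dpp,
                    schedule$thermalization_sweeps, schedule$total_sweeps,
                    schedule$exchange_period, schedule$stride,
                    bin_lo, bin_width, as.integer(n_bins), seed)

  hs <- histogram_set(bin_centers, res$hist, ladder$temperatures,
                      timeseries = list(E = res$e_series,
                                        rg2 = res$rg2_series),
                      stride = schedule$stride)
  gk <- res$global_min_thread
  out <- list(
    histograms = hs,
    ladder = ladder,
    params = params,
    schedule = schedule,
    min_energy = res$min_energy,
    min_conformations = lapply(res$min_conformations, conformation),
    global_min_energy = res$min_energy[gk],
    global_min_conformation = conformation(res$min_conformations[[gk]]),
    diagnostics = list(
      acc_displacement = res$acc_displacement,
      acc_pivot = res$acc_pivot,
      acc_exchange = res$acc_exchange,
      replica_min_thread = res$replica_min_thread,
      replica_max_thread = res$replica_max_thread,
      rd = rd, calibration = calib),
    seed = seed)
  class(out) <- "pt_run"
  mix <- res$replica_min_thread == 1 & res$replica_max_thread == ladder$count
  if (ladder$count > 1 && schedule$total_sweeps > 0 && !any(mix))
    warning("replica mixing diagnostic: no replica visited both ends of the ladder")
  out
}

#' @export
print.pt_run <- function(x, ...) {
  cat(sprintf("Parallel tempering run: N = %d, kappa = %g, K = %d threads\n",
              x$params$n_monomers, x$params$kappa, x$ladder$count))
  cat(sprintf("  %d measurement sweeps/thread (+%d thermalization), exchange every %d\n",
              x$schedule$total_sweeps, x$schedule$thermalization_sweeps,
              x$schedule$exchange_period))
  cat(sprintf("  lowest energy found: %.4f\n", x$global_min_energy))
  cat(sprintf("  displacement acceptance: %.2f-%.2f, exchange acceptance: %.2f-%.2f\n",
              min(x$diagnostics$acc_displacement),
              max(x$diagnostics$acc_displacement),
              min(x$diagnostics$acc_exchange),
              max(x$diagnostics$acc_exchange)))
  invisible(x)
}

#' @export
summary.pt_run <- function(object, ...) {
  d <- object$diagnostics
  data.frame(temperature = object$ladder$temperatures,
             rd = d$rd,
             acc_displacement = d$acc_displacement,
             acc_pivot = d$acc_pivot,
             min_energy = object$min_energy)
}

#' Annealing schedule
#'
#' Strictly decreasing temperature stages, geometric by default.
#'
#' @param t_start,t_end schedule endpoints (t_start > t_end > 0).
#' @param n_stages number of temperature stages.
#' @param sweeps_per_stage sweeps at each stage.
#' @param cooling `"geometric"` or `"linear"`.
#' @export
annealing_schedule <- function(t_start = 2, t_end = 0.01, n_stages = 200,
                               sweeps_per_stage = 500,
                               cooling = c("geometric", "linear")) {
  cooling <- match.arg(cooling)
  stopifnot(t_start > t_end, t_end > 0, n_stages >= 1, sweeps_per_stage >= 1)
  temps <- switch(cooling,
    geometric = exp(seq(log(t_start), log(t_end), length.out = n_stages)),
    linear = seq(t_start, t_end, length.out = n_stages))
  structure(list(temperatures = temps, sweeps_per_stage = as.integer(sweeps_per_stage)),
            class = "annealing_schedule")
}

#' Simulated annealing ground-state search
#'
#' Metropolis dynamics with a decreasing temperature schedule, displacement
#' plus pivot updates and on-the-fly step-size adaptation; supports
#' independent restarts (the best-ever energy is non-increasing as restarts
#' accumulate).
#'
#' @param params a [model_params()] object.
#' @param schedule an [annealing_schedule()].
#' @param start starting [conformation()] or `NULL` (straight chain).
#' @param restarts number of independent restarts.
#' @param disp_per_pivot displacement sweeps per pivot sweep.
#' @param rd_init initial displacement step size.
#' @param seed integer master seed (restart r uses a derived stream).
#' @return `sa_result`: best conformation, best energy and per-restart
#'   energies.
#' @export
simulated_annealing <- function(params, schedule = annealing_schedule(),
                                start = NULL, restarts = 1,
                                disp_per_pivot = 10, rd_init = 0.3,
                                seed = 1) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  pos0 <- if (is.null(start)) straight_chain(params) else start
  stopifnot(nrow(pos0) == params$n_monomers)
  best <- NULL
  per_restart <- numeric(restarts)
  for (r in seq_len(restarts)) {
    res <- cpp_anneal(unclass(pos0), unclass(params), schedule$temperatures,
                      schedule$sweeps_per_stage, as.integer(disp_per_pivot),
                      rd_init, seed * 1000 + r)
    per_restart[r] <- res$best_energy
    if (is.null(best) || res$best_energy < best$best_energy) best <- res
  }
  structure(list(best_conformation = conformation(best$best_pos),
                 best_energy = best$best_energy,
                 restart_energies = per_restart,
                 schedule = schedule, params = params, seed = seed),
            class = "sa_result")
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf("Simulated annealing: N = %d, kappa = %g, %d restart(s)\n",
              x$params$n_monomers, x$params$kappa, length(x$restart_energies)))
  cat(sprintf("  best energy: %.4f\n", x$best_energy))
  invisible(x)
}

#' Fixed-temperature Metropolis sampling
#'
#' Plain canonical Metropolis run at one temperature, recording the energy
#' and squared radius of gyration every `stride` sweeps. Used for
#' equilibrium cross-checks (e.g. the dimer bond-length distribution
#' against direct Boltzmann quadrature).
#'
#' @param params a [model_params()] object.
#' @param T temperature.
#' @param n_sweeps number of sweeps.
#' @param rd displacement step size.
#' @param stride recording stride in sweeps.
#' @param disp_per_pivot displacement sweeps per pivot sweep (pivots are
#'   skipped for N < 3).
#' @param start starting conformation or `NULL` (straight chain).
#' @param seed integer seed.
#' @export
sample_fixed_temperature <- function(params, T, n_sweeps, rd = 0.3,
                                     stride = 1, disp_per_pivot = 25,
                                     start = NULL, seed = 1) {
  pos0 <- if (is.null(start)) straight_chain(params) else start
  res <- cpp_mc_fixed_t(unclass(pos0), unclass(params), T, rd,
                        as.integer(n_sweeps), as.integer(stride),
                        as.integer(disp_per_pivot), seed)
  list(E = res$e_series, rg2 = res$rg2_series,
       final_conformation = conformation(res$final_pos),
       final_energy = res$final_energy,
       acc_displacement = res$acc_displacement,
       acc_pivot = res$acc_pivot)
}
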