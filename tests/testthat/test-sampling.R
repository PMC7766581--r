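test_that("Metropolis rule accepts downhill always, uphill with Boltzmann weight", {
  u <- seq(0, 0.999, by = 0.001)
  expect_true(all(metropolis_accept(-2, 1, u)))
  expect_true(all(metropolis_accept(0, 1, u)))
  # delta = T log 2: acceptance probability exactly 1/2
  acc <- metropolis_accept(1.3 * log(2), 1.3, u)
  expect_equal(mean(acc), 0.5, tolerance = 1e-3)
  expect_true(all(acc == (u < 0.5)))
  expect_false(any(metropolis_accept(Inf, 1, u)))
})

test_that("replica-exchange probability matches the direct evaluation", {
  # downhill-in-beta-weighted-energy pair: always swaps
  expect_equal(exchange_probability(-10, -12, 1.0, 1.25), 1)
  expect_true(replica_exchange_step(c(-10, -12), c(1.0, 1.25), 1, 0.999))
  # interchanged energies: exp(-0.4)
  expect_equal(exchange_probability(-12, -10, 1.0, 1.25), exp(-0.4))
  expect_equal(exchange_probability(-12, -10, 1.0, 1.25), 0.6703, tolerance = 1e-4)
  expect_true(replica_exchange_step(c(-12, -10), c(1.0, 1.25), 1, 0.5))
  expect_false(replica_exchange_step(c(-12, -10), c(1.0, 1.25), 1, 0.7))
  # equal energies or equal temperatures: exponent zero, always swap
  expect_equal(exchange_probability(-5, -5, 0.7, 0.9), 1)
  expect_equal(exchange_probability(-5, -9, 0.8, 0.8), 1)
})

test_that("displacement proposals are symmetric, centered and rd-scaled", {
  p <- model_params(3)
  cf <- straight_chain(p)
  set.seed(10)
  z <- displacement_move(cf, p, rd = 0)
  expect_equal(z$move$shift, c(0, 0, 0))
  expect_equal(z$delta, 0)
  n <- 30000
  set.seed(11)
  shifts <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)  # the proposal law
  # empirical mean shift of actual proposals is 0 within 3 standard errors
  set.seed(12)
  got <- t(replicate(2000, displacement_move(cf, p, rd = 1)$move$shift))
  se <- 1 / sqrt(12 * nrow(got))
  expect_true(all(abs(colMeans(got)) < 3 * se))
  expect_true(all(abs(got) <= 0.5))
  expect_true(all(abs(colMeans(shifts)) < 3 * se * sqrt(nrow(got) / n)))
})

test_that("step-size calibration reaches the target band, monotonically in T", {
  p <- model_params(13)
  lad <- temperature_ladder(t_min = 0.3, t_max = 3, count = 5)
  cal <- calibrate_step_sizes(lad, p, trial_sweeps = 150, seed = 5)
  expect_true(all(cal$converged))
  expect_true(all(cal$acceptance >= 0.45 & cal$acceptance <= 0.55))
  expect_true(all(diff(cal$rd) >= -1e-12))
  cal2 <- calibrate_step_sizes(lad, p, trial_sweeps = 150, seed = 5)
  expect_identical(cal$rd, cal2$rd)
})

test_that("a short parallel-tempering run is reproducible and conserves counts", {
  p <- model_params(8)
  lad <- temperature_ladder(t_min = 0.5, t_max = 2, count = 4)
  sch <- sweep_schedule(total_sweeps = 500, thermalization_sweeps = 100,
                        exchange_period = 50)
  r1 <- run_parallel_tempering(p, lad, sch, seed = 3, bin_width = 0.25)
  r2 <- run_parallel_tempering(p, lad, sch, seed = 3, bin_width = 0.25)
  expect_identical(r1$histograms$counts, r2$histograms$counts)
  expect_identical(r1$global_min_energy, r2$global_min_energy)
  # histogram totals equal the number of measurements per thread
  expect_equal(unname(r1$histograms$totals), rep(500, 4))
  expect_equal(colSums(r1$histograms$counts), r1$histograms$totals)
  # cached energies stay in sync with full recomputation
  ts_last <- r1$histograms$timeseries$E[500, ]
  expect_true(all(is.finite(ts_last)))
  # time series and min conformations are consistent with the model
  for (k in 1:4) {
    e <- total_energy(r1$min_conformations[[k]], p)$total
    expect_equal(e, r1$min_energy[k], tolerance = 1e-6)
  }
  expect_equal(r1$global_min_energy, min(r1$min_energy))
})

test_that("zero measurement sweeps give empty but valid outputs", {
  p <- model_params(5)
  lad <- temperature_ladder(t_min = 0.5, t_max = 2, count = 3)
  sch <- sweep_schedule(total_sweeps = 0, thermalization_sweeps = 10,
                        exchange_period = 5)
  r <- run_parallel_tempering(p, lad, sch, seed = 1, bin_width = 0.5)
  expect_true(all(r$histograms$counts == 0))
  expect_equal(nrow(r$histograms$timeseries$E), 0)
})

test_that("dimer sampling reproduces the Boltzmann bond-length distribution", {
  p <- model_params(2)
  T <- 0.3
  run <- sample_fixed_temperature(p, T = T, n_sweeps = 1e6, rd = 0.25,
                                  stride = 10, seed = 77)
  r_samples <- 2 * sqrt(run$rg2)          # dimer: Rgyr^2 = (r/2)^2
  expect_gte(length(r_samples), 1e5)
  ks <- ks_distance(r_samples, dimer_bond_cdf(p, T))
  expect_lt(ks, 0.02)
})

test_that("simulated annealing finds the trimer ground state and tracks the best", {
  p <- model_params(3)
  sched <- annealing_schedule(t_start = 1, t_end = 0.005, n_stages = 60,
                              sweeps_per_stage = 300)
  res <- simulated_annealing(p, sched, restarts = 3, seed = 9)
  # brute-force oracle: optimize the 3-body surface directly
  obj <- function(x) {
    cf <- conformation(rbind(c(0, 0, 0), c(x[1], 0, 0), c(x[2], x[3], 0)))
    e <- total_energy(cf, p)$total
    if (!is.finite(e)) 1e6 else e
  }
  opt <- stats::optim(c(1, 0.5, 0.9), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_lt(opt$value, -2.95)
  expect_lte(res$best_energy, -2.95)
  expect_equal(res$best_energy, opt$value, tolerance = 1e-3)
  # best-so-far aggregation over restarts is non-increasing
  expect_equal(res$best_energy, min(res$restart_energies))
  expect_true(all(diff(cummin(res$restart_energies)) <= 0))
})

test_that("annealing a single near-zero-temperature stage keeps a local minimum", {
  p <- model_params(2)
  start <- conformation(rbind(c(0, 0, 0), c(1, 0, 0)))  # bond at its minimum
  sched <- annealing_schedule(t_start = 1e-9, t_end = 1e-10, n_stages = 2,
                              sweeps_per_stage = 200)
  res <- simulated_annealing(p, sched, start = start, rd_init = 0.05, seed = 2)
  expect_equal(res$best_energy, total_energy(start, p)$total,
               tolerance = 1e-9)
})

test_that("ladder and schedule constructors validate their invariants", {
  expect_error(temperature_ladder(temperatures = c(1, 0.5)), "increasing")
  expect_error(temperature_ladder(temperatures = c(-1, 0.5)), "positive")
  lad <- temperature_ladder(count = 48)
  expect_equal(lad$count, 48)
  expect_equal(range(lad$temperatures), c(0.1, 5.0))
  expect_true(all(diff(lad$temperatures) > 0))
  expect_error(sweep_schedule(100, 10, exchange_period = 0))
  dpp <- semiflex:::pivot_intervals(sweep_schedule(10, 1), 6)
  expect_equal(dpp[1], 70)
  expect_equal(dpp[6], 20)
  expect_true(all(diff(dpp) <= 0))
})
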