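# WHAM and run combination, checked against exact-sampling oracles.

make_truth <- function(n_bins = 200) {
  synthetic_dos("single_gaussian", seq(-45, 10, length.out = n_bins),
                mu = 0, sigma = 5)
}

test_that("single-histogram limit: ln g = ln h + E/T up to a constant", {
  truth <- make_truth()
  lad <- temperature_ladder(temperatures = 1.0)
  hs <- sample_histograms_from_dos(truth, lad, n = 2e5, seed = 4)
  dos <- wham(hs)
  sup <- dos$support
  h <- hs$counts[match(round(dos$energies / diff(hs$bin_centers[1:2])),
                       round(hs$bin_centers / diff(hs$bin_centers[1:2]))), 1]
  resid <- dos$ln_g[sup] - (log(h[sup]) + dos$energies[sup] / 1.0)
  expect_lt(diff(range(resid)), 1e-8)
})

test_that("WHAM recovers a known density of states within pooled errors", {
  truth <- make_truth()
  lad <- temperature_ladder(temperatures = c(0.8, 1.0, 1.3))
  doses <- lapply(1:3, function(r) {
    wham(sample_histograms_from_dos(truth, lad, n = 1e5, seed = 100 + r))
  })
  comb <- combine_runs(doses)
  # align the combined estimate to the truth on its support; the gauge
  # constant is estimated with count weights so noisy tail bins do not
  # drag it
  key <- function(e) round(e / diff(truth$energies[1:2]))
  idx <- match(key(comb$energies), key(truth$energies))
  sup <- comb$support & is.finite(comb$stderr)
  h_tot <- Reduce(`+`, lapply(1:3, function(r) {
    hs <- sample_histograms_from_dos(truth, lad, n = 1e5, seed = 100 + r)
    rowSums(hs$counts)
  }))
  w <- h_tot[idx[sup]]
  off <- sum(w * (truth$ln_g[idx[sup]] - comb$ln_g[sup])) / sum(w)
  resid <- comb$ln_g[sup] + off - truth$ln_g[idx[sup]]
  # pooled per-bin error: replicate spread plus the Poisson floor of the
  # pooled counts
  pooled <- sqrt(comb$stderr[sup]^2 + 1 / w)
  expect_true(all(abs(resid) < 3 * pooled))
  # and the bulk of the support is tight
  expect_lt(stats::median(abs(resid) / pooled), 1)
})

test_that("duplicating all counts leaves the estimate unchanged", {
  truth <- make_truth(80)
  lad <- temperature_ladder(temperatures = c(0.9, 1.2))
  hs <- sample_histograms_from_dos(truth, lad, n = 2e4, seed = 9)
  hs2 <- histogram_set(hs$bin_centers, hs$counts * 2L, hs$temperatures)
  d1 <- wham(hs)
  d2 <- wham(hs2)
  expect_equal(d1$ln_g, d2$ln_g, tolerance = 1e-7)
})

test_that("converged estimates are self-consistent in ln Z", {
  truth <- make_truth(80)
  lad <- temperature_ladder(temperatures = c(0.8, 1.0, 1.3))
  hs <- sample_histograms_from_dos(truth, lad, n = 5e4, seed = 10)
  dos <- wham(hs, tol = 1e-10)
  expect_lt(wham_self_consistency(dos), 1e-8)
})

test_that("degenerate inputs are flagged: empty histograms, missing overlap", {
  truth <- make_truth(80)
  lad <- temperature_ladder(temperatures = c(0.9, 1.2))
  empty <- histogram_set(truth$energies,
                         matrix(0L, length(truth$energies), 2),
                         lad$temperatures)
  expect_error(wham(empty), "empty")
  # two disjoint single-bin histograms: no overlap
  counts <- matrix(0L, length(truth$energies), 2)
  counts[10, 1] <- 100L
  counts[60, 2] <- 100L
  hs <- histogram_set(truth$energies, counts, lad$temperatures)
  expect_warning(dosn <- wham(hs), "overlap")
  expect_false(dosn$state$overlap_ok)
})

test_that("combine_runs aligns gauges and reports honest errors", {
  truth <- make_truth(60)
  base <- dos_estimate(truth$energies, truth$ln_g)
  # identical replicates: zero error
  c1 <- combine_runs(list(base, base, base))
  expect_true(all(abs(c1$stderr[c1$support]) < 1e-12))
  # constant-shifted replicates: zero error after alignment
  shifted <- dos_estimate(truth$energies, truth$ln_g + 7.5)
  c2 <- combine_runs(list(base, shifted))
  expect_true(all(abs(c2$stderr[c2$support]) < 1e-10))
  expect_equal(c2$ln_g[c2$support] - base$ln_g[c2$support],
               rep(mean(c2$ln_g[c2$support] - base$ln_g[c2$support]),
                   sum(c2$support)), tolerance = 1e-10)
  # single run: errors absent, not zero
  c3 <- combine_runs(list(base))
  expect_true(all(is.na(c3$stderr)))
  # injected iid noise of known scale is recovered on average
  set.seed(21)
  sig <- 0.3
  reps <- lapply(1:6, function(r)
    dos_estimate(truth$energies,
                 truth$ln_g + stats::rnorm(length(truth$ln_g), sd = sig)))
  c4 <- combine_runs(reps)
  expect_equal(mean(c4$stderr[c4$support]), sig / sqrt(6), tolerance = 0.3)
})

test_that("the estimate gauge does not leak into observables", {
  truth <- make_truth(80)
  up <- dos_estimate(truth$energies, truth$ln_g + 123.4)
  for (T in c(0.5, 1, 2)) {
    expect_equal(canonical_mean_energy(up, T), canonical_mean_energy(truth, T),
                 tolerance = 1e-10)
    expect_equal(heat_capacity(up, T), heat_capacity(truth, T),
                 tolerance = 1e-8)
  }
})
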