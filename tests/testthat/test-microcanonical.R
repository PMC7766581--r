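# Bezier smoothing, derivative curves and transition classification on
# synthetic constructions with known answers.

test_that("entropy is kB ln g on the support, gauge shifting only S", {
  d <- dos_estimate(c(0, 1, 2, 3), log(c(1, 2, 4, 8)))
  ec <- entropy_from_dos(d)
  expect_equal(ec$S[1:2], c(0, log(2)))
  up <- entropy_from_dos(dos_estimate(c(0, 1, 2, 3), log(c(1, 2, 4, 8)) + 3))
  expect_equal(up$S - ec$S, rep(3, 4))
  expect_error(entropy_from_dos(dos_estimate(1:4, rep(NA_real_, 4))), "support")
})

test_that("Bezier smoothing is affine-exact and interpolates endpoints", {
  x <- sort(c(0, 10, stats::runif(28, 0, 10)))   # non-uniform abscissae
  set.seed(1)
  x <- sort(stats::runif(30, 0, 10)); x[1] <- 0; x[30] <- 10
  y <- 2.5 * x - 1
  bz <- bezier_smooth(x, y)
  pr <- predict(bz, seq(0, 10, length.out = 101))
  expect_equal(pr$y, 2.5 * pr$x - 1, tolerance = 1e-9)
  expect_equal(pr$d1, rep(2.5, 101), tolerance = 1e-8)
  expect_true(all(abs(pr$d2) < 1e-8))
  expect_equal(predict(bz, c(0, 10))$y, c(-1, 24), tolerance = 1e-12)
  expect_error(bezier_smooth(c(1, 3, 2, 4), 1:4), "increasing")
})

test_that("Bezier smoothing preserves convexity of the control data", {
  for (s in 1:3) {
    set.seed(s)
    x <- seq(0, 4, length.out = 40)
    y <- exp(x) + cumsum(abs(stats::rnorm(40, sd = 0)))  # exactly convex
    bz <- bezier_smooth(x, y)
    pr <- predict(bz, seq(0.05, 3.95, length.out = 200))
    expect_true(all(pr$d2 >= -1e-8))
    # random convex polygon data
    slopes <- sort(stats::rnorm(39))
    y2 <- cumsum(c(0, slopes))
    pr2 <- predict(bezier_smooth(x, y2), seq(0.05, 3.95, length.out = 200))
    expect_true(all(pr2$d2 >= -1e-8))
  }
})

test_that("derivative curves match analytic derivatives of a log entropy", {
  e_off <- -5; cc <- 12; a <- 2
  E <- seq(0, 40, length.out = 400)
  ec <- structure(list(energies = E, S = a + cc * log(E - e_off),
                       errors = rep(NA_real_, 400), kB = 1),
                  class = "entropy_curve")
  cv <- derivative_curves(ec, grid_size = 800)
  inner <- cv$energies > 4 & cv$energies < 36
  expect_equal(cv$beta[inner], cc / (cv$energies[inner] - e_off),
               tolerance = 0.01)
  expect_equal(cv$gamma[inner], -cc / (cv$energies[inner] - e_off)^2,
               tolerance = 0.01)
  # beta is numerically the derivative of the smoothed S
  fd <- diff(cv$S) / diff(cv$energies)
  mid <- (cv$beta[-1] + cv$beta[-length(cv$beta)]) / 2
  expect_equal(fd[inner[-1] & inner[-length(inner)]],
               mid[inner[-1] & inner[-length(inner)]], tolerance = 1e-3)
  # strictly concave, monotone beta: no transitions of any order
  expect_equal(nrow(find_transitions(cv)), 0)
})

test_that("affine entropy has vanishing gamma and delta", {
  E <- seq(-3, 7, length.out = 200)
  ec <- structure(list(energies = E, S = 0.7 * E + 2,
                       errors = rep(NA_real_, 200), kB = 1),
                  class = "entropy_curve")
  cv <- derivative_curves(ec, grid_size = 300)
  expect_equal(cv$beta, rep(0.7, 300), tolerance = 1e-8)
  expect_true(all(abs(cv$gamma) < 1e-8))
  expect_true(all(abs(cv$delta) < 1e-7))
  expect_equal(nrow(find_transitions(cv)), 0)
})

test_that("the two-Gaussian intruder yields one first-order transition at the Maxwell slope", {
  dos <- two_gaussian_testbed()
  fit <- microcanonical(dos)
  tr <- fit$transitions
  o1 <- tr[tr$order == 1, ]
  expect_equal(nrow(o1), 1)
  expect_equal(o1$dependence, "independent")
  expect_gt(o1$beta_tr, 0)
  # independent oracle: Maxwell double tangent on the exact curve, computed
  # from the closed-form ln g on a fine grid (no smoothing involved)
  Ef <- seq(-25, 30, length.out = 8000)
  dt <- double_tangent_slope(Ef, two_gaussian_ln_g(Ef))
  expect_false(is.na(dt$slope))
  expect_equal(o1$beta_tr, dt$slope, tolerance = 0.05)
  # E_tr lies inside the intruder bracketed by the tangent touch points
  expect_gt(o1$E_tr, dt$e1)
  expect_lt(o1$E_tr, dt$e2)
  # no spurious independent records of other orders
  expect_equal(nrow(tr[tr$order == 2 & tr$dependence == "independent", ]), 0)
})

test_that("a cubic flat point in beta is classified as a second-order transition", {
  dos <- cubic_flat_dos(n_bins = 300, e_star = 0)
  fit <- microcanonical(dos)
  tr <- fit$transitions
  expect_equal(nrow(tr[tr$order == 1, ]), 0)
  o2 <- tr[tr$order == 2 & tr$dependence == "independent", ]
  expect_equal(nrow(o2), 1)
  grid_cell <- diff(fit$curves$energies[1:2])
  expect_lt(abs(o2$E_tr - 0), 2 * grid_cell)
  expect_lt(o2$signal, 0)
})

test_that("featureless densities of states produce no records", {
  gauss <- synthetic_dos("single_gaussian", seq(-30, 30, length.out = 300),
                         mu = 0, sigma = 8)
  expect_equal(nrow(microcanonical(gauss)$transitions), 0)
  logc <- synthetic_dos("log_concave", seq(1, 100, length.out = 300), a = 30)
  expect_equal(nrow(microcanonical(logc)$transitions), 0)
})

test_that("records are gauge-invariant and energy-shift covariant", {
  dos <- two_gaussian_testbed()
  fit <- microcanonical(dos)
  up <- dos_estimate(dos$energies, dos$ln_g + 55)
  fit_up <- microcanonical(up)
  expect_equal(fit_up$transitions$E_tr, fit$transitions$E_tr)
  expect_equal(fit_up$transitions$beta_tr, fit$transitions$beta_tr)
  sh <- dos_estimate(dos$energies + 13, dos$ln_g)
  fit_sh <- microcanonical(sh)
  expect_equal(fit_sh$transitions$E_tr, fit$transitions$E_tr + 13,
               tolerance = 1e-8)
  expect_equal(fit_sh$transitions$beta_tr, fit$transitions$beta_tr,
               tolerance = 1e-8)
})

test_that("the first-order location is stable under halving the bin width", {
  f1 <- microcanonical(two_gaussian_testbed(400))
  f2 <- microcanonical(two_gaussian_testbed(800))
  b1 <- f1$transitions$beta_tr[f1$transitions$order == 1]
  b2 <- f2$transitions$beta_tr[f2$transitions$order == 1]
  expect_equal(length(b1), 1)
  expect_equal(length(b2), 1)
  expect_lt(abs(b2 / b1 - 1), 0.02)
})

test_that("transition tables report reduced energies against E_min", {
  rec <- structure(data.frame(order = 1L, dependence = "independent",
                              E_tr = -225.2, beta_tr = 2.95, signal = 1,
                              significance = 10, noisy = FALSE),
                   class = c("transition_records", "data.frame"))
  tab <- transition_table(rec, e_min = -261.7, kappa = 0)
  expect_equal(tab$delta_E, 36.5, tolerance = 1e-9)
  expect_equal(tab$kappa, 0)
  # empty records give a header-only table
  empty <- find_transitions(derivative_curves(structure(
    list(energies = seq(0, 1, length.out = 50), S = seq(0, 1, length.out = 50),
         errors = rep(NA_real_, 50), kB = 1), class = "entropy_curve"),
    grid_size = 100))
  tab0 <- transition_table(empty, e_min = 0)
  expect_equal(nrow(tab0), 0)
  expect_true(all(c("kappa", "E_tr", "delta_E", "beta_tr", "order") %in%
                  names(tab0)))
})

test_that("replicate spread propagates into curve errors and significance", {
  base <- two_gaussian_testbed(300)
  set.seed(33)
  reps <- lapply(1:4, function(r)
    dos_estimate(base$energies,
                 base$ln_g + stats::rnorm(length(base$ln_g), sd = 0.02)))
  fit <- microcanonical(reps)
  expect_equal(fit$curves$n_replicates, 4)
  expect_true(all(is.finite(fit$curves$errors$beta)))
  o1 <- fit$transitions[fit$transitions$order == 1, ]
  expect_equal(nrow(o1), 1)
  expect_true(is.finite(o1$significance))
  expect_gt(o1$significance, 2)
})
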