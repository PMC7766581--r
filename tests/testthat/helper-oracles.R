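# Shared helpers: independent reference implementations (oracles) and
# random-input generators used across the test files.

# full-recomputation reference for the total energy, built only from the
# R-level potential formulas (independent of the compiled path)
ref_total_energy <- function(conf, p) {
  n <- nrow(conf)
  enb <- 0
  if (n >= 3) {
    for (i in 3:n) for (j in 1:(i - 2))
      enb <- enb + nonbonded_potential(sqrt(sum((conf[i, ] - conf[j, ])^2)), p)
  }
  eb <- sum(bond_potential(bond_lengths(conf), p))
  ebend <- sum(bending_potential(bend_angles(conf), p))
  list(nonbonded = enb, bonded = eb, bending = ebend,
       total = enb + eb + ebend)
}

# random valid chain: correlated-direction walk with bond lengths well
# inside the FENE range; produces compact coils with active non-bonded
# contacts but no extreme overlaps
rand_chain <- function(n, seed) {
  set.seed(seed)
  d <- c(1, 0, 0)
  pos <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      cand <- d + 0.7 * stats::rnorm(3)
      cand <- cand / sqrt(sum(cand^2))
      step <- stats::runif(1, 0.9, 1.1) * cand
      newp <- pos[i - 1, ] + step
      # keep monomers from near-coincidence so LJ energies stay moderate
      if (i < 3 || min(sqrt(rowSums(sweep(pos[1:(i - 2), , drop = FALSE],
                                          2, newp)^2))) > 0.8) break
    }
    pos[i, ] <- newp
    d <- cand
  }
  conformation(pos)
}

# rigid-body transform for isometry-invariance checks
rigid_transform <- function(conf, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  phi <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
  shift <- stats::rnorm(3, sd = 5)
  conformation(sweep(unclass(conf) %*% R, 2, shift, `+`))
}

# exact two-Gaussian log density of states (same formula the fixture uses,
# evaluated independently on an arbitrary grid)
two_gaussian_ln_g <- function(E, mu = c(0, 60), sigma = c(4, 8),
                              log_weights = c(0, 35.6)) {
  q1 <- log_weights[1] - (E - mu[1])^2 / (2 * sigma[1]^2)
  q2 <- log_weights[2] - (E - mu[2])^2 / (2 * sigma[2]^2)
  pmax(q1, q2) + log1p(exp(-abs(q1 - q2)))
}

# entropy table whose beta(E) has a near-flat cubic inflection at e_star:
# beta = beta0 - a (E - e_star) - c (E - e_star)^3, integrated analytically
cubic_flat_dos <- function(n_bins = 300, e_star = 0, beta0 = 1,
                           a = 0.02, c = 0.001) {
  E <- seq(-10, 10, length.out = n_bins)
  ln_g <- beta0 * E - a * (E - e_star)^2 / 2 - c * (E - e_star)^4 / 4
  synthetic_dos("custom", E, ln_g = ln_g)
}

# normalized Boltzmann CDF of the dimer bond length on the FENE range,
# by quadrature of r^2 exp(-V_B(r)/T) (the radial measure of the relative
# coordinate)
dimer_bond_cdf <- function(p, T, n_grid = 20000) {
  lo <- p$r0 - p$fene_R + 1e-9
  hi <- p$r0 + p$fene_R - 1e-9
  r <- seq(lo, hi, length.out = n_grid)
  lw <- 2 * log(r) - bond_potential(r, p) / (p$kB * T)
  w <- exp(lw - max(lw))
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(r, cdf, yleft = 0, yright = 1)
}

ks_distance <- function(samples, cdf_fun) {
  s <- sort(samples)
  n <- length(s)
  cd <- cdf_fun(s)
  max(abs(cd - seq_len(n) / n), abs(cd - (seq_len(n) - 1) / n))
}
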