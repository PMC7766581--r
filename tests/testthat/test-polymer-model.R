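test_that("model parameters satisfy the derived-scale invariants", {
  p <- model_params(55, kappa = 1)
  expect_equal(p$sigma, 2^(-1 / 6) * p$r0)
  expect_equal(p$r_cutoff, 2.5 * p$sigma)
  expect_equal(p$v_shift, lennard_jones(p$r_cutoff, p))
  expect_lt(p$fene_R, p$r0)
  expect_error(model_params(1), "n_monomers")
  expect_error(model_params(10, kappa = -1))
})

test_that("Lennard-Jones potential has its minimum, zero and cutoff values", {
  p <- model_params(10)
  expect_equal(lennard_jones(p$r0, p), -1)
  expect_equal(lennard_jones(p$sigma, p), 0)
  expect_equal(lennard_jones(2.5 * p$sigma, p), 4 * (2.5^-12 - 2.5^-6),
               tolerance = 1e-12)
  expect_equal(lennard_jones(2.5 * p$sigma, p), -0.0163169, tolerance = 1e-5)
  expect_error(lennard_jones(0, p), "positive")
  expect_error(lennard_jones(-1, p), "positive")
})

test_that("non-bonded potential is shifted, truncated and continuous at the cutoff", {
  p <- model_params(10)
  expect_equal(nonbonded_potential(p$r_cutoff, p), 0)
  expect_equal(nonbonded_potential(3 * p$sigma, p), 0)
  expect_equal(nonbonded_potential(10, p), 0)
  expect_equal(nonbonded_potential(p$r0, p), -0.9836831, tolerance = 1e-6)
  expect_lt(abs(nonbonded_potential(p$r_cutoff - 1e-8, p)), 1e-6)
})

test_that("FENE bond potential has its minimum at r0 and diverges at the range ends", {
  p <- model_params(10)
  expect_equal(bond_potential(p$r0, p), nonbonded_potential(p$r0, p))
  expect_equal(bond_potential(p$r0, p), -0.9836831, tolerance = 1e-6)
  expect_identical(bond_potential(p$r0 + p$fene_R, p), Inf)
  expect_identical(bond_potential(p$r0 - p$fene_R, p), Inf)
  expect_identical(bond_potential(2, p), Inf)
  r <- seq(p$r0 - p$fene_R + 1e-4, p$r0 + p$fene_R - 1e-4, length.out = 20001)
  v <- bond_potential(r, p)
  expect_equal(r[which.min(v)], p$r0, tolerance = 1e-3)
})

test_that("bending potential is zero at the reference angle and kappa-linear", {
  p2 <- model_params(10, kappa = 2)
  expect_equal(bending_potential(0, p2), 0)
  expect_equal(bending_potential(pi, p2), 4)
  p0 <- model_params(10, kappa = 0)
  expect_equal(bending_potential(seq(0, pi, length.out = 11), p0),
               rep(0, 11))
  th <- seq(0, pi, length.out = 11)
  expect_true(all(bending_potential(th, p2) >= 0))
})

test_that("total energy matches the hand-computed dimer and trimer values", {
  p2 <- model_params(2)
  dimer <- conformation(rbind(c(0, 0, 0), c(1, 0, 0)))
  e <- total_energy(dimer, p2)
  expect_equal(e$total, -0.9836831, tolerance = 1e-6)
  expect_equal(e$nonbonded, 0)
  expect_equal(e$bending, 0)

  p3 <- model_params(3, kappa = 3)   # collinear: bending term vanishes
  trimer <- conformation(cbind(0:2, 0, 0))
  e3 <- total_energy(trimer, p3)
  expect_equal(e3$total, -1.9820552, tolerance = 1e-6)
  expect_equal(e3$nonbonded, nonbonded_potential(2, p3), tolerance = 1e-12)
  expect_equal(e3$bending, 0)
  expect_equal(e3$total, e3$nonbonded + e3$bonded + e3$bending)
})

test_that("total energy agrees with the R formula reference on random chains", {
  for (s in 1:4) {
    p <- model_params(12, kappa = c(0, 0.5, 1, 2)[s])
    cf <- rand_chain(12, 100 + s)
    got <- total_energy(cf, p)
    want <- ref_total_energy(cf, p)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
    if (p$kappa == 0) expect_identical(got$bending, 0)
  }
})

test_that("total energy is invariant under isometries and chain reversal", {
  p <- model_params(12, kappa = 1.5)
  cf <- rand_chain(12, 7)
  e0 <- total_energy(cf, p)$total
  for (s in 1:3)
    expect_equal(total_energy(rigid_transform(cf, s), p)$total, e0,
                 tolerance = 1e-10)
  rev_cf <- conformation(unclass(cf)[nrow(cf):1, ])
  expect_equal(total_energy(rev_cf, p)$total, e0, tolerance = 1e-10)
})

test_that("an out-of-range bond gives the infinite-energy sentinel", {
  p <- model_params(3)
  bad <- conformation(rbind(c(0, 0, 0), c(1.6, 0, 0), c(2.6, 0, 0)))
  expect_identical(total_energy(bad, p)$total, Inf)
})

test_that("displacement deltas match full recomputation on random moves", {
  p <- model_params(10, kappa = 1)
  cf <- rand_chain(10, 42)
  e_before <- total_energy(cf, p)$total
  set.seed(1)
  for (t in 1:400) {
    mv <- displacement_move_spec(sample(10, 1), stats::runif(3, -0.2, 0.2))
    d <- energy_delta(cf, mv, p)
    e_after <- total_energy(apply_move(cf, mv), p)$total
    if (is.finite(e_after)) {
      expect_equal(d, e_after - e_before,
                   tolerance = 1e-9 * max(1, abs(e_after - e_before)))
    } else {
      expect_identical(d, Inf)
    }
  }
  # null move
  expect_equal(energy_delta(cf, displacement_move_spec(3, c(0, 0, 0)), p), 0)
})

test_that("pivot deltas match full recomputation on random moves", {
  p <- model_params(10, kappa = 1)
  cf <- rand_chain(10, 43)
  e_before <- total_energy(cf, p)$total
  set.seed(2)
  for (t in 1:400) {
    mv <- pivot_move_spec(sample(2:9, 1), stats::rnorm(3),
                          stats::runif(1, 0, 2 * pi))
    d <- energy_delta(cf, mv, p)
    e_after <- total_energy(apply_move(cf, mv), p)$total
    expect_equal(d, e_after - e_before,
                 tolerance = 1e-9 * max(1, abs(e_after - e_before)))
  }
})

test_that("pivot moves are rigid: bonds and non-pivot angles are preserved", {
  p <- model_params(12, kappa = 1)
  cf <- rand_chain(12, 5)
  set.seed(3)
  for (t in 1:50) {
    i <- sample(2:11, 1)
    mv <- pivot_move_spec(i, stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    after <- apply_move(cf, mv)
    expect_equal(bond_lengths(after), bond_lengths(cf), tolerance = 1e-10)
    ang0 <- bend_angles(cf); ang1 <- bend_angles(after)
    keep <- setdiff(seq_along(ang0), i - 1)   # angle l lives at monomer l+1
    expect_equal(ang1[keep], ang0[keep], tolerance = 1e-10)
  }
  # zero angle is the identity
  mv0 <- pivot_move_spec(5, c(0, 0, 1), 0)
  expect_equal(unclass(apply_move(cf, mv0)), unclass(cf), tolerance = 1e-14)
  expect_equal(energy_delta(cf, mv0, p), 0, tolerance = 1e-10)
})
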