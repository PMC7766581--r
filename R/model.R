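#' Model parameters for the coarse-grained bead-spring chain
#'
#' Builds the full parameter set of the polymer energy model: a truncated and
#' shifted 12-6 Lennard-Jones potential between non-bonded monomers, a
#' combined FENE + Lennard-Jones bond potential, and a cosine bending
#' potential controlled by the stiffness `kappa`. All quantities are in
#' reduced units: the energy scale `epsilon_lj`, the reference bond length
#' `r0` and the Boltzmann constant `kB` default to 1.
#'
#' Derived quantities are computed internally and cannot drift out of sync:
#' `sigma = 2^(-1/6) r0` (so the LJ minimum sits at `r0`),
#' `r_cutoff = 2.5 sigma`, and the shift constant
#' `v_shift = lennard_jones(r_cutoff)` which makes the non-bonded potential
#' continuous (and zero) at the cutoff. The FENE parameters are the standard
#' choice `R = (3/7) r0` and `K = (98/5) r0^2`; bond lengths are confined to
#' the open interval `(r0 - R, r0 + R)`.
#'
#' @param n_monomers chain length N (>= 2).
#' @param kappa bending stiffness (>= 0); `kappa = 0` is the fully flexible
#'   chain.
#' @param epsilon_lj Lennard-Jones energy scale.
#' @param r0 reference bond length and location of the LJ minimum.
#' @param theta0 reference bending angle in radians (0 = straight chain).
#' @param kB Boltzmann constant.
#' @return An object of class `model_params` (a named list with all couplings
#'   and geometric scales).
#' @examples
#' p <- model_params(55, kappa = 1)
#' lennard_jones(p$r0, p)  # -1 by construction
#' @export
model_params <- function(n_monomers, kappa = 0, epsilon_lj = 1, r0 = 1,
                         theta0 = 0, kB = 1) {
  stopifnot(n_monomers >= 2, kappa >= 0, epsilon_lj > 0, r0 > 0, kB > 0)
  sigma <- 2^(-1 / 6) * r0
  p <- list(
    epsilon_lj = epsilon_lj,
    r0         = r0,
    sigma      = sigma,
    r_cutoff   = 2.5 * sigma,
    fene_R     = (3 / 7) * r0,
    fene_K     = (98 / 5) * r0^2,
    kappa      = kappa,
    theta0     = theta0,
    n_monomers = as.integer(n_monomers),
    kB         = kB
  )
  p$v_shift <- 4 * epsilon_lj * ((sigma / p$r_cutoff)^12 - (sigma / p$r_cutoff)^6)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bead-spring chain model (reduced units)\n")
  cat(sprintf("  N = %d monomers, kappa = %g%s\n", x$n_monomers, x$kappa,
              if (x$kappa == 0) " (flexible)" else " (semiflexible)"))
  cat(sprintf("  LJ: epsilon = %g, sigma = %.6f, cutoff = %.6f, shift = %.7f\n",
              x$epsilon_lj, x$sigma, x$r_cutoff, x$v_shift))
  cat(sprintf("  FENE: r0 = %g, R = %.6f, K = %g\n", x$r0, x$fene_R, x$fene_K))
  cat(sprintf("  bending: theta0 = %g rad\n", x$theta0))
  invisible(x)
}

#' Unshifted 12-6 Lennard-Jones potential
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6]`, no cutoff, no shift. The minimum is
#' at `r0` with value `-eps`; the zero crossing is at `sigma`.
#'
#' @param r distance(s), must be positive.
#' @param params a [model_params()] object.
#' @return potential energy (vectorized over `r`).
#' @export
lennard_jones <- function(r, params) {
  if (any(r <= 0)) stop("lennard_jones: r must be positive")
  x6 <- (params$sigma / r)^6
  4 * params$epsilon_lj * (x6^2 - x6)
}

#' Truncated and shifted non-bonded potential
#'
#' `lennard_jones(r) - v_shift` for distances below `r_cutoff` and exactly 0
#' beyond; the shift makes the potential continuous at the cutoff.
#'
#' @inheritParams lennard_jones
#' @export
nonbonded_potential <- function(r, params) {
  if (any(r <= 0)) stop("nonbonded_potential: r must be positive")
  ifelse(r < params$r_cutoff, lennard_jones(r, params) - params$v_shift, 0)
}

#' FENE + Lennard-Jones bond potential
#'
#' `-(1/2) K R^2 log(1 - ((r - r0)/R)^2) + lennard_jones(r) - v_shift` inside
#' the FENE range `(r0 - R, r0 + R)`; outside, the bond is invalid and the
#' infinite-energy sentinel `Inf` is returned (not an error), so Metropolis
#' sampling rejects such moves uniformly. The minimum is at `r0`.
#'
#' @inheritParams lennard_jones
#' @export
bond_potential <- function(r, params) {
  q2 <- ((r - params$r0) / params$fene_R)^2
  out <- rep(Inf, length(r))
  ok <- q2 < 1 & r > 0
  if (any(ok)) {
    out[ok] <- -0.5 * params$fene_K * params$fene_R^2 * log1p(-q2[ok]) +
      lennard_jones(r[ok], params) - params$v_shift
  }
  out
}

#' Bending potential
#'
#' `kappa [1 - cos(theta - theta0)]` where `theta` is the angle between two
#' successive bond vectors (`theta = 0` for a straight chain). Non-negative,
#' and zero iff `theta = theta0` (for `kappa > 0`).
#'
#' @param theta bend angle(s) in radians, in `[0, pi]`.
#' @param params a [model_params()] object.
#' @export
bending_potential <- function(theta, params) {
  params$kappa * (1 - cos(theta - params$theta0))
}

#' Construct a conformation
#'
#' A conformation is an N x 3 numeric matrix of monomer positions (rows =
#' monomers in chain order, lengths in units of `r0`), carrying class
#' `conformation`. A conformation with a bond length outside the FENE range
#' is representable but has infinite energy.
#'
#' @param positions N x 3 numeric matrix.
#' @export
conformation <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 2 || !is.numeric(positions))
    stop("conformation: positions must be a numeric N x 3 matrix with N >= 2")
  if (any(!is.finite(positions)))
    stop("conformation: positions must be finite")
  structure(positions, class = c("conformation", "matrix", "array"))
}

#' Straight initial chain
#'
#' All monomers on the x axis at bond length `r0`: valid under FENE for any
#' `kappa`, used as the initial state of every simulation thread.
#'
#' @param params a [model_params()] object.
#' @export
straight_chain <- function(params) {
  n <- params$n_monomers
  conformation(cbind((seq_len(n) - 1) * params$r0, 0, 0))
}

#' Bend angles of a conformation
#'
#' Angle between successive bond vectors at each interior monomer
#' (length N - 2 vector); 0 = straight. The cosine is clamped to `[-1, 1]`
#' before `acos`.
#'
#' @param conf a [conformation()].
#' @export
bend_angles <- function(conf) {
  n <- nrow(conf)
  if (n < 3) return(numeric(0))
  b <- diff(conf)                      # (n-1) x 3 bond vectors
  nb <- sqrt(rowSums(b^2))
  dots <- rowSums(b[-nrow(b), , drop = FALSE] * b[-1, , drop = FALSE])
  cth <- dots / (nb[-length(nb)] * nb[-1])
  acos(pmin(1, pmax(-1, cth)))
}

#' Bond lengths of a conformation
#' @param conf a [conformation()].
#' @export
bond_lengths <- function(conf) {
  sqrt(rowSums(diff(conf)^2))
}

#' Total energy of a conformation
#'
#' Sums the truncated-shifted LJ interaction over non-bonded pairs
#' (`i > j + 1`; adjacent bonded pairs are excluded since the bond potential
#' already carries an LJ term), the FENE bond potential over the N - 1
#' bonds, and the bending potential over the N - 2 interior angles. If any
#' bond is outside the FENE range the bonded and total components are the
#' infinite-energy sentinel `Inf`.
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @return An `energy_report`: list with components `nonbonded`, `bonded`,
#'   `bending`, `total`.
#' @export
total_energy <- function(conf, params) {
  stopifnot(nrow(conf) == params$n_monomers)
  e <- cpp_total_energy(unclass(conf), unclass(params))
  structure(as.list(e), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("Energy: total = %.6f (non-bonded %.6f, bonded %.6f, bending %.6f)\n",
              x$total, x$nonbonded, x$bonded, x$bending))
  invisible(x)
}

#' Incremental energy change of a Monte Carlo move
#'
#' Computes `total_energy(after) - total_energy(before)` by recomputing only
#' the terms a move can change: for a single-monomer displacement, the
#' non-bonded, bond and bend terms involving that monomer; for a pivot
#' rotation, the bend angle at the pivot and the non-bonded pairs straddling
#' it (bond lengths and all other angles are preserved by the rigid
#' rotation). A move that takes a bond outside the FENE range returns `Inf`.
#'
#' @param conf a [conformation()].
#' @param move a move description: `displacement_move_spec(i, shift)` or
#'   `pivot_move_spec(i, axis, angle)`.
#' @param params a [model_params()] object.
#' @return scalar energy difference.
#' @export
energy_delta <- function(conf, move, params) {
  stopifnot(inherits(move, "mc_move"))
  if (move$type == "displacement") {
    cpp_displacement_delta(unclass(conf), unclass(params), move$i,
                           as.numeric(move$shift))
  } else {
    cpp_pivot_delta(unclass(conf), unclass(params), move$i,
                    as.numeric(move$axis), move$angle)
  }
}

#' Move descriptions
#'
#' Plain descriptions of the two Monte Carlo update types, used with
#' [energy_delta()] and [apply_move()]. Monomer indices are 1-based.
#'
#' @param i monomer index (displacement: 1..N; pivot: interior, 2..N-1).
#' @param shift length-3 displacement vector.
#' @rdname mc_move
#' @export
displacement_move_spec <- function(i, shift) {
  structure(list(type = "displacement", i = as.integer(i),
                 shift = as.numeric(shift)), class = "mc_move")
}

#' @param axis length-3 rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @rdname mc_move
#' @export
pivot_move_spec <- function(i, axis, angle) {
  axis <- as.numeric(axis)
  structure(list(type = "pivot", i = as.integer(i),
                 axis = axis / sqrt(sum(axis^2)), angle = angle),
            class = "mc_move")
}

#' Apply a move to a conformation
#'
#' Returns the conformation after the move (the pivot rotates monomers
#' `i+1..N` rigidly about the axis through monomer `i`, Rodrigues formula).
#'
#' @inheritParams energy_delta
#' @export
apply_move <- function(conf, move, params = NULL) {
  stopifnot(inherits(move, "mc_move"))
  out <- unclass(conf)
  if (move$type == "displacement") {
    out[move$i, ] <- out[move$i, ] + move$shift
  } else {
    n <- nrow(out)
    i <- move$i
    if (i < 2 || i > n - 1) stop("pivot index must be interior (2..N-1)")
    u <- move$axis
    phi <- move$angle
    tail_idx <- (i + 1):n
    v <- sweep(out[tail_idx, , drop = FALSE], 2, out[i, ])
    cphi <- cos(phi); sphi <- sin(phi)
    dotu <- drop(v %*% u)
    crossu <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
                    u[3] * v[, 1] - u[1] * v[, 3],
                    u[1] * v[, 2] - u[2] * v[, 1])
    vr <- v * cphi + crossu * sphi + outer(dotu * (1 - cphi), u)
    out[tail_idx, ] <- sweep(vr, 2, out[i, ], `+`)
  }
  conformation(out)
}
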