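# Synthetic densities of states with known transition structure, and exact
# categorical sampling of canonical histograms from them. These make every
# analysis stage testable without running long simulations.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Synthetic density of states
#'
#' Deterministic `ln g` tables for exercising the reweighting and
#' microcanonical machinery against known answers:
#' * `single_gaussian`: `ln g = -(E - mu)^2 / (2 sigma^2)`; `beta(E)` is
#'   linear, `gamma` a negative constant, no transitions.
#' * `two_gaussian`: `ln g = log[w1 N1(E) + w2 N2(E)]` (weights given as
#'   logs). With the second center well above the first and the weights
#'   chosen so both phases contribute, the entropy develops a convex
#'   intruder: the testbed for a first-order transition, whose Maxwell
#'   double-tangent slope is an independent oracle for `beta_tr`. The
#'   defaults produce a shallow intruder with exactly one positive-valued
#'   interior minimum of `beta`.
#' * `log_concave`: `ln g = a log(E - e_off)`; `beta = a / (E - e_off)` is
#'   positive and strictly monotone, so every derivative is extremum-free:
#'   no transitions of any order.
#' * `custom`: a user-supplied `ln_g` table.
#'
#' @param family one of `"single_gaussian"`, `"two_gaussian"`,
#'   `"log_concave"`, `"custom"`.
#' @param energies energy bin grid (uniform).
#' @param mu,sigma center(s) and width(s); scalars for `single_gaussian`,
#'   length-2 vectors for `two_gaussian`.
#' @param log_weights log mixture weights for `two_gaussian`.
#' @param a,e_off exponent and offset for `log_concave` (requires
#'   `min(energies) > e_off`).
#' @param ln_g explicit table for `custom`.
#' @return A [dos_estimate()] (finite on the whole grid).
#' @export
synthetic_dos <- function(family = c("single_gaussian", "two_gaussian",
                                     "log_concave", "custom"),
                          energies,
                          mu = 0, sigma = 1,
                          log_weights = c(0, 0),
                          a = 10, e_off = NULL,
                          ln_g = NULL) {
  family <- match.arg(family)
  energies <- as.numeric(energies)
  stopifnot(length(energies) >= 4, !is.unsorted(energies, strictly = TRUE))
  val <- switch(family,
    single_gaussian = {
      stopifnot(length(mu) == 1, length(sigma) == 1, sigma > 0)
      -(energies - mu)^2 / (2 * sigma^2)
    },
    two_gaussian = {
      stopifnot(length(mu) == 2, length(sigma) == 2, all(sigma > 0),
                length(log_weights) == 2)
      q1 <- log_weights[1] - (energies - mu[1])^2 / (2 * sigma[1]^2)
      q2 <- log_weights[2] - (energies - mu[2])^2 / (2 * sigma[2]^2)
      pmax(q1, q2) + log1p(exp(-abs(q1 - q2)))
    },
    log_concave = {
      if (is.null(e_off)) e_off <- energies[1] - diff(range(energies))
      stopifnot(a > 0, energies[1] > e_off)
      a * log(energies - e_off)
    },
    custom = {
      stopifnot(!is.null(ln_g), length(ln_g) == length(energies),
                all(is.finite(ln_g)))
      as.numeric(ln_g)
    })
  if (any(!is.finite(val))) stop("synthetic_dos: non-finite ln g")
  dos_estimate(energies, val,
               state = list(family = family,
                            params = list(mu = mu, sigma = sigma,
                                          log_weights = log_weights,
                                          a = a, e_off = e_off)))
}

#' Default two-Gaussian testbed for a first-order transition
#'
#' The parameterization used throughout the tests: centers 0 and 60, widths
#' 4 and 8, and a log-weight difference chosen so the entropy's convex
#' intruder is shallow — `beta` has exactly one positive-valued interior
#' minimum whose value lies close to the Maxwell double-tangent slope of
#' the same curve (the independent construction [double_tangent_slope()]
#' recovers it to within a few percent).
#'
#' @param n_bins number of energy bins.
#' @export
two_gaussian_testbed <- function(n_bins = 400) {
  synthetic_dos("two_gaussian", seq(-25, 30, length.out = n_bins),
                mu = c(0, 60), sigma = c(4, 8),
                log_weights = c(0, 35.6))
}

#' Maxwell double-tangent slope of an entropy curve
#'
#' Independent geometric construction for the first-order transition
#' temperature: the common tangent across the convex intruder of `S(E)` is
#' the segment of the upper concave hull of the sampled curve that bridges
#' the intruder. The hull is computed by a direct monotone scan on the raw
#' samples; no smoothing is involved, so this is an oracle independent of
#' the Bezier pipeline.
#'
#' @param energies,S sampled entropy curve (strictly increasing energies).
#' @return list with the tangent `slope` and the touch energies `e1`, `e2`
#'   (`NA`s if the curve is concave, i.e. has no intruder).
#' @export
double_tangent_slope <- function(energies, S) {
  stopifnot(length(energies) == length(S), length(energies) >= 3)
  x <- energies; y <- S
  hull <- integer(0)
  for (i in seq_along(x)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross >= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  if (length(hull) < 2) return(list(slope = NA_real_, e1 = NA_real_, e2 = NA_real_))
  gaps <- diff(x[hull])
  g <- which.max(gaps)
  i1 <- hull[g]; i2 <- hull[g + 1]
  if (i2 == i1 + 1)  # hull follows the curve everywhere: concave, no intruder
    return(list(slope = NA_real_, e1 = NA_real_, e2 = NA_real_))
  list(slope = (y[i2] - y[i1]) / (x[i2] - x[i1]), e1 = x[i1], e2 = x[i2])
}

#' Exact canonical histogram sampling from a density of states
#'
#' Draws per-thread energies by exact categorical sampling from
#' `p_k(E) proportional to g(E) exp(-E / kB T_k)` on the estimate's grid
#' and bins them — an exact-sampling oracle for the reweighting stage.
#'
#' @param dos a [dos_estimate()] with finite support.
#' @param ladder a [temperature_ladder()].
#' @param n samples per thread.
#' @param seed integer seed (R RNG, restored afterwards).
#' @param kB Boltzmann constant.
#' @return A [histogram_set()] on the estimate's grid.
#' @export
sample_histograms_from_dos <- function(dos, ladder, n, seed = 1, kB = 1) {
  stopifnot(inherits(dos, "dos_estimate"),
            inherits(ladder, "temperature_ladder"), n >= 0)
  E <- dos$energies
  sup <- dos$support
  K <- ladder$count
  counts <- matrix(0L, length(E), K)
  with_seed(seed, {
    for (k in seq_len(K)) {
      lw <- dos$ln_g[sup] - E[sup] / (kB * ladder$temperatures[k])
      p <- exp(lw - logsumexp(lw))
      if (n > 0)
        counts[sup, k] <- as.integer(stats::rmultinom(1, n, p))
    }
  })
  histogram_set(E, counts, ladder$temperatures)
}

#' Closed-form thread mean energy for categorical sampling
#'
#' `sum_E E p_k(E)` with `p_k(E) proportional to g(E) exp(-E/kB T)`; the
#' exact mean against which sampled thread means are checked.
#'
#' @inheritParams sample_histograms_from_dos
#' @param T thread temperature.
#' @export
categorical_mean_energy <- function(dos, T, kB = 1) {
  canonical_mean_energy(dos, T, kB)
}
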