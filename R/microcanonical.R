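# Generalized microcanonical inflection-point analysis: entropy from the
# density of states, global Bezier (Bernstein) smoothing with analytic
# derivatives, least-sensitive inflection-point detection and transition
# classification.

#' Microcanonical entropy from a density of states
#'
#' Boltzmann form `S(E) = kB ln g(E)` on the support of the estimate; the
#' additive gauge constant of `ln g` is irrelevant for every downstream
#' quantity (it cancels in all derivatives).
#'
#' @param dos a [dos_estimate()].
#' @param kB Boltzmann constant.
#' @return An `entropy_curve`: energies, S values and per-point errors
#'   (copied from the estimate, `NA` when absent).
#' @export
entropy_from_dos <- function(dos, kB = 1) {
  stopifnot(inherits(dos, "dos_estimate"))
  if (!any(dos$support)) stop("entropy_from_dos: empty support")
  keep <- dos$support
  structure(list(energies = dos$energies[keep],
                 S = kB * dos$ln_g[keep],
                 errors = kB * dos$stderr[keep],
                 kB = kB),
            class = "entropy_curve")
}

# Bernstein basis matrix: rows = evaluation parameters t in [0,1],
# columns = i = 0..n. Computed through logs for numerical stability at
# degree ~10^3; values <= 1 by construction, far terms underflow to 0.
bernstein_basis <- function(n, t) {
  iv <- 0:n
  lc <- lchoose(n, iv)
  B <- matrix(0, length(t), n + 1)
  interior <- t > 0 & t < 1
  if (any(interior)) {
    ti <- t[interior]
    Bi <- exp(sweep(outer(log(ti), iv) + outer(log1p(-ti), n - iv), 2, lc, `+`))
    B[interior, ] <- Bi
  }
  B[t <= 0, 1] <- 1
  B[t >= 1, n + 1] <- 1
  B
}

#' Global Bezier smoothing of a sampled curve
#'
#' Builds the single Bezier curve in Bernstein form that takes all data
#' points as control points (degree = number of points - 1). The curve
#' interpolates the endpoints and smooths everything in between; the
#' parametric derivatives are themselves Bernstein forms in the finite
#' differences of the control points, so derivatives with respect to the
#' abscissa follow analytically by the chain rule through the
#' parameter-to-abscissa map. Evaluation uses log-space Bernstein weights,
#' stable at degree ~10^3.
#'
#' @param x strictly increasing abscissae (>= 4 points).
#' @param y ordinates.
#' @return A `bezier_curve` object; evaluate with [predict.bezier_curve()].
#' @export
bezier_smooth <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (is.unsorted(x, strictly = TRUE))
    stop("bezier_smooth: abscissae must be strictly increasing")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x) - 1L),
            class = "bezier_curve")
}

# parametric value and derivatives (up to order 3) of a Bernstein-form
# curve with control ordinates v at parameters t
bezier_param_derivs <- function(v, t, max_deriv = 3) {
  n <- length(v) - 1L
  out <- list(bernstein_basis(n, t) %*% v)
  d <- v
  fac <- 1
  for (k in seq_len(max_deriv)) {
    d <- diff(d)
    fac <- fac * (n - k + 1)
    out[[k + 1]] <- if (length(d) >= 1 && n - k >= 0)
      fac * (bernstein_basis(n - k, t) %*% d)
    else matrix(0, length(t), 1)
    if (length(d) <= 1 && k < max_deriv) {
      # all higher differences vanish
      for (j in (k + 1):max_deriv) out[[j + 1]] <- matrix(0, length(t), 1)
      break
    }
  }
  lapply(out, drop)
}

# invert the (monotone) parameter-to-abscissa map X(t) for target abscissae
bezier_t_for_x <- function(object, x_out) {
  xc <- object$x
  n <- object$n
  h <- diff(xc)
  if (max(abs(h - h[1])) <= 1e-9 * abs(h[1])) {
    # uniform control abscissae: X(t) is exactly affine in t
    return((x_out - xc[1]) / (xc[n + 1] - xc[1]))
  }
  lo <- rep(0, length(x_out)); hi <- rep(1, length(x_out))
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    xm <- drop(bernstein_basis(n, mid) %*% xc)
    below <- xm < x_out
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Evaluate a Bezier curve and its derivatives
#'
#' Returns the smoothed ordinate and its first three derivatives with
#' respect to the abscissa at the requested points, via the chain rule
#' through the parameter-to-abscissa map.
#'
#' @param object a [bezier_smooth()] curve.
#' @param x_out evaluation abscissae (inside the data range).
#' @param max_deriv highest derivative order to return (0..3).
#' @param ... unused.
#' @return list with `x`, `y` and (as requested) `d1`, `d2`, `d3`.
#' @export
predict.bezier_curve <- function(object, x_out, max_deriv = 3, ...) {
  t <- pmin(1, pmax(0, bezier_t_for_x(object, x_out)))
  Y <- bezier_param_derivs(object$y, t, max_deriv)
  out <- list(x = x_out, y = Y[[1]])
  if (max_deriv >= 1) {
    X <- bezier_param_derivs(object$x, t, max_deriv)
    Xp <- X[[2]]
    out$d1 <- Y[[2]] / Xp
    if (max_deriv >= 2) {
      Xpp <- X[[3]]
      out$d2 <- (Y[[3]] * Xp - Y[[2]] * Xpp) / Xp^3
      if (max_deriv >= 3) {
        Xppp <- X[[4]]
        gp <- (Y[[4]] * Xp - Y[[2]] * Xppp) / Xp^3 -
          3 * Xpp * (Y[[3]] * Xp - Y[[2]] * Xpp) / Xp^4
        out$d3 <- gp / Xp
      }
    }
  }
  out
}

#' Smoothed entropy derivative curves
#'
#' Bezier-smooths the microcanonical entropy and evaluates
#' `beta(E) = dS/dE`, `gamma(E) = d beta/dE` and `delta(E) = d gamma/dE`
#' on a uniform energy grid. When per-replicate entropy curves are given,
#' the same construction is repeated per run on the common grid and the
#' cross-run spread (standard error of the mean) is attached to every
#' curve.
#'
#' @param entropy an [entropy_from_dos()] curve (the central estimate).
#' @param grid_size number of uniform evaluation points.
#' @param replicates optional list of per-run `entropy_curve`s.
#' @param control_thin keep every `control_thin`-th support point as a
#'   Bezier control point (1 = all; decimation option for noisy data).
#' @return A `microcanonical_curves` object: `energies`, `S`, `beta`,
#'   `gamma`, `delta`, matching `errors`, and the replicate count.
#' @export
derivative_curves <- function(entropy, grid_size = 1000, replicates = NULL,
                              control_thin = 1) {
  stopifnot(inherits(entropy, "entropy_curve"))
  rngs <- range(entropy$energies)
  if (!is.null(replicates)) {
    for (r in replicates) {
      rngs[1] <- max(rngs[1], min(r$energies))
      rngs[2] <- min(rngs[2], max(r$energies))
    }
    if (rngs[1] >= rngs[2])
      stop("derivative_curves: replicate supports do not overlap")
  }
  grid <- seq(rngs[1], rngs[2], length.out = grid_size)

  eval_one <- function(ec) {
    keep <- is.finite(ec$S)
    x <- ec$energies[keep]; y <- ec$S[keep]
    if (control_thin > 1) {
      idx <- unique(c(seq(1, length(x), by = control_thin), length(x)))
      x <- x[idx]; y <- y[idx]
    }
    bz <- bezier_smooth(x, y)
    p <- predict(bz, grid, max_deriv = 3)
    list(S = p$y, beta = p$d1, gamma = p$d2, delta = p$d3)
  }

  central <- eval_one(entropy)
  errors <- list(S = rep(NA_real_, grid_size), beta = rep(NA_real_, grid_size),
                 gamma = rep(NA_real_, grid_size), delta = rep(NA_real_, grid_size))
  n_rep <- 0L
  if (!is.null(replicates) && length(replicates) >= 2) {
    n_rep <- length(replicates)
    per <- lapply(replicates, eval_one)
    for (nm in names(errors)) {
      M <- vapply(per, `[[`, numeric(grid_size), nm)
      errors[[nm]] <- apply(M, 1, stats::sd) / sqrt(n_rep)
    }
  }
  structure(list(energies = grid, S = central$S, beta = central$beta,
                 gamma = central$gamma, delta = central$delta,
                 errors = errors, n_replicates = n_rep),
            class = "microcanonical_curves")
}

#' @export
as.data.frame.microcanonical_curves <- function(x, ...) {
  data.frame(E = x$energies, S = x$S, beta = x$beta, gamma = x$gamma,
             delta = x$delta, S_err = x$errors$S, beta_err = x$errors$beta,
             gamma_err = x$errors$gamma, delta_err = x$errors$delta)
}

# strict interior local extrema of a curve segment, with a prominence
# filter (against the absolute threshold `prom_min`) that discards
# numerically flat wiggles
local_extrema <- function(c, kind = c("min", "max"), prom_min = 0) {
  kind <- match.arg(kind)
  v <- if (kind == "min") -c else c
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  keep <- vapply(idx, function(i) {
    left <- if (i > 1) min(v[1:(i - 1)]) else v[1]
    right <- if (i < n) min(v[(i + 1):n]) else v[n]
    prom <- v[i] - max(left, right)
    prom > prom_min
  }, logical(1))
  idx[keep]
}

#' Locate and classify phase transitions
#'
#' Implements the least-sensitive inflection-point rules on the smoothed
#' derivative curves:
#' * order 1 (independent): interior positive-valued local minimum of
#'   `beta` (a least-sensitive inflection of `S`, i.e. the backbending /
#'   convex-intruder signature);
#' * order 2 independent: interior negative-valued local maximum of
#'   `gamma`;
#' * order 2 dependent: interior positive-valued local minimum of `gamma`,
#'   admitted only with an independent order-1 partner at lower energy;
#' * order 3 independent: interior positive-valued local minimum of
#'   `delta`;
#' * order 3 dependent: interior negative-valued local maximum of `delta`,
#'   admitted only with an independent order-2 partner at lower energy.
#'
#' A configurable margin at each end of the support is excluded to avoid
#' endpoint artifacts of the global Bezier curve. Each record carries
#' `beta_tr = beta(E_tr)`, the extremal value of the classifying curve and
#' its significance (|value| / propagated error at `E_tr`; `NA` without
#' replicate errors). Records below the significance threshold are flagged
#' noisy but still listed. Multiple same-sign extrema are kept as separate
#' records; an empty result is valid.
#'
#' @param curves a [derivative_curves()] object.
#' @param max_order highest transition order searched (orders above 3 are
#'   not supported).
#' @param margin fraction of the energy range excluded at each end.
#' @param prom_tol_rel relative prominence below which an extremum is
#'   treated as numerical noise.
#' @param noise_threshold significance below which a record is flagged.
#' @return A `transition_records` data frame sorted by `E_tr` with columns
#'   `order`, `dependence`, `E_tr`, `beta_tr`, `signal`, `significance`,
#'   `noisy`.
#' @export
find_transitions <- function(curves, max_order = 3, margin = 0.02,
                             prom_tol_rel = 1e-5, noise_threshold = 2) {
  stopifnot(inherits(curves, "microcanonical_curves"), max_order <= 3)
  n <- length(curves$energies)
  lo <- max(2L, ceiling(margin * n))
  hi <- min(n - 1L, n - ceiling(margin * n) + 1L)
  win <- lo:hi
  E <- curves$energies[win]
  beta <- curves$beta[win]
  gamma <- curves$gamma[win]
  delta <- curves$delta[win]
  err <- lapply(curves$errors, function(e) e[win])

  # prominence floors: an extremum of the k-th entropy derivative must rise
  # above both a fraction of its own curve's span and the scale implied by
  # the entropy variation over the window (so exactly flat or affine
  # entropies produce nothing despite float-level wiggles)
  L <- diff(range(E))
  spanS <- diff(range(curves$S[win]))
  prom_min <- function(c, k)
    prom_tol_rel * max(diff(range(c)), spanS / L^k)

  rec <- list()
  add <- function(i, order, dependence, curve_vals, curve_err) {
    sig <- if (all(is.na(curve_err))) NA_real_ else abs(curve_vals[i]) / curve_err[i]
    rec[[length(rec) + 1]] <<- data.frame(
      order = order, dependence = dependence, E_tr = E[i],
      beta_tr = beta[i], signal = curve_vals[i], significance = sig)
  }

  for (i in local_extrema(beta, "min", prom_min(beta, 1)))
    if (beta[i] > 0) add(i, 1L, "independent", beta, err$beta)
  if (max_order >= 2) {
    for (i in local_extrema(gamma, "max", prom_min(gamma, 2)))
      if (gamma[i] < 0) add(i, 2L, "independent", gamma, err$gamma)
    for (i in local_extrema(gamma, "min", prom_min(gamma, 2)))
      if (gamma[i] > 0) add(i, 2L, "dependent", gamma, err$gamma)
  }
  if (max_order >= 3) {
    for (i in local_extrema(delta, "min", prom_min(delta, 3)))
      if (delta[i] > 0) add(i, 3L, "independent", delta, err$delta)
    for (i in local_extrema(delta, "max", prom_min(delta, 3)))
      if (delta[i] < 0) add(i, 3L, "dependent", delta, err$delta)
  }

  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(order = integer(0), dependence = character(0),
               E_tr = numeric(0), beta_tr = numeric(0), signal = numeric(0),
               significance = numeric(0))

  # dependent transitions are admissible only as higher-energy precursors
  # of an independent partner of the next-lower order
  if (nrow(out)) {
    keep <- rep(TRUE, nrow(out))
    for (r in seq_len(nrow(out))) {
      if (out$dependence[r] != "dependent") next
      partner <- out$order == out$order[r] - 1L &
        out$dependence == "independent" & out$E_tr < out$E_tr[r]
      if (!any(partner)) keep[r] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$E_tr), , drop = FALSE]
    rownames(out) <- NULL
  }
  out$noisy <- !is.na(out$significance) & out$significance < noise_threshold
  class(out) <- c("transition_records", "data.frame")
  out
}

#' Transition table
#'
#' Formats transition records the way they are reported for the polymer
#' systems: one row per transition with the bending stiffness, transition
#' energy, distance from the putative ground-state energy
#' `delta_E = E_tr - E_min`, inverse microcanonical transition temperature
#' and classification.
#'
#' @param records a [find_transitions()] result.
#' @param e_min putative ground-state energy `E_min` (e.g. from sampling's
#'   best conformation).
#' @param kappa bending stiffness label for the table.
#' @export
transition_table <- function(records, e_min, kappa = NA_real_) {
  df <- as.data.frame(records)
  data.frame(kappa = rep(kappa, nrow(df)), E_tr = df$E_tr,
             delta_E = df$E_tr - e_min, beta_tr = df$beta_tr,
             order = df$order, dependence = df$dependence,
             significance = df$significance)
}

#' Microcanonical inflection-point analysis
#'
#' The top-level analysis fit: takes one density-of-states estimate (or a
#' list of per-run estimates, which are gauge-aligned and combined, with
#' cross-run errors propagated into all curves), computes the entropy and
#' its first three smoothed derivatives, and locates and classifies the
#' phase transitions.
#'
#' @param dos a [dos_estimate()] or a list of them (independent runs).
#' @param e_min putative ground-state energy; defaults to the lower edge of
#'   the support (used only for reduced energies in reports).
#' @param grid_size uniform evaluation grid size.
#' @param margin endpoint exclusion fraction for transition search.
#' @param control_thin Bezier control-point decimation (1 = all bins).
#' @param max_order highest transition order searched.
#' @param kB Boltzmann constant.
#' @return A `microcanonical_fit` with components `entropy`, `curves`,
#'   `transitions`, `e_min`, plus print/summary/plot methods.
#' @export
microcanonical <- function(dos, e_min = NULL, grid_size = 1000,
                           margin = 0.02, control_thin = 1, max_order = 3,
                           kB = 1) {
  replicates <- NULL
  if (is.list(dos) && !inherits(dos, "dos_estimate")) {
    stopifnot(all(vapply(dos, inherits, TRUE, "dos_estimate")))
    replicates <- lapply(dos, entropy_from_dos, kB = kB)
    if (length(replicates) < 2) replicates <- NULL
    dos <- combine_runs(dos)
  }
  entropy <- entropy_from_dos(dos, kB = kB)
  if (is.null(e_min)) e_min <- min(entropy$energies)
  curves <- derivative_curves(entropy, grid_size = grid_size,
                              replicates = replicates,
                              control_thin = control_thin)
  trans <- find_transitions(curves, max_order = max_order, margin = margin)
  structure(list(dos = dos, entropy = entropy, curves = curves,
                 transitions = trans, e_min = e_min),
            class = "microcanonical_fit")
}

#' @export
print.microcanonical_fit <- function(x, ...) {
  cat(sprintf("Microcanonical inflection-point analysis: E in [%.4g, %.4g], %d grid points\n",
              min(x$curves$energies), max(x$curves$energies),
              length(x$curves$energies)))
  if (x$curves$n_replicates >= 2)
    cat(sprintf("  errors from %d independent runs\n", x$curves$n_replicates))
  if (nrow(x$transitions) == 0) {
    cat("  no transitions found\n")
  } else {
    cat(sprintf("  %d transition(s):\n", nrow(x$transitions)))
    print(transition_table(x$transitions, x$e_min), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.microcanonical_fit <- function(object, kappa = NA_real_, ...) {
  transition_table(object$transitions, object$e_min, kappa = kappa)
}

#' @export
plot.microcanonical_fit <- function(x, ...) {
  cv <- x$curves
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  dE <- cv$energies - x$e_min
  graphics::plot(dE, cv$S, type = "l", xlab = expression(Delta * E),
                 ylab = "S")
  graphics::plot(dE, cv$beta, type = "l", xlab = expression(Delta * E),
                 ylab = expression(beta))
  if (nrow(x$transitions))
    graphics::points(x$transitions$E_tr - x$e_min, x$transitions$beta_tr,
                     pch = 19)
  graphics::plot(dE, cv$gamma, type = "l", xlab = expression(Delta * E),
                 ylab = expression(gamma))
  graphics::plot(dE, cv$delta, type = "l", xlab = expression(Delta * E),
                 ylab = expression(delta))
  invisible(x)
}
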