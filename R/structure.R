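# Geometric characterization of conformations: squared radius of gyration,
# pair distributions, contact maps and secondary-structure streaks.

#' Squared radius of gyration
#'
#' Mean squared distance of the monomers from their centroid (uniform
#' masses): `Rgyr^2 = (1/N) sum_i |r_i - r_cm|^2`.
#'
#' @param conf a [conformation()].
#' @export
radius_of_gyration_sq <- function(conf) {
  p <- unclass(conf)
  ctr <- colMeans(p)
  mean(rowSums(sweep(p, 2, ctr)^2))
}

#' Pair distribution of a conformation
#'
#' Counts every unordered monomer pair (bonded pairs included) into the
#' unique distance bin of half-width `r_t` containing it: bins are centered
#' on `r_t (2m + 1)` for non-negative integer `m`, a disjoint partition of
#' the positive axis into
#' cells of width `2 r_t`, so the total count is exactly `N (N - 1) / 2`.
#'
#' @param conf a [conformation()].
#' @param r_t bin half-width (binning threshold), default 0.01.
#' @return A `pair_distribution`: data frame with bin centers `r` and
#'   `count` (only nonzero bins), with the total pair count as an
#'   attribute.
#' @export
pair_distribution <- function(conf, r_t = 0.01) {
  d <- as.numeric(stats::dist(unclass(conf)))
  m <- floor(d / (2 * r_t))
  tab <- table(m)
  out <- data.frame(r = (2 * as.numeric(names(tab)) + 1) * r_t,
                    count = as.integer(tab))
  attr(out, "n_pairs") <- length(d)
  attr(out, "r_t") <- r_t
  class(out) <- c("pair_distribution", "data.frame")
  out
}

#' Contact map of a conformation
#'
#' Non-bonded monomer pairs `(i, j)` with `j > i + 1` and distance strictly
#' below the cutoff (default 1.2). Bonded pairs are never included; pairs
#' are stored once with `j > i` (1-based indices).
#'
#' @param conf a [conformation()].
#' @param cutoff contact distance cutoff (strict inequality).
#' @return A `contact_map`: two-column integer matrix of pairs, with the
#'   chain length and cutoff as attributes.
#' @export
contact_map <- function(conf, cutoff = 1.2) {
  p <- unclass(conf)
  n <- nrow(p)
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (n >= 3) {
    d <- as.matrix(stats::dist(p))
    idx <- which(upper.tri(d) & row(d) + 1 < col(d) & d < cutoff, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    }
  }
  structure(pairs, class = c("contact_map", class(pairs)),
            n_monomers = n, cutoff = cutoff)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d contacts among %d monomers (cutoff %g)\n",
              nrow(x), attr(x, "n_monomers"), attr(x, "cutoff")))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  n <- attr(x, "n_monomers")
  graphics::plot(NA, xlim = c(1, n), ylim = c(1, n), xlab = "i", ylab = "j",
                 asp = 1, ...)
  if (nrow(x)) {
    graphics::points(x[, 1], x[, 2], pch = 15, cex = 0.6)
    graphics::points(x[, 2], x[, 1], pch = 15, cex = 0.6)
  }
  invisible(x)
}

# maximal runs of consecutive values within each group
runs_in_group <- function(i_sorted) {
  breaks <- c(0, which(diff(i_sorted) != 1), length(i_sorted))
  lengths <- diff(breaks)
  starts <- i_sorted[breaks[-length(breaks)] + 1]
  data.frame(start_i = starts, length = lengths)
}

#' Secondary-structure streaks in a contact map
#'
#' Maximal runs of contacts with constant `i + j` (anti-diagonal streaks,
#' the hairpin signature of two linear strands in contact around a turn)
#' and with constant `j - i` (diagonal streaks, associated with helix-like
#' alignments). Runs shorter than `min_length` (default 2) are dropped.
#'
#' @param map a [contact_map()].
#' @param min_length minimum reported run length.
#' @return Data frame with columns `type` (`"antidiagonal"`/`"diagonal"`),
#'   `key` (the constant `i + j` or `j - i`), `start_i` and `length`.
#' @export
secondary_structure_streaks <- function(map, min_length = 2) {
  empty <- data.frame(type = character(0), key = integer(0),
                      start_i = integer(0), length = integer(0))
  if (nrow(map) == 0) return(empty)
  res <- list(empty)
  for (typ in c("antidiagonal", "diagonal")) {
    key <- if (typ == "antidiagonal") map[, 1] + map[, 2] else map[, 2] - map[, 1]
    for (k in sort(unique(key))) {
      is <- sort(map[key == k, 1])
      r <- runs_in_group(is)
      r <- r[r$length >= min_length, , drop = FALSE]
      if (nrow(r))
        res[[length(res) + 1]] <- data.frame(type = typ, key = k,
                                             start_i = r$start_i,
                                             length = r$length)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
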