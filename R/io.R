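# Persistence: JSON run containers, plain-text tabular exports, and
# conformation export in XYZ and minimal PDB for visualization.

#' Save a parallel-tempering run
#'
#' Writes the run to a single structured JSON container with the layout
#' `ladder`, `histograms`, `timeseries`, `minimum`, `diagnostics`, `meta`
#' (config echo, seed, package version). Numbers are written at full
#' precision.
#'
#' @param run a `pt_run` from [run_parallel_tempering()].
#' @param path output file path.
#' @export
save_run <- function(run, path) {
  stopifnot(inherits(run, "pt_run"))
  hs <- run$histograms
  obj <- list(
    ladder = run$ladder$temperatures,
    histograms = list(bin_centers = hs$bin_centers, counts = hs$counts,
                      totals = hs$totals),
    timeseries = list(E = hs$timeseries$E, rg2 = hs$timeseries$rg2,
                      stride = hs$stride),
    minimum = list(energy = run$global_min_energy,
                   conformation = unclass(run$global_min_conformation),
                   per_thread_energy = run$min_energy),
    diagnostics = run$diagnostics[c("acc_displacement", "acc_pivot",
                                    "acc_exchange", "rd",
                                    "replica_min_thread", "replica_max_thread")],
    meta = list(
      n_monomers = run$params$n_monomers, kappa = run$params$kappa,
      theta0 = run$params$theta0, epsilon_lj = run$params$epsilon_lj,
      r0 = run$params$r0, kB = run$params$kB,
      schedule = unclass(run$schedule), seed = run$seed,
      package_version = as.character(utils::packageVersion("semiflex"))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a saved run
#'
#' Restores the parts of a JSON run container needed for analysis: the
#' histogram set (with time series), the minimum-energy conformation and
#' the metadata.
#'
#' @param path file written by [save_run()].
#' @export
read_run <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- NULL
  if (!is.null(obj$timeseries$E) && length(obj$timeseries$E))
    ts <- list(E = as.matrix(obj$timeseries$E),
               rg2 = as.matrix(obj$timeseries$rg2))
  hs <- histogram_set(obj$histograms$bin_centers,
                      as.matrix(obj$histograms$counts),
                      obj$ladder, timeseries = ts,
                      stride = obj$timeseries$stride)
  list(histograms = hs,
       global_min_energy = obj$minimum$energy,
       global_min_conformation = conformation(as.matrix(obj$minimum$conformation)),
       min_energy = obj$minimum$per_thread_energy,
       diagnostics = obj$diagnostics,
       meta = obj$meta)
}

#' Tabular export of energy histograms
#'
#' One row per (bin, thread) with nonzero count; columns
#' `E_bin_center`, `thread`, `temperature`, `count`.
#'
#' @param histograms a [histogram_set()].
#' @param path output TSV path (or `NULL` to return the data frame).
#' @export
write_histograms <- function(histograms, path = NULL) {
  idx <- which(histograms$counts > 0, arr.ind = TRUE)
  df <- data.frame(E_bin_center = histograms$bin_centers[idx[, 1]],
                   thread = idx[, 2],
                   temperature = histograms$temperatures[idx[, 2]],
                   count = histograms$counts[idx])
  df <- df[order(df$thread, df$E_bin_center), ]
  rownames(df) <- NULL
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabular density-of-states export / import
#'
#' Columns `E_bin_center`, `ln_g`, `stderr`, `support_flag`.
#'
#' @param dos a [dos_estimate()].
#' @param path output TSV path.
#' @export
write_dos <- function(dos, path) {
  utils::write.table(as.data.frame(dos), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dos
#' @export
read_dos <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  dos_estimate(df$E_bin_center, ifelse(df$support_flag, df$ln_g, NA_real_),
               df$stderr)
}

#' XYZ export of conformations
#'
#' One frame per conformation, element tag `C`, comment line carrying the
#' energy and bending stiffness.
#'
#' @param confs a [conformation()] or list of them.
#' @param path output path.
#' @param params optional [model_params()] (for the comment line).
#' @param energies optional energies (one per frame).
#' @export
write_xyz <- function(confs, path, params = NULL, energies = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(confs)) {
    p <- unclass(confs[[f]])
    e <- if (!is.null(energies)) sprintf("E = %.6f", energies[f]) else ""
    k <- if (!is.null(params)) sprintf(" kappa = %g", params$kappa) else ""
    writeLines(as.character(nrow(p)), con)
    writeLines(trimws(paste0(e, k)), con)
    writeLines(sprintf("C %12.6f %12.6f %12.6f", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Minimal PDB export of a conformation
#'
#' HETATM records (element C) with CONECT records along the backbone, for
#' quick visualization of bead-spring conformations.
#'
#' @param conf a [conformation()].
#' @param path output path.
#' @export
write_pdb <- function(conf, path) {
  p <- unclass(conf)
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "HETATM%5d  C   MON A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), p[, 1], p[, 2], p[, 3]), con)
  if (n >= 2)
    writeLines(sprintf("CONECT%5d%5d", seq_len(n - 1), 2:n), con)
  writeLines("END", con)
  invisible(path)
}

#' Tabular export of microcanonical curves
#'
#' Columns `E`, `S`, `beta`, `gamma`, `delta` and their errors.
#'
#' @param curves a [derivative_curves()] object.
#' @param path output TSV path.
#' @export
write_curves <- function(curves, path) {
  utils::write.table(as.data.frame(curves), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Tabular export of a transition table
#'
#' @param tab a [transition_table()] data frame.
#' @param path output TSV path.
#' @export
write_transition_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
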