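#' Configuration for an end-to-end scheme run
#'
#' Three schemes are supported. \code{scheme0}: the complex trajectory is
#' analysed directly (frames from the 3-4 ns window by default).
#' \code{mnm1}/\code{mnm2}: unbound-chain ensembles are clustered (over
#' 0-12 ns for mnm1, 80-100 ns for mnm2), the representative conformers are
#' assembled into a Mix-and-Match complex, and -- after the user's own
#' production simulation of that complex, an explicit external step -- the
#' resulting complex trajectory is analysed over 40-50 ns.
#'
#' @param scheme "scheme0", "mnm1" or "mnm2".
#' @param clustering_window,analysis_window time windows, ps (half-open).
#' @param n_frames frames for the end-point average.
#' @param rmsd_cutoff GROMOS C-alpha cutoff, Angstrom.
#' @param n_waters interfacial waters retained in the receptor (0 = none).
#' @param interface_threshold Delta-SASA threshold, A^2.
#' @param ligand_chain ligand chain label.
#' @param gb a \code{\link{gb_params}}.
#' @param gamma,b surface-area model constants.
#' @param seed RNG seed recorded in the manifest.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(scheme = c("scheme0", "mnm1", "mnm2"),
                       clustering_window = NULL, analysis_window = NULL,
                       n_frames = 100, rmsd_cutoff = 1.0, n_waters = 30,
                       interface_threshold = 0.50, ligand_chain = "B",
                       gb = gb_params(), gamma = 0.0072, b = 0, seed = 1) {
  scheme <- match.arg(scheme)
  if (is.null(clustering_window))
    clustering_window <- switch(scheme, scheme0 = NULL,
                                mnm1 = c(0, 12000), mnm2 = c(80000, 100000))
  if (is.null(analysis_window))
    analysis_window <- switch(scheme, scheme0 = c(3000, 4000),
                              c(40000, 50000))
  stopifnot(n_frames >= 1, diff(analysis_window) > 0)
  structure(list(scheme = scheme, clustering_window = clustering_window,
                 analysis_window = analysis_window, n_frames = n_frames,
                 rmsd_cutoff = rmsd_cutoff, n_waters = n_waters,
                 interface_threshold = interface_threshold,
                 ligand_chain = ligand_chain, gb = gb, gamma = gamma, b = b,
                 seed = seed),
            class = "run_config")
}

#' Run one scheme end-to-end on prepared inputs
#'
#' Executes the post-simulation stages: (MnM schemes) cluster each unbound
#' chain, pick representatives, assemble and write the Mix-and-Match
#' complex with a clash report; then select evenly spaced frames from the
#' complex trajectory, detect the interface, retain the closest waters per
#' frame (when the trajectory contains explicit water and
#' \code{n_waters > 0}), run MM-GBSA and the pairwise decomposition. Every
#' stage writes a delimited artifact plus a manifest with parameters and
#' checksums, so a rerun with the same inputs and config is bit-identical.
#'
#' The production simulation of an assembled MnM complex is an external
#' hand-off: this function never simulates; for MnM schemes the supplied
#' \code{complex_traj} must already be the post-assembly trajectory.
#'
#' @param config a \code{\link{run_config}}.
#' @param complex_traj \code{\link{trajectory}} of the complex.
#' @param outdir output directory (created if needed).
#' @param crystal optional list(topology, frame) of the crystal complex
#'   (required for MnM schemes).
#' @param chain_trajs optional list(A =, B =) of unbound-chain trajectories
#'   (required for MnM schemes).
#' @return list of class \code{run_report}: mmgbsa fit, decomposition,
#'   interface, retained waters, representative frames, file paths.
#' @export
run_scheme <- function(config, complex_traj, outdir, crystal = NULL,
                       chain_trajs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name); paths[[name]] <<- p; p
  }
  reps <- NULL; mnm <- NULL
  if (config$scheme != "scheme0") {
    if (is.null(crystal) || is.null(chain_trajs))
      stop("MnM schemes need `crystal` and `chain_trajs` inputs")
    reps <- list()
    for (ch in c("A", "B")) {
      traj <- chain_trajs[[ch]]
      if (is.null(traj)) stop("missing unbound trajectory for chain ", ch)
      win <- which(frame_times(traj) >= config$clustering_window[1] &
                   frame_times(traj) < config$clustering_window[2])
      sub <- trajectory(traj$topology, traj$frames[win])
      cl <- gromos_cluster(rmsd_matrix(sub, "calpha"), config$rmsd_cutoff)
      write_cluster_report(cl, emit(sprintf("cluster_chain%s.tsv", ch)))
      rep_local <- select_representative(cl)
      reps[[ch]] <- list(frame_index = win[rep_local],
                         time_ps = frame_times(traj)[win[rep_local]],
                         xyz = sub$frames[[rep_local]]$xyz)
    }
    mnm <- build_mnm_complex(crystal$topology, crystal$frame,
                             reps$A$xyz, reps$B$xyz,
                             provenance = list(scheme = config$scheme,
                                               chainA_ps = reps$A$time_ps,
                                               chainB_ps = reps$B$time_ps))
    write_pdb(crystal$topology, mnm$frame, emit("mnm_complex.pdb"))
    cr <- clash_report(mnm$frame, crystal$topology)
    utils::write.table(cr$pairs, emit("clash_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  frames <- select_evenly_spaced_frames(complex_traj,
                                        config$analysis_window[1],
                                        config$analysis_window[2],
                                        config$n_frames)
  utils::write.table(data.frame(frame = frames,
                                time_ps = frame_times(complex_traj)[frames]),
                     emit("frames.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  top <- complex_traj$topology
  iface <- find_interface_residues(complex_traj$frames[[frames[1]]], top,
                                   threshold = config$interface_threshold)
  write_interface_report(iface, emit("interface.tsv"))
  waters <- NULL
  if (config$n_waters > 0 && any(is_water(top))) {
    waters <- lapply(seq_along(complex_traj), function(fi) {
      fr <- complex_traj$frames[[fi]]
      com <- interface_com(fr, top, iface)
      select_closest_waters(fr, top, com, n = config$n_waters)
    })
    wtab <- do.call(rbind, lapply(frames, function(fi)
      data.frame(frame = fi,
                 water_residue = waters[[fi]]$water_residues,
                 distance = waters[[fi]]$distances)))
    utils::write.table(wtab, emit("retained_waters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  part <- partition_system(top, ligand_chain = config$ligand_chain,
                           retained_waters = waters)
  fit <- mmgbsa(complex_traj, part, frames, params = config$gb,
                gamma = config$gamma, b = config$b)
  write_mmgbsa_report(fit, emit("mmgbsa.tsv"))
  dec <- pairwise_decomposition(complex_traj, part, frames,
                                params = config$gb)
  write_decomposition(dec, emit("decomposition.tsv"))
  manifest <- data.frame(
    file = names(paths),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE)
  scalar <- c("scheme", "clustering_window", "analysis_window", "n_frames",
              "rmsd_cutoff", "n_waters", "interface_threshold",
              "ligand_chain", "seed")
  cfgline <- paste(scalar,
                   vapply(unclass(config)[scalar], function(v)
                     paste(format(v), collapse = ","), ""),
                   sep = "=", collapse = "; ")
  writeLines(c(paste("#", cfgline),
               paste(manifest$file, manifest$md5, sep = "\t")),
             file.path(outdir, "manifest.tsv"))
  structure(list(mmgbsa = fit, decomposition = dec, interface = iface,
                 waters = waters, representatives = reps, mnm = mnm,
                 frames = frames, paths = paths, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Scheme run (", x$config$scheme, "): ", length(x$frames),
      " frames analysed\n", sep = "")
  print(x$mmgbsa)
  invisible(x)
}
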