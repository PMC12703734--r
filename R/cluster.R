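#' GROMOS (Daura) RMSD clustering
#'
#' Iterative neighbor-count clustering: among unassigned frames, the frame
#' with the most neighbors within \code{cutoff} becomes a cluster center;
#' it and its neighbors form a cluster and are removed; repeat until no
#' frame remains. Ties on neighbor count are broken by the lowest frame
#' index, making the procedure deterministic.
#'
#' @param mat an \code{\link{rmsd_matrix}} (or a plain symmetric matrix).
#' @param cutoff RMSD cutoff, Angstrom (1.0 for C-alpha clustering of
#'   unbound-chain ensembles).
#' @return object of class \code{cluster_set}: list of clusters (each with
#'   \code{members}, \code{center}, \code{size}), ordered by non-increasing
#'   size (ties by formation order), plus the cutoff.
#' @export
gromos_cluster <- function(mat, cutoff) {
  v <- if (inherits(mat, "rmsd_matrix")) mat$values else as.matrix(mat)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-6)
    stop("RMSD matrix must be symmetric")
  n <- nrow(v)
  neigh <- v < cutoff        # includes self; constant offset, harmless
  remaining <- rep(TRUE, n)
  clusters <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- rowSums(neigh[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]           # which.max = lowest index tie-break
    members <- idx[neigh[center, idx]]
    clusters[[length(clusters) + 1L]] <-
      list(members = members, center = center, size = length(members))
    remaining[members] <- FALSE
  }
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  ord <- order(-sizes)                          # stable: keeps formation order on ties
  structure(list(clusters = clusters[ord], cutoff = cutoff, n = n),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("GROMOS clustering:", length(x$clusters), "cluster(s) of", x$n,
      "frames at cutoff", x$cutoff, "A\n")
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("  #%d size %d center frame %d\n", k, cl$size, cl$center))
  }
  invisible(x)
}

#' Representative frame of a clustered ensemble
#'
#' The center of the most populated cluster (first in the ordered list);
#' equal-size clusters resolve to the one formed first.
#'
#' @param clusters a \code{cluster_set}.
#' @return a frame index.
#' @export
select_representative <- function(clusters) {
  if (!length(clusters$clusters)) stop("empty cluster set")
  clusters$clusters[[1L]]$center
}

#' Write a cluster report as delimited text
#' @param clusters a \code{cluster_set}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- do.call(rbind, lapply(seq_along(clusters$clusters), function(k) {
    cl <- clusters$clusters[[k]]
    data.frame(cluster = k, size = cl$size, center = cl$center,
               members = paste(cl$members, collapse = ","))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-residue side-chain RMSF
#'
#' Root-mean-square fluctuation of side-chain heavy atoms about their
#' time-average positions (mass-unweighted), averaged over each residue's
#' side-chain atoms. Glycine-like residues without side-chain heavy atoms
#' fall back to the C-alpha atom and are flagged.
#'
#' @param traj a \code{\link{trajectory}}; frames are C-alpha-superposed
#'   onto the first frame before the fluctuation computation unless
#'   \code{align = FALSE} (for pre-aligned input).
#' @param residues residue indices to report (default: all protein residues).
#' @param reference \code{"mean"} (fluctuation about the time-mean
#'   structure, the standard definition) or \code{"first"} (about frame 1).
#' @param align superpose frames onto frame 1 over C-alpha first.
#' @return data.frame(residue_index, chain_id, rmsf, calpha_fallback).
#' @export
sidechain_rmsf <- function(traj, residues = NULL,
                           reference = c("mean", "first"), align = TRUE) {
  reference <- match.arg(reference)
  top <- traj$topology
  at <- top$atoms
  prot <- !is_water(top) & !is_ion(top)
  if (is.null(residues)) residues <- sort(unique(at$residue_index[prot]))
  frames <- lapply(traj$frames, `[[`, "xyz")
  if (align) {
    ca <- atom_selection(top, "calpha")
    frames <- lapply(frames, function(x)
      apply_superposition(x, kabsch_superpose(x, frames[[1L]], ca)))
  }
  arr <- simplify2array(frames)                 # N x 3 x T
  mean_xyz <- apply(arr, c(1, 2), mean)
  ref_xyz <- if (reference == "mean") mean_xyz else frames[[1L]]
  dev2 <- apply(arr, 3, function(x) rowSums((x - ref_xyz)^2))  # N x T
  atom_rmsf <- sqrt(rowMeans(as.matrix(dev2)))
  bb <- c("N", "CA", "C", "O", "OXT")
  heavy <- toupper(substr(at$element, 1, 1)) != "H"
  out <- lapply(residues, function(r) {
    in_res <- at$residue_index == r & prot
    sc <- which(in_res & heavy & !(at$name %in% bb))
    fallback <- length(sc) == 0L
    if (fallback) sc <- which(in_res & at$name == "CA")
    if (!length(sc)) return(NULL)
    data.frame(residue_index = r, chain_id = at$chain_id[sc[1L]],
               rmsf = mean(atom_rmsf[sc]), calpha_fallback = fallback)
  })
  do.call(rbind, out)
}

#' Write a per-residue RMSF profile as two-column text
#' @param rmsf data.frame from \code{\link{sidechain_rmsf}}.
#' @param path output path.
#' @export
write_rmsf <- function(rmsf, path) {
  utils::write.table(rmsf[, c("residue_index", "rmsf")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
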