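#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of \code{mobile} onto \code{reference} over a common
#' atom selection. The rotation is forced proper (determinant +1), so
#' reflections are never returned. Fits are mass-unweighted.
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param selection atom indices used for the fit (defaults to all rows);
#'   must resolve to at least 3 non-collinear points.
#' @return list of class \code{superposition}: \code{rotation} (3 x 3,
#'   applied on the right of centred row vectors), \code{translation}
#'   (length-3), \code{rmsd} (Angstrom over the selection) and
#'   \code{selection}. Apply with \code{\link{apply_superposition}}.
#' @export
kabsch_superpose <- function(mobile, reference,
                             selection = seq_len(nrow(mobile))) {
  selection <- as.integer(selection)
  if (!length(selection)) stop("empty fit selection")
  if (length(selection) < 3L)
    stop("need at least 3 points for a unique rotation")
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference))
    stop("selection exceeds coordinate-set length")
  x <- mobile[selection, , drop = FALSE]
  y <- reference[selection, , drop = FALSE]
  if (nrow(x) != nrow(y)) stop("selection length mismatch")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))          # 3x3 covariance
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("degenerate (collinear) fit selection")
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- xc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  structure(list(rotation = R, translation = cy, center = cx, rmsd = rmsd,
                 selection = selection), class = "superposition")
}

#' Apply a superposition to a full coordinate set
#' @param xyz N x 3 matrix.
#' @param sp result of \code{\link{kabsch_superpose}}.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(sweep(xyz, 2, sp$center) %*% sp$rotation, 2, sp$translation, "+")
}

#' Pairwise minimized-RMSD matrix over a trajectory
#'
#' Entry (i, j) is the RMSD after optimal pairwise superposition of frame i
#' onto frame j over the selection (the metric used by GROMOS clustering).
#'
#' @param traj a \code{\link{trajectory}} with at least 2 frames.
#' @param selection \code{"calpha"} (default), \code{"backbone"} or an
#'   integer atom-index vector.
#' @return object of class \code{rmsd_matrix}: list(n, values, selection).
#' @export
rmsd_matrix <- function(traj, selection = "calpha") {
  idx <- atom_selection(traj$topology, selection)
  if (length(idx) < 3L) stop("selection resolves to fewer than 3 atoms")
  n <- length(traj)
  if (n < 2L) stop("need at least 2 frames")
  coords <- lapply(traj$frames, function(f) f$xyz[idx, , drop = FALSE])
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    v[i, j] <- r; v[j, i] <- r
  }
  structure(list(n = n, values = v,
                 selection = if (is.character(selection)) selection
                             else "custom"),
            class = "rmsd_matrix")
}

#' Evenly spaced frame selection within a time window
#'
#' The window is half-open in time, \code{[t_start, t_end)}; within it,
#' \code{n} frame indices are taken at uniform index stride with the first
#' and last window frames always included.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param t_start,t_end window bounds, ps.
#' @param n number of frames to select.
#' @return increasing integer frame indices (into the trajectory), length n.
#' @export
select_evenly_spaced_frames <- function(traj, t_start, t_end, n) {
  tm <- frame_times(traj)
  win <- which(tm >= t_start & tm < t_end)
  m <- length(win)
  if (m < n)
    stop("window [", t_start, ", ", t_end, ") contains ", m,
         " frames; ", n, " requested")
  if (n == 1L) return(win[1L])
  # floor((k-1)(m-1)/(n-1)) is strictly increasing when m >= n
  win[floor((seq_len(n) - 1) * (m - 1) / (n - 1)) + 1L]
}
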