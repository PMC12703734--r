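#' Molecular topology and coordinate containers
#'
#' A \code{topology} is a light-weight list describing atoms, bonded
#' force-field terms, exclusions and molecule segmentation. Coordinates are
#' carried separately as \code{frame} objects (N x 3 matrices in Angstrom)
#' grouped into a \code{trajectory}. Partial charges are stored in elementary
#' charge units; the Amber 18.2223 conversion is applied only at
#' parameter-topology I/O. All indices are 1-based.
#'
#' @param atoms data.frame with one row per atom and columns \code{serial},
#'   \code{name}, \code{element}, \code{residue_index}, \code{residue_name},
#'   \code{chain_id}, and optionally \code{charge} (e), \code{mass} (amu),
#'   \code{lj_rmin_half} (Angstrom), \code{lj_epsilon} (kcal/mol),
#'   \code{gb_radius} (Angstrom, mbondi3 convention), \code{gb_screen}
#'   (dimensionless).
#' @param bonds data.frame(i, j, k, r0): harmonic bonds, k in kcal/mol/A^2.
#' @param angles data.frame(i, j, k, ktheta, theta0): theta0 in radians.
#' @param dihedrals data.frame(i, j, k, l, pk, periodicity, phase): Amber
#'   convention E = pk * (1 + cos(periodicity*phi - phase)), phase in radians.
#' @param water_names residue names recognised as water.
#' @param ion_names residue names recognised as monoatomic ions.
#' @return object of class \code{topology}.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, dihedrals = NULL,
                     water_names = c("WAT", "HOH", "TIP3", "SOL"),
                     ion_names = c("NA+", "CL-", "NA", "CL", "K+", "K")) {
  need <- c("serial", "name", "element", "residue_index", "residue_name",
            "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty atom table")
  if (any(diff(atoms$serial) <= 0))
    stop("atom serial numbers must be strictly increasing")
  opt <- c(charge = NA_real_, mass = NA_real_, lj_rmin_half = NA_real_,
           lj_epsilon = NA_real_, gb_radius = NA_real_, gb_screen = NA_real_)
  for (cn in names(opt)) if (is.null(atoms[[cn]])) atoms[[cn]] <- opt[[cn]]
  rownames(atoms) <- NULL
  top <- structure(
    list(atoms = atoms,
         bonds = empty_if_null(bonds, c("i", "j", "k", "r0")),
         angles = empty_if_null(angles, c("i", "j", "k", "ktheta", "theta0")),
         dihedrals = empty_if_null(dihedrals,
                                   c("i", "j", "k", "l", "pk", "periodicity",
                                     "phase")),
         water_names = water_names, ion_names = ion_names),
    class = "topology")
  check_bonded_indices(top)
  top$molecules <- molecule_ranges(top)
  top$exclusions <- derive_exclusions(top)
  top
}

empty_if_null <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols)))
    names(x) <- cols
  }
  rownames(x) <- NULL
  x
}

check_bonded_indices <- function(top) {
  n <- n_atoms(top)
  idx <- c(top$bonds$i, top$bonds$j, top$angles$i, top$angles$j, top$angles$k,
           top$dihedrals$i, top$dihedrals$j, top$dihedrals$k, top$dihedrals$l)
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    stop("bonded term references atom outside topology (n = ", n, ")")
  invisible(top)
}

#' @export
n_atoms <- function(top) nrow(top$atoms)

#' @rdname topology
#' @param top a \code{topology}.
#' @export
is_water <- function(top) top$atoms$residue_name %in% top$water_names

#' @rdname topology
#' @export
is_ion <- function(top) top$atoms$residue_name %in% top$ion_names

#' Contiguous molecule segmentation
#'
#' Labels every atom range as \code{chainA}/\code{chainB}/... for protein
#' chains (by \code{chain_id}), \code{water} or \code{ion}. Ranges partition
#' the atom list; water molecules are checked for the 3-site convention.
#'
#' @param top a \code{topology}.
#' @return data.frame(label, start, end) of contiguous atom ranges.
#' @export
molecule_ranges <- function(top) {
  at <- top$atoms
  kind <- ifelse(is_water(top), "water",
                 ifelse(is_ion(top), "ion",
                        paste0("chain", at$chain_id)))
  r <- rle(kind)
  end <- cumsum(r$lengths)
  out <- data.frame(label = r$values,
                    start = c(1L, head(end, -1L) + 1L),
                    end = end, stringsAsFactors = FALSE)
  wat <- out$label == "water"
  if (any(wat)) {
    for (k in which(wat)) {
      res <- at$residue_index[out$start[k]:out$end[k]]
      if (any(table(res) != 3L))
        warning("water residue(s) without exactly 3 atoms (expected 3-site model)")
    }
  }
  out
}

#' Atom indices of a labelled molecule range
#' @param top a \code{topology}.
#' @param label molecule label, e.g. \code{"chainA"}, \code{"water"}.
#' @return integer vector of atom indices (possibly empty).
#' @export
molecule_atoms <- function(top, label) {
  m <- top$molecules[top$molecules$label == label, , drop = FALSE]
  if (nrow(m) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(m)), function(k) m$start[k]:m$end[k]),
         use.names = FALSE)
}

# 1-2/1-3 excluded and 1-4 scaled pairs, derived from the bonded terms
# (Amber convention: bonds -> 1-2, angles -> 1-3, dihedral end atoms -> 1-4
# unless already excluded as 1-2/1-3).
derive_exclusions <- function(top) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  p12 <- cbind(top$bonds$i, top$bonds$j)
  p13 <- cbind(top$angles$i, top$angles$k)
  ex <- rbind(p12, p13)
  ex_key <- unique(key(ex[, 1], ex[, 2]))
  dh <- top$dihedrals
  # multi-term/improper dihedrals can be flagged to not generate 1-4 pairs
  if (!is.null(dh$gen14)) dh <- dh[dh$gen14, , drop = FALSE]
  p14 <- cbind(dh$i, dh$l)
  if (nrow(p14)) {
    keep <- !(key(p14[, 1], p14[, 2]) %in% ex_key) & p14[, 1] != p14[, 2]
    p14 <- p14[keep, , drop = FALSE]
    p14 <- p14[!duplicated(key(p14[, 1], p14[, 2])), , drop = FALSE]
  }
  list(excluded = unique_pairs(rbind(p12, p13)), scaled14 = unique_pairs(p14))
}

unique_pairs <- function(m) {
  if (is.null(m) || nrow(m) == 0L)
    return(matrix(integer(0), ncol = 2L))
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
}

#' Restrict a topology to an atom subset
#'
#' Keeps atoms in \code{keep} (index vector, original order preserved) and all
#' bonded terms fully inside the subset; exclusions are re-derived.
#'
#' @param top a \code{topology}.
#' @param keep integer atom indices to retain.
#' @return a \code{topology} over the subset, with attribute
#'   \code{"orig_index"} mapping new to old indices.
#' @export
subset_topology <- function(top, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(n_atoms(top)); map[keep] <- seq_along(keep)
  inside <- function(...) {
    cols <- list(...)
    ok <- rep(TRUE, length(cols[[1]]))
    for (v in cols) ok <- ok & v %in% keep
    ok
  }
  b <- top$bonds[inside(top$bonds$i, top$bonds$j), , drop = FALSE]
  a <- top$angles[inside(top$angles$i, top$angles$j, top$angles$k), ,
                  drop = FALSE]
  d <- top$dihedrals[inside(top$dihedrals$i, top$dihedrals$j,
                            top$dihedrals$k, top$dihedrals$l), , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  a$i <- map[a$i]; a$j <- map[a$j]; a$k <- map[a$k]
  d$i <- map[d$i]; d$j <- map[d$j]; d$k <- map[d$k]; d$l <- map[d$l]
  at <- top$atoms[keep, , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  out <- topology(at, b, a, d, water_names = top$water_names,
                  ion_names = top$ion_names)
  attr(out, "orig_index") <- keep
  out
}

#' @export
print.topology <- function(x, ...) {
  m <- x$molecules
  cat("Molecular topology:", n_atoms(x), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_index))),
      "residues\n")
  cat("  segments:",
      paste(sprintf("%s[%d-%d]", m$label, m$start, m$end), collapse = " "),
      "\n")
  cat("  bonded terms:", nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals\n")
  invisible(x)
}

#' Construct a single coordinate frame
#' @param xyz N x 3 numeric matrix, Angstrom.
#' @param time_ps time stamp, picoseconds.
#' @param box optional length-6 vector (3 lengths, 3 angles).
#' @return object of class \code{frame}.
#' @export
frame <- function(xyz, time_ps = 0, box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("coordinates must be an N x 3 matrix")
  if (!all(is.finite(xyz))) stop("non-finite coordinate")
  structure(list(xyz = xyz, time_ps = time_ps, box = box), class = "frame")
}

#' Construct a trajectory
#' @param top a \code{topology} (all frames must match its atom count).
#' @param frames list of \code{frame} objects with non-decreasing time stamps.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(top, frames) {
  n <- n_atoms(top)
  for (f in frames)
    if (nrow(f$xyz) != n)
      stop("frame has ", nrow(f$xyz), " atoms; topology has ", n)
  tm <- vapply(frames, function(f) f$time_ps, numeric(1))
  if (is.unsorted(tm)) stop("frame time stamps must be non-decreasing")
  structure(list(topology = top, frames = frames), class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
print.trajectory <- function(x, ...) {
  tm <- frame_times(x)
  cat("Trajectory:", length(x), "frames,", n_atoms(x$topology), "atoms")
  if (length(tm)) cat(sprintf(", t = %g..%g ps", min(tm), max(tm)))
  cat("\n")
  invisible(x)
}

#' @export
frame_times <- function(traj)
  vapply(traj$frames, function(f) f$time_ps, numeric(1))

#' Resolve a named atom selection to indices
#'
#' @param top a \code{topology}.
#' @param selection \code{"calpha"}, \code{"backbone"} (N, CA, C, O of
#'   non-water, non-ion residues), \code{"heavy"} or an integer vector.
#' @return integer atom indices.
#' @export
atom_selection <- function(top, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  at <- top$atoms
  prot <- !is_water(top) & !is_ion(top)
  idx <- switch(match.arg(selection, c("calpha", "backbone", "heavy", "all")),
    calpha = which(prot & at$name == "CA"),
    backbone = which(prot & at$name %in% c("N", "CA", "C", "O")),
    heavy = which(toupper(substr(at$element, 1, 1)) != "H"),
    all = seq_len(nrow(at)))
  if (!length(idx)) stop("selection '", selection, "' matches no atoms")
  idx
}
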