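# Amber parameter-topology and ASCII-coordinate I/O.
#
# Section reading of the %VERSION/%FLAG/%FORMAT layout is delegated to
# bio3d::read.prmtop; this file owns unit conversion (charges / 18.2223),
# Lennard-Jones A/B -> (rmin/2, epsilon) per atom, bonded-term unpacking,
# chain segmentation and exclusion reconstruction.

AMBER_CHARGE_CONV <- 18.2223

# mandatory %FLAG sections for the energetics pipeline
.prmtop_mandatory <- c("POINTERS", "ATOM_NAME", "CHARGE", "MASS",
                       "ATOM_TYPE_INDEX", "NONBONDED_PARM_INDEX",
                       "LENNARD_JONES_ACOEF", "LENNARD_JONES_BCOEF",
                       "RESIDUE_LABEL", "RESIDUE_POINTER", "RADII", "SCREEN")

#' Read an Amber parameter-topology file
#'
#' Populates a full \code{\link{topology}}: charges converted from the
#' internal Amber representation (stored value / 18.2223) to elementary
#' charges, per-atom Lennard-Jones \code{rmin/2} and \code{epsilon} recovered
#' from the diagonal A/B coefficients, bonds/angles/dihedrals unpacked with
#' their force constants, intrinsic Born radii and screening factors read
#' from RADII/SCREEN, and 1-2/1-3/1-4 exclusions reconstructed from the
#' bonded terms. Only the sections required for MM-GBSA are interpreted;
#' others are ignored.
#'
#' Chains: if ATOMS_PER_MOLECULE is present, consecutive non-water, non-ion
#' molecules become chains A, B, ...; otherwise contiguous runs of protein
#' residues separated by water/ion blocks are used.
#'
#' @param path prmtop file path.
#' @param water_names,ion_names residue-name sets for solvent and counterions.
#' @return a \code{\link{topology}}.
#' @export
read_prmtop <- function(path, water_names = c("WAT", "HOH", "TIP3", "SOL"),
                        ion_names = c("NA+", "CL-", "NA", "CL", "K+", "K")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- bio3d::read.prmtop(path)
  miss <- setdiff(.prmtop_mandatory, names(raw))
  if (length(miss))
    stop("prmtop is missing mandatory section(s): ",
         paste(miss, collapse = ", "))
  p <- raw$POINTERS
  natom <- p[1]; ntypes <- p[2]
  for (s in c("CHARGE", "MASS", "ATOM_TYPE_INDEX", "RADII", "SCREEN"))
    if (length(raw[[s]]) != natom)
      stop("section ", s, " has ", length(raw[[s]]),
           " entries; POINTERS declares ", natom, " atoms")

  type <- raw$ATOM_TYPE_INDEX
  nb_idx <- raw$NONBONDED_PARM_INDEX
  diag_idx <- nb_idx[ntypes * (type - 1) + type]
  A <- raw$LENNARD_JONES_ACOEF[diag_idx]
  B <- raw$LENNARD_JONES_BCOEF[diag_idx]
  eps <- ifelse(A > 0, B^2 / (4 * A), 0)
  rmin_half <- ifelse(A > 0 & B > 0, 0.5 * (2 * A / B)^(1 / 6), 0)

  res_ptr <- raw$RESIDUE_POINTER
  res_of_atom <- findInterval(seq_len(natom), res_ptr)
  res_lab <- trimws(raw$RESIDUE_LABEL)[res_of_atom]

  # chain segmentation
  wat <- res_lab %in% water_names
  ion <- res_lab %in% ion_names
  chain <- rep("A", natom)
  apm <- raw$ATOMS_PER_MOLECULE
  if (!is.null(apm)) {
    mol_of_atom <- rep(seq_along(apm), apm)
    prot_mols <- unique(mol_of_atom[!wat & !ion])
    for (k in seq_along(prot_mols))
      chain[mol_of_atom == prot_mols[k]] <- LETTERS[k]
  } else {
    prot_res <- unique(res_of_atom[!wat & !ion])
    if (length(prot_res)) {
      brk <- cumsum(c(1L, diff(prot_res) != 1L))
      for (k in unique(brk))
        chain[res_of_atom %in% prot_res[brk == k]] <- LETTERS[k]
    }
  }
  mass <- raw$MASS
  at <- data.frame(
    serial = seq_len(natom), name = trimws(raw$ATOM_NAME),
    element = element_from_mass(mass),
    residue_index = res_of_atom, residue_name = res_lab,
    chain_id = chain, charge = raw$CHARGE / AMBER_CHARGE_CONV,
    mass = mass, lj_rmin_half = rmin_half, lj_epsilon = eps,
    gb_radius = raw$RADII, gb_screen = raw$SCREEN,
    stringsAsFactors = FALSE)

  clean <- function(v) { v <- v[!is.na(v)]; if (length(v)) v else NULL }
  unpack3 <- function(v) {
    v <- clean(v)
    if (is.null(v)) return(NULL)
    m <- matrix(v, ncol = 3, byrow = TRUE)
    cbind(m[, 1] / 3 + 1, m[, 2] / 3 + 1, m[, 3])
  }
  unpack4 <- function(v) {
    v <- clean(v)
    if (is.null(v)) return(NULL)
    matrix(v, ncol = 4, byrow = TRUE)
  }
  unpack5 <- function(v) {
    v <- clean(v)
    if (is.null(v)) return(NULL)
    matrix(v, ncol = 5, byrow = TRUE)
  }
  bm <- rbind(unpack3(raw$BONDS_WITHOUT_HYDROGEN),
              unpack3(raw$BONDS_INC_HYDROGEN))
  bonds <- NULL
  if (!is.null(bm))
    bonds <- data.frame(i = bm[, 1], j = bm[, 2],
                        k = raw$BOND_FORCE_CONSTANT[bm[, 3]],
                        r0 = raw$BOND_EQUIL_VALUE[bm[, 3]])
  am <- rbind(unpack4(raw$ANGLES_WITHOUT_HYDROGEN),
              unpack4(raw$ANGLES_INC_HYDROGEN))
  angles <- NULL
  if (!is.null(am)) {
    ai <- abs(am[, 1:3]) / 3 + 1
    angles <- data.frame(i = ai[, 1], j = ai[, 2], k = ai[, 3],
                         ktheta = raw$ANGLE_FORCE_CONSTANT[am[, 4]],
                         theta0 = raw$ANGLE_EQUIL_VALUE[am[, 4]])
  }
  dm <- rbind(unpack5(raw$DIHEDRALS_WITHOUT_HYDROGEN),
              unpack5(raw$DIHEDRALS_INC_HYDROGEN))
  dihedrals <- NULL
  if (!is.null(dm)) {
    # negative third index: 1-4 pair already counted elsewhere;
    # negative fourth index: improper
    gen14 <- dm[, 3] >= 0 & dm[, 4] >= 0
    di <- abs(dm[, 1:4]) / 3 + 1
    dihedrals <- data.frame(i = di[, 1], j = di[, 2], k = di[, 3],
                            l = di[, 4],
                            pk = raw$DIHEDRAL_FORCE_CONSTANT[dm[, 5]],
                            periodicity = raw$DIHEDRAL_PERIODICITY[dm[, 5]],
                            phase = raw$DIHEDRAL_PHASE[dm[, 5]],
                            gen14 = gen14)
  }
  topology(at, bonds, angles, dihedrals,
           water_names = water_names, ion_names = ion_names)
}

element_from_mass <- function(mass) {
  ref <- c(H = 1.008, C = 12.01, N = 14.01, O = 16.00, P = 30.97, S = 32.06,
           NA. = 22.99, CL = 35.45, K = 39.10, MG = 24.31, F = 19.00)
  nm <- sub("\\.$", "", names(ref))
  nm[max.col(-abs(outer(mass, ref, "-")))]
}

#' Read a trajectory from file
#'
#' Amber ASCII coordinates are parsed as 10F8.3 (with an optional box line
#' per frame); multi-model PDB is delegated to \code{\link{read_pdb}}.
#' Time stamps are assigned from \code{t0} and \code{dt} (Amber ASCII files
#' carry none).
#'
#' @param path file path.
#' @param top the matching \code{\link{topology}}.
#' @param format \code{"amber-ascii"} or \code{"multi-model-pdb"}.
#' @param has_box whether each Amber ASCII frame is followed by a box line.
#' @param t0,dt time of the first frame and frame spacing, ps.
#' @return a \code{\link{trajectory}}.
#' @export
read_trajectory <- function(path, top,
                            format = c("amber-ascii", "multi-model-pdb"),
                            has_box = FALSE, t0 = 0, dt = 10) {
  format <- match.arg(format)
  n <- n_atoms(top)
  if (format == "multi-model-pdb") {
    pdb <- read_pdb(path)
    if (n_atoms(pdb$topology) != n)
      stop("file has ", n_atoms(pdb$topology), " atoms; topology has ", n)
    frames <- pdb$frames
    for (m in seq_along(frames)) frames[[m]]$time_ps <- t0 + (m - 1) * dt
    return(trajectory(top, frames))
  }
  lines <- readLines(path)
  if (length(lines) < 2L) stop("truncated trajectory file: ", path)
  vals_per_frame <- 3L * n
  lines_per_frame <- ceiling(vals_per_frame / 10L) + if (has_box) 1L else 0L
  body <- lines[-1L]
  # drop trailing blank lines
  while (length(body) && !nzchar(trimws(body[length(body)])))
    body <- body[-length(body)]
  if (length(body) %% lines_per_frame != 0L) {
    got <- length(body) %% lines_per_frame
    stop("truncated final frame: expected ", vals_per_frame,
         " coordinates (", lines_per_frame, " lines) per frame, found ",
         got, " leftover line(s)")
  }
  n_frames <- length(body) %/% lines_per_frame
  frames <- vector("list", n_frames)
  for (m in seq_len(n_frames)) {
    block <- body[((m - 1L) * lines_per_frame + 1L):(m * lines_per_frame)]
    box <- NULL
    if (has_box) {
      box <- as.numeric(strsplit(trimws(block[length(block)]), "\\s+")[[1]])
      block <- block[-length(block)]
    }
    v <- parse_f8(block)
    if (length(v) != vals_per_frame)
      stop("frame ", m, ": expected ", vals_per_frame,
           " coordinates, found ", length(v))
    frames[[m]] <- frame(matrix(v, ncol = 3, byrow = TRUE),
                         time_ps = t0 + (m - 1) * dt, box = box)
  }
  trajectory(top, frames)
}

# split fixed-width 10F8.3 lines into numbers
parse_f8 <- function(lines) {
  out <- lapply(lines, function(l) {
    nf <- nchar(l) %/% 8L
    if (nf == 0L) return(numeric(0))
    v <- as.numeric(substring(l, 8L * (seq_len(nf) - 1L) + 1L, 8L * seq_len(nf)))
    if (anyNA(v)) stop("malformed 10F8.3 coordinate line: '", l, "'")
    v
  })
  unlist(out, use.names = FALSE)
}

#' Write an Amber ASCII coordinate trajectory (10F8.3)
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory_crd <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("generated by mnmgbsa", con)
  for (f in traj$frames) {
    v <- as.vector(t(f$xyz))
    if (any(abs(v) > 9999.999))
      stop("coordinate overflows the 10F8.3 field")
    idx <- split(seq_along(v), (seq_along(v) - 1L) %/% 10L)
    writeLines(vapply(idx, function(k) paste(sprintf("%8.3f", v[k]),
                                             collapse = ""), ""), con)
    if (!is.null(f$box))
      writeLines(paste(sprintf("%8.3f", f$box[1:3]), collapse = ""), con)
  }
  invisible(path)
}
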