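# Synthetic toy systems with fully specified force-field terms and known
# ground truth, so every pipeline stage is testable without MD input.
# Pseudo-residues of 3-4 atoms keep brute-force oracles (all-pair energies,
# quadrature GB, analytic SASA) exact and fast.

#' Build a toy two-chain complex
#'
#' Two short pseudo-peptide chains with printed charges, Lennard-Jones and
#' bonded parameters and intrinsic Born radii, arranged so one residue pair
#' forms a designed contact interface (chain B approaches chain A at the
#' middle residue). Deterministic for a given seed.
#'
#' @param n_res_a,n_res_b residues per chain (3-4 pseudo-atoms each).
#' @param contact_gap interchain gap at the designed contact, Angstrom.
#' @param net_charge_zero balance charges so the total is exactly 0.
#' @param seed RNG seed (coordinates get a tiny deterministic ripple).
#' @return list(topology, frame, contact = list(res_a, res_b)) where
#'   \code{contact} names the designed interfacial residue pair.
#' @export
make_toy_dimer <- function(n_res_a = 5, n_res_b = 4, contact_gap = 4.0,
                           net_charge_zero = TRUE, seed = 1) {
  set.seed(seed)
  spacing <- 3.8
  build_chain <- function(n_res, chain, z, x0, serial0, res0, flip) {
    atoms <- list(); xyz <- list()
    nm <- c("N", "CA", "C", "CB")
    el <- c("N", "C", "C", "C")
    q <- c(-0.4, 0.1, 0.3, 0.0)
    rad <- c(1.55, 1.70, 1.70, 1.70)
    mass <- c(14.007, 12.011, 12.011, 12.011)
    for (r in seq_len(n_res)) {
      nat <- if (r %% 2 == 0) 4L else 3L
      base <- c(x0 + (r - 1) * spacing, 0, z)
      offs <- rbind(c(0, 0, 0), c(1.5, 0.6, 0), c(3.0, 0, 0),
                    c(1.5, 0.6, if (flip) -1.5 else 1.5))
      for (a in seq_len(nat)) {
        atoms[[length(atoms) + 1L]] <- data.frame(
          serial = serial0 + length(atoms) + 1L, name = nm[a],
          element = el[a], residue_index = res0 + r,
          residue_name = paste0("R", LETTERS[(r - 1) %% 4 + 1]),
          chain_id = chain, charge = q[a], mass = mass[a],
          lj_rmin_half = 1.9, lj_epsilon = 0.1, gb_radius = rad[a],
          gb_screen = if (el[a] == "N") 0.79 else 0.72,
          stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <- base + offs[a, ]
      }
    }
    list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
  }
  # chain B is shorter and sits above chain A's middle residue
  mid_a <- ceiling(n_res_a / 2)
  a <- build_chain(n_res_a, "A", z = 0, x0 = 0, serial0 = 0L, res0 = 0L,
                   flip = FALSE)
  zb <- contact_gap + 3.0   # CB(up, +1.5) of A to CB(down) of B across the gap
  xb <- (mid_a - 1) * spacing - (ceiling(n_res_b / 2) - 1) * spacing
  b <- build_chain(n_res_b, "B", z = zb, x0 = xb, serial0 = nrow(a$atoms),
                   res0 = n_res_a, flip = TRUE)
  atoms <- rbind(a$atoms, b$atoms)
  if (net_charge_zero) atoms$charge <- atoms$charge - mean(atoms$charge)
  xyz <- rbind(a$xyz, b$xyz)
  # bonded terms: sequential bonds within each residue + peptide-like link
  bonds <- list(); angles <- list()
  for (ch in c("A", "B")) {
    idx <- which(atoms$chain_id == ch)
    res <- unique(atoms$residue_index[idx])
    prev_c <- NA
    for (r in res) {
      ra <- idx[atoms$residue_index[idx] == r]
      nm <- atoms$name[ra]
      link <- function(i, j) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        bonds[[length(bonds) + 1L]] <<- data.frame(i = i, j = j, k = 300,
                                                   r0 = d)
      }
      link(ra[nm == "N"], ra[nm == "CA"])
      link(ra[nm == "CA"], ra[nm == "C"])
      if ("CB" %in% nm) link(ra[nm == "CA"], ra[nm == "CB"])
      if (!is.na(prev_c)) link(prev_c, ra[nm == "N"])
      # one harmonic angle per residue at its equilibrium value
      i3 <- c(ra[nm == "N"], ra[nm == "CA"], ra[nm == "C"])
      v1 <- xyz[i3[1], ] - xyz[i3[2], ]; v2 <- xyz[i3[3], ] - xyz[i3[2], ]
      th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
      angles[[length(angles) + 1L]] <-
        data.frame(i = i3[1], j = i3[2], k = i3[3], ktheta = 50, theta0 = th)
      prev_c <- ra[nm == "C"]
    }
  }
  top <- topology(atoms, do.call(rbind, bonds), do.call(rbind, angles))
  list(topology = top, frame = frame(xyz),
       contact = list(res_a = mid_a, res_b = n_res_a + ceiling(n_res_b / 2)))
}

#' Generate a conformer-mixture trajectory
#'
#' Each frame is one of the supplied conformers, drawn with the given
#' population weights, plus isotropic Gaussian coordinate jitter. The
#' ground-truth conformer labels are recorded so tests never re-derive
#' them from the code under test.
#'
#' @param top a \code{\link{topology}}.
#' @param conformers list of N x 3 coordinate matrices.
#' @param weights population weights (sum to 1).
#' @param n_frames number of frames.
#' @param sigma per-axis jitter standard deviation, Angstrom.
#' @param seed RNG seed.
#' @param dt frame spacing, ps.
#' @return a \code{\link{trajectory}} with attribute \code{"labels"}
#'   (true conformer index per frame).
#' @export
make_conformer_trajectory <- function(top, conformers, weights, n_frames,
                                      sigma = 0.2, seed = 1, dt = 10) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (sigma < 0) stop("negative jitter sigma")
  set.seed(seed)
  labels <- sample.int(length(conformers), n_frames, replace = TRUE,
                       prob = weights)
  n <- n_atoms(top)
  frames <- lapply(seq_len(n_frames), function(k) {
    xyz <- as.matrix(conformers[[labels[k]]])
    frame(xyz + matrix(stats::rnorm(3 * n, 0, sigma), n, 3),
          time_ps = (k - 1) * dt)
  })
  traj <- trajectory(top, frames)
  attr(traj, "labels") <- labels
  traj
}

#' Append 3-site waters at prescribed positions
#'
#' Waters (TIP3P geometry: O-H 0.9572 Angstrom, H-O-H 104.52 degrees) are
#' appended to the topology with their oxygens at \code{center + distance *
#' direction}. The ground-truth distance ranking is recorded. Overlapping
#' placements (O-O below 2.4 Angstrom) are an error.
#'
#' @param top a \code{\link{topology}} (no waters yet, or more waters).
#' @param fr the solute \code{\link{frame}}.
#' @param center reference point, length-3 (e.g. interface center of mass).
#' @param distances,directions per-water distance (Angstrom) and direction
#'   (rows of an M x 3 matrix; normalised internally).
#' @param seed seed for random hydrogen orientation.
#' @return list(topology, frame, water_order = ground-truth residue indices
#'   sorted by distance).
#' @export
make_hydrated_frames <- function(top, fr, center, distances, directions,
                                 seed = 1) {
  m <- length(distances)
  directions <- as.matrix(directions)
  if (nrow(directions) != m) stop("one direction per distance required")
  set.seed(seed)
  o_pos <- sweep(directions / sqrt(rowSums(directions^2)), 1, distances,
                 "*")
  o_pos <- sweep(o_pos, 2, center, "+")
  if (m > 1 && min(stats::dist(o_pos)) < 2.4)
    stop("overlapping water placements (O-O < 2.4 A)")
  oh <- 0.9572; half <- (104.52 / 2) * pi / 180
  at0 <- top$atoms
  res0 <- max(at0$residue_index)
  wat_atoms <- list(); wat_xyz <- list()
  for (w in seq_len(m)) {
    # random orthonormal pair for the HOH plane
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    h1 <- o_pos[w, ] + oh * (cos(half) * u + sin(half) * v)
    h2 <- o_pos[w, ] + oh * (cos(half) * u - sin(half) * v)
    for (a in 1:3) {
      wat_atoms[[length(wat_atoms) + 1L]] <- data.frame(
        serial = nrow(at0) + length(wat_atoms) + 1L,
        name = c("O", "H1", "H2")[a], element = c("O", "H", "H")[a],
        residue_index = res0 + w, residue_name = "WAT", chain_id = "W",
        charge = c(-0.834, 0.417, 0.417)[a],
        mass = c(15.999, 1.008, 1.008)[a],
        lj_rmin_half = c(1.7683, 0, 0)[a],
        lj_epsilon = c(0.152, 0, 0)[a],
        gb_radius = c(1.5, 1.2, 1.2)[a], gb_screen = c(0.85, 0.85, 0.85)[a],
        stringsAsFactors = FALSE)
      wat_xyz[[length(wat_xyz) + 1L]] <- rbind(o_pos[w, ], h1, h2)[a, ]
    }
  }
  atoms <- rbind(at0, do.call(rbind, wat_atoms))
  bonds <- top$bonds
  for (w in seq_len(m)) {
    o <- nrow(at0) + (w - 1L) * 3L + 1L
    bonds <- rbind(bonds,
                   data.frame(i = o, j = o + 1L, k = 553, r0 = oh),
                   data.frame(i = o, j = o + 2L, k = 553, r0 = oh))
  }
  angles <- rbind(top$angles,
                  do.call(rbind, lapply(seq_len(m), function(w) {
                    o <- nrow(at0) + (w - 1L) * 3L + 1L
                    data.frame(i = o + 1L, j = o, k = o + 2L, ktheta = 100,
                               theta0 = 104.52 * pi / 180)
                  })))
  new_top <- topology(atoms, bonds, angles, top$dihedrals,
                      water_names = top$water_names,
                      ion_names = top$ion_names)
  new_xyz <- rbind(fr$xyz, do.call(rbind, wat_xyz))
  list(topology = new_top, frame = frame(new_xyz, time_ps = fr$time_ps),
       water_order = (res0 + seq_len(m))[order(distances)])
}
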