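# Gas-phase molecular-mechanics terms (Amber functional forms).

#' Coulomb constant, kcal Angstrom / (mol e^2)
#' @export
COULOMB_CONST <- 332.0636

#' Bonded energy of an atom subset
#'
#' Harmonic bonds \eqn{\sum k (r - r_0)^2}, harmonic angles
#' \eqn{\sum k (\theta - \theta_0)^2} and periodic dihedrals
#' \eqn{\sum pk (1 + \cos(n\phi - \gamma))} (Amber convention, \code{pk}
#' already divided by the term divider). Only terms whose atoms all lie in
#' \code{atoms} are evaluated; a term referencing a mix of included and
#' excluded atoms is an error (it would silently split a molecule).
#'
#' @param top a \code{\link{topology}}.
#' @param fr a \code{\link{frame}}.
#' @param atoms atom index set (default: all atoms).
#' @return named vector: E_bond, E_angle, E_dihedral (kcal/mol).
#' @export
bonded_energy <- function(top, fr, atoms = seq_len(n_atoms(top))) {
  inset <- logical(n_atoms(top)); inset[atoms] <- TRUE
  xyz <- fr$xyz
  chk <- function(m) {
    ins <- rowSums(!matrix(inset[as.matrix(m)], nrow = nrow(m))) # excluded count
    if (any(ins > 0 & ins < ncol(m)))
      stop("bonded term straddles the atom-set boundary")
    ins == 0
  }
  eb <- 0
  b <- top$bonds
  if (nrow(b)) {
    keep <- chk(b[, c("i", "j")])
    if (any(keep)) {
      d <- sqrt(rowSums((xyz[b$i[keep], , drop = FALSE] -
                         xyz[b$j[keep], , drop = FALSE])^2))
      eb <- sum(b$k[keep] * (d - b$r0[keep])^2)
    }
  }
  ea <- 0
  a <- top$angles
  if (nrow(a)) {
    keep <- chk(a[, c("i", "j", "k")])
    if (any(keep)) {
      v1 <- xyz[a$i[keep], , drop = FALSE] - xyz[a$j[keep], , drop = FALSE]
      v2 <- xyz[a$k[keep], , drop = FALSE] - xyz[a$j[keep], , drop = FALSE]
      ct <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      th <- acos(pmin(1, pmax(-1, ct)))
      ea <- sum(a$ktheta[keep] * (th - a$theta0[keep])^2)
    }
  }
  ed <- 0
  dh <- top$dihedrals
  if (nrow(dh)) {
    keep <- chk(dh[, c("i", "j", "k", "l")])
    if (any(keep)) {
      phi <- dihedral_angle(xyz, dh$i[keep], dh$j[keep], dh$k[keep],
                            dh$l[keep])
      ed <- sum(dh$pk[keep] *
                (1 + cos(dh$periodicity[keep] * phi - dh$phase[keep])))
    }
  }
  c(E_bond = eb, E_angle = ea, E_dihedral = ed)
}

dihedral_angle <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

cross3 <- function(a, b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])

# all unordered pairs within `atoms`, annotated with exclusion class:
# 0 = full interaction, 14 = scaled 1-4, NA rows (1-2/1-3) dropped.
pair_table <- function(top, atoms) {
  atoms <- sort(as.integer(atoms))
  n <- length(atoms)
  if (n < 2L)
    return(data.frame(i = integer(0), j = integer(0), scaled = logical(0)))
  i <- rep(atoms, times = n - seq_len(n))
  j <- unlist(lapply(seq_len(n - 1L), function(k) atoms[(k + 1L):n]),
              use.names = FALSE)
  key <- paste(i, j)
  ex <- top$exclusions
  excl <- key %in% paste(ex$excluded[, 1], ex$excluded[, 2])
  s14 <- key %in% paste(ex$scaled14[, 1], ex$scaled14[, 2])
  data.frame(i = i[!excl], j = j[!excl], scaled = s14[!excl])
}

#' Gas-phase nonbonded energy of an atom subset
#'
#' 12-6 Lennard-Jones with Amber combining rules
#' (\code{rmin = rmin/2_i + rmin/2_j}, \code{eps = sqrt(eps_i eps_j)}) and
#' Coulomb electrostatics with constant 332.0636 and interior dielectric
#' \code{eps_in}. No distance cutoff (end-point convention). 1-2 and 1-3
#' pairs are excluded; 1-4 pairs are scaled by 1/1.2 (electrostatics) and
#' 1/2.0 (van der Waals), the ff14SB defaults.
#'
#' @param top a \code{\link{topology}} with charges and LJ parameters.
#' @param fr a \code{\link{frame}}.
#' @param atoms atom index set (default: all).
#' @param eps_in interior dielectric.
#' @param scee,scnb 1-4 electrostatic and van der Waals divisors.
#' @return named vector: E_vdW, E_elec (kcal/mol).
#' @export
nonbonded_gas_energy <- function(top, fr, atoms = seq_len(n_atoms(top)),
                                 eps_in = 1.0, scee = 1.2, scnb = 2.0) {
  pt <- pair_table(top, atoms)
  if (!nrow(pt)) return(c(E_vdW = 0, E_elec = 0))
  e <- pair_energies(top, fr$xyz, pt$i, pt$j, eps_in)
  wel <- ifelse(pt$scaled, 1 / scee, 1)
  wvd <- ifelse(pt$scaled, 1 / scnb, 1)
  c(E_vdW = sum(e$vdw * wvd), E_elec = sum(e$elec * wel))
}

# per-pair LJ and Coulomb energies (no scaling applied)
pair_energies <- function(top, xyz, i, j, eps_in = 1.0) {
  at <- top$atoms
  r <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
  eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
  sr6 <- (rmin / r)^6
  vdw <- eps * (sr6^2 - 2 * sr6)
  vdw[eps == 0] <- 0
  elec <- COULOMB_CONST * at$charge[i] * at$charge[j] / (eps_in * r)
  list(vdw = vdw, elec = elec, r = r)
}
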