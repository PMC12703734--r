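# Shared independent oracles and tiny builders. These deliberately use the
# plainest possible formulations (double loops, full sorts, quadrature) so
# they stay independent of the implementation paths they check.

# minimal topology of free atoms (no bonded terms)
point_topology <- function(n, charge = 0, gb_radius = 1.7, gb_screen = 0.72,
                           lj_rmin_half = 1.9, lj_epsilon = 0.1,
                           element = "C", resname = "RES") {
  topology(data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), element = element,
    residue_index = seq_len(n), residue_name = resname, chain_id = "A",
    charge = rep_len(charge, n), mass = 12,
    lj_rmin_half = rep_len(lj_rmin_half, n),
    lj_epsilon = rep_len(lj_epsilon, n),
    gb_radius = rep_len(gb_radius, n), gb_screen = rep_len(gb_screen, n),
    stringsAsFactors = FALSE))
}

# brute-force gas-phase nonbonded energy with explicit exclusion handling
brute_nonbonded <- function(top, xyz, atoms, eps_in = 1, scee = 1.2,
                            scnb = 2.0) {
  at <- top$atoms
  ex <- top$exclusions
  exkey <- paste(ex$excluded[, 1], ex$excluded[, 2])
  s14key <- paste(ex$scaled14[, 1], ex$scaled14[, 2])
  vdw <- elec <- 0
  atoms <- sort(atoms)
  for (a in seq_along(atoms)) for (b in seq_along(atoms)) {
    if (b <= a) next
    i <- atoms[a]; j <- atoms[b]
    k <- paste(min(i, j), max(i, j))
    if (k %in% exkey) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
    eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
    ev <- if (eps > 0) eps * ((rmin / r)^12 - 2 * (rmin / r)^6) else 0
    ee <- 332.0636 * at$charge[i] * at$charge[j] / (eps_in * r)
    if (k %in% s14key) { ev <- ev / scnb; ee <- ee / scee }
    vdw <- vdw + ev; elec <- elec + ee
  }
  c(E_vdW = vdw, E_elec = elec)
}

# brute-force GROMOS clustering, written independently from the package
brute_gromos <- function(v, cutoff) {
  n <- nrow(v)
  unassigned <- seq_len(n)
  out <- list()
  while (length(unassigned)) {
    counts <- sapply(unassigned, function(i)
      sum(v[i, unassigned] < cutoff))
    center <- unassigned[which.max(counts)]
    members <- unassigned[v[center, unassigned] < cutoff]
    out[[length(out) + 1L]] <- list(center = center,
                                    members = sort(members),
                                    size = length(members))
    unassigned <- setdiff(unassigned, members)
  }
  sizes <- vapply(out, `[[`, integer(1), "size")
  out[order(-sizes)]
}

# numeric quadrature of the HCT descreening integral
hct_quadrature <- function(d, rhoi, sr, nr = 3000, nt = 1500) {
  if (d + sr <= rhoi) return(0)
  r <- seq(rhoi, d + sr, length.out = nr)
  th <- seq(0, pi, length.out = nt)
  g <- expand.grid(r = r, th = th)
  dj2 <- g$r^2 + d^2 - 2 * g$r * d * cos(g$th)
  keep <- dj2 <= sr^2
  0.5 * sum(sin(g$th[keep]) / g$r[keep]^2) * (r[2] - r[1]) * (th[2] - th[1])
}

# accessible area of sphere 1 partially occluded by sphere 2 (inflated
# radii R1, R2 at center distance d): full area minus the buried cap
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  a1 <- 4 * pi * R1^2; a2 <- 4 * pi * R2^2
  if (d >= R1 + R2) return(c(a1, a2))
  cap <- function(R, Rother) {
    h <- R - (d^2 + R^2 - Rother^2) / (2 * d)
    2 * pi * R * h
  }
  c(a1 - cap(R1, R2), a2 - cap(R2, R1))
}

# rotation matrix about z
rot_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# hydrated toy dimer with waters placed strictly along +/- y, clear of the
# slab-like solute, at known distances from the interface centre of mass;
# alternating sides with step >= 1.25 A keeps all O-O pairs > 2.4 A
hydrated_dimer <- function(n_waters = 40, d_min = 7, d_step = 1.5,
                           seed = 1) {
  d <- make_toy_dimer(seed = seed)
  iface <- find_interface_residues(d$frame, d$topology)
  com <- interface_com(d$frame, d$topology, iface)
  dist <- d_min + (seq_len(n_waters) - 1) * d_step
  dirs <- cbind(0, rep(c(1, -1), length.out = n_waters), 0)
  hyd <- make_hydrated_frames(d$topology, d$frame, com, dist, dirs,
                              seed = seed)
  c(hyd, list(com = com, interface = iface, dimer = d))
}
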