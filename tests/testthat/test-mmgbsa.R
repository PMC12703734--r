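make_hydrated_traj <- function(n_waters = 8, n_frames = 3, seed = 30,
                               sigma = 0.15) {
  hyd <- hydrated_dimer(n_waters = n_waters, seed = seed)
  set.seed(seed + 1)
  n <- n_atoms(hyd$topology)
  frames <- lapply(seq_len(n_frames), function(k)
    frame(hyd$frame$xyz + matrix(rnorm(3 * n, 0, sigma), n, 3),
          time_ps = (k - 1) * 10))
  list(traj = trajectory(hyd$topology, frames), hyd = hyd)
}

test_that("single-trajectory bonded terms cancel exactly and water terms
           cancel between complex and receptor", {
  ht <- make_hydrated_traj()
  top <- ht$traj$topology
  sel <- lapply(seq_along(ht$traj), function(fi)
    select_closest_waters(ht$traj$frames[[fi]], top, ht$hyd$com, n = 5))
  part <- partition_system(top, retained_waters = sel)
  fit <- mmgbsa(ht$traj, part, params = gb_params(), sasa_n_points = 240)
  # bonded deltas identically zero per frame
  expect_equal(unname(as.matrix(fit$per_frame[, c("E_bond", "E_angle",
                                                  "E_dihedral")])),
               matrix(0, 3, 3), tolerance = 0)
  # gas-phase delta equals the direct ligand-cross interaction sum: all
  # water-water and water-receptor terms cancel between complex and receptor
  for (k in seq_along(ht$traj)) {
    sets <- partition_atoms(part, k)
    fr <- ht$traj$frames[[k]]
    lig <- sets$ligand
    rec <- sets$receptor
    cross <- 0
    for (i in lig) for (j in rec) {
      e <- mnmgbsa:::pair_energies(top, fr$xyz, i, j)
      cross <- cross + e$vdw + e$elec
    }
    expect_equal(fit$per_frame$E_vdW[k] + fit$per_frame$E_elec[k], cross,
                 tolerance = 1e-8)
  }
})

test_that("separated ligand leaves only the solvation difference", {
  d <- make_toy_dimer(seed = 31)
  top <- d$topology
  ib <- which(top$atoms$chain_id == "B")
  x <- d$frame$xyz
  x[ib, 1] <- x[ib, 1] + 200
  traj <- trajectory(top, list(frame(x)))
  part <- partition_system(top)
  fit <- mmgbsa(traj, part, sasa_n_points = 240)
  expect_lt(abs(fit$per_frame$E_vdW), 1e-4)
  expect_lt(abs(fit$per_frame$E_elec) , 0.05)  # 1/r tail at 200 A
  # at infinite separation SASA and GB radii are additive: dG ~ 0
  expect_lt(abs(fit$per_frame$G_nonpolar), 1e-6)
  expect_lt(abs(fit$mean), 0.05)
})

test_that("per-frame dG matches a brute-force re-evaluation and the mean/sd
           summarise the frames", {
  ht <- make_hydrated_traj(n_waters = 4, n_frames = 5, seed = 32)
  top <- ht$traj$topology
  part <- partition_system(top)      # no waters: simplest brute force
  p <- gb_params()
  fit <- mmgbsa(ht$traj, part, params = p, sasa_n_points = 240)
  for (k in c(1, 4)) {
    fr <- ht$traj$frames[[k]]
    sets <- partition_atoms(part, k)
    g <- vapply(sets, function(idx) {
      nb <- brute_nonbonded(top, fr$xyz, idx)
      r <- effective_born_radii(top, fr, idx, p)
      gp <- gb_polar_energy(top, fr, r, idx, p)
      sa <- sa_nonpolar_energy(compute_sasa(fr, top, atoms = idx,
                                            n_points = 240)$total)
      sum(nb) + gp + sa + sum(bonded_energy(top, fr, idx))
    }, numeric(1))
    expect_equal(fit$per_frame$dG_bind[k],
                 unname(g["complex"] - g["receptor"] - g["ligand"]),
                 tolerance = 1e-8)
  }
  expect_equal(fit$mean, mean(fit$per_frame$dG_bind), tolerance = 1e-12)
  expect_equal(fit$sd, sd(fit$per_frame$dG_bind), tolerance = 1e-12)
  expect_error(mmgbsa(ht$traj, part, frames = 99), "out of range")
  # the entropy field reports not-computed, never zero
  expect_true(is.na(fit$entropy_TdS))
})

test_that("identical inputs give bit-identical results (pipeline determinism)", {
  ht <- make_hydrated_traj(seed = 33)
  part <- partition_system(ht$traj$topology)
  f1 <- mmgbsa(ht$traj, part, sasa_n_points = 120)
  f2 <- mmgbsa(ht$traj, part, sasa_n_points = 120)
  expect_identical(f1$per_frame, f2$per_frame)
})

test_that("two-residue system puts the whole interaction on its single pair", {
  atoms <- data.frame(serial = 1:2, name = c("X1", "X2"), element = "C",
                      residue_index = 1:2, residue_name = c("LYS", "GLU"),
                      chain_id = c("A", "B"), charge = c(0.4, -0.4),
                      mass = 12, lj_rmin_half = 1.9, lj_epsilon = 0.1,
                      gb_radius = 1.7, gb_screen = 0.72)
  top <- topology(atoms)
  traj <- trajectory(top, list(frame(rbind(c(0, 0, 0), c(4, 0, 0)))))
  part <- partition_system(top)
  p <- gb_params()
  dec <- pairwise_decomposition(traj, part, params = p)
  expect_equal(nrow(dec$pairs), 1L)
  expect_equal(dec$pairs$res_a, "GLU2")
  expect_equal(dec$pairs$res_b, "LYS1")
  fit <- mmgbsa(traj, part, params = p, sasa_n_points = 240)
  expect_equal(dec$pairs$vdw + dec$pairs$elec,
               fit$per_frame$E_vdW + fit$per_frame$E_elec,
               tolerance = 1e-9)
})

test_that("decomposition conserves the cross-partition interaction energy", {
  ht <- make_hydrated_traj(n_waters = 6, n_frames = 2, seed = 34)
  top <- ht$traj$topology
  sel <- lapply(seq_along(ht$traj), function(fi)
    select_closest_waters(ht$traj$frames[[fi]], top, ht$hyd$com, n = 4))
  part <- partition_system(top, retained_waters = sel)
  p <- gb_params()
  dec <- pairwise_decomposition(ht$traj, part, params = p)
  fit <- mmgbsa(ht$traj, part, params = p, sasa_n_points = 120)
  # gas part: sum over pairs equals dE_vdW + dE_elec frame by frame
  expect_equal(dec$conservation$gas_cross,
               fit$per_frame$E_vdW + fit$per_frame$E_elec,
               tolerance = 1e-6)
  # table sums equal the frame-averaged conservation sums
  expect_equal(sum(dec$pairs$vdw + dec$pairs$elec),
               mean(dec$conservation$gas_cross), tolerance = 1e-6)
  expect_equal(sum(dec$pairs$gb), mean(dec$conservation$gb_cross),
               tolerance = 1e-6)
})

test_that("decomposition matches brute-force per-pair re-evaluation on a
           4-residue fixture", {
  atoms <- data.frame(serial = 1:8, name = paste0("X", 1:8), element = "C",
                      residue_index = rep(1:4, each = 2),
                      residue_name = rep(c("ALA", "GLY", "SER", "THR"),
                                         each = 2),
                      chain_id = rep(c("A", "B"), each = 4),
                      charge = c(0.3, -0.1, 0.2, -0.4, 0.25, -0.15, 0.1,
                                 -0.2),
                      mass = 12, lj_rmin_half = 1.9, lj_epsilon = 0.1,
                      gb_radius = 1.7, gb_screen = 0.72)
  top <- topology(atoms)
  set.seed(35)
  xyz <- matrix(rnorm(24, sd = 3), 8, 3)
  traj <- trajectory(top, list(frame(xyz)))
  part <- partition_system(top)
  p <- gb_params()
  dec <- pairwise_decomposition(traj, part, params = p)
  radii <- effective_born_radii(top, traj$frames[[1]], 1:8, p)
  kap <- p$kappa_scale * p$kappa
  for (rr in seq_len(nrow(dec$pairs))) {
    ra <- dec$pairs$res_a[rr]; rb <- dec$pairs$res_b[rr]
    ia <- which(paste0(atoms$residue_name, atoms$residue_index) == ra)
    ib <- which(paste0(atoms$residue_name, atoms$residue_index) == rb)
    vdw <- elec <- gb <- 0
    for (i in ia) for (j in ib) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sr6 <- ((atoms$lj_rmin_half[i] + atoms$lj_rmin_half[j]) / r)^6
      vdw <- vdw + 0.1 * (sr6^2 - 2 * sr6)
      elec <- elec + 332.0636 * atoms$charge[i] * atoms$charge[j] / r
      f <- sqrt(r^2 + radii[i] * radii[j] *
                  exp(-r^2 / (4 * radii[i] * radii[j])))
      gb <- gb - 332.0636 * atoms$charge[i] * atoms$charge[j] *
        (1 - exp(-kap * f) / 78.5) / f
    }
    expect_equal(dec$pairs$vdw[rr], unname(vdw), tolerance = 1e-9)
    expect_equal(dec$pairs$elec[rr], unname(elec), tolerance = 1e-9)
    expect_equal(dec$pairs$gb[rr], unname(gb), tolerance = 1e-9)
  }
})

test_that("atom-pair distance series resolves named atoms and measures
           Euclidean distance", {
  d <- make_toy_dimer(seed = 36)
  top <- d$topology
  x <- d$frame$xyz
  ia <- resolve_atom(top, "A:1:N")
  ib <- resolve_atom(top, "A:1:CA")
  x[ia, ] <- c(0, 0, 0); x[ib, ] <- c(3, 4, 0)   # classic 3-4-5
  traj <- trajectory(top, list(frame(x), frame(x)))
  s <- atom_pair_distance_series(traj, "A:1:N", "A:1:CA")
  expect_equal(s$distance, c(5, 5), tolerance = 1e-12)
  expect_equal(atom_pair_distance_series(traj, "A:1:N", "A:1:N")$distance,
               c(0, 0))
  # direct norm oracle on a random pair over frames
  s2 <- atom_pair_distance_series(traj, "A:2:CA", "B:7:CB")
  i2 <- resolve_atom(top, "A:2:CA"); j2 <- resolve_atom(top, "B:7:CB")
  expect_equal(s2$distance[1], sqrt(sum((x[i2, ] - x[j2, ])^2)),
               tolerance = 1e-12)
  expect_error(resolve_atom(top, "A:1:ZZ"), "no atom")
  expect_error(resolve_atom(top, "A:1"), "chain:residue:atom")
})
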