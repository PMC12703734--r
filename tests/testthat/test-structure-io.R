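test_that("PDB writer/reader round-trip preserves atoms, chains and coordinates", {
  d <- make_toy_dimer(seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d$topology, d$frame, path)
  back <- read_pdb(path)
  expect_equal(n_atoms(back$topology), n_atoms(d$topology))
  expect_equal(back$topology$atoms$name, d$topology$atoms$name)
  expect_equal(back$topology$atoms$chain_id, d$topology$atoms$chain_id)
  expect_equal(back$frames[[1]]$xyz, unname(d$frame$xyz), tolerance = 1e-12)
  expect_lt(max(abs(back$frames[[1]]$xyz - d$frame$xyz)), 0.001)
  # atom order preserved: serial order in = order out
  expect_equal(back$topology$atoms$serial, seq_len(n_atoms(d$topology)))
})

test_that("multi-model PDB yields one frame per MODEL with equal atom counts", {
  d <- make_toy_dimer(seed = 4)
  f2 <- frame(d$frame$xyz + 1.5, time_ps = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d$topology, list(d$frame, f2), path)
  back <- read_pdb(path)
  expect_length(back$frames, 2L)
  expect_equal(nrow(back$frames[[2]]$xyz), n_atoms(d$topology))
  expect_equal(back$frames[[2]]$xyz - back$frames[[1]]$xyz,
               matrix(1.5, n_atoms(d$topology), 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("chain segmentation matches hand-parsed residue layout", {
  d <- make_toy_dimer(n_res_a = 5, n_res_b = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d$topology, d$frame, path)
  top <- read_pdb(path)$topology
  m <- top$molecules
  expect_equal(m$label, c("chainA", "chainB"))
  resA <- unique(top$atoms$residue_index[m$start[1]:m$end[1]])
  resB <- unique(top$atoms$residue_index[m$start[2]:m$end[2]])
  expect_length(resA, 5L)
  expect_length(resB, 4L)
  # renumbering convention: chain B continues after chain A
  expect_equal(min(resB), max(resA) + 1L)
})

test_that("PDB parser agrees with an independent reader on a fixture", {
  d <- make_toy_dimer(seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(d$topology, d$frame, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(ours$topology$atoms$name, ref$atom$elety)
  expect_equal(as.vector(t(ours$frames[[1]]$xyz)), as.vector(ref$xyz),
               tolerance = 1e-9)
})

test_that("PDB errors: malformed records name the line, empty input rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK none here", "END"), path)
  expect_error(read_pdb(path), "no ATOM/HETATM")
  d <- make_toy_dimer()
  write_pdb(d$topology, d$frame, path)
  lines <- readLines(path)
  substr(lines[3], 31, 38) <- "  xx.yyy"
  writeLines(lines, path)
  expect_error(read_pdb(path), "line 3")
  # coordinate overflow refuses to truncate silently
  bad <- frame(d$frame$xyz + 1e5)
  expect_error(write_pdb(d$topology, bad, path), "overflow")
})

test_that("prmtop parsing converts charges and recovers bonded/GB fields", {
  path <- withr::local_tempfile(fileext = ".prmtop")
  writeLines(c(
    "%VERSION  VERSION_STAMP = V0001.000",
    "%FLAG TITLE", "%FORMAT(20a4)", "toy",
    "%FLAG POINTERS", "%FORMAT(10I8)",
    sprintf("%8d", c(3, 2, 1, 1, 0, 0, 0, 0, 0, 0)) |> paste(collapse = ""),
    sprintf("%8d", c(0, 1, 0, 1, 1, 1, 1, 0, 0, 0)) |> paste(collapse = ""),
    sprintf("%8d", c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0)) |> paste(collapse = ""),
    sprintf("%8d", 0),
    "%FLAG ATOM_NAME", "%FORMAT(20a4)", "N   CA  C",
    "%FLAG CHARGE", "%FORMAT(5E16.8)",
    "  1.82223000E+01 -9.11115000E+00 -9.11115000E+00",
    "%FLAG MASS", "%FORMAT(5E16.8)",
    "  1.40100000E+01  1.20100000E+01  1.20100000E+01",
    "%FLAG ATOM_TYPE_INDEX", "%FORMAT(10I8)",
    "       1       2       2",
    "%FLAG NONBONDED_PARM_INDEX", "%FORMAT(10I8)",
    "       1       2       2       3",
    "%FLAG RESIDUE_LABEL", "%FORMAT(20a4)", "ALA",
    "%FLAG RESIDUE_POINTER", "%FORMAT(10I8)", "       1",
    "%FLAG BOND_FORCE_CONSTANT", "%FORMAT(5E16.8)", "  1.00000000E+02",
    "%FLAG BOND_EQUIL_VALUE", "%FORMAT(5E16.8)", "  1.00000000E+00",
    "%FLAG ANGLE_FORCE_CONSTANT", "%FORMAT(5E16.8)", "",
    "%FLAG ANGLE_EQUIL_VALUE", "%FORMAT(5E16.8)", "",
    "%FLAG DIHEDRAL_FORCE_CONSTANT", "%FORMAT(5E16.8)", "",
    "%FLAG DIHEDRAL_PERIODICITY", "%FORMAT(5E16.8)", "",
    "%FLAG DIHEDRAL_PHASE", "%FORMAT(5E16.8)", "",
    "%FLAG BONDS_INC_HYDROGEN", "%FORMAT(10I8)", "",
    "%FLAG BONDS_WITHOUT_HYDROGEN", "%FORMAT(10I8)",
    "       0       3       1",
    "%FLAG LENNARD_JONES_ACOEF", "%FORMAT(5E16.8)",
    "  1.00000000E+06  5.00000000E+05  2.50000000E+05",
    "%FLAG LENNARD_JONES_BCOEF", "%FORMAT(5E16.8)",
    "  1.00000000E+03  7.00000000E+02  5.00000000E+02",
    "%FLAG RADII", "%FORMAT(5E16.8)",
    "  1.55000000E+00  1.70000000E+00  1.70000000E+00",
    "%FLAG SCREEN", "%FORMAT(5E16.8)",
    "  7.90000000E-01  7.20000000E-01  7.20000000E-01"), path)
  top <- read_prmtop(path)
  # documented conversion constant: stored 18.2223 -> exactly 1 e
  expect_equal(top$atoms$charge[1], 1.0, tolerance = 1e-12)
  expect_equal(sum(top$atoms$charge), 0, tolerance = 1e-9)
  expect_equal(top$bonds,
               data.frame(i = 1, j = 2, k = 100, r0 = 1),
               ignore_attr = TRUE)
  expect_equal(top$atoms$gb_radius, c(1.55, 1.7, 1.7))
  expect_equal(top$atoms$gb_screen, c(0.79, 0.72, 0.72))
  # LJ diagonal recovery: eps = B^2/(4A), rmin/2 = ((2A/B)^(1/6))/2
  expect_equal(top$atoms$lj_epsilon[1], 1e3^2 / (4e6), tolerance = 1e-12)
  expect_equal(top$atoms$lj_rmin_half[1], 0.5 * (2e6 / 1e3)^(1 / 6),
               tolerance = 1e-12)
  # missing mandatory section is named
  lines <- readLines(path)
  drop <- grep("%FLAG RADII", lines)
  writeLines(lines[-(drop:(drop + 2))], path)
  expect_error(read_prmtop(path), "RADII")
})

test_that("Amber ASCII trajectory round-trips at format precision", {
  d <- make_toy_dimer(seed = 6)
  set.seed(10)
  frames <- lapply(0:1, function(k)
    frame(d$frame$xyz + matrix(rnorm(3 * n_atoms(d$topology), 0, 2),
                               ncol = 3), time_ps = k * 10))
  traj <- trajectory(d$topology, frames)
  path <- withr::local_tempfile(fileext = ".crd")
  write_trajectory_crd(traj, path)
  back <- read_trajectory(path, d$topology, "amber-ascii", dt = 10)
  expect_length(back, 2L)
  for (k in 1:2)
    expect_lt(max(abs(back$frames[[k]]$xyz - frames[[k]]$xyz)), 0.001)
  expect_equal(frame_times(back), c(0, 10))
})

test_that("trajectory reader rejects truncated files and wrong atom counts", {
  d <- make_toy_dimer(seed = 6)
  traj <- trajectory(d$topology, list(d$frame, d$frame))
  path <- withr::local_tempfile(fileext = ".crd")
  write_trajectory_crd(traj, path)
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)
  expect_error(read_trajectory(path, d$topology), "truncated|expected")
  # one atom too few in the topology
  top_small <- subset_topology(d$topology, seq_len(n_atoms(d$topology) - 1))
  write_trajectory_crd(traj, path)
  expect_error(read_trajectory(path, top_small), "truncated|expected")
})

test_that("large generated trajectories read back with the generator count", {
  top <- point_topology(4)
  set.seed(11)
  frames <- lapply(seq_len(1000), function(k)
    frame(matrix(rnorm(12, 0, 5), 4, 3), time_ps = (k - 1) * 10))
  traj <- trajectory(top, frames)
  path <- withr::local_tempfile(fileext = ".crd")
  write_trajectory_crd(traj, path)
  expect_length(read_trajectory(path, top), 1000L)
})

test_that("water renaming and renumbering flags behave at the file boundary", {
  hyd <- hydrated_dimer(n_waters = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(hyd$topology, hyd$frame, path, water_resname = "HOH")
  back <- read_pdb(path)
  expect_equal(sum(is_water(back$topology)), 9L)  # 3 waters x 3 sites
})
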