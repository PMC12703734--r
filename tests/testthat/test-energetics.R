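test_that("bonded terms match hand arithmetic and vanish at equilibrium", {
  top <- topology(
    data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
               residue_index = 1, residue_name = "RES", chain_id = "A"),
    bonds = data.frame(i = 1, j = 2, k = 100, r0 = 1.0))
  # k (r - r0)^2 with r = 1.1 -> 100 * 0.01 = 1 kcal/mol
  e <- bonded_energy(top, frame(rbind(c(0, 0, 0), c(1.1, 0, 0))))
  expect_equal(unname(e["E_bond"]), 1.0, tolerance = 1e-12)
  e0 <- bonded_energy(top, frame(rbind(c(0, 0, 0), c(1.0, 0, 0))))
  expect_equal(unname(e0["E_bond"]), 0, tolerance = 1e-12)
  # toy dimer is built at equilibrium: all bonded terms zero
  d <- make_toy_dimer(seed = 22)
  eb <- bonded_energy(d$topology, d$frame)
  expect_equal(unname(eb), c(0, 0, 0), tolerance = 1e-9)
  # hand-summed terms on a perturbed frame
  x <- d$frame$xyz * 1.03
  eb2 <- bonded_energy(d$topology, frame(x))
  b <- d$topology$bonds
  manual <- sum(b$k * (sqrt(rowSums((x[b$i, ] - x[b$j, ])^2)) - b$r0)^2)
  expect_equal(unname(eb2["E_bond"]), manual, tolerance = 1e-9)
  expect_gt(eb2["E_bond"], 0)
})

test_that("dihedral energy follows the Amber periodic convention", {
  # butane-like 4 atoms with a single 3-fold torsion
  top <- topology(
    data.frame(serial = 1:4, name = paste0("C", 1:4), element = "C",
               residue_index = 1, residue_name = "RES", chain_id = "A"),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, pk = 1.4,
                           periodicity = 3, phase = 0))
  make_phi <- function(phi) {
    rbind(c(1, 0, -1), c(0, 0, -1), c(0, 0, 0),
          c(cos(phi), sin(phi), 0))
  }
  for (phi in c(0, pi / 3, pi / 2, pi, 4)) {
    e <- bonded_energy(top, frame(make_phi(phi)))
    expect_equal(unname(e["E_dihedral"]), 1.4 * (1 + cos(3 * phi)),
                 tolerance = 1e-9)
  }
})

test_that("point-charge and LJ-minimum pair energies are exact", {
  top <- point_topology(2, charge = c(1, 1), lj_rmin_half = 0,
                        lj_epsilon = 0)
  # 332.0636 / 3.320636 = 100 exactly
  e <- nonbonded_gas_energy(top, frame(rbind(c(0, 0, 0),
                                             c(3.320636, 0, 0))))
  expect_equal(unname(e["E_elec"]), 100.0, tolerance = 1e-9)
  expect_equal(unname(e["E_vdW"]), 0)
  # LJ pair at the combined minimum distance gives -sqrt(eps_i eps_j)
  top2 <- point_topology(2, charge = 0, lj_rmin_half = c(1.8, 2.0),
                         lj_epsilon = c(0.09, 0.16))
  e2 <- nonbonded_gas_energy(top2, frame(rbind(c(0, 0, 0), c(3.8, 0, 0))))
  expect_equal(unname(e2["E_vdW"]), -sqrt(0.09 * 0.16), tolerance = 1e-12)
})

test_that("nonbonded energy equals the double-loop oracle with exclusions and 1-4 scaling", {
  # 20-atom chain with bonds/angles/dihedrals so all exclusion classes occur
  set.seed(23)
  n <- 20
  atoms <- data.frame(serial = 1:n, name = paste0("C", 1:n), element = "C",
                      residue_index = rep(1:5, each = 4),
                      residue_name = "RES", chain_id = "A",
                      charge = round(rnorm(n, 0, 0.3), 3), mass = 12,
                      lj_rmin_half = runif(n, 1.6, 2.1),
                      lj_epsilon = runif(n, 0.05, 0.2),
                      gb_radius = 1.7, gb_screen = 0.72)
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, k = 300, r0 = 1.5)
  angles <- data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
                       ktheta = 50, theta0 = 1.9)
  dihedrals <- data.frame(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1),
                          l = 4:n, pk = 1.4, periodicity = 3, phase = 0)
  top <- topology(atoms, bonds, angles, dihedrals)
  xyz <- matrix(0, n, 3)
  for (k in 2:n)   # loose random walk so distances vary
    xyz[k, ] <- xyz[k - 1, ] + rnorm(3, 0, 1) + c(1.2, 0, 0)
  got <- nonbonded_gas_energy(top, frame(xyz))
  want <- brute_nonbonded(top, xyz, 1:n)
  expect_equal(got, want, tolerance = 1e-10)
  # subset evaluation also matches
  sub <- c(1:7, 12:20)
  expect_equal(nonbonded_gas_energy(top, frame(xyz), sub),
               brute_nonbonded(top, xyz, sub), tolerance = 1e-10)
})

test_that("gas-phase energies are invariant under rigid motion", {
  d <- make_toy_dimer(seed = 24)
  set.seed(25)
  R <- random_rotation()
  moved <- frame(d$frame$xyz %*% R + matrix(rep(c(3, -7, 11),
                                                each = n_atoms(d$topology)),
                                            ncol = 3))
  e1 <- nonbonded_gas_energy(d$topology, d$frame)
  e2 <- nonbonded_gas_energy(d$topology, moved)
  expect_equal(e1, e2, tolerance = 1e-8)
  b1 <- bonded_energy(d$topology, d$frame)
  b2 <- bonded_energy(d$topology, moved)
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("isolated-atom effective radius equals the reduced intrinsic radius", {
  ion <- point_topology(1, charge = 1, gb_radius = 1.5, gb_screen = 0.8,
                        element = "O")
  r <- effective_born_radii(ion, frame(matrix(0, 1, 3)))
  expect_equal(unname(r), 1.5 - 0.195141, tolerance = 1e-12)
  # two atoms pulled far apart approach their isolated values
  two <- point_topology(2, charge = 0, gb_radius = 1.7, gb_screen = 0.72)
  r2 <- effective_born_radii(two, frame(rbind(c(0, 0, 0), c(500, 0, 0))))
  expect_equal(unname(r2), rep(1.7 - 0.195141, 2), tolerance = 1e-6)
  bad <- point_topology(1, gb_radius = -1)
  expect_error(effective_born_radii(bad, frame(matrix(0, 1, 3))),
               "non-positive")
})

test_that("descreening integrals match the quadrature oracle on a 5-atom fixture", {
  set.seed(26)
  n <- 5
  top <- point_topology(n, charge = 0.2,
                        gb_radius = c(1.2, 1.55, 1.7, 1.5, 1.8),
                        gb_screen = c(0.85, 0.79, 0.72, 0.85, 0.96))
  xyz <- matrix(rnorm(15, sd = 2.5), n, 3)
  p <- gb_params(element_screen = FALSE)
  # oracle: effective radii from quadrature of the HCT integral, with the
  # same neck and tanh mapping applied on top
  rhot <- top$atoms$gb_radius - p$offset
  scr <- top$atoms$gb_screen
  got <- effective_born_radii(top, frame(xyz), params = p, neck = FALSE)
  ep <- mnmgbsa:::gb_element_params(top$atoms$element)
  for (i in seq_len(n)) {
    I <- 0
    for (j in setdiff(seq_len(n), i)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      I <- I + hct_quadrature(d, rhot[i], scr[j] * rhot[j])
    }
    psi <- I * rhot[i]
    invR <- 1 / rhot[i] -
      tanh(ep$alpha[i] * psi - ep$beta[i] * psi^2 + ep$gamma[i] * psi^3) /
        top$atoms$gb_radius[i]
    expect_equal(unname(got[i]), 1 / invR, tolerance = 1e-3)
  }
})

test_that("GB energy obeys the Born limit and the distant-ion closed form", {
  # Born grid: q, R, eps_out
  for (q in c(-1, 0.5, 2)) for (R in c(1, 2, 5)) for (eo in c(40, 78.5)) {
    ion <- point_topology(1, charge = q, gb_radius = R + 0.195141,
                          gb_screen = 0.8)
    p <- gb_params(eps_out = eo, salt = 0)
    r <- effective_born_radii(ion, frame(matrix(0, 1, 3)), params = p)
    g <- gb_polar_energy(ion, frame(matrix(0, 1, 3)), r, params = p)
    expect_equal(g, -0.5 * 332.0636 * q^2 * (1 - 1 / eo) / R,
                 tolerance = 1e-6)
  }
  # zero charge -> zero energy
  none <- point_topology(3, charge = 0)
  fr <- frame(matrix(rnorm(9), 3, 3))
  r <- effective_born_radii(none, fr)
  expect_equal(gb_polar_energy(none, fr, r), 0)
  # two distant ions: Born self terms + screened Coulomb cross term
  p <- gb_params(salt = 0.15)
  two <- point_topology(2, charge = c(1, -1), gb_radius = 2.195141,
                        gb_screen = 0.8)
  fr2 <- frame(rbind(c(0, 0, 0), c(50, 0, 0)))
  r2 <- effective_born_radii(two, fr2, params = p)
  g2 <- gb_polar_energy(two, fr2, r2, params = p)
  kap <- 0.73 * sqrt(0.10806 * 0.15)
  f <- sqrt(50^2 + 4 * exp(-2500 / 16))
  want <- 2 * (-0.5 * 332.0636 * (1 - exp(-kap * 2) / 78.5) / 2) +
    (-332.0636 * (1) * (-1) * (1 - exp(-kap * f) / 78.5) / f) * -1
  # (cross term written out: -C q1 q2 (1/ei - exp(-kf)/eo) / f)
  want <- 2 * (-0.5 * 332.0636 * (1 - exp(-kap * 2) / 78.5) / 2) -
    332.0636 * (1 * -1) * (1 - exp(-kap * f) / 78.5) / f
  expect_equal(g2, want, tolerance = 1e-6)
})

test_that("polar energy vanishes as the solvent dielectric approaches the interior", {
  set.seed(27)
  top <- point_topology(4, charge = c(0.5, -0.3, 0.8, -1.0))
  fr <- frame(matrix(rnorm(12, sd = 3), 4, 3))
  p <- gb_params(eps_out = 1 + 1e-9, salt = 0)
  r <- effective_born_radii(top, fr, params = p)
  expect_lt(abs(gb_polar_energy(top, fr, r, params = p)), 1e-6)
})

test_that("GB energy is invariant under rigid motion", {
  d <- make_toy_dimer(seed = 28)
  set.seed(29)
  p <- gb_params()
  moved <- frame(d$frame$xyz %*% random_rotation() +
                   matrix(rep(c(5, 5, -9), each = n_atoms(d$topology)),
                          ncol = 3))
  r1 <- effective_born_radii(d$topology, d$frame, params = p)
  r2 <- effective_born_radii(d$topology, moved, params = p)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_equal(gb_polar_energy(d$topology, d$frame, r1, params = p),
               gb_polar_energy(d$topology, moved, r2, params = p),
               tolerance = 1e-6)
})

test_that("surface-area nonpolar term is the stated linear map", {
  expect_equal(sa_nonpolar_energy(100), 0.72, tolerance = 1e-12)
  expect_equal(sa_nonpolar_energy(0), 0)
  expect_equal(sa_nonpolar_energy(100, gamma = 0.005, b = 1), 1.5)
  expect_error(sa_nonpolar_energy(-5), "negative")
})
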