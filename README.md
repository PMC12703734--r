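# mnmgbsa

Post-simulation MM-GBSA binding free energies for protein–protein
complexes, with **Mix-and-Match (MnM)** conformational sampling and
**interfacial-water retention**.

Standard end-point MM-GBSA struggles on protein–protein interfaces: the
unbound partners relax away from their bound geometry, and bridging waters
at the large, solvent-exposed interface carry real energetic weight. This
package implements the post-MD half of a protocol that tackles both — it
clusters unbound-chain ensembles, rebuilds the complex from the most
populated conformer of each chain, retains the waters closest to the
interface as part of the receptor, and averages single-trajectory MM-GBSA
energies over evenly spaced frames. It is aimed at structural/computational
chemists ranking protein–protein and protein–peptide binders.

## The method in brief

Per frame of the complex trajectory,

```
ΔG_bind = G_complex − G_receptor − G_ligand
G       = E_bond + E_angle + E_dihedral + E_vdW + E_elec + G_polar + G_nonpolar
```

with `G_polar` from a GB-Neck2-class generalized Born model (mbondi3
intrinsic radii, 0.15 M salt, effective radii from HCT descreening + neck
correction + tanh rescaling) and `G_nonpolar = γ·SASA + b`
(γ = 0.0072 kcal·mol⁻¹·Å⁻², b = 0, Shrake–Rupley SASA). In the
single-trajectory convention all bonded terms — and all water–receptor
terms when the 30 interfacial waters ride with the receptor — cancel
exactly in the difference. The −TΔS term is reported as *not computed*.
Supporting stages: GROMOS (Daura) clustering at a 1 Å Cα RMSD cutoff,
backbone Kabsch superposition for MnM assembly, ΔSASA > 0.50 Å²
interfacial-residue detection, per-residue pairwise energy decomposition,
and `ΔG ≈ RT ln K_D` affinity benchmarking with r² / ΔΔG reports.

## Worked example

A fully synthetic two-chain complex with designed contacts and 34 placed
waters; 10 frames of jittered dynamics; 30 waters retained per frame:

```r
library(mnmgbsa)
set.seed(7)
dimer <- make_toy_dimer(seed = 7)
iface <- find_interface_residues(dimer$frame, dimer$topology)
com   <- interface_com(dimer$frame, dimer$topology, iface)
hyd   <- make_hydrated_frames(dimer$topology, dimer$frame, com,
                              distances  = 7 + 1.5 * (0:33),
                              directions = cbind(0, rep(c(1, -1), 17), 0))
n    <- n_atoms(hyd$topology)
traj <- trajectory(hyd$topology, lapply(0:9, function(k)
  frame(hyd$frame$xyz + matrix(rnorm(3 * n, 0, 0.08), n, 3),
        time_ps = k * 10)))
waters <- lapply(seq_along(traj), function(fi)
  select_closest_waters(traj$frames[[fi]], hyd$topology, com, n = 30))
part <- partition_system(hyd$topology, ligand_chain = "B",
                         retained_waters = waters)
fit <- mmgbsa(traj, part)
summary(fit)
```

```
MM-GBSA component summary (kcal/mol) over 10 frame(s), 30 retained water(s):
       term    mean      sd
     E_bond  0.0000 0.00000
    E_angle  0.0000 0.00000
 E_dihedral  0.0000 0.00000
      E_vdW -0.8206 0.03150
     E_elec  4.4093 0.30135
    G_polar -4.0372 0.30643
 G_nonpolar -0.6437 0.05139
    dG_bind -1.0922 0.07897
```

Reading it: the bonded rows are exactly zero (single-trajectory
cancellation); the unfavourable interchain electrostatics (+4.41) is
almost fully screened by the polar solvation change (−4.04); packing
(−0.82) and buried surface (−0.64) leave a weakly favourable
ΔG_bind = −1.09 ± 0.08 kcal/mol for this toy contact. The decomposition
names the residue pairs carrying it:

```r
pairwise_decomposition(traj, part, frames = 1:3)
#> Pairwise per-residue decomposition over 3 frame(s); top pairs by total (kcal/mol):
#>  res_a res_b      vdw   elec      gb    total
#>    RD9   RA5 -0.10414 1.0187 -1.0047 -0.09021
#>    RD9   RD4 -0.08844 0.3021 -0.3006 -0.08695
#>    ...
```

Experimental benchmarking uses the packaged 20-complex affinity table:

```r
tab <- read_affinity_table(system.file("extdata",
        "ppi_benchmark_affinities.tsv", package = "mnmgbsa"))
correlation_report(tab$dg, predicted, ids = tab$pdb_id, exclude = "3SGB")
```

A thin command-line front end ships in `exec/mnmgbsa`
(`cluster`, `build-mnm`, `interface`, `select-waters`, `gbsa`,
`correlate`); `run_scheme()` orchestrates a whole scheme from one
`run_config()` and writes per-stage artifacts plus a checksum manifest.

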