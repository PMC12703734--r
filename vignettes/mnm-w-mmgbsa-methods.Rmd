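---
title: "Methods: Mix-and-Match MM-GBSA with interfacial waters"
author: "mnmgbsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mix-and-Match MM-GBSA with interfacial waters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnmgbsa)
```

## The problem and the model

Protein–protein interfaces are large, shallow and solvent-exposed, which
makes end-point binding free-energy estimates hard: the unbound partners
sample conformations far from their bound geometry, and bridging water
molecules carry real energetic weight. `mnmgbsa` implements a
post-simulation protocol that addresses both: *Mix-and-Match* (MnM)
reconstruction of a complex from the most populated unbound conformer of
each chain, and retention of a fixed number of interfacial waters as part
of the receptor during the MM-GBSA average.

The end-point estimator is the single-trajectory MM-GBSA decomposition

$$\Delta G_{bind} = G_{complex} - G_{receptor} - G_{ligand},$$

evaluated per frame with

$$G = \underbrace{E_{bonds} + E_{angles} + E_{dihedrals} + E_{vdW} +
E_{elec}}_{E_{MM}} + \underbrace{G_{polar} + G_{nonpolar}}_{G_{solv}},$$

where $G_{polar}$ comes from a generalized Born model (GB-Neck2 class,
below) and $G_{nonpolar} = \gamma\,\mathrm{SASA} + b$ with
$\gamma = 0.0072$ kcal mol$^{-1}$ Å$^{-2}$, $b = 0$.
All three subsystems are evaluated on the frames of the *complex*
trajectory, so every bonded term — and every gas-phase pair interaction
internal to a subsystem, including water–water and water–receptor terms
when waters ride with the receptor — cancels identically in the
difference. The package verifies that cancellation numerically in each run
and records the bonded deltas as exact zeros. The configurational entropy
term $-T\Delta S$ of the full decomposition
$\Delta G = \Delta H - T\Delta S$ is *not computed*; the fitted object
reports it as `NA`, never as zero, because only relative ranking across
complexes is claimed.

## Ensemble analysis and Mix-and-Match assembly

Unbound-chain trajectories are clustered with the GROMOS
(neighbor-counting) algorithm on the pairwise C$\alpha$ RMSD matrix at a
1 Å cutoff: the frame with the most neighbors within the cutoff becomes a
center, its neighborhood is removed, and the procedure repeats. Two
choices the original algorithm leaves open are fixed for determinism:
neighbor-count ties break on the lowest frame index, and the
"representative" conformer is the *center of the most populated cluster*
(first-formed cluster on size ties). RMSD uses mass-unweighted Kabsch
superposition with the rotation forced proper (no reflections).

MnM assembly superposes each representative chain onto the corresponding
chain of the crystal complex using the backbone heavy atoms (N, CA, C, O)
of residues matched by chain and residue index — the standard two-chain
renumbering (chain B continues after chain A) makes that correspondence
exact, so no sequence alignment is attempted. Placement is chain-local and
the output preserves crystal atom order, which lets one topology serve the
whole downstream pipeline. Reassembled complexes can clash; the package
reports all interchain heavy-atom pairs below a threshold (grid-based
neighbor search, verified against an all-pairs scan) and expects the user
to relax and re-simulate the assembly externally. That production
simulation is an explicit hand-off: `run_scheme()` ingests the resulting
complex trajectory, it never simulates.

Time windows follow the protocol's three schemes: clustering over 0–12 ns
(`mnm1`) or 80–100 ns (`mnm2`) of the 100 ns unbound-chain runs, and
end-point averaging over 100 evenly spaced frames from 3–4 ns (`scheme0`,
crystal-start) or 40–50 ns (MnM schemes). Windows are half-open in time,
$[t_0, t_1)$, so adjacent windows never double-count a frame; within a
window the first and last frames are always selected.

## Interface, waters, partition

A residue is interfacial when its solvent-accessible surface area in the
isolated chain exceeds its SASA in the complex by more than 0.50 Å²,
computed once on the analysis frame (per-frame recomputation is a flag;
the default mirrors the single published listing per complex). SASA is
Shrake–Rupley on a deterministic Fibonacci sphere lattice (default 960
points), heavy atoms only, probe 1.4 Å, per-element radii
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å). A fixed per-atom
golden-angle spin of the lattice, keyed on the atom's identity, keeps the
quadrature error of an atom identical between the isolated-chain and
complex evaluations, so interface detection sees signal, not lattice
noise. Doubling the point count changes fixture totals by under 0.2%;
absolute SASA values remain implementation-dependent across tools, which
is why only *differences* carry meaning here.

The retained solvent is the $n = 30$ water molecules whose oxygen lies
closest to the mass-weighted center of the interfacial residues, selected
independently per frame (membership may change frame to frame), with
distance ties broken on the water's molecule index. The oxygen is used as
the water's reference point because for 3-site waters it coincides with
the molecular center of mass to within a few hundredths of an Ångström; a
center-of-mass mode is available. Waters always join the *receptor*:
assigning them to the smaller partner is known to inflate frame-to-frame
scatter without improving ranking. The partition invariant
(complex = receptor ⊎ ligand, waters ⊂ receptor) is asserted in tests for
every frame.

## Energetics

Gas-phase terms use the Amber functional forms: harmonic bonds and angles,
periodic dihedrals $pk(1 + \cos(n\phi - \gamma))$, 12-6 Lennard-Jones with
$r_{min} = r^{i}_{min}/2 + r^{j}_{min}/2$ and
$\varepsilon = \sqrt{\varepsilon_i \varepsilon_j}$, Coulomb constant
332.0636 kcal Å mol$^{-1}$ e$^{-2}$, 1-2/1-3 exclusions, 1-4 scaling by
1/1.2 (electrostatic) and 1/2.0 (van der Waals). No distance cutoff is
applied — cutoffs belong to trajectory generation, not to the end-point
average. Charges are stored in elementary-charge units; the Amber
18.2223 conversion exists only at parameter-topology I/O. All internal
indexing is 1-based, the native R convention; 1-based file conventions
pass through unchanged.

The polar solvation term is a GB-Neck2-class generalized Born model.
Effective radii come from pairwise HCT descreening over reduced intrinsic
radii $\tilde\rho = \rho - 0.195141$ Å (mbondi3 intrinsic radii expected
in the topology), a neck correction for the solvent-excluded crevice
between near-contact spheres, and the tanh rescaling

$$R_i^{-1} = \tilde\rho_i^{-1} - \rho_i^{-1}
\tanh(\alpha\Psi - \beta\Psi^2 + \gamma\Psi^3), \qquad
\Psi = I_i\,\tilde\rho_i,$$

with per-element $\alpha,\beta,\gamma$ and screening factors shipped as a
versioned table (`inst/extdata/gbneck2_params.tsv`). The neck term uses
the usual fitted bump $m_0 / (1 + 100(d-d_0)^2 + 3\times10^5 (d-d_0)^6)$;
because the $(d_0, m_0)$ lookup of the reference implementation is not
published as printable text, the package *derives* it at run time: for
each unique radius pair it integrates $r^{-4}$ over the exact
solvent-excluded neck region between two spheres (probe 1.4 Å) by 2-D
quadrature, locates the maximum over separation, and caches the result.
This reproduces the model's geometric definition rather than transcribing
a binary table; the HCT part of the integral is independently verified
against quadrature in the tests to $10^{-3}$ Å on effective radii.

The pair energy uses the still-exponential form
$f_{ij} = \sqrt{r_{ij}^2 + R_iR_j \exp(-r_{ij}^2/4R_iR_j)}$, $f_{ii} =
R_i$, interior dielectric 1.0, solvent dielectric 78.5, and salt screening
$\exp(-\kappa' f)/\epsilon_{out}$ with
$\kappa = \sqrt{0.10806\,c_{salt}}$ Å$^{-1}$ (Debye–Hückel at 298.15 K)
scaled by the conventional 0.73 to correct the overscreening of that
functional form; 0.15 M is the default. Effective radii and SASA are
recomputed per subsystem — the standard single-trajectory convention —
rather than masked from the complex; the alternative masking convention
would make the GB cross-sum exactly additive but is not what reference
end-point codes do.

Deeply buried atoms can drive the rescaled inverse radius toward zero;
the implementation clamps effective radii at 1000 Å, the same guard the
reference codes apply.

### Pairwise decomposition

The cross-partition interaction is attributed to receptor/ligand residue
pairs: van der Waals and electrostatics as direct atom-pair sums, GB by
attributing each $i \in a, j \in b$ term of the double sum evaluated with
*complex* radii. GB self terms stay with their own residue and never enter
the pair table. Conservation — pair sums equal the cross-partition part of
each component to $10^{-6}$ kcal/mol — is asserted per frame in the tests.

## Affinity benchmarking

Experimental affinities convert through $\Delta G \approx RT\ln K_D$ with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$; $K_i$ and IC$_{50}$
are treated as $K_D$ surrogates, the usual benchmark convention. The
conversion temperature defaults to 298.15 K; the protocol's preparation
step uses 300 K but the conversion temperature is nowhere pinned, and the
difference is under 0.1 kcal/mol across the benchmark's affinity range.
$r^2$ is the squared Pearson correlation (equivalently the unadjusted
$R^2$ of the univariate least-squares fit). Relative binding free
energies pair complexes either as all $n(n-1)/2$ unordered differences
(default) or against a chosen reference; both are provided because the
pairing convention is genuinely open, and constant offsets cancel either
way. Leave-one-out exclusion is recorded in the report to keep outlier
analyses explicit.

## What the synthetic fixtures emulate — and what they do not

The generators build pseudo-peptide dimers (3–4 atoms per residue, fully
printed charges, LJ, bonded terms and Born radii), conformer-mixture
trajectories with known population weights and jitter, and 3-site waters
(O–H 0.9572 Å, H–O–H 104.52°) at prescribed distances from a stated
point, with ground truth (conformer labels, water rankings, designed
contacts) emitted alongside the data so tests never re-derive it from the
code under test. Pseudo-residues keep the brute-force oracles — all-pair
energies, quadrature GB, analytic two-sphere SASA — exact and fast.

Passing these tests demonstrates the *machinery* is correct: clustering,
assembly, selection, energies and statistics do what their definitions
say. It does not demonstrate force-field realism, nor that desk-scale toys
reproduce published per-complex energies — those require the original
50–100 ns explicit-solvent ensembles of twenty real complexes. The
benchmark correlation statistics are therefore reproducible here only
from a transcription of the published per-complex means, of which only
the experimental side (the 20-entry affinity table) is printed in the main
text and shipped; the package's acceptance suite states this explicitly
rather than substituting a weaker check.

## Numerical choices and problem sizes

- SASA: 960 lattice points by default; fixture checks use 120–480 where
  only differences matter. Single-sphere error is below 0.5%, two-sphere
  overlap within 1% of the closed form.
- Neck quadrature: 240 × 120 grid per separation, 24-point coarse scan
  plus golden-section refinement for the maximum, cached per radius pair.
- Test and acceptance runs use toy systems of 30–140 atoms, trajectories
  of 10–200 frames; the full suite completes in about half a minute and
  the acceptance script in well under a minute on one CPU.
- Degenerate inputs are errors, not warnings: fewer than 3 fit atoms,
  collinear selections, non-positive Born radii, empty interfaces,
  truncated trajectory files, bonded terms straddling a partition.
- Determinism: every stochastic fixture takes a seed; reports are
  bit-identical on rerun with the same inputs and configuration.

## Known limitations

Poisson–Boltzmann solvation, normal-mode entropy, QM corrections and
alchemical routes are out of scope. The PDB reader handles the fixed
column layout only (no mmCIF, no NetCDF trajectories). The GB neck table
is derived from the geometric definition, not transcribed from a
reference binary, so third-party codes will differ at the margin of that
correction. Absolute SASA values are radii-set dependent; only
differences are used by the method.
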