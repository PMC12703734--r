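Package: mnmgbsa
Title: Mix-and-Match MM-GBSA Binding Free Energies for Protein-Protein
    Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-simulation toolkit for end-point MM-GBSA binding free
    energies of protein-protein complexes with Mix-and-Match (MnM)
    conformational sampling and explicit interfacial-water retention.
    Reads PDB structures, Amber parameter-topology files and Amber ASCII
    trajectories; clusters unbound-chain ensembles with the GROMOS
    (Daura) algorithm; rebuilds complexes from representative conformers
    by backbone superposition; detects interfacial residues by
    solvent-accessible surface-area change and retains the waters
    closest to the interface centre of mass as part of the receptor;
    evaluates single-trajectory MM-GBSA energetics with the GB-Neck2
    generalized Born model, a linear surface-area nonpolar term and
    pairwise per-residue decomposition; and benchmarks predictions
    against experimental affinities (K_D to free-energy conversion,
    squared-correlation and relative binding free energy reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, bio3d
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
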