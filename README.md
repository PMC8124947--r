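# kemlead

Fragment-based prediction of lead structures for protein–ligand docking,
using the counterpoise-corrected Kernel Energy Method (KEM-CP).

Scoring functions used in molecular docking are fast but unreliable: the
best-scored pose of a ligand is often not the pose found in the crystal
structure, and how badly a score fails depends on the chemistry of the
binding pocket.  A fragment-based quantum-crystallographic alternative is
to *compute* the protein–ligand interaction energy directly.  The complex
is partitioned into **kernels** — single active-site residues plus the
ligand, with severed covalent bonds capped by hydrogens — and energies of
single and double kernels are reassembled:

- total energy of `n` kernels:
  `E_total = Σ_{i<j} E_ij − (n − 2) Σ_i E_i`
- pairwise interaction energy: `I_ij = E_ij − E_i − E_j`
- protein–ligand interaction energy: the sum of `I_ij` over all
  ligand–residue kernel pairs.

Each pair energy is evaluated both raw and with the Boys–Bernardi
counterpoise (CP) correction for basis-set superposition error; the
average of the two is the headline "averaged IE" (more negative =
stronger predicted binding).  A docked pose family ("orientation type")
selected by the most negative averaged IE is adjudicated *correct* when
its in-place heavy-atom RMSD to the crystallised ligand is ≤ 2.0 Å, and
ligand rankings by IE or by docking fitness are compared against
experimental IC50 values by rank correlation.

The package is aimed at structural bioinformaticians and computational
chemists who want to re-score docked poses with kernel energies: it
handles structure preparation (major conformer, solvent stripping,
active-site sphere), fragmentation and H-capping, Gaussian-dialect
counterpoise job writing and log parsing, pose clustering and RMSD
adjudication, and ranking against IC50.  It also ships an exactly
pairwise-additive classical backend (point charges + Lennard-Jones) and a
synthetic-data generator, so the whole pipeline is verifiable end to end
on a desk machine: for any pairwise-additive potential the KEM assembly
is algebraically exact, which turns the reconstruction into a
machine-precision test.

## Worked example

Adjudicate the packaged human-aldose-reductase benchmark (five ligands,
two orientation types each, docking fitness scores and averaged IEs per
type, RMSDs to the crystallised ligand):

```r
library(kemlead)
har <- lead_table("hAR")
adjudicate(har, rmsd_cutoff = 2.0)
#>   ligand_id fitness_type fitness_rmsd fitness_correct ie_type ie_rmsd ie_correct
#> 1        10            1        0.223            TRUE       1   0.223       TRUE
#> 2        16            1        0.263            TRUE       1   0.263       TRUE
#> 3        19            1        0.137            TRUE       1   0.137       TRUE
#> 4        24            2        2.342           FALSE       1   0.943       TRUE
#> 5        25            2        2.603           FALSE       1   1.180       TRUE
summarize_target(har)
#>   n_ligands fitness_correct ie_correct fitness_pct ie_pct
#> 1         5               3          5          60    100
```

For ligands 24 and 25 the docking score prefers a pose type displaced by
more than 2 Å from the crystal geometry (incorrect), while the most
negative averaged IE picks the near-native type for all five ligands:
3/5 (60%) correct by fitness score versus 5/5 (100%) by interaction
energy.

The same machinery runs on generated data.  A seeded toy complex, cut
into kernels and scored with the classical backend:

```r
spec <- synthetic_spec(seed = 42)
cx <- make_complex(spec)
kerns <- fragment_complex(complex_units(cx, roles = "protein-residue"),
                          ligand_unit(cx))
recs <- classical_energy_records(kerns, pairs = "ligand")
protein_ligand_ie(kerns[[1]], kerns[-1], recs)
#> KEM-CP protein-ligand IE: -127.0504 kcal/mol over 5 pairs
```

The per-residue table (`$ie_pairwise`) shows the salt-bridge contact
dominating at −125 kcal/mol with the remaining residues contributing a
few kcal/mol each — and `raw`, `cp` and `averaged` columns agreeing
exactly, since a classical potential has no basis sets to superpose.

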