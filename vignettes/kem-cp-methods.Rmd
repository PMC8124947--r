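---
title: "Kernel energies for pose adjudication: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel energies for pose adjudication: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kemlead)
```

## The model

The Kernel Energy Method reconstructs the energy of a macromolecular
system from fragments small enough to compute accurately.  The complex is
partitioned into *kernels* — here always one active-site residue per
kernel plus the ligand as its own kernel — such that every atom belongs
to exactly one kernel.  With single-kernel energies $E_i$ and
double-kernel (dimer) energies $E_{ij}$,

$$E_\mathrm{total} = \sum_{i<j} E_{ij} \;-\; (n-2)\sum_{i=1}^{n} E_i,
\qquad
I_{ij} = E_{ij} - E_i - E_j,
\qquad
I_\mathrm{protein\text{-}ligand} = \sum_{j \ne \mathrm{lig}} I_{\mathrm{lig},j}.$$

The double sum over pairs counts each $E_i$ exactly $n-1$ times, so the
correction term leaves each single-kernel energy represented once plus
all pairwise couplings — for any *pairwise-additive* energy model the
reconstruction is an algebraic identity, not an approximation.  That is
the central internal oracle: with the built-in classical backend,
`kem_total_energy()` must agree with the brute-force all-atom energy to
numerical round-off (we assert $10^{-9}$ relative; observed
$\sim10^{-15}$), and `protein_ligand_ie()` must equal the explicit
ligand–site cross-term.  At a quantum level of theory the identity
becomes an approximation that neglects three-body terms; nothing in the
assembly changes.

Dimer energies computed in finite basis sets acquire basis-set
superposition error.  The counterpoise (CP) scheme corrects it by
evaluating monomers in the dimer basis; since the raw value typically
overbinds and the CP-corrected value underbinds, the package follows the
convention of averaging the two, and this *averaged IE* is the headline
quantity everywhere (`(raw + cp)/2`, with both components retained for
audit).  A classical backend has no basis sets, so there `cp == raw` and
the average must equal the raw IE identically — a deliberate degeneracy
used to validate the averaging plumbing.

`pair_interaction_energy()` accepts either convention through the
record's `kind` field: backends reporting *total* dimer energies
(classical) are differenced against the monomers, while backends
reporting *complexation* energies directly (the counterpoise log parser)
are passed through.  Summing averaged IEs per pair and then totalling, or
totalling raw and CP sums and then averaging, is the same number for a
fixed pair set; the distinction only matters when pairs fail, and the
package always reports failed pairs explicitly (`missing_pairs`,
`complete = FALSE`) rather than silently renormalising.

## Structure preparation and fragmentation

Preparation mirrors standard practice: keep the highest-occupancy
alternate conformer (ties broken to the alphabetically first altloc code,
so the choice is reproducible), strip solvent and ions by residue-name
whitelist, and select the active site as every protein residue with at
least one atom within a closed-boundary radius (default 5 Å) of the
center unit, by minimum atom–atom distance.  Atom–atom rather than
centroid distance matches docking-software convention; the closed
boundary makes the "exactly at radius" case inclusive.  Waters are
removed entirely by default — including potential bridging waters; a
retained-water analysis is possible by simply not calling
`strip_solvent()`, since solvent units fragment like residues.

Fragmenting residue-per-kernel severs the backbone.  The cut site is the
peptide amide C–N bond between consecutive residues: the acyl side is
capped with a hydrogen on its carbonyl carbon, the amine side on its
nitrogen.  Amide cuts are the standard kernel choice because they leave
side chains — the chemistry that binds the ligand — intact.  Caps are
placed exactly on the severed-bond ray at fixed lengths (C–H 1.09 Å,
N–H 1.01 Å, O–H 0.96 Å, S–H 1.34 Å; standard covalent values,
config-overridable), and the cap direction is asserted to coincide with
the bond direction to $10^{-9}$ rad.  Formal charges come from
physiological-pH templates (ASP/GLU −1, LYS/ARG +1, HIS 0) with an
explicit override path for ligands and non-standard residues;
multiplicity defaults to 1, as every system considered is closed-shell.

## Energy backends

The classical backend evaluates
$\sum_{i<j} k\,q_i q_j / r_{ij} + 4\varepsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} - (\sigma_{ij}/r_{ij})^6]$
with $k = 332.0636$ kcal·Å·mol⁻¹·e⁻², Lorentz–Berthelot combination, and
deliberately *no* cutoff or switching function: exact pairwise
additivity is the property that makes the KEM reconstruction exact, so
nothing may break it.  Cap hydrogens carry their own parameters and
participate fully.

The external-QM interface writes two-fragment counterpoise inputs in the
Gaussian dialect (route line with the level of theory and
`Counterpoise=2`, combined charge/multiplicity header listing the pair
total and then each fragment, atom lines tagged `(Fragment=n)`, caps
travelling with their kernel) and parses the matching logs.  The parser
reads `complexation energy = … (raw)` / `(corrected)` summary lines in
Hartree and converts by 627.5095 kcal·mol⁻¹; a log without a
normal-termination marker, or with unparseable energies, becomes a
record with `status = "failed"` — never an exception — because a failed
pose must propagate as a missing value that downstream selection skips.
A synthetic log writer (`write_synthetic_cp_log()`, labelled synthetic)
exists solely so the writer→log→parser path is testable without a
quantum-chemistry program.

## Poses, RMSD and adjudication

Pose similarity uses **in-place** heavy-atom RMSD: no Kabsch
superposition, because the question is whether a pose reproduces the
crystallised ligand's *localization* in the binding site, not whether
its conformation is similar somewhere else in space.  Two documented
limitations follow: symmetry-equivalent atoms are not corrected for, and
comparing a pose of one ligand against the crystal geometry of a
*different* reference ligand requires an explicit user-supplied atom
correspondence over the shared scaffold (no automatic
maximum-common-substructure inference, which fails silently too often).

Grouping poses into orientation types is, in manual practice, a visual
call.  The package substitutes a reproducible stand-in: greedy leader
clustering in order of descending fitness, joining a type when the RMSD
to its representative is within a threshold (default 2.0 Å, aligned with
the correctness criterion) and founding a new type otherwise.  The
founder of each type is by construction its best-fitness member, and
type indices come out ordered by representative fitness — Type 1 is the
docking program's favourite orientation, matching the tables'
convention.  Best-pose selection then takes either the highest
representative fitness or the most negative averaged IE (failed IEs
skipped; ties resolved to the lowest type index, with a message), and a
selection is *correct* when its RMSD to the crystal geometry is
≤ 2.0 Å.  Percentages in `summarize_target()` are integer-rounded, the
convention of the benchmark tables (6/7 prints as 86%).

Rankings: IC50 ascends (smaller = more potent), averaged IE ascends
(more negative = better), fitness descends; ties share the mean rank.
`rank_agreement()` reports Spearman's rank correlation as a percentage
by default, with Kendall's τ available and the method recorded in the
output.  The benchmark literature's own correlation percentages are
method-unspecified, so the package reports its correlations labelled
with the method rather than asserting equality with any published
percentage.  IC50 uncertainties are carried for display but ignored in
ranking.

## The packaged benchmark tables

`lead_table()` loads transcriptions of the published per-ligand records
for three targets of deliberately different active-site character —
human aldose reductase (hAR, moderately hydrophobic, five ligands, two
pose types), cyclin-dependent kinase 2 (CDK2, hydrophilic, seven
ligands, three types) and estrogen receptor β (ERβ, strongly
hydrophobic, ten ligands, four types) — as long-format CSV: one row per
ligand and orientation type with averaged IE, fitness score, docking
rank, RMSD to the crystal ligand and IC50.  A type with no poses (CDK2
ligand 28, Type 2) has no row; a type whose IE calculation failed (CDK2
ligand 34, Type 3) has `NA` in `avg_ie` and is skipped by IE selection
but remains eligible for fitness selection.  Running
`adjudicate()` + `summarize_target()` on these tables reproduces the
per-target correct-pose counts (3/5 vs 5/5, 7/7 vs 6/7, 7/10 vs 9/10),
which the test suite asserts exactly.

```{r benchmark}
do.call(rbind, lapply(c("hAR", "CDK2", "ERbeta"), function(t)
  cbind(target = t, summarize_target(lead_table(t)))))
```

## The synthetic generator

`make_complex()` builds a toy active site: a ligand of 6 atoms at the
origin, residues of 4 atoms each with centres 4.5–6.5 Å out on random
directions, intra-unit spacing ≥ 1 Å (bonded scale) and inter-unit
clearance ≥ 2.8 Å (van der Waals scale), regenerating a residue's
placement up to 100 times before giving up.  Parameters are drawn from
bounded uniform ranges (|q| ≤ 0.5 e, σ ∈ [2.5, 3.5] Å,
ε ∈ [0.05, 0.3] kcal·mol⁻¹).  Partial charges are mean-centred within
each unit so every unit is net-neutral and long-range tails are
multipole-only; on top of that, the default salt-bridge option adds a
+1/−1 pair on the closest ligand–site atom contact, giving the bound
placement an unmistakable electrostatic signature.  Formal charges are
exercised by renaming residues to LYS/ASP until the configured total
charge is met.

`make_pose_set()` emulates a docking run of 30 poses in 3 orientation
types: the bound family at the reference placement, decoy families
rigidly rotated and displaced by 8 Å per type index along the candidate
direction with the most clearance from the site (so decoys never collide
with the protein shell), and per-coordinate Gaussian jitter of 0.3 Å
within a family.  The 8 Å displacement is required to exceed
$2(\text{jitter} + 2\,\text{Å})$, so planted families can never straddle
the 2 Å clustering radius.  Fitness is monotone decreasing in each
pose's true classical interaction energy plus optional noise; truth
labels are numbered with the same best-fitness convention the clusterer
documents, so "clustering recovers the labels" is a well-defined exact
comparison, and the planted binding family's label is returned as
`binding_type`.

`make_ic50()` maps interaction energies to IC50 as
$\mathrm{IC50} = \exp(a + b\,\mathrm{IE} + \varepsilon)$ nM with
$a = 5$, $b = 0.05$ per kcal·mol⁻¹ and $\varepsilon \sim N(0,\sigma)$.
The slope is the generator's calibration: at $\sigma = 0.5$ a 10-ligand
panel's IE/IC50 Spearman correlation averages near 80% over replicates —
inside the 60–95% band that brackets the rank-correlation regime
reported for real targets — while $\sigma = 0$ reproduces the IE ranking
exactly.

What the generator does *not* emulate matters for interpreting green
tests: there is no covalent topology (toy residues are disconnected atom
clusters, so backbone capping is exercised on constructed bonds rather
than on generated complexes), no conformational flexibility within a
pose family beyond isotropic jitter, no MP2-scale energetics, and
classical parameters rather than chemistry.  Passing tests therefore
demonstrate that the assembly, clustering, adjudication and ranking
machinery is correct and exact for pairwise-additive energies — not that
any particular quantum result on a real complex is reproduced, which
requires the external-QM route.

```{r pipeline}
spec <- synthetic_spec(seed = 42)
cx <- make_complex(spec)
kerns <- fragment_complex(complex_units(cx, roles = "protein-residue"),
                          ligand_unit(cx))
recs <- classical_energy_records(kerns, pairs = "ligand")
protein_ligand_ie(kerns[[1]], kerns[-1], recs)
```

## Numerical choices and problem sizes

Constants: Coulomb 332.0636 kcal·Å·mol⁻¹·e⁻², Hartree→kcal·mol⁻¹
627.5095.  Coincident atoms (r = 0) and cross-kernel atom overlap are
hard errors; severed bonds must cross the kernel boundary exactly once.
Energy identities are asserted at $10^{-9}$ relative (observed
$\sim10^{-15}$); the CP-degeneracy check is exact (`identical`); the
distant-kernel IE bound is $10^{-6}$ kcal·mol⁻¹ at 100 Å for an
uncharged kernel, where only the $r^{-6}$ dispersion tail
($\sim10^{-9}$ kcal·mol⁻¹) survives.  A *neutral* kernel here means
uncharged atoms: a merely net-neutral charged kernel retains
dipole–dipole tails of order $10^{-4}$ kcal·mol⁻¹ at that range, which
is physics, not error.  The test suite and the acceptance script use 50
random complexes of 3–8 kernels for the exactness sweeps and 20
replicates of 30-pose sets for recovery rates — sizes at which the whole
suite runs in seconds while every property is exercised across dozens of
random geometries.

## Known limitations

No symmetry-aware RMSD; no automatic atom mapping across different
ligands; single-residue kernels only (no multi-residue kernels, no
covalently bound ligands); no three-body KEM corrections; the classical
backend is a validation instrument, not a force field — its parameters
are synthetic and its IEs are not comparable to quantum results; job
files and logs follow one Gaussian-style dialect, and logs from other
programs need converting.  Protonation and tautomer assignment are out
of scope: kernels receive caps, not full protonation.
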