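---
title: "Methods: disulfide and structural dynamics analysis of a saposin-fold dimer"
author: "psitraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disulfide and structural dynamics analysis of a saposin-fold dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psitraj)
```

## The system and the questions

Saposin-like proteins share a four-to-five amphipathic-helix fold stapled
by three conserved disulfide bonds. The plant-specific insert (PSI) of
plant aspartic proteases — the potato variant is the motivating system —
forms an "open" homodimer whose two ~100-residue monomers expose a shared
hydrophobic inner face, with a long disordered loop (residues 40–63)
between helices 2 and 3. Two questions drive the analyses implemented
here: what do the three disulfide bonds (Cys6–Cys99, Cys31–Cys71,
Cys37–Cys68) contribute to the structure in solution, and how does that
depend on pH (vacuolar 3.0 vs cytosolic 7.4)?

The package post-processes trajectory ensembles of such a dimer under the
eight disulfide-reduction conditions — `AI` (all intact), `D1`–`D3` (one
bond reduced), `D4`–`D6` (two), `AR` (all reduced) — returned by
`condition_codes()`. It does not run molecular dynamics; inputs are
multi-model PDB ensembles, a frame-CSV dialect, and per-frame DSSP
assignments, or the package's own synthetic generator.

## Analysis procedures

### S-gamma separations and reformability

For each cysteine pair the Euclidean separation of the two sidechain
sulfur atoms (S-gamma) is computed per frame and chain
(`sg_distances()`). An intact disulfide bond sits at 0.2038 nm. Series
are histogrammed on a shared uniform grid (bin width 0.01 nm) after
per-series normalisation to unit sum, so monomers and replicates of
unequal length pool cleanly; `pooled_histogram()` reports the per-bin
mean and standard deviation across the pooled series (n = chains ×
replicates = 6 in the three-replicate design).

`reformability()` renders the geometric call: the fraction of samples
with separation below 0.4 nm (4 Å), with the qualitative verdict "likely
reform" when at least half the samples fall below the cutoff. Geometry
motivates only the 4 Å cutoff; the 0.5 verdict threshold is this
package's explicit rule, and the underlying fraction is always reported
so the verdict stays auditable.
The same screen applied to the two sterically feasible non-native
pairings (Cys31–Cys37, Cys68–Cys71; `interchange_distances()`) assesses
disulfide interchange.

### Loop-partitioned structure metrics

Because the 40–63 loop is intrinsically disordered, every global metric
is computed with and without it. `rmsd_series()` superposes each frame on
the reference using **only non-loop backbone atoms** (Kabsch
least-squares with the proper-rotation constraint, `superpose()`) and
measures backbone RMSD over either the full backbone or the non-loop
backbone. `radius_of_gyration()` is mass-weighted, over all atoms or
excluding the loop. `com_separation()` reports mass-weighted centroid
distances (monomer–monomer with/without loop, or helix–helix).
Trajectory-level summaries are reported as mean ± SEM with n = number of
replicates; residue-level profiles as mean ± SD with n = chains ×
replicates.

`rmsf_profile()` computes per-residue fluctuation about the time mean
after superposition. Its `"pc1"` mode reconstructs the trajectory from
its projection onto the first eigenvector of the coordinate covariance
(essential-dynamics filtering) before applying the same formula. This is
covariance PCA on the analysis window — fitting the trajectory to its
first eigenvector — not Hessian normal-mode analysis, and the filtered
profile is never larger than the raw one, a property the test suite
asserts.

Two details are deliberately parameters rather than constants, because
conventions genuinely vary: the analysis window (tails of 10 ns and
50 ns are both common in this literature; the default here is the last
10% of the supplied trajectory, via `select_window()`, whose time
threshold is inclusive so the final frame is always kept), and the RMSD
reference structure (default: the first frame of the supplied
trajectory).

### Secondary-structure variation

DSSP letters are collapsed into three classes: H/G/I → helix (3-10 and
pi helices count as helical character), E/B → beta, T/S/C/blank/~ →
disordered. The variation index of a residue is the count of
class-change events between consecutive frames, normalised by the
maximum possible count, frames − 1 — the constant 1000 for a 1001-frame
window arises, it is never hard-coded. Change events could be counted at
the DSSP-letter level or at the class level; the class level is adopted
(the index is defined over the three classes), so letter changes within
a class (H→G) are not events. Pooling across both
monomers of all replicates yields the per-residue mean ± SD (n = 6).
`ss_mode()` reports the per-residue modal class with a fixed, documented
tie-break precedence helix > beta > disordered; `region_summary()` and
`dimer_net_variation()` give interval totals (and per-residue averages)
and the whole-dimer sum.

### Contact censuses

Three interaction types are counted per frame, at residue-pair
granularity (a pair within the criteria counts once per frame regardless
of how many atom pairs qualify — the natural unit of a minimum-distance
contact map):

* **Hydrogen bonds** — donor–acceptor N/O pairs within 0.35 nm with
  H–donor–acceptor angle ≤ 30° (the defaults of standard MD H-bond
  counting; the H–D–A angle convention is adopted and documented — some
  tools use D–H–A instead). When the input carries
  no hydrogens, an idealised donor-H along the donor–acceptor axis is
  assumed — the angle criterion then always passes — and the output is
  flagged (`approx_hydrogens`). Pairs separated by fewer than 2 residues
  within a chain are excluded as trivially bonded neighbours.
* **Hydrophobic contacts** — minimum heavy-atom sidechain–sidechain
  distance ≤ 0.45 nm, both residues in the wholly hydrophobic set. The
  default set {Ala, Val, Leu, Ile, Pro, Phe, Met, Trp} excludes Gly (no
  sidechain), Tyr (hydroxyl) and amphipathic sidechains such as Lys,
  whose aliphatic stem is explicitly not counted; the set is
  configurable because no canonical list exists.
* **Salt bridges** — minimum distance ≤ 0.45 nm between the sidechain
  oxygens of a **deprotonated** acid and a residue-specific basic site:
  Lys NZ; Arg, the centre of mass of the three guanidinium nitrogens;
  His, the centre of mass of ND1, NE2 and CE1 (the delta/epsilon
  nitrogens and the epsilon carbon sharing the charge). Eligibility
  follows the protonation map: the pH 3.0 default neutralises every
  carboxylate (so salt bridges are impossible without overrides), and
  His is omitted entirely at pH 7.4 where it is neutral.

A conservative cation-pi screen (`cation_pi_screen()`: charged basic
site within 0.6 nm of a Phe/Tyr/Trp six-ring centroid, no angular term)
is advisory by design: it reports candidates only and never enters the
census totals.

Every counted pair is labelled intra-monomer A/B or inter-monomer
(exhaustive and disjoint), and additionally intra-loop (both residues in
the loop of the same chain) or loop–non-loop (exactly one loop residue,
either chain — a loop reaching across the interface counts here).
Summaries pool per-frame counts: across replicates for inter-monomer
categories (n = 3), across monomers × replicates for the rest (n = 6),
with the SD taken over the pooled per-frame counts, matching how such
tables are reported.

### Protonation model

`assign_protonation()` is categorical and rule-based: at pH 3.0 all
Asp/Glu are protonated/neutral (the loop acidics Asp40, Glu54, Glu56,
Glu58 and the pH-sensor Glu72 included) and His is charged; at pH 7.4
Asp/Glu are charged and His neutral; Lys/Arg are charged at both. No pKa
values are computed — residue-level pKa sets from any external
calculation can be plugged in through per-residue overrides, which are
flagged by provenance. Termini appear in the map for completeness but
the pseudo-atom topology carries no terminal atoms, so they never enter
contact counts.

## The synthetic generator

`make_trajectory()` and `make_ss_series()` exist so that every analysis
stage can be exercised against known ground truth without MD output.
The generator emulates the study system — a 2 × 104-residue dimer with
cysteines at 6/31/37/68/71/99, acidic residues at 40/54/56/58/72, loop
40–63, four helices — as pseudo-atom scaffolding: backbone N/CA/C/O on
ideal helix geometry (rise 0.15 nm/residue, 100°/residue twist) plus the
minimal named sidechain atoms the analyses address (S-gamma, basic
nitrogens, carboxylate oxygens, ring atoms, CB).

Ground truth is planted in four ways, all seeded and bit-reproducible:

* per-residue isotropic Gaussian displacements with a prescribed sigma
  profile (defaults: helices 0.035–0.058 nm, loop tent-shaped
  0.10–0.145 nm, linkers 0.060–0.075 nm, strictly graded so the profile
  has no ties), spatially smoothed over ±3 residues with per-residue
  variance preserved exactly — the smoothing keeps bonded geometry sane
  without changing the amplitudes the RMSF must recover (raw RMSF →
  sigma × sqrt(3));
* S-gamma pair separations drawn from per-condition laws
  (`condition_sg_laws()`): intact pairs pinned at 0.2038 nm; reduced
  6–99 near 0.50 nm, reduced 31–71 near 0.35 nm, reduced 37–68 at
  0.40 nm (pH 3.0) vs 0.50 nm (pH 7.4) and broader once its partners
  are also gone — centres follow the observed behaviour of the system;
* planted contacts enforced exactly every frame: an inter-monomer
  hydrophobic pair at 0.40 nm and a Glu–Lys salt bridge at 0.42 nm,
  plus decoys of both kinds at 0.54 nm (1.2 × the cutoff) that must
  never be detected;
* per-residue two-state Markov secondary structure (helices H↔C at
  switch probability 0.01, loop C↔G at 0.02, linkers C↔H at 0.08). Loop
  residues exit the transient 3-10 state faster (probability 0.25 by
  default) so they are disordered-dominant; with symmetric chains
  (`loop_alt_exit = NULL`) the expected normalised variation equals the
  switch probability exactly, which is what the Markov-recovery tests
  exploit. Secondary-structure dynamics are deliberately independent of
  the disulfide condition: the generator embodies the null model in
  which reduction leaves net secondary structure unchanged.

What the generator does **not** emulate: forces, solvent, thermostats,
correlated collective motions beyond the first-order spatial smoothing,
rotamer chemistry, or any coupling between disulfide state and backbone
dynamics beyond the S-gamma laws. Passing tests therefore demonstrate
that the estimators recover what was planted at realistic magnitudes —
not that the biology of the real system is reproduced.

## Numerical choices and degenerate inputs

* Histogram grids span [0, ceil(max/width)·width]; per-bin spread is the
  sample SD (n − 1), switchable to population SD.
* Superposition requires ≥ 3 non-collinear fit atoms; degeneracy is
  detected from the singular values and rejected. Reflections are never
  used (det = +1 enforced).
* The broken-periodic-image guard in `read_ensemble()` rejects frames
  with any consecutive intra-chain CA–CA step above 0.7 nm: genuine
  breakage jumps by box lengths (several nm), while 0.7 nm stays safely
  above thermal fluctuation of an intact chain, so the guard separates
  the two cleanly.
* Coincident S-gamma atoms yield distance 0 with a degeneracy warning;
  empty selections, empty windows, roster mismatches (named by model or
  frame), unknown condition codes and overrides for nonexistent residues
  are all rejected with informative errors.
* Windows are selected by time with an inclusive threshold; fraction 1.0
  is the identity.

## Problem sizes

The shipped analyses and tests use 2 × 104 residues (~1100 pseudo-atoms),
1001 frames per replicate, three replicates per condition, tail windows
of 10% (101 frames), and 2000 frames for the fluctuation-recovery
experiment — sizes chosen so a full condition sweep completes in minutes
on a single core while keeping Monte-Carlo error well inside the test
tolerances. Oracle-equivalence checks run the vectorised contact
operators against naive nested-loop references on 100+ random
sub-50-atom-per-chain systems.

## Known limitations

* Contact counts on synthetic geometry are magnitude references only;
  absolute counts from real MD ensembles depend on details (hydrogen
  placement, rotamers) the pseudo-atom model does not carry.
* The idealised-hydrogen H-bond path reduces to a distance criterion;
  with explicit hydrogens the full angular test applies.
* `"pc1"` RMSF filtering is covariance PCA, not Hessian normal-mode
  analysis.
* GROMACS binary formats (XTC/TRR) are out of contract; convert to
  multi-model PDB or the frame-CSV dialect first.
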